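format-version: 1.2
ontology: mini-cell

[Term]
id: MC_0000001
name: cell

[Term]
id: MC_0000002
name: native cell
is_a: MC_0000001 ! cell

[Term]
id: MC_0000003
name: germ cell
synonym: "gamete precursor cell" EXACT []
is_a: MC_0000002 ! native cell

[Term]
id: MC_0000004
name: oocyte
synonym: "egg cell" EXACT []
is_a: MC_0000003 ! germ cell

[Term]
id: MC_0000005
name: spermatocyte
is_a: MC_0000003 ! germ cell

[Term]
id: MC_0000006
name: smooth muscle cell
synonym: "SMC" RELATED []
is_a: MC_0000002 ! native cell

[Term]
id: MC_0000007
name: natural killer cell
synonym: "NK cell" EXACT []
is_a: MC_0000002 ! native cell

[Term]
id: MC_0000008
name: hippocampal neuron
synonym: "hippocampal neurons" RELATED []
is_a: MC_0000002 ! native cell

[Term]
id: MC_0000009
name: P1
is_a: MC_0000001 ! cell

[Term]
id: MC_0000010
name: retired cell
is_obsolete: true
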