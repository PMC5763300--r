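# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in coverage
#' reports use conventional half-up rounding instead (58.58 -> 59).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(58.58, 0) # 59
#' round_half_up(0.5, 0)   # 1, where round(0.5) is 0
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Collapse internal whitespace runs to single spaces and trim ends.
normalize_ws <- function(x) {
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

# Lexicon key: whitespace-collapsed, case-folded. Original casing is kept
# separately for display and for case-sensitive matching.
surface_key <- function(x) {
  stringi::stri_trans_tolower(normalize_ws(x))
}

is_digit_only <- function(x) {
  # no letter anywhere, at least one digit: "548", "2-2", "2 2"
  stringi::stri_detect_regex(x, "^[^\\p{L}]*$") &
    stringi::stri_detect_regex(x, "\\p{Nd}")
}

# 0-based half-open span -> substring
span_text <- function(text, start, end) {
  stringi::stri_sub(text, start + 1L, end)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
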