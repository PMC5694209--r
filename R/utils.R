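#' Round half-up
#'
#' Conventional rounding where exact halves round away from zero (towards
#' +Inf for positive input), as used for all printed percentages. Base
#' [round()] uses round-half-to-even, which disagrees on values such as
#' `round(0.5)`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(29.6875, 0) # 30
#' round_half_up(21.15, 1)   # 21.2
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a non-empty string.", what))
  }
  invisible(x)
}

# Validate an amino-acid sequence string; returns the upper-cased sequence.
# B/Z/U/J/O and '*' are rejected; X is allowed (scored neutral downstream).
check_aa_seq <- function(seq, id = "<sequence>") {
  assert_scalar_chr(seq, "seq")
  seq <- toupper(seq)
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% the_amino_acids)
  if (length(bad) > 0) {
    abort(sprintf(
      "Record '%s': disallowed residue letter '%s' at position %d.",
      id, letters[bad[1]], bad[1]
    ))
  }
  seq
}

seq_len_chr <- function(seq) nchar(seq)

# tibble of spans with zero rows, used wherever a prediction has no TM span
empty_spans <- function() {
  tibble(start = integer(), end = integer(), certainty = character())
}
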