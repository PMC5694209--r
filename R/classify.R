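#' Terminal-zone parameters for TM-span location classification
#'
#' The N-terminal zone is the first `n_frac` of the sequence, the C-terminal
#' zone the last `c_frac`; everything between is central. Defaults split the
#' protein into thirds.
#'
#' @param n_frac fraction of the length forming the N-terminal zone.
#' @param c_frac fraction forming the C-terminal zone.
#' @return list of class `classify_params`.
#' @export
classify_params <- function(n_frac = 1 / 3, c_frac = 1 / 3) {
  stopifnot(n_frac > 0, n_frac < 1, c_frac > 0, c_frac < 1,
            n_frac + c_frac <= 1)
  structure(list(n_frac = n_frac, c_frac = c_frac), class = "classify_params")
}

#' Classify a TM span as N-terminal, central or C-terminal
#'
#' Uses the span midpoint `m = (start + end) / 2`:
#' `m <= n_frac * length` is N-terminal (`"N"`), `m > (1 - c_frac) * length`
#' is C-terminal (`"C"`), anything else central (`"M"`). Boundary ties
#' resolve toward the terminal classes (`<=` for N, `>` for C).
#'
#' @param start,end span coordinates (vectors allowed).
#' @param length protein length(s).
#' @param params [classify_params()].
#' @return character vector over `{"N", "M", "C"}`.
#' @export
classify_span_location <- function(start, end, length, params = classify_params()) {
  if (any(start < 1 | end > length | start > end)) {
    abort("Span out of range for its protein length.")
  }
  m <- (start + end) / 2
  dplyr::case_when(
    m <= params$n_frac * length ~ "N",
    m > (1 - params$c_frac) * length ~ "C",
    TRUE ~ "M"
  )
}

#' Location pattern code of an MTF
#'
#' Concatenation of per-span class letters in N-to-C order, e.g. `"N"`,
#' `"C"`, `"M"`, `"NC"`, `"NN"`, `"MMM"`. This is the `location_pattern`
#' recorded on MTF calls.
#'
#' @param spans span tibble with at least one row.
#' @param length protein length.
#' @param params [classify_params()].
#' @return pattern string.
#' @export
pattern_code <- function(spans, length, params = classify_params()) {
  spans <- check_spans(spans, length)
  if (nrow(spans) == 0) abort("Cannot compute a location pattern without spans.")
  paste(classify_span_location(spans$start, spans$end, length, params),
        collapse = "")
}

#' Attach location patterns to an MTF table
#'
#' @param mtfs MTF tibble from [merge_branches()].
#' @param params [classify_params()].
#' @return `mtfs` with a `location_pattern` column.
#' @export
classify_mtfs <- function(mtfs, params = classify_params()) {
  if (nrow(mtfs) == 0) return(mutate(mtfs, location_pattern = character()))
  mutate(mtfs, location_pattern = map2_chr(
    .data$spans, .data$length,
    function(s, l) pattern_code(s, l, params)
  ))
}

#' @importFrom purrr map2_chr
NULL
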