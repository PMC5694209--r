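#' Convert a per-residue topology string to TM spans
#'
#' A topology string is a sequence over `{i, M, o}` (inside loop, membrane,
#' outside loop). Spans are the maximal runs of `M`, reported as 1-based
#' inclusive residue intervals.
#'
#' @param states topology string over `{i, M, o}`.
#' @param certainty certainty label attached to every span
#'   (`"certain"` or `"putative"`).
#' @return tibble with columns `start`, `end`, `certainty`.
#' @examples
#' states_to_spans("iiiMMMMMoo")
#' @export
states_to_spans <- function(states, certainty = "certain") {
  assert_scalar_chr(states, "states")
  letters <- strsplit(states, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% c("i", "M", "o"))
  if (length(bad) > 0) {
    abort(sprintf(
      "Illegal topology character '%s' at position %d.", letters[bad[1]], bad[1]
    ))
  }
  r <- rle(letters == "M")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty_spans())
  tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    certainty = certainty
  )
}

#' Convert TM spans to a per-residue topology string
#'
#' Loops alternate between inside (`i`) and outside (`o`) starting from
#' `first_loop` at the N terminus; membrane positions are `M`.
#'
#' @param spans tibble with `start`, `end` (1-based inclusive), sorted and
#'   non-overlapping.
#' @param length protein length in residues.
#' @param first_loop state of the N-terminal loop, `"i"` or `"o"`.
#' @return topology string of length `length`.
#' @examples
#' spans_to_states(tibble::tibble(start = 4, end = 8), 10, "i")
#' @export
spans_to_states <- function(spans, length, first_loop = "i") {
  stopifnot(length >= 1, first_loop %in% c("i", "o"))
  spans <- check_spans(spans, length)
  out <- character(length)
  loop_state <- first_loop
  pos <- 1L
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]
    if (s > pos) out[pos:(s - 1L)] <- loop_state
    out[s:e] <- "M"
    loop_state <- if (loop_state == "i") "o" else "i"
    pos <- e + 1L
  }
  if (pos <= length) out[pos:length] <- loop_state
  paste(out, collapse = "")
}

# Validate a span tibble against a protein length; returns it sorted.
check_spans <- function(spans, length = NULL) {
  if (is.null(spans) || nrow(spans) == 0) return(empty_spans())
  spans <- as_tibble(spans)
  if (!all(c("start", "end") %in% names(spans))) {
    abort("Spans need `start` and `end` columns.")
  }
  if (!"certainty" %in% names(spans)) spans$certainty <- "certain"
  spans <- arrange(spans, .data$start)
  if (any(spans$start > spans$end) || any(spans$start < 1)) {
    abort("Invalid span: need 1 <= start <= end.")
  }
  if (!is.null(length) && any(spans$end > length)) {
    abort(sprintf("Span out of range: end %d > protein length %d.",
                  max(spans$end), length))
  }
  if (nrow(spans) > 1) {
    gap <- spans$start[-1] - spans$end[-nrow(spans)]
    if (any(gap < 2)) {
      abort("Spans must be non-overlapping and separated by >= 1 residue.")
    }
  }
  spans[c("start", "end", "certainty")]
}

# Do the non-M loop labels alternate i/o along the string?
loops_alternate <- function(states) {
  letters <- strsplit(states, "", fixed = TRUE)[[1]]
  r <- rle(letters)
  loops <- r$values[r$values != "M"]
  if (length(loops) <= 1) return(TRUE)
  all(loops[-1] != loops[-length(loops)])
}

# State of the N-terminal loop; a string starting with M falls back to the
# first loop after the span, or "i" for an all-M string.
first_loop_state <- function(states) {
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  loop <- ch[ch != "M"]
  if (length(loop) == 0) "i" else loop[1]
}

#' Build a one-row topology prediction tibble
#'
#' The common currency of the package: one row per (protein, predictor) with
#' the per-residue `states` string and a `spans` list-column. Either `states`
#' or `spans` (+ `length`) may be given; the other is derived, keeping the
#' spans-are-maximal-M-runs invariant true by construction.
#'
#' @param protein_id protein identifier.
#' @param predictor predictor name (e.g. `"hydro-builtin"`, `"TMHMM"`,
#'   `"generic"`).
#' @param states topology string over `{i, M, o}`; derived from `spans` when
#'   absent.
#' @param spans span tibble (`start`, `end`, optional `certainty`); derived
#'   from `states` when absent.
#' @param length protein length; required when only `spans` are given.
#' @param first_loop N-terminal loop state used when building `states` from
#'   `spans`.
#' @param span_conf optional numeric vector in `[0, 1]`, one value per span.
#' @return one-row tibble with columns `protein_id`, `predictor`, `length`,
#'   `states`, `n_tm`, `valid`, `spans` (list), `span_conf` (list).
#' @export
new_topology <- function(protein_id, predictor, states = NULL, spans = NULL,
                         length = NULL, first_loop = "i", span_conf = NULL) {
  assert_scalar_chr(protein_id, "protein_id")
  assert_scalar_chr(predictor, "predictor")
  if (is.null(states)) {
    if (is.null(length)) abort("`length` is required when `states` is absent.")
    spans <- check_spans(spans, length)
    states <- spans_to_states(spans, length, first_loop)
  } else {
    if (!is.null(length) && nchar(states) != length) {
      abort(sprintf("`states` has length %d but `length` is %d.",
                    nchar(states), length))
    }
    length <- nchar(states)
    derived <- states_to_spans(states)
    if (is.null(spans)) {
      spans <- derived
    } else {
      spans <- check_spans(spans, length)
      if (!identical(derived[c("start", "end")], spans[c("start", "end")])) {
        abort("`spans` disagree with the maximal M-runs of `states`.")
      }
    }
  }
  if (!is.null(span_conf)) {
    if (length(span_conf) != nrow(spans)) {
      abort("`span_conf` must have one value per span.")
    }
    if (any(span_conf < 0 | span_conf > 1)) {
      abort("`span_conf` values must lie in [0, 1].")
    }
  }
  tibble(
    protein_id = protein_id,
    predictor = predictor,
    length = as.integer(length),
    states = states,
    n_tm = nrow(spans),
    valid = loops_alternate(states),
    spans = list(spans),
    span_conf = list(span_conf)
  )
}

#' Unnest the spans of a topology or MTF tibble
#'
#' @param x tibble with a `spans` list-column (topology predictions or MTF
#'   calls).
#' @return tibble with one row per span.
#' @export
topology_spans <- function(x) {
  stopifnot("spans" %in% names(x))
  keep <- intersect(c("protein_id", "id", "predictor"), names(x))
  tidyr::unnest(x[c(keep, "spans")], "spans")
}
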