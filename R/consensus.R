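#' Do two topology predictions agree?
#'
#' Agreement requires the same protein length, the same number of TM spans,
#' pairwise overlap of at least `min_overlap` residues between corresponding
#' spans, and the same N-terminal loop orientation. Reflexive and symmetric
#' by construction.
#'
#' @param a,b one-row topology tibbles (or single rows of a topology tibble).
#' @param min_overlap minimum residue overlap between the k-th spans.
#' @return logical.
#' @export
topologies_agree <- function(a, b, min_overlap = 5) {
  a <- as_topology_row(a); b <- as_topology_row(b)
  if (a$length != b$length) {
    abort(sprintf("Cannot compare predictions of different lengths (%d vs %d).",
                  a$length, b$length))
  }
  if (a$n_tm != b$n_tm) return(FALSE)
  if (first_loop_state(a$states) != first_loop_state(b$states)) return(FALSE)
  if (a$n_tm == 0) return(TRUE)
  sa <- a$spans[[1]]; sb <- b$spans[[1]]
  ov <- pmin(sa$end, sb$end) - pmax(sa$start, sb$start) + 1L
  all(ov >= min_overlap)
}

as_topology_row <- function(x) {
  x <- as_tibble(x)
  stopifnot(nrow(x) == 1, all(c("length", "states", "n_tm", "spans") %in% names(x)))
  x
}

#' Consensus topology over several predictors
#'
#' Greedy agreement clustering for one protein: predictions are visited in
#' priority order, each joining the first existing class whose founding
#' representative it agrees with (else founding a new class). The winner is
#' the representative of the largest class; ties go to the class founded
#' first, i.e. whose representative ranks highest in the priority order. A
#' winning 0-span topology means a "soluble" consensus.
#'
#' @param preds topology tibble, all rows for the same protein.
#' @param priority character vector of predictor names, highest priority
#'   first; predictors absent from it keep their input order afterwards.
#' @param min_overlap passed to [topologies_agree()].
#' @return one-row tibble: `protein_id`, `support`, `n_classes`,
#'   `winner_predictor`, `length`, `states`, `n_tm`, `spans` (list),
#'   `classes` (list: predictor -> class index).
#' @export
consensus_topology <- function(preds, priority = NULL, min_overlap = 5) {
  preds <- as_tibble(preds)
  if (nrow(preds) == 0) abort("Consensus needs at least one prediction.")
  if (length(unique(preds$protein_id)) != 1) {
    abort("`consensus_topology()` takes predictions for one protein; use `consensus_all()` for a whole table.")
  }
  ord <- priority_order(preds$predictor, priority)
  preds <- preds[ord, ]
  class_of <- integer(nrow(preds))
  reps <- integer(0)  # row index of each class representative
  for (k in seq_len(nrow(preds))) {
    joined <- FALSE
    for (c in seq_along(reps)) {
      if (topologies_agree(preds[k, ], preds[reps[c], ], min_overlap)) {
        class_of[k] <- c
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, k)
      class_of[k] <- length(reps)
    }
  }
  sizes <- tabulate(class_of, nbins = length(reps))
  win <- which.max(sizes)  # first maximum = earliest-founded class
  w <- preds[reps[win], ]
  tibble(
    protein_id = w$protein_id,
    support = as.integer(sizes[win]),
    n_classes = length(reps),
    winner_predictor = w$predictor,
    length = w$length,
    states = w$states,
    n_tm = w$n_tm,
    spans = w$spans,
    classes = list(stats::setNames(class_of, preds$predictor))
  )
}

priority_order <- function(predictors, priority) {
  if (is.null(priority)) return(seq_along(predictors))
  rank <- match(predictors, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  order(rank)
}

#' Consensus for every protein of a topology table
#'
#' @param preds topology tibble covering one or more proteins.
#' @inheritParams consensus_topology
#' @return tibble with one consensus row per protein (see
#'   [consensus_topology()]).
#' @export
consensus_all <- function(preds, priority = NULL, min_overlap = 5) {
  bind_rows(map(split(preds, preds$protein_id), consensus_topology,
                priority = priority, min_overlap = min_overlap))
}

#' Filter TMHMM spans by posterior probability
#'
#' Keeps only spans whose membrane-state posterior statistic over the span
#' is strictly greater than `threshold` (the high-confidence rule "included
#' if probability score greater than 0.90"). States are rebuilt from the
#' surviving spans, preserving the original N-terminal loop orientation.
#'
#' @param pred one-row topology tibble with predictor `"TMHMM"`.
#' @param track posterior track: numeric vector or tibble from
#'   [parse_posterior_track()]. `NULL` keeps all spans, with a warning.
#' @param threshold posterior cutoff (strict inequality).
#' @param statistic `"mean"` (default) or `"min"` posterior over the span.
#' @return one-row topology tibble with the surviving spans; `span_conf`
#'   holds the computed statistic per surviving span.
#' @export
filter_tmhmm <- function(pred, track, threshold = 0.90,
                         statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  pred <- as_topology_row(pred)
  if (is.null(track)) {
    warn(sprintf("No posterior track for '%s'; TMHMM spans accepted unfiltered.",
                 pred$protein_id))
    return(pred)
  }
  p <- if (is.data.frame(track)) track$p_membrane else as.numeric(track)
  if (length(p) != pred$length) {
    abort(sprintf("Posterior track length %d does not match protein length %d.",
                  length(p), pred$length))
  }
  spans <- pred$spans[[1]]
  stat_fun <- if (statistic == "mean") mean else min
  conf <- map_dbl(seq_len(nrow(spans)), function(k) {
    stat_fun(p[spans$start[k]:spans$end[k]])
  })
  keep <- conf > threshold
  new_topology(pred$protein_id, pred$predictor,
               spans = spans[keep, ], length = pred$length,
               first_loop = first_loop_state(pred$states),
               span_conf = conf[keep])
}

#' Merge the consensus and TMHMM branches into the final MTF set
#'
#' A protein is called an MTF iff its consensus winner has at least one TM
#' span OR its (posterior-filtered) TMHMM prediction has at least one span
#' (union of the two branches). Spans come from the consensus winner when it
#' called membrane, otherwise from TMHMM; `provenance` records which
#' branch(es) fired.
#'
#' @param consensus consensus tibble from [consensus_all()] (or NULL).
#' @param tmhmm topology tibble of filtered TMHMM predictions (or NULL).
#' @param proteins optional protein tibble; when given, `locus`, `species`,
#'   `family` and `seq` are attached by id.
#' @return MTF tibble: `id`, `n_tm`, `spans` (list), `states`, `length`,
#'   `support`, `provenance`, plus annotation columns when available.
#' @export
merge_branches <- function(consensus, tmhmm, proteins = NULL) {
  cons_calls <- if (!is.null(consensus) && nrow(consensus) > 0) {
    filter(consensus, .data$n_tm >= 1)
  } else {
    NULL
  }
  tm_calls <- if (!is.null(tmhmm) && nrow(tmhmm) > 0) {
    filter(tmhmm, .data$n_tm >= 1)
  } else {
    NULL
  }
  ids <- union(
    if (is.null(cons_calls)) character() else cons_calls$protein_id,
    if (is.null(tm_calls)) character() else tm_calls$protein_id
  )
  rows <- map(ids, function(id) {
    from_cons <- !is.null(cons_calls) && id %in% cons_calls$protein_id
    from_tm <- !is.null(tm_calls) && id %in% tm_calls$protein_id
    src <- if (from_cons) {
      cons_calls[cons_calls$protein_id == id, ]
    } else {
      tm_calls[tm_calls$protein_id == id, ]
    }
    tibble(
      id = id,
      n_tm = src$n_tm,
      spans = src$spans,
      states = src$states,
      length = src$length,
      support = if (from_cons) src$support else NA_integer_,
      provenance = paste(c(if (from_cons) "consensus", if (from_tm) "tmhmm"),
                         collapse = "+")
    )
  })
  out <- if (length(rows) == 0) {
    tibble(
      id = character(), n_tm = integer(), spans = list(), states = character(),
      length = integer(), support = integer(), provenance = character()
    )
  } else {
    bind_rows(rows)
  }
  if (!is.null(proteins)) {
    out <- left_join(
      out,
      proteins[intersect(c("id", "locus", "species", "family", "seq"), names(proteins))],
      by = "id"
    )
  }
  arrange(out, .data$id)
}
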