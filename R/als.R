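#' Global pairwise alignment with affine gap scoring
#'
#' Needleman-Wunsch-style global alignment of two protein sequences under a
#' match/mismatch substitution scheme and affine gaps: a gap of length L
#' scores `gap_open + L * gap_extend`. Backed by
#' [Biostrings::pairwiseAlignment()]; co-optimal alignments resolve by its
#' deterministic traceback.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gap_open gap opening score (negative).
#' @param gap_extend per-residue gap extension score (negative).
#' @return list of class `aa_alignment` with elements `a` and `b` (gapped
#'   aligned strings of equal length) and `score`.
#' @examples
#' align_global("MKT", "MT")
#' @export
align_global <- function(a, b, match = 2, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  a <- check_aa_seq(a, "a"); b <- check_aa_seq(b, "b")
  mat <- matrix(mismatch, length(the_amino_acids), length(the_amino_acids),
                dimnames = list(the_amino_acids, the_amino_acids))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, type = "global",
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  structure(
    list(
      a = as.character(Biostrings::alignedPattern(aln)),
      b = as.character(Biostrings::alignedSubject(aln)),
      score = Biostrings::score(aln)
    ),
    class = "aa_alignment"
  )
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", x$a, "\n", x$b, "\n", sep = "")
  invisible(x)
}

#' Fraction of a domain retained identically in an aligned variant
#'
#' For a domain interval on the first (reference) sequence of an alignment,
#' the fraction of domain positions aligned to an identical residue in the
#' second sequence. Gaps and mismatches both count as uncovered.
#'
#' @param alignment an `aa_alignment` from [align_global()].
#' @param start,end 1-based inclusive domain interval on the reference.
#' @return coverage fraction in `[0, 1]`.
#' @export
domain_coverage <- function(alignment, start, end) {
  a <- strsplit(alignment$a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$b, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(a != "-")
  ref_len <- ref_pos[length(ref_pos)]
  if (start < 1 || end > ref_len || start > end) {
    abort(sprintf("Domain %d-%d outside reference length %d.", start, end, ref_len))
  }
  in_dom <- a != "-" & ref_pos >= start & ref_pos <= end
  sum(a[in_dom] == b[in_dom]) / (end - start + 1)
}

#' Screen the isoforms of one locus for splicing-based MTF activation
#'
#' A variant isoform qualifies when (a) the built-in hydrophobicity
#' predictor finds no TM span on it, and (b) at least `coverage_min` of the
#' reference's transcription-factor domain aligns identically in the
#' variant. The locus is flagged when any variant qualifies: such a locus
#' can produce a constitutively nuclear isoform by alternative splicing.
#'
#' @param iso isoform set: a list with `locus`, `reference` (list/row with
#'   `id`, `seq`), `variants` (tibble with `id`, `seq`), and `domain`
#'   (`c(start, end)` on the reference).
#' @param hydro [hydro_params()] used to call TM spans.
#' @param coverage_min minimum retained-domain fraction.
#' @param ... further arguments for [align_global()].
#' @return one-row tibble: `locus`, `n_variants`, `qualifying` (list of
#'   variant ids), `flagged`.
#' @export
screen_isoforms <- function(iso, hydro = hydro_params(), coverage_min = 0.9, ...) {
  stopifnot(all(c("locus", "reference", "variants", "domain") %in% names(iso)))
  ref <- as_tibble(iso$reference)
  ref_pred <- predict_topology_hydro(ref, hydro)
  if (ref_pred$n_tm == 0) {
    abort(sprintf("Locus '%s': reference isoform has no predicted TM span.",
                  iso$locus))
  }
  dom <- iso$domain
  variants <- as_tibble(iso$variants)
  qualifying <- character(0)
  if (nrow(variants) > 0) {
    var_pred <- predict_topology_hydro(variants, hydro)
    for (k in seq_len(nrow(variants))) {
      if (var_pred$n_tm[k] != 0) next
      aln <- align_global(ref$seq, variants$seq[k], ...)
      if (domain_coverage(aln, dom[1], dom[2]) >= coverage_min) {
        qualifying <- c(qualifying, variants$id[k])
      }
    }
  }
  any_qualify <- length(qualifying) > 0
  tibble(
    locus = iso$locus,
    n_variants = nrow(variants),
    qualifying = list(qualifying),
    flagged = any_qualify
  )
}

#' Screen all loci of an isoform table
#'
#' Groups an isoform protein tibble by locus, picks as reference the isoform
#' with predicted TM spans (the longest such isoform when several have
#' spans), and screens the remaining isoforms as variants. Loci whose
#' isoforms carry no TM span at all are skipped (they are not MTF loci).
#'
#' @param isoforms tibble with `id`, `locus`, `seq`.
#' @param domains domain tibble (`protein_id`, `start`, `end`) giving the
#'   TF-domain interval on each reference isoform.
#' @param hydro,coverage_min,... see [screen_isoforms()].
#' @return AlsCall tibble, one row per screened locus.
#' @export
screen_als <- function(isoforms, domains, hydro = hydro_params(),
                       coverage_min = 0.9, ...) {
  stopifnot(all(c("id", "locus", "seq") %in% names(isoforms)))
  preds <- predict_topology_hydro(isoforms, hydro)
  isoforms <- mutate(isoforms,
                     n_tm = preds$n_tm[match(.data$id, preds$protein_id)],
                     length = nchar(.data$seq))
  calls <- map(split(isoforms, isoforms$locus), function(grp) {
    with_tm <- filter(grp, .data$n_tm >= 1)
    if (nrow(with_tm) == 0) return(NULL)
    ref <- with_tm[order(-with_tm$length, with_tm$id), ][1, ]
    dom <- domains[domains$protein_id == ref$id, ]
    if (nrow(dom) == 0) {
      warn(sprintf("Locus '%s': no domain interval for reference '%s'; skipped.",
                   grp$locus[1], ref$id))
      return(NULL)
    }
    screen_isoforms(
      list(
        locus = grp$locus[1],
        reference = ref[c("id", "seq")],
        variants = grp[grp$id != ref$id, c("id", "seq")],
        domain = c(dom$start[1], dom$end[1])
      ),
      hydro = hydro, coverage_min = coverage_min, ...
    )
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    return(tibble(locus = character(), n_variants = integer(),
                  qualifying = list(), flagged = logical()))
  }
  arrange(out, .data$locus)
}

#' ALS-activatable fraction of MTF loci
#'
#' @param calls AlsCall tibble from [screen_als()], or a flagged count.
#' @param total total locus count (required when `calls` is a count).
#' @return tibble with `flagged`, `total`, `percent` (half-up, 0 decimals).
#' @examples
#' als_fraction(19, 64)  # 30 percent
#' @export
als_fraction <- function(calls, total = NULL) {
  if (is.data.frame(calls)) {
    flagged <- sum(calls$flagged)
    total <- nrow(calls)
  } else {
    flagged <- calls
    if (is.null(total)) abort("`total` is required when `calls` is a count.")
  }
  if (total < 1) abort("ALS fraction needs at least one locus.")
  tibble(
    flagged = as.integer(flagged),
    total = as.integer(total),
    percent = round_half_up(100 * flagged / total, 0)
  )
}
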