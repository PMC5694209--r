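#' Load a bundled hydropathy scale
#'
#' Scales ship as plain-text two-column tables (residue, value). `"GES"` is
#' the Goldman-Engelman-Steitz transfer free-energy scale (kcal/mol,
#' hydrophobic positive), the convention the default cutoffs are expressed
#' in; `"KD"` is the Kyte-Doolittle index. The unknown residue X scores 0 on
#' both.
#'
#' @param name scale name (`"GES"` or `"KD"`), or a path to a two-column TSV.
#' @return named numeric vector, residue -> hydropathy value.
#' @export
hydro_scale <- function(name = "GES") {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "scales", paste0(name, ".tsv"),
                package = "mtfscan", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("Unknown hydropathy scale '%s'.", name))
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "value"))
  stats::setNames(tab$value, tab$residue)
}

#' Parameters of the hydrophobicity-profile TM predictor
#'
#' Defaults follow the classical hydrophobicity-profile parameterization:
#' GES scale, trapezoid window of 21 residues (11-residue core flanked by
#' 5-residue wedges), upper/lower cutoffs 1.0/0.6 in GES units.
#'
#' @param scale scale name or path, see [hydro_scale()].
#' @param core_len odd core window length (weight 1 across the core).
#' @param wedge_len wedge length on each side; wedge weights decay linearly
#'   to `1/(wedge_len + 1)`.
#' @param upper_cutoff profile peak at or above this makes a span "certain".
#' @param lower_cutoff profile threshold defining candidate segments.
#' @param min_helix_len minimum segment length (residues) kept as a TM span.
#' @param min_loop_len segments separated by a gap shorter than this are
#'   merged before the length test.
#' @param loop_charge_window residues adjacent to each span counted per loop
#'   by the positive-inside orientation rule.
#' @return list of class `hydro_params`.
#' @export
hydro_params <- function(scale = "GES", core_len = 11, wedge_len = 5,
                         upper_cutoff = 1.0, lower_cutoff = 0.6,
                         min_helix_len = 17, min_loop_len = 2,
                         loop_charge_window = 15) {
  stopifnot(
    core_len >= 1, core_len %% 2 == 1, wedge_len >= 0,
    lower_cutoff <= upper_cutoff, min_helix_len >= 1, min_loop_len >= 1,
    loop_charge_window >= 1
  )
  structure(
    list(
      scale = scale, core_len = as.integer(core_len),
      wedge_len = as.integer(wedge_len), upper_cutoff = upper_cutoff,
      lower_cutoff = lower_cutoff, min_helix_len = as.integer(min_helix_len),
      min_loop_len = as.integer(min_loop_len),
      loop_charge_window = as.integer(loop_charge_window)
    ),
    class = "hydro_params"
  )
}

# Trapezoid window weights: 1.0 across the core, decaying linearly to
# 1/(wedge_len+1) across each wedge. Symmetric, odd total length.
trapezoid_weights <- function(core_len, wedge_len) {
  if (wedge_len == 0) return(rep(1, core_len))
  wedge <- (wedge_len:1) / (wedge_len + 1)
  c(rev(wedge), rep(1, core_len), wedge)
}

#' Windowed hydropathy profile of a protein sequence
#'
#' The value at position p is the trapezoid-weighted mean of the scale values
#' in the window centred at p. Windows truncated at the sequence ends are
#' renormalized by the weights actually applied, so short sequences are still
#' scored (a single residue scores its own scale value).
#'
#' @param seq amino-acid sequence (string).
#' @param params [hydro_params()].
#' @return numeric vector, one value per residue.
#' @examples
#' hydropathy_profile("MKT", hydro_params(scale = "KD"))
#' @export
hydropathy_profile <- function(seq, params = hydro_params()) {
  seq <- check_aa_seq(seq)
  scale <- if (is.numeric(params$scale)) params$scale else hydro_scale(params$scale)
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  vals <- unname(scale[letters])
  if (anyNA(vals)) {
    miss <- letters[which(is.na(vals))[1]]
    abort(sprintf("Residue '%s' is missing from the hydropathy scale.", miss))
  }
  w <- trapezoid_weights(params$core_len, params$wedge_len)
  half <- (length(w) - 1L) %/% 2L
  n <- length(vals)
  pad <- rep(0, half)
  num <- stats::filter(c(pad, vals, pad), w, sides = 2)
  den <- stats::filter(c(pad, rep(1, n), pad), w, sides = 2)
  idx <- (half + 1L):(half + n)
  as.numeric(num[idx] / den[idx])
}

#' Call candidate TM segments on a hydropathy profile
#'
#' Candidate segments are the maximal runs of profile values at or above
#' `lower_cutoff`. Runs separated by a gap shorter than `min_loop_len` are
#' merged, then segments shorter than `min_helix_len` are dropped. A kept
#' segment is `"certain"` when its peak reaches `upper_cutoff`, otherwise
#' `"putative"`.
#'
#' @param profile numeric profile from [hydropathy_profile()].
#' @param params [hydro_params()].
#' @return span tibble (`start`, `end`, `certainty`), possibly empty.
#' @export
find_tm_segments <- function(profile, params = hydro_params()) {
  stopifnot(is.numeric(profile), length(profile) >= 1)
  above <- profile >= params$lower_cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty_spans())
  # merge runs whose gap is shorter than min_loop_len
  merged <- runs[1, ]
  for (k in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
    if (gap < params$min_loop_len) {
      merged$end[nrow(merged)] <- runs$end[k]
    } else {
      merged <- bind_rows(merged, runs[k, ])
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= params$min_helix_len, ]
  if (nrow(merged) == 0) return(empty_spans())
  merged$certainty <- map_chr(seq_len(nrow(merged)), function(k) {
    if (max(profile[merged$start[k]:merged$end[k]]) >= params$upper_cutoff) {
      "certain"
    } else {
      "putative"
    }
  })
  mutate(merged, start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Orient a topology by the positive-inside rule
#'
#' Of the two alternating loop labellings (N-terminal loop inside vs
#' outside), returns the per-residue topology string whose inside loops
#' contain more lysine/arginine residues. Only up to `loop_charge_window`
#' residues adjacent to each membrane span are counted per loop. Ties (and
#' span-free proteins) default to first-loop-inside.
#'
#' @param seq amino-acid sequence.
#' @param spans span tibble, sorted and non-overlapping.
#' @param loop_charge_window residues counted next to each span per loop.
#' @return topology string over `{i, M, o}`.
#' @export
orient_topology <- function(seq, spans, loop_charge_window = 15) {
  seq <- check_aa_seq(seq)
  n <- nchar(seq)
  spans <- check_spans(spans, n)
  if (nrow(spans) == 0) return(strrep("i", n))
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  kr <- letters %in% c("K", "R")

  bounds <- rbind(
    c(1L, spans$start[1] - 1L),
    if (nrow(spans) > 1) {
      cbind(spans$end[-nrow(spans)] + 1L, spans$start[-1] - 1L)
    },
    c(spans$end[nrow(spans)] + 1L, n)
  )
  loop_charge <- map_dbl(seq_len(nrow(bounds)), function(l) {
    s <- bounds[l, 1]; e <- bounds[l, 2]
    if (s > e) return(0)
    counted <- integer(0)
    # side adjacent to the preceding span (all loops but the first)
    if (l > 1) counted <- c(counted, s:min(e, s + loop_charge_window - 1L))
    # side adjacent to the following span (all loops but the last)
    if (l < nrow(bounds)) counted <- c(counted, max(s, e - loop_charge_window + 1L):e)
    sum(kr[unique(counted)])
  })
  odd <- seq_along(loop_charge) %% 2 == 1
  inside_first <- sum(loop_charge[odd])
  outside_first <- sum(loop_charge[!odd])
  first_loop <- if (inside_first >= outside_first) "i" else "o"
  spans_to_states(spans, n, first_loop)
}

#' Predict TM topology with the built-in hydrophobicity-profile method
#'
#' Composition of [hydropathy_profile()], [find_tm_segments()] and
#' [orient_topology()], applied to every row of a protein tibble.
#'
#' @param proteins tibble with at least `id` and `seq` columns (see
#'   [read_tf_fasta()]); a single named list/one-row tibble also works.
#' @param params [hydro_params()].
#' @return topology tibble (see [new_topology()]), predictor
#'   `"hydro-builtin"`, one row per protein.
#' @export
predict_topology_hydro <- function(proteins, params = hydro_params()) {
  proteins <- as_tibble(proteins)
  stopifnot(all(c("id", "seq") %in% names(proteins)))
  scale <- if (is.numeric(params$scale)) params$scale else hydro_scale(params$scale)
  params$scale <- scale  # resolve once for the whole table
  rows <- map(seq_len(nrow(proteins)), function(k) {
    seq <- proteins$seq[k]
    prof <- hydropathy_profile(seq, params)
    spans <- find_tm_segments(prof, params)
    states <- orient_topology(seq, spans, params$loop_charge_window)
    new_topology(proteins$id[k], "hydro-builtin",
                 states = states, spans = spans)
  })
  bind_rows(rows)
}
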