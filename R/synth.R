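# Residue sampling frequencies for the synthetic generator.
#
# Planted TM blocks favour Leu/Ile/Phe/Met (mean GES hydropathy ~ +3.0,
# typical of single-pass helices); the soluble background emulates the
# Ser/Thr/Gly/Pro-rich disordered regions common in transcription factors,
# with a sprinkling of charged residues (mean GES ~ -0.67, below the 0.6
# lower cutoff as required of the background).
block_freqs <- c(L = 0.28, I = 0.24, V = 0.14, F = 0.16, A = 0.04, M = 0.14)
background_freqs <- c(
  S = 0.26, T = 0.17, N = 0.05, Q = 0.05, D = 0.01,
  E = 0.02, K = 0.03, R = 0.02, G = 0.22, P = 0.17
)
# The few residues flanking a planted block come from a cooler subpool, so
# the hydropathy run a block produces ends close to the block edge on both
# sides and the called span midpoint stays centred on the plant.
shoulder_freqs <- c(N = 0.25, Q = 0.25, S = 0.25, T = 0.25)
shoulder_width <- 12L

sample_residues <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Resample background windows until no profile position outside the
# influence zone of a planted block reaches the lower cutoff. This makes
# "zero spurious spans" true by construction rather than statistically.
clean_background <- function(letters, blocks, params, protect = integer(0),
                             max_iter = 60) {
  n <- length(letters)
  half <- (params$core_len - 1L) %/% 2L + params$wedge_len
  in_block <- rep(FALSE, n)
  for (k in seq_len(nrow(blocks))) in_block[blocks$start[k]:blocks$end[k]] <- TRUE
  near_block <- rep(FALSE, n)
  if (any(in_block)) {
    idx <- which(in_block)
    lo <- pmax(1L, idx - half); hi <- pmin(n, idx + half)
    for (k in seq_along(idx)) near_block[lo[k]:hi[k]] <- TRUE
  }
  pool <- background_freqs
  for (iter in seq_len(max_iter)) {
    prof <- hydropathy_profile(paste(letters, collapse = ""), params)
    bad <- which(prof >= params$lower_cutoff & !near_block)
    if (length(bad) == 0) return(letters)
    if (iter > max_iter / 2) {
      # stubborn windows: draw from the strongly hydrophilic residues only
      pool <- background_freqs[c("N", "Q", "D", "E", "K", "R")]
    }
    resample <- unique(unlist(map(bad, function(p) {
      max(1L, p - half):min(n, p + half)
    })))
    resample <- setdiff(resample[!in_block[resample]], protect)
    letters[resample] <- sample_residues(length(resample), pool)
  }
  abort("Background cleanup did not converge.")  # not reached in practice
}

zone_bounds <- function(zone, length) {
  third <- floor(length / 3)
  switch(zone,
    N = c(1L, third),
    M = c(third + 1L, 2L * third),
    C = c(2L * third + 1L, length),
    abort(sprintf("Unknown location zone '%s'.", zone))
  )
}

place_blocks <- function(locations, length, min_gap = 25L, tries = 200L,
                         margin = 12L) {
  # `margin` keeps blocks clear of the sequence termini so truncated edge
  # windows cannot extend a called span asymmetrically.
  for (t in seq_len(tries)) {
    lens <- sample(19:23, length(locations), replace = TRUE,
                   prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
    centers <- map_dbl(seq_along(locations), function(k) {
      zb <- zone_bounds(locations[k], length)
      half <- (lens[k] - 1) / 2
      lo <- max(zb[1] + half, half + 1 + margin)
      hi <- min(zb[2] - half, length - half - margin)
      if (lo > hi) return(NA_real_)
      cand <- seq(ceiling(lo), floor(hi))
      cand[sample.int(length(cand), 1)]
    })
    if (anyNA(centers)) next
    starts <- as.integer(round(centers - (lens - 1) / 2))
    ends <- starts + lens - 1L
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    if (length(starts) == 1 ||
        all(starts[-1] - ends[-length(ends)] - 1L >= min_gap)) {
      return(tibble(start = starts, end = ends))
    }
  }
  abort("Zones too crowded to place non-overlapping TM blocks.")
}

#' Generate a protein with planted TM helices
#'
#' The background is drawn from hydrophilic residues and adversarially
#' resampled below the detection cutoff away from the blocks; each planted
#' span is a contiguous hydrophobic block of 19-23 residues centred inside
#' its requested zone (N-terminal / central / C-terminal third).
#'
#' @param n_tm number of planted helices.
#' @param locations character vector of zones (`"N"`, `"M"`, `"C"`), one per
#'   helix.
#' @param length protein length (must be at least `40 * n_tm`).
#' @param seed integer seed; the same seed reproduces the same protein.
#' @param id protein identifier.
#' @param params [hydro_params()] defining the cutoff the background is held
#'   under.
#' @return list with `protein` (one-row tibble: `id`, `seq`, `length`) and
#'   `spans` (truth tibble: `start`, `end`).
#' @export
plant_tm_protein <- function(n_tm, locations, length, seed,
                             id = sprintf("synthTM_%d", seed),
                             params = hydro_params()) {
  stopifnot(n_tm == base::length(locations), length >= 40 * n_tm, n_tm >= 1)
  withr::with_seed(seed, {
    for (attempt in 1:25) {
      blocks <- place_blocks(locations, length)
      letters <- sample_residues(length, background_freqs)
      for (k in seq_len(nrow(blocks))) {
        sh <- setdiff(
          intersect(seq_len(length),
                    (blocks$start[k] - shoulder_width):(blocks$end[k] + shoulder_width)),
          blocks$start[k]:blocks$end[k]
        )
        letters[sh] <- sample_residues(base::length(sh), shoulder_freqs)
        letters[blocks$start[k]:blocks$end[k]] <-
          sample_residues(blocks$end[k] - blocks$start[k] + 1L, block_freqs)
      }
      letters <- clean_background(letters, blocks, params)
      # the generator guarantees its own truth: every planted block must be
      # recoverable as one well-centred span, else the draw is rejected
      called <- find_tm_segments(
        hydropathy_profile(paste(letters, collapse = ""), params), params
      )
      if (nrow(called) == nrow(blocks) &&
          all(abs((called$start + called$end) / 2 -
                  (blocks$start + blocks$end) / 2) <= 3)) {
        return(list(
          protein = tibble(id = id, seq = paste(letters, collapse = ""),
                           length = as.integer(length)),
          spans = blocks
        ))
      }
    }
    abort("Could not plant recoverable TM blocks in 25 attempts.")
  })
}

#' Generate a soluble decoy protein
#'
#' Hydrophilic background only, resampled until every profile position lies
#' strictly below the lower cutoff, so the decoy can never be called
#' membrane by the built-in predictor.
#'
#' @param length protein length (at least 30).
#' @param seed integer seed.
#' @param id protein identifier.
#' @param params [hydro_params()].
#' @return one-row tibble: `id`, `seq`, `length`.
#' @export
soluble_decoy <- function(length, seed, id = sprintf("synthSOL_%d", seed),
                          params = hydro_params()) {
  stopifnot(length >= 30)
  withr::with_seed(seed, {
    letters <- sample_residues(length, background_freqs)
    letters <- clean_background(letters, empty_spans(), params)
    tibble(id = id, seq = paste(letters, collapse = ""),
           length = as.integer(length))
  })
}

#' Generate an isoform set for the ALS screen
#'
#' The reference isoform is a single-TM protein (block in the C-terminal
#' region) with a 60-residue transcription-factor "domain" placed away from
#' the span. The variant excises the TM block when `drop_tm`, and/or half
#' the domain when `drop_domain`; with both FALSE the variant is a full copy
#' of the reference.
#'
#' @param locus locus name; isoform ids are `<locus>.1` (reference) and
#'   `<locus>.2` (variant).
#' @param drop_tm excise the TM block (plus 2-residue flanks) from the
#'   variant.
#' @param drop_domain excise the first half of the domain from the variant.
#' @param seed integer seed.
#' @param params [hydro_params()].
#' @return isoform set list (`locus`, `reference`, `variants`, `domain`) as
#'   consumed by [screen_isoforms()], plus `truth_flagged` (whether the
#'   screen should flag this locus).
#' @export
isoform_fixture <- function(locus, drop_tm = TRUE, drop_domain = FALSE,
                            seed = 1, params = hydro_params()) {
  len <- 300L
  gen <- plant_tm_protein(1, "C", len, seed, id = paste0(locus, ".1"),
                          params = params)
  domain <- c(41L, 100L)
  ref_letters <- strsplit(gen$protein$seq, "", fixed = TRUE)[[1]]
  block <- gen$spans
  drop <- integer(0)
  if (drop_tm) {
    drop <- c(drop, max(1L, block$start - 2L):min(len, block$end + 2L))
  }
  if (drop_domain) drop <- c(drop, domain[1]:(domain[1] + 29L))
  var_letters <- if (length(drop) > 0) ref_letters[-drop] else ref_letters
  list(
    locus = locus,
    reference = tibble(id = paste0(locus, ".1"), seq = gen$protein$seq),
    variants = tibble(id = paste0(locus, ".2"),
                      seq = paste(var_letters, collapse = "")),
    domain = domain,
    truth_flagged = drop_tm && !drop_domain
  )
}

#' Generate a synthetic multi-species TF proteome with known truth
#'
#' A shrunk stand-in for a multi-proteome transcription-factor screen:
#' per species, `round(n_tf_per_species * mtf_fraction)` proteins carry
#' planted TM helices (mostly one, sometimes two or three, in distinct
#' zones) and the rest are soluble decoys held below the detection cutoff.
#' FASTA headers record the per-protein seed and the planted truth.
#'
#' @param dir output directory (created if needed); FASTA, annotation TSV
#'   and truth TSV are written there.
#' @param n_species number of species.
#' @param n_tf_per_species proteins per species.
#' @param mtf_fraction fraction of proteins with planted helices.
#' @param families family labels, drawn uniformly.
#' @param seed master seed; all per-protein seeds derive from it.
#' @param params [hydro_params()].
#' @return list with paths (`fasta`, `annotation_file`, `truth_file`) and
#'   tibbles (`proteins`, `annotations`, `truth`); `truth` has a `spans`
#'   list-column of planted blocks.
#' @export
genome_fixture <- function(dir = tempfile("genome_fixture"),
                           n_species = 3, n_tf_per_species = 100,
                           mtf_fraction = 0.05,
                           families = c("NAC", "bZIP", "SBP", "C2H2",
                                        "MYB-related", "bHLH", "WRKY", "ERF"),
                           seed = 1, params = hydro_params()) {
  stopifnot(mtf_fraction >= 0, mtf_fraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  total <- n_species * n_tf_per_species
  n_mtf <- round(n_tf_per_species * mtf_fraction)
  rows <- withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, total)
    fams <- sample(families, total, replace = TRUE)
    n_tms <- sample(1:3, total, replace = TRUE, prob = c(0.70, 0.25, 0.05))
    lens <- sample(180:450, total, replace = TRUE)
    list(sub_seeds = sub_seeds, fams = fams, n_tms = n_tms, lens = lens)
  })
  out <- vector("list", total)
  k <- 0L
  for (s in seq_len(n_species)) {
    species <- sprintf("sp%02d", s)
    for (i in seq_len(n_tf_per_species)) {
      k <- k + 1L
      id <- sprintf("%s_TF%04d", species, i)
      is_mtf <- i <= n_mtf
      if (is_mtf) {
        n_tm <- rows$n_tms[k]
        len <- max(rows$lens[k], 40L * n_tm + 80L)
        locations <- withr::with_seed(rows$sub_seeds[k], {
          sample(c("N", "M", "C"), n_tm)
        })
        gen <- plant_tm_protein(n_tm, locations, len, rows$sub_seeds[k],
                                id = id, params = params)
        prot <- gen$protein
        spans <- gen$spans
      } else {
        prot <- soluble_decoy(rows$lens[k], rows$sub_seeds[k], id = id,
                              params = params)
        spans <- empty_spans()[c("start", "end")]
      }
      out[[k]] <- tibble(
        id = id, species = species, family = rows$fams[k],
        locus = paste0("LOC_", id), seq = prot$seq, length = prot$length,
        is_mtf = is_mtf, seed = rows$sub_seeds[k], spans = list(spans)
      )
    }
  }
  all <- bind_rows(out)
  spans_txt <- map_chr(all$spans, function(s) {
    if (nrow(s) == 0) "." else paste(sprintf("%d-%d", s$start, s$end), collapse = ";")
  })
  fasta <- file.path(dir, "proteins.fasta")
  write_tf_fasta(
    mutate(all, desc = sprintf("seed=%d;mtf=%d;spans=%s",
                               .data$seed, as.integer(.data$is_mtf), spans_txt)),
    fasta
  )
  ann_file <- file.path(dir, "annotations.tsv")
  writeLines(
    c("#id\tlocus\tspecies\tfamily",
      sprintf("%s\t%s\t%s\t%s", all$id, all$locus, all$species, all$family)),
    ann_file
  )
  truth_file <- file.path(dir, "truth.tsv")
  writeLines(
    c("#id\tspecies\tfamily\tis_mtf\tspans",
      sprintf("%s\t%s\t%s\t%d\t%s", all$id, all$species, all$family,
              as.integer(all$is_mtf), spans_txt)),
    truth_file
  )
  list(
    fasta = fasta, annotation_file = ann_file, truth_file = truth_file,
    proteins = all[c("id", "locus", "species", "family", "seq", "length")],
    annotations = all[c("id", "locus", "species", "family")],
    truth = all[c("id", "species", "family", "is_mtf", "spans")]
  )
}

#' Simulate a noisy multi-predictor panel from planted truth
#'
#' Emulates the outputs of an external predictor battery: for each protein,
#' `n_predictors - n_wrong` predictors report the planted topology with each
#' span shifted by at most `jitter` residues, and the remaining predictors
#' report the opposite label (a spurious helix on soluble proteins, no helix
#' on membrane proteins).
#'
#' @param truth truth tibble from [genome_fixture()] (`id`, `is_mtf`,
#'   `spans`) joined with protein `length`s.
#' @param lengths named vector or tibble (`id`, `length`) of protein lengths.
#' @param predictors predictor names to simulate.
#' @param n_wrong number of wrong predictors per protein.
#' @param jitter maximum per-span shift (residues).
#' @param seed integer seed.
#' @return topology tibble with one row per protein per predictor.
#' @export
simulate_predictor_panel <- function(truth, lengths,
                                     predictors = c("HMMTOP", "PHOBIUS",
                                                    "S-TMHMM", "TOPPRED",
                                                    "SCAMPI-single", "MEMSAT"),
                                     n_wrong = 1, jitter = 3, seed = 1) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$id)
  }
  withr::with_seed(seed, {
    rows <- map(seq_len(nrow(truth)), function(k) {
      id <- truth$id[k]
      len <- as.integer(lengths[[id]])
      spans <- truth$spans[[k]]
      wrong <- sample(length(predictors), n_wrong)
      map(seq_along(predictors), function(p) {
        if (p %in% wrong) {
          sp <- if (nrow(spans) > 0) {
            empty_spans()
          } else {
            st <- sample(seq_len(len - 20L), 1)
            tibble(start = st, end = st + 20L, certainty = "certain")
          }
        } else if (nrow(spans) == 0) {
          sp <- empty_spans()
        } else {
          shift <- sample(-jitter:jitter, nrow(spans), replace = TRUE)
          sp <- tibble(
            start = pmax(1L, pmin(len, spans$start + shift)),
            end = pmax(1L, pmin(len, spans$end + shift)),
            certainty = "certain"
          )
        }
        new_topology(id, predictors[p], spans = sp, length = len)
      })
    })
    bind_rows(unlist(rows, recursive = FALSE))
  })
}
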