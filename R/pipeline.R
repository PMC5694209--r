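#' Pipeline configuration
#'
#' Bundles every tunable of the scan: built-in predictor parameters,
#' location-zone fractions, consensus agreement settings, the TMHMM
#' posterior filter, and the ALS coverage threshold. Round-trips losslessly
#' through YAML via [write_scan_config()] / [read_scan_config()].
#'
#' @param hydro [hydro_params()].
#' @param classify [classify_params()].
#' @param min_overlap consensus span-overlap requirement (residues).
#' @param tmhmm_threshold posterior cutoff of the TMHMM branch.
#' @param tmhmm_statistic `"mean"` or `"min"` posterior over a span.
#' @param predictor_priority predictor order used for consensus
#'   tie-breaking; `NULL` keeps input order.
#' @param coverage_min ALS screen domain-coverage threshold.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(hydro = hydro_params(), classify = classify_params(),
                        min_overlap = 5, tmhmm_threshold = 0.90,
                        tmhmm_statistic = "mean",
                        predictor_priority = c("HMMTOP", "PHOBIUS", "S-TMHMM",
                                               "TOPPRED", "SCAMPI-single",
                                               "MEMSAT", "hydro-builtin"),
                        coverage_min = 0.9) {
  structure(
    list(
      hydro = hydro, classify = classify, min_overlap = min_overlap,
      tmhmm_threshold = tmhmm_threshold, tmhmm_statistic = tmhmm_statistic,
      predictor_priority = predictor_priority, coverage_min = coverage_min
    ),
    class = "scan_config"
  )
}

#' @rdname scan_config
#' @param config a `scan_config`.
#' @param path YAML file path.
#' @export
write_scan_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname scan_config
#' @export
read_scan_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scan_config(
    hydro = do.call(hydro_params, raw$hydro),
    classify = do.call(classify_params, raw$classify),
    min_overlap = raw$min_overlap,
    tmhmm_threshold = raw$tmhmm_threshold,
    tmhmm_statistic = raw$tmhmm_statistic,
    predictor_priority = unlist(raw$predictor_priority),
    coverage_min = raw$coverage_min
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Run the full MTF identification scan
#'
#' Orchestrates the two-branch workflow: all non-TMHMM predictor outputs
#' (plus the built-in hydrophobicity predictor) feed an agreement-based
#' consensus; TMHMM predictions, posterior-filtered, form the second branch;
#' the branches are merged by union into the final MTF call set, which is
#' classified and summarized. Without external predictor reports the
#' built-in predictor alone feeds both branches (a degenerate consensus of
#' one, noted in the log).
#'
#' @param fasta protein FASTA path, or an already-read protein tibble.
#' @param annotations annotation TSV path or tibble (optional).
#' @param predictor_reports optional directory of external predictor
#'   reports, see [read_predictor_dir()].
#' @param config [scan_config()].
#' @param out_dir optional output directory; when given, the MTF report,
#'   summary tables, resolved config and run log are written there.
#' @return object of class `mtf_scan`: list with `proteins`, `mtfs`,
#'   `consensus`, `summary`, `config`, `log`.
#' @export
run_scan <- function(fasta, annotations = NULL, predictor_reports = NULL,
                     config = scan_config(), out_dir = NULL) {
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)
  if (is.character(annotations)) annotations <- read_annotation_table(annotations)
  proteins <- if (is.character(fasta)) {
    read_tf_fasta(fasta, annotations)
  } else {
    attach_annotations(as_tibble(fasta), annotations) |>
      mutate(length = nchar(.data$seq))
  }
  note(sprintf("Read %d proteins.", nrow(proteins)))

  if (nrow(proteins) == 0) {
    mtfs <- classify_mtfs(merge_branches(NULL, NULL), config$classify)
    res <- structure(
      list(proteins = proteins, mtfs = mtfs, consensus = NULL,
           summary = summarize_mtfs(mtfs, config$classify),
           config = config, log = log),
      class = "mtf_scan"
    )
    if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
    return(res)
  }

  builtin <- predict_topology_hydro(proteins, config$hydro)
  note("Ran built-in hydrophobicity-profile predictor.")

  reports <- if (!is.null(predictor_reports)) {
    read_predictor_dir(predictor_reports)
  }
  consensus_input <- builtin
  tmhmm_branch <- NULL
  if (!is.null(reports) && nrow(reports$topologies) > 0) {
    consensus_input <- bind_rows(reports$topologies, builtin)
    note(sprintf("Loaded %d external prediction(s) from %d predictor(s).",
                 nrow(reports$topologies),
                 length(unique(reports$topologies$predictor))))
  } else {
    note("No external predictor reports; built-in predictor feeds both branches (degenerate consensus of one).")
  }
  if (!is.null(reports) && !is.null(reports$tmhmm)) {
    tmhmm_branch <- bind_rows(map(seq_len(nrow(reports$tmhmm)), function(k) {
      pred <- reports$tmhmm[k, ]
      track <- reports$posteriors[[pred$protein_id]]
      if (is.null(track)) {
        note(sprintf("No posterior track for '%s'; TMHMM spans accepted unfiltered.",
                     pred$protein_id))
        pred
      } else {
        filter_tmhmm(pred, track, config$tmhmm_threshold,
                     config$tmhmm_statistic)
      }
    }))
    note(sprintf("TMHMM branch: %d prediction(s), posterior threshold %g (%s over span).",
                 nrow(tmhmm_branch), config$tmhmm_threshold,
                 config$tmhmm_statistic))
  }

  consensus <- consensus_all(consensus_input,
                             priority = config$predictor_priority,
                             min_overlap = config$min_overlap)
  note(sprintf("Consensus: %d membrane call(s) of %d proteins.",
               sum(consensus$n_tm >= 1), nrow(consensus)))

  mtfs <- merge_branches(consensus, tmhmm_branch, proteins) |>
    classify_mtfs(config$classify)
  note(sprintf("Merged MTF set: %d call(s).", nrow(mtfs)))

  tf_totals <- count(proteins, .data$species, name = "tf_loci")
  res <- structure(
    list(
      proteins = proteins, mtfs = mtfs, consensus = consensus,
      summary = summarize_mtfs(mtfs, config$classify, tf_totals = tf_totals),
      config = config, log = log
    ),
    class = "mtf_scan"
  )
  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

write_scan_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mtf_report(res$mtfs, file.path(out_dir, "mtf_report.tsv"))
  write_summary_tables(res$summary, file.path(out_dir, "summary"))
  write_scan_config(res$config, file.path(out_dir, "config.yaml"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.mtf_scan <- function(x, ...) {
  cat(sprintf("MTF scan: %d / %d proteins called membrane-bound (%s)\n",
              nrow(x$mtfs), nrow(x$proteins),
              paste(unique(x$mtfs$provenance), collapse = ", ")))
  invisible(x)
}

#' Tidy an MTF scan result
#'
#' @param x `mtf_scan` object.
#' @param ... unused.
#' @return the MTF call tibble (one row per MTF, `spans` as list-column).
#' @exportS3Method generics::tidy
tidy.mtf_scan <- function(x, ...) x$mtfs

#' @rdname tidy.mtf_scan
#' @exportS3Method generics::glance
glance.mtf_scan <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$proteins),
    n_mtf = nrow(x$mtfs),
    pct_mtf = if (nrow(x$proteins) > 0) {
      round_half_up(100 * nrow(x$mtfs) / nrow(x$proteins), 1)
    } else {
      NA_real_
    },
    n_species = length(unique(x$proteins$species)),
    n_families = length(unique(x$mtfs$family))
  )
}
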