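#' Parse a TMHMM-style long-format report
#'
#' Accepts the classic long format: one line per topology segment,
#' `"<id> TMHMM2.0 <inside|outside|TMhelix> <start> <end>"`, with `#`
#' comment lines and `key=value` metadata lines ignored. Segments of one
#' protein must form a contiguous block of lines (interleaved proteins are
#' rejected) and must tile the sequence from position 1 without gaps or
#' overlaps.
#'
#' @param text report content as a single string or character vector of
#'   lines; a path to an existing file also works.
#' @return topology tibble, one row per protein, predictor `"TMHMM"`.
#' @export
parse_tmhmm_long <- function(text) {
  lines <- as_report_lines(text)
  lines <- lines[nzchar(str_trim(lines))]
  lines <- lines[!startsWith(str_trim(lines), "#")]
  lines <- lines[!str_detect(lines, "=")]  # short-format metadata (PredHel=, len=, ...)
  if (length(lines) == 0) return(empty_topology_tbl())
  fields <- strsplit(str_trim(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 5)) {
    abort(sprintf("TMHMM report: expected 5 fields, got %d in line '%s'.",
                  nf[nf != 5][1], lines[nf != 5][1]))
  }
  seg <- tibble(
    id = map_chr(fields, 1),
    state = map_chr(fields, 3),
    start = as.integer(map_chr(fields, 4)),
    end = as.integer(map_chr(fields, 5))
  )
  if (any(!seg$state %in% c("inside", "outside", "TMhelix"))) {
    abort(sprintf("TMHMM report: unknown segment type '%s'.",
                  setdiff(seg$state, c("inside", "outside", "TMhelix"))[1]))
  }
  blocks <- rle(seg$id)
  if (anyDuplicated(blocks$values)) {
    abort(sprintf("TMHMM report: lines for protein '%s' are interleaved with another protein.",
                  blocks$values[duplicated(blocks$values)][1]))
  }
  bind_rows(map(split(seg, factor(seg$id, levels = blocks$values)), tmhmm_block_to_topology))
}

tmhmm_block_to_topology <- function(seg) {
  id <- seg$id[1]
  if (seg$start[1] != 1) {
    abort(sprintf("TMHMM report (%s): segments must start at residue 1.", id))
  }
  if (any(seg$start > seg$end)) {
    abort(sprintf("TMHMM report (%s): segment with start > end.", id))
  }
  if (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L)) {
    abort(sprintf("TMHMM report (%s): segments overlap or leave gaps.", id))
  }
  code <- c(inside = "i", outside = "o", TMhelix = "M")[seg$state]
  states <- paste(strrep(code, seg$end - seg$start + 1L), collapse = "")
  new_topology(id, "TMHMM", states = states)
}

as_report_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) && file.exists(text)) {
    return(readLines(text))
  }
  unlist(strsplit(text, "\n", fixed = TRUE))
}

empty_topology_tbl <- function() {
  tibble(
    protein_id = character(), predictor = character(), length = integer(),
    states = character(), n_tm = integer(), valid = logical(),
    spans = list(), span_conf = list()
  )
}

#' Parse a per-residue posterior probability track
#'
#' Reads TMHMM plp-style lines: residue index, residue letter, then state
#' probability columns, of which one is the membrane-state posterior.
#' Indices must be consecutive from 1; probabilities must lie in `[0, 1]`.
#'
#' @param text track content (string, lines, or file path).
#' @param membrane_col 1-based field number of the membrane-state
#'   probability (default 4: index, residue, inside, membrane, outside).
#' @return tibble with columns `pos`, `residue`, `p_membrane`.
#' @export
parse_posterior_track <- function(text, membrane_col = 4) {
  lines <- as_report_lines(text)
  lines <- lines[nzchar(str_trim(lines)) & !startsWith(str_trim(lines), "#")]
  if (length(lines) == 0) abort("Empty posterior track.")
  fields <- strsplit(str_trim(lines), "\\s+")
  if (any(lengths(fields) < membrane_col)) {
    abort(sprintf("Posterior track: fewer than %d fields in line '%s'.",
                  membrane_col, lines[lengths(fields) < membrane_col][1]))
  }
  pos <- as.integer(map_chr(fields, 1))
  if (anyNA(pos) || !identical(pos, seq_along(pos))) {
    abort("Posterior track: residue indices must run 1, 2, ... without gaps.")
  }
  p <- as.numeric(map_chr(fields, membrane_col))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("Posterior track: membrane probabilities must lie in [0, 1].")
  }
  tibble(pos = pos, residue = map_chr(fields, 2), p_membrane = p)
}

#' Parse a multi-protein posterior file
#'
#' Blocks of plp-style lines, each preceded by a `# <id>` header line.
#'
#' @param text file content (string, lines, or file path).
#' @param membrane_col see [parse_posterior_track()].
#' @return named list of posterior-track tibbles, one per protein.
#' @export
parse_posterior_file <- function(text, membrane_col = 4) {
  lines <- as_report_lines(text)
  heads <- which(startsWith(str_trim(lines), "#"))
  if (length(heads) == 0) abort("Posterior file has no '# <id>' block headers.")
  ids <- str_trim(sub("^\\s*#\\s*", "", lines[heads]))
  ends <- c(heads[-1] - 1L, length(lines))
  out <- map(seq_along(heads), function(k) {
    parse_posterior_track(lines[(heads[k] + 1L):ends[k]], membrane_col)
  })
  stats::setNames(out, ids)
}

#' Parse a generic per-residue topology string
#'
#' Any external predictor can be ingested through this format: a string over
#' `{i, M, o}`. Non-alternating loop labels (e.g. `iMi` followed by `i`
#' again on the other side) are accepted as written but flagged
#' `valid = FALSE`.
#'
#' @param protein_id protein identifier.
#' @param s topology string.
#' @param predictor predictor name recorded on the row.
#' @return one-row topology tibble.
#' @export
parse_topology_string <- function(protein_id, s, predictor = "generic") {
  assert_scalar_chr(s, "s")
  new_topology(protein_id, predictor, states = s)
}

#' Read a one-topology-per-line table
#'
#' Lines of the form `id<TAB>topology-string`; `#` comments skipped.
#'
#' @param text table content (string, lines, or file path).
#' @param predictor predictor name for every row.
#' @return topology tibble.
#' @export
read_topology_table <- function(text, predictor = "generic") {
  lines <- as_report_lines(text)
  lines <- lines[nzchar(str_trim(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_topology_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    abort("Topology table lines must be 'id<TAB>topology-string'.")
  }
  bind_rows(map(fields, function(f) parse_topology_string(f[1], f[2], predictor)))
}

#' Read a directory of predictor reports
#'
#' Integration contract: one report file per predictor per proteome.
#' `<name>.top` files hold generic topology tables (predictor = file name);
#' `tmhmm.long` holds a TMHMM long-format report; `tmhmm.plp` holds
#' posterior blocks headed by `# <id>` lines.
#'
#' @param dir directory path.
#' @return list with `topologies` (topology tibble over all non-TMHMM
#'   predictors), `tmhmm` (topology tibble or NULL), `posteriors` (named
#'   list of tracks or NULL).
#' @export
read_predictor_dir <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("Predictor report directory not found: %s", dir))
  tops <- list.files(dir, pattern = "\\.top$", full.names = TRUE)
  topo <- bind_rows(map(tops, function(f) {
    read_topology_table(f, predictor = sub("\\.top$", "", basename(f)))
  }))
  tm_file <- file.path(dir, "tmhmm.long")
  plp_file <- file.path(dir, "tmhmm.plp")
  list(
    topologies = topo,
    tmhmm = if (file.exists(tm_file)) parse_tmhmm_long(tm_file) else NULL,
    posteriors = if (file.exists(plp_file)) parse_posterior_file(plp_file) else NULL
  )
}
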