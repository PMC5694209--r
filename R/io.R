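#' Read a transcription-factor protein FASTA
#'
#' Sequences are upper-cased and validated against the 20 standard amino
#' acids plus X. Header IDs are taken up to the first whitespace (PlantTFDB
#' style headers or plain IDs both work). When an annotation table is given,
#' locus/species/family are attached by ID; unannotated records get `"NA"`.
#'
#' @param path FASTA file.
#' @param annotations optional annotation tibble from
#'   [read_annotation_table()].
#' @return tibble with columns `id`, `locus`, `species`, `family`, `seq`,
#'   `length`.
#' @export
read_tf_fasta <- function(path, annotations = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && !startsWith(first, ">")) {
    abort(sprintf("Malformed FASTA (no '>' header on line 1): %s", path))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  proteins <- tibble(id = ids, seq = unname(seqs))
  if (any(!nzchar(proteins$seq))) {
    abort(sprintf("Empty sequence for record '%s'.",
                  proteins$id[!nzchar(proteins$seq)][1]))
  }
  for (k in seq_len(nrow(proteins))) {
    proteins$seq[k] <- check_aa_seq(proteins$seq[k], proteins$id[k])
  }
  proteins <- attach_annotations(proteins, annotations)
  mutate(proteins, length = nchar(.data$seq)) |>
    select("id", "locus", "species", "family", "seq", "length")
}

attach_annotations <- function(proteins, annotations) {
  if (is.null(annotations)) {
    return(mutate(proteins, locus = "NA", species = "NA", family = "NA"))
  }
  out <- left_join(proteins, annotations, by = "id")
  miss <- is.na(out$family)
  if (any(miss)) {
    warn(sprintf("%d FASTA record(s) missing from the annotation table (e.g. '%s'); family set to \"NA\".",
                 sum(miss), out$id[miss][1]))
  }
  mutate(out,
         locus = dplyr::coalesce(.data$locus, "NA"),
         species = dplyr::coalesce(.data$species, "NA"),
         family = dplyr::coalesce(.data$family, "NA"))
}

#' Write a protein tibble to FASTA
#'
#' @param proteins tibble with `id` and `seq`; an optional `desc` column is
#'   appended to headers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tf_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$seq)
  names(set) <- if ("desc" %in% names(proteins)) {
    paste(proteins$id, proteins$desc)
  } else {
    proteins$id
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Tab-separated, four columns: `id`, `locus`, `species`, `family`. Lines
#' starting with `#` are treated as comments/header.
#'
#' @param path TSV file.
#' @return tibble with those four character columns.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation table not found: %s", path))
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(str_trim(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    abort(sprintf("Annotation table line %d has %d column(s), expected 4 (id, locus, species, family).",
                  keep[bad], nf[bad]))
  }
  tab <- tibble(
    id = map_chr(fields, 1), locus = map_chr(fields, 2),
    species = map_chr(fields, 3), family = map_chr(fields, 4)
  )
  if (anyDuplicated(tab$id)) {
    abort(sprintf("Duplicate protein id in annotation table: %s",
                  tab$id[duplicated(tab$id)][1]))
  }
  if (any(!nzchar(tab$family))) abort("Empty family label in annotation table.")
  tab
}

#' Read a domain-interval table
#'
#' Tab-separated: `protein_id`, `start`, `end` (1-based inclusive
#' coordinates of the DNA-binding domain on that protein). Lines starting
#' with `#` are skipped.
#'
#' @param path TSV file.
#' @return tibble with columns `protein_id`, `start`, `end`.
#' @export
read_domain_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#",
                         col_names = c("protein_id", "start", "end"),
                         col_types = "cii", progress = FALSE)
  if (any(tab$start < 1 | tab$start > tab$end)) {
    abort("Domain intervals need 1 <= start <= end.")
  }
  tab
}

#' Write the MTF call report
#'
#' Tab-separated, one row per MTF, ordered by species then id. Coordinates
#' are 1-based inclusive, spans joined as `start-end;start-end`. An empty
#' call set writes a header-only file.
#'
#' @param mtfs MTF tibble from [merge_branches()] / [classify_mtfs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mtf_report <- function(mtfs, path) {
  cols <- c("id", "locus", "species", "family", "tm_count", "spans",
            "location_pattern", "provenance")
  header <- c(
    "# MTF call report; coordinates 1-based, inclusive on both ends",
    paste(cols, collapse = "\t")
  )
  if (nrow(mtfs) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- mtfs |>
    mutate(
      tm_count = .data$n_tm,
      spans_txt = map_chr(.data$spans, function(s) {
        paste(sprintf("%d-%d", s$start, s$end), collapse = ";")
      }),
      location_pattern = if ("location_pattern" %in% names(mtfs)) {
        .data$location_pattern
      } else {
        "NA"
      }
    ) |>
    arrange(.data$species, .data$id)
  body <- sprintf("%s\t%s\t%s\t%s\t%d\t%s\t%s\t%s",
                  rows$id, rows$locus, rows$species, rows$family,
                  rows$tm_count, rows$spans_txt, rows$location_pattern,
                  rows$provenance)
  writeLines(c(header, body), path)
  invisible(path)
}
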