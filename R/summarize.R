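#' Family-by-species MTF count matrix
#'
#' @param mtfs MTF tibble with `family` and `species` columns.
#' @return integer matrix, family rows x species columns, both in
#'   alphabetical order; absent combinations are 0.
#' @export
family_species_matrix <- function(mtfs) {
  if (nrow(mtfs) == 0) {
    return(matrix(integer(), 0, 0))
  }
  if (any(is.na(mtfs$family) | !nzchar(mtfs$family))) {
    abort("Every MTF needs a non-empty family label.")
  }
  m <- table(factor(mtfs$family), factor(mtfs$species))
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  out[alpha_order(rownames(out)), alpha_order(colnames(out)), drop = FALSE]
}

# Locale-independent dictionary ordering (case-insensitive, then exact),
# so "bZIP" sorts before "NAC" on every platform.
alpha_order <- function(x) order(tolower(x), x, method = "radix")

#' Per-family MTF totals, largest first
#'
#' @param mat matrix from [family_species_matrix()], or a data frame with a
#'   `family` column followed by per-species count columns.
#' @return tibble (`family`, `total`) sorted by descending total, ties
#'   alphabetical.
#' @export
family_totals <- function(mat) {
  if (is.data.frame(mat)) {
    fams <- mat$family
    counts <- as.matrix(mat[setdiff(names(mat), "family")])
    rownames(counts) <- fams
    mat <- counts
  }
  totals <- rowSums(mat)
  tbl <- tibble(family = rownames(mat), total = as.integer(totals))
  tbl[order(-tbl$total, tolower(tbl$family), tbl$family, method = "radix"), ]
}

#' TM-count distribution of an MTF set
#'
#' @param mtfs MTF tibble with an `n_tm` column.
#' @return tibble (`tm_count`, `n`, `percent`), percent rounded half-up to
#'   one decimal of the MTF total.
#' @export
tm_count_percentages <- function(mtfs) {
  if (nrow(mtfs) == 0) abort("TM-count distribution needs at least one MTF.")
  tab <- count(mtfs, tm_count = .data$n_tm)
  mutate(tab, percent = round_half_up(100 * .data$n / sum(.data$n), 1))
}

#' Terminal-location distribution of 1-TM and 2-TM MTFs
#'
#' For single-span MTFs, counts per location class (N-terminal / central /
#' C-terminal); for two-span MTFs, counts per pattern bucket NN / CC / NC /
#' others. Each group uses its own denominator; the NC bucket counts both
#' orders (`NC`, `CN`).
#'
#' @param mtfs MTF tibble with `spans` and `length` (location patterns are
#'   computed if not already present).
#' @param params [classify_params()].
#' @return tibble (`group`, `category`, `n`, `percent`), percent half-up to
#'   one decimal.
#' @export
location_percentages <- function(mtfs, params = classify_params()) {
  if (nrow(mtfs) == 0) abort("Location distribution needs at least one MTF.")
  if (!"location_pattern" %in% names(mtfs)) {
    mtfs <- classify_mtfs(mtfs, params)
  }
  one <- filter(mtfs, .data$n_tm == 1)
  two <- filter(mtfs, .data$n_tm == 2)
  out <- list()
  if (nrow(one) > 0) {
    tab <- count(one, category = factor(.data$location_pattern,
                                        levels = c("N", "C", "M")),
                 .drop = FALSE)
    out$one <- mutate(tab,
                      group = "1TM",
                      category = as.character(.data$category),
                      percent = round_half_up(100 * .data$n / nrow(one), 1))
  }
  if (nrow(two) > 0) {
    bucket <- dplyr::case_when(
      two$location_pattern == "NN" ~ "NN",
      two$location_pattern == "CC" ~ "CC",
      two$location_pattern %in% c("NC", "CN") ~ "NC",
      TRUE ~ "others"
    )
    tab <- count(tibble(category = factor(bucket, levels = c("NN", "CC", "NC", "others"))),
                 .data$category, .drop = FALSE)
    out$two <- mutate(tab,
                      group = "2TM",
                      category = as.character(.data$category),
                      percent = round_half_up(100 * .data$n / nrow(two), 1))
  }
  bind_rows(out)[c("group", "category", "n", "percent")]
}

#' Summarize an MTF call set
#'
#' Bundles the family-by-species matrix, family totals, TM-count histogram,
#' terminal-location table and per-species totals.
#'
#' @param mtfs MTF tibble (annotated, from [merge_branches()] /
#'   [classify_mtfs()]).
#' @param params [classify_params()].
#' @param tf_totals optional tibble (`species`, `tf_loci`) of total screened
#'   TF counts per species, reported alongside MTF totals.
#' @return object of class `mtf_summary`.
#' @export
summarize_mtfs <- function(mtfs, params = classify_params(), tf_totals = NULL) {
  mtfs <- if (nrow(mtfs) > 0) classify_mtfs(mtfs, params) else mtfs
  totals <- if (nrow(mtfs) > 0) {
    count(mtfs, .data$species, name = "mtf_loci")
  } else {
    tibble(species = character(), mtf_loci = integer())
  }
  if (!is.null(tf_totals)) {
    totals <- left_join(tf_totals, totals, by = "species") |>
      mutate(mtf_loci = dplyr::coalesce(.data$mtf_loci, 0L))
  }
  structure(
    list(
      family_species = family_species_matrix(mtfs),
      family_totals = if (nrow(mtfs) > 0) {
        family_totals(family_species_matrix(mtfs))
      } else {
        tibble(family = character(), total = integer())
      },
      tm_count = if (nrow(mtfs) > 0) tm_count_percentages(mtfs) else NULL,
      location = if (nrow(mtfs) > 0) location_percentages(mtfs, params) else NULL,
      totals = totals,
      n_mtf = nrow(mtfs),
      params = params
    ),
    class = "mtf_summary"
  )
}

#' @export
print.mtf_summary <- function(x, ...) {
  cat(sprintf("MTF summary: %d MTFs, %d families, %d species\n",
              x$n_mtf, nrow(x$family_species), ncol(x$family_species)))
  if (!is.null(x$tm_count)) {
    cat("TM-count distribution:\n")
    print(as.data.frame(x$tm_count), row.names = FALSE)
  }
  if (!is.null(x$location)) {
    cat("Span locations (1-TM classes, 2-TM patterns):\n")
    print(as.data.frame(x$location), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname summarize_mtfs
#' @param x `mtf_summary` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mtf_summary <- function(x, ...) {
  fam <- as_tibble(as.data.frame.table(x$family_species,
                                       responseName = "n",
                                       stringsAsFactors = FALSE))
  names(fam) <- c("family", "species", "n")
  fam
}

#' @rdname summarize_mtfs
#' @exportS3Method generics::glance
glance.mtf_summary <- function(x, ...) {
  tibble(
    n_mtf = x$n_mtf,
    n_families = nrow(x$family_species),
    n_species = ncol(x$family_species),
    pct_single_tm = if (is.null(x$tm_count)) NA_real_ else {
      p <- x$tm_count$percent[x$tm_count$tm_count == 1]
      if (length(p) == 0) 0 else p
    }
  )
}

#' Write the tables of an MTF summary as TSV files
#'
#' @param x `mtf_summary` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_summary_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- cbind(family = rownames(x$family_species),
               as.data.frame(x$family_species))
  utils::write.table(fam, file.path(dir, "family_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  readr::write_tsv(x$family_totals, file.path(dir, "family_totals.tsv"))
  if (!is.null(x$tm_count)) {
    readr::write_tsv(x$tm_count, file.path(dir, "tm_count.tsv"))
  }
  if (!is.null(x$location)) {
    readr::write_tsv(x$location, file.path(dir, "location.tsv"))
  }
  readr::write_tsv(x$totals, file.path(dir, "species_totals.tsv"))
  invisible(dir)
}
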