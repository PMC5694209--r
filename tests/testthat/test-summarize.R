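mk_mtf <- function(id, species, family, pattern_spans, len = 300) {
  # pattern_spans: list of c(start, end)
  spans <- dplyr::bind_rows(lapply(pattern_spans, function(p) {
    tibble::tibble(start = p[1], end = p[2], certainty = "certain")
  }))
  tibble::tibble(
    id = id, locus = paste0("LOC_", id), species = species, family = family,
    n_tm = nrow(spans), spans = list(spans), length = len,
    provenance = "consensus"
  )
}

test_that("family-by-species matrix counts with deterministic ordering", {
  mtfs <- dplyr::bind_rows(
    mk_mtf("a1", "spA", "NAC", list(c(10, 30))),
    mk_mtf("a2", "spA", "NAC", list(c(10, 30))),
    mk_mtf("b1", "spB", "bZIP", list(c(10, 30)))
  )
  m <- family_species_matrix(mtfs)
  expect_equal(rownames(m), c("bZIP", "NAC"))  # alphabetical
  expect_equal(unname(m["NAC", ]), c(2L, 0L))  # spA, spB columns
  expect_equal(unname(rowSums(m)), c(1L, 2L))
  expect_equal(dim(family_species_matrix(mtfs[0, ])), c(0, 0))
  expect_error(family_species_matrix(dplyr::mutate(mtfs, family = "")),
               "non-empty family")
})

test_that("published family rows sum to the printed totals", {
  path <- system.file("extdata", "published_family_species_counts.tsv",
                      package = "mtfscan")
  pub <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  totals <- family_totals(pub)
  expect_equal(totals$total[totals$family == "NAC"], 128L)
  expect_equal(totals$total[totals$family == "bZIP"], 67L)
  expect_equal(totals$family[1], "NAC")  # largest family first
  # single-family input: that family first
  single <- family_totals(matrix(c(1L, 2L), 1, dimnames = list("SBP", NULL)))
  expect_equal(single$family, "SBP")
})

test_that("TM-count and location percentages follow half-up rounding", {
  # one protein, three spans
  one <- mk_mtf("x", "spA", "NAC", list(c(10, 30), c(60, 80), c(110, 130)))
  tc <- tm_count_percentages(one)
  expect_equal(tc$percent, 100.0)
  expect_equal(tc$tm_count, 3L)
  # two proteins, one span each
  two <- dplyr::bind_rows(mk_mtf("x", "spA", "NAC", list(c(10, 30))),
                          mk_mtf("y", "spA", "NAC", list(c(10, 30))))
  expect_equal(tm_count_percentages(two)$percent, 100.0)
  expect_error(tm_count_percentages(two[0, ]), "at least one")

  # a single 1-TM N-terminal protein
  loc <- location_percentages(mk_mtf("x", "spA", "NAC", list(c(10, 30))))
  expect_equal(loc$percent[loc$category == "N"], 100.0)
  expect_equal(loc$percent[loc$category == "C"], 0.0)
})

test_that("summary bundles are invariant to input order", {
  withr::local_seed(606)
  mtfs <- dplyr::bind_rows(lapply(1:20, function(k) {
    mk_mtf(sprintf("p%02d", k),
           sample(c("spA", "spB"), 1), sample(c("NAC", "bZIP", "SBP"), 1),
           list(c(10, 30)))
  }))
  s1 <- summarize_mtfs(mtfs)
  s2 <- summarize_mtfs(mtfs[sample(nrow(mtfs)), ])
  expect_identical(s1$family_species, s2$family_species)
  expect_identical(s1$tm_count, s2$tm_count)
  expect_identical(s1$location, s2$location)
})

test_that("summary invariants hold on a fixture-derived call set", {
  fx <- genome_fixture(withr::local_tempdir(), n_species = 2,
                       n_tf_per_species = 30, mtf_fraction = 0.4, seed = 77)
  scan <- run_scan(fx$fasta, fx$annotation_file)
  s <- scan$summary
  # matrix column sums equal per-species MTF totals computed independently
  col_sums <- colSums(s$family_species)
  indep <- table(scan$mtfs$species)
  expect_equal(unname(col_sums[names(indep)]), unname(as.integer(indep)))
  # histogram sums to the MTF total
  expect_equal(sum(s$tm_count$n), nrow(scan$mtfs))
  # raw percents sum to 100 within each denominator group
  expect_equal(sum(100 * s$tm_count$n / sum(s$tm_count$n)), 100)
  # tidy/glance interfaces
  expect_equal(sum(tidy(s)$n), nrow(scan$mtfs))
  expect_equal(glance(s)$n_mtf, nrow(scan$mtfs))
})
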