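test_that("global alignment matches hand-checked small cases", {
  id <- align_global("MKT", "MKT")
  expect_equal(id$score, 6)
  expect_equal(id$a, "MKT")
  expect_equal(id$b, "MKT")

  gap <- align_global("MKT", "MT")
  expect_equal(gap$score, -2)  # 2 matches + one length-1 gap (-5 - 1)
  expect_equal(nchar(gap$a), 3)
  expect_true(grepl("-", gap$b, fixed = TRUE))

  mis <- align_global("AAAA", "TTTT")
  expect_equal(mis$score, -4)  # four mismatches beat any gapped layout
  expect_false(grepl("-", mis$a, fixed = TRUE))

  expect_error(align_global("", "MKT"), "non-empty")
})

test_that("alignment scores equal the exhaustive enumeration oracle", {
  withr::local_seed(404)
  alphabet <- c("A", "C", "D", "E")
  for (rep in 1:30) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(align_global(a, b)$score, enumerate_best_score(a, b),
                 info = paste(a, b))
  }
})

test_that("domain coverage counts identical aligned domain positions", {
  ref <- paste0(strrep("A", 10), "CDEFGHIKLM", strrep("T", 10))
  aln_id <- align_global(ref, ref)
  expect_equal(domain_coverage(aln_id, 11, 20), 1.0)

  # whole domain deleted
  var_del <- paste0(strrep("A", 10), strrep("T", 10))
  expect_equal(domain_coverage(align_global(ref, var_del), 11, 20), 0.0)

  # one domain residue deleted: 9 of 10 identities survive
  var_one <- paste0(strrep("A", 10), "CDEFGHIKL", strrep("T", 10))
  expect_equal(domain_coverage(align_global(ref, var_one), 11, 20), 0.9)

  expect_error(domain_coverage(aln_id, 20, 40), "outside reference")
})

test_that("coverage never increases as more domain residues are deleted", {
  ref <- paste0(strrep("S", 5), "ACDEFGHIKLMNPQRSTVWY", strrep("G", 5))
  prev <- 1
  for (ndel in 0:10) {
    var <- paste0(
      strrep("S", 5),
      substr("ACDEFGHIKLMNPQRSTVWY", ndel + 1, 20),
      strrep("G", 5)
    )
    cov <- domain_coverage(align_global(ref, var), 6, 25)
    expect_lte(cov, prev + 1e-12)
    prev <- cov
  }
})

test_that("isoform screening requires TM loss AND domain retention", {
  iso_good <- isoform_fixture("LOC1", drop_tm = TRUE, drop_domain = FALSE,
                              seed = 5)
  call_good <- screen_isoforms(iso_good)
  expect_true(call_good$flagged)
  expect_equal(call_good$qualifying[[1]], "LOC1.2")

  # variant identical to the reference still has its TM spans
  iso_same <- isoform_fixture("LOC2", drop_tm = FALSE, drop_domain = FALSE,
                              seed = 6)
  expect_false(screen_isoforms(iso_same)$flagged)

  # TM lost but half the domain lost too: coverage below 0.9
  iso_dom <- isoform_fixture("LOC3", drop_tm = TRUE, drop_domain = TRUE,
                             seed = 7)
  expect_false(screen_isoforms(iso_dom)$flagged)
})

test_that("locus-level screen recovers the exact planted flagged set", {
  withr::local_seed(500)
  n_loci <- 20
  drop_tm <- sample(c(TRUE, FALSE), n_loci, replace = TRUE)
  drop_dom <- ifelse(drop_tm, sample(c(TRUE, FALSE), n_loci, replace = TRUE),
                     FALSE)
  sets <- lapply(seq_len(n_loci), function(k) {
    isoform_fixture(sprintf("LOC%03d", k), drop_tm[k], drop_dom[k], seed = k)
  })
  isoforms <- dplyr::bind_rows(lapply(sets, function(s) {
    dplyr::bind_rows(
      dplyr::mutate(s$reference, locus = s$locus),
      dplyr::mutate(s$variants, locus = s$locus)
    )
  }))
  domains <- dplyr::bind_rows(lapply(sets, function(s) {
    tibble::tibble(protein_id = s$reference$id,
                   start = s$domain[1], end = s$domain[2])
  }))
  calls <- screen_als(isoforms, domains)
  planted <- vapply(sets, function(s) s$truth_flagged, logical(1))
  expect_equal(nrow(calls), n_loci)
  expect_equal(calls$flagged,
               planted[match(calls$locus, vapply(sets, `[[`, "", "locus"))])
})

test_that("ALS fractions reproduce printed worked examples", {
  expect_equal(als_fraction(19, 64)$percent, 30)
  expect_equal(als_fraction(59, 111)$percent, 53)
  expect_equal(als_fraction(0, 10)$percent, 0)
  expect_error(als_fraction(0, 0), "at least one")
  calls <- tibble::tibble(locus = c("a", "b", "c"),
                          flagged = c(TRUE, FALSE, TRUE))
  expect_equal(als_fraction(calls)$percent, 67)
})
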