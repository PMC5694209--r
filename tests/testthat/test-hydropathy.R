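test_that("profile of constant and degenerate sequences is exact", {
  kd <- hydro_params(scale = "KD")
  expect_equal(hydropathy_profile(strrep("L", 30), kd), rep(3.8, 30))
  expect_equal(hydropathy_profile("M", kd), 1.9)
  # X scores 0 on every scale
  expect_equal(hydropathy_profile(strrep("X", 5)), rep(0, 5))
})

test_that("profile equals the brute-force oracle on random sequences", {
  withr::local_seed(301)
  params_list <- list(
    hydro_params(),                                  # GES defaults
    hydro_params(scale = "KD"),
    hydro_params(core_len = 7, wedge_len = 3),
    hydro_params(core_len = 9, wedge_len = 0)
  )
  for (rep in 1:50) {
    seq <- random_aa(sample(10:500, 1))
    params <- params_list[[sample(length(params_list), 1)]]
    expect_equal(hydropathy_profile(seq, params),
                 brute_force_profile(seq, params), tolerance = 1e-9)
  }
})

test_that("more hydrophobic substitutions never decrease the profile", {
  withr::local_seed(33)
  params <- hydro_params()
  scale <- hydro_scale("GES")
  for (rep in 1:20) {
    seq <- random_aa(60)
    letters <- strsplit(seq, "")[[1]]
    p <- sample(60, 1)
    # replace by a residue at least as hydrophobic
    stronger <- names(scale)[scale >= scale[[letters[p]]]]
    letters[p] <- sample(stronger, 1)
    prof0 <- hydropathy_profile(seq, params)
    prof1 <- hydropathy_profile(paste(letters, collapse = ""), params)
    expect_true(all(prof1 - prof0 >= -1e-12))
  }
})

test_that("segment calling follows cutoff, merge and length rules", {
  params <- hydro_params(lower_cutoff = 0.6, upper_cutoff = 1.0,
                         min_helix_len = 17, min_loop_len = 2)
  # whole 25-L homopolymer above cutoff -> one certain span
  prof <- hydropathy_profile(strrep("L", 25), hydro_params(scale = "KD"))
  seg <- find_tm_segments(prof, params)
  expect_equal(seg, tibble::tibble(start = 1L, end = 25L,
                                   certainty = "certain"))
  # all below cutoff -> none
  prof_s <- hydropathy_profile(strrep("S", 30), hydro_params(scale = "KD"))
  expect_equal(nrow(find_tm_segments(prof_s, params)), 0)
  # two above-cutoff runs separated by 1 residue merge (gap < min_loop_len);
  # run extents enumerated by hand on the constructed profile
  prof_gap <- c(rep(0.8, 10), 0.1, rep(0.8, 10))
  seg2 <- find_tm_segments(prof_gap, params)
  expect_equal(seg2[, c("start", "end")], tibble::tibble(start = 1L, end = 21L))
  expect_equal(seg2$certainty, "putative")  # peak 0.8 < upper cutoff
  # same two runs with a 2-residue gap stay apart and both fail min length
  prof_gap2 <- c(rep(0.8, 10), 0.1, 0.1, rep(0.8, 10))
  expect_equal(nrow(find_tm_segments(prof_gap2, params)), 0)
  # certainty from the peak
  prof_peak <- c(rep(0.8, 8), 1.5, rep(0.8, 11))
  expect_equal(find_tm_segments(prof_peak, params)$certainty, "certain")
})

test_that("positive-inside orientation follows loop K/R counts", {
  span <- tibble::tibble(start = 11, end = 30)
  # K-rich N-terminal loop forces first-loop-inside
  seq_in <- paste0("KKK", strrep("S", 7), strrep("L", 20), strrep("S", 10))
  expect_equal(substr(orient_topology(seq_in, span), 1, 1), "i")
  # K-rich C-terminal loop flips the orientation
  seq_out <- paste0(strrep("S", 10), strrep("L", 20), "KKKK", strrep("S", 6))
  expect_equal(substr(orient_topology(seq_out, span), 1, 1), "o")
  # tie (no charges anywhere): first loop inside
  seq_tie <- paste0(strrep("S", 10), strrep("L", 20), strrep("S", 10))
  expect_equal(substr(orient_topology(seq_tie, span), 1, 1), "i")
  # no spans: soluble default, all inside
  expect_equal(orient_topology("MKTA", mtfscan:::empty_spans()), "iiii")
  # charge window: K residues farther than the window from any span
  # do not count
  far_k <- paste0("KKKK", strrep("S", 26), strrep("L", 20),
                  strrep("S", 10), "KK")
  # N-loop has 4 K beyond window 15 from span (loop is 1..30, span at 31);
  # window counts residues 16..30 only, so C-side 2 K win
  expect_equal(
    substr(orient_topology(far_k, tibble::tibble(start = 31, end = 50), 15), 1, 1),
    "o"
  )
})

test_that("orientation flip property: KKKK at the N-loop end forces first-loop-inside", {
  withr::local_seed(44)
  for (rep in 1:10) {
    gen <- plant_tm_protein(1, sample(c("M", "C"), 1), 200, seed = rep)
    # append KKKK to the end of the N-terminal loop, inside the charge window
    s <- gen$spans$start[1]
    seq <- paste0(substr(gen$protein$seq, 1, s - 1), "KKKK",
                  substr(gen$protein$seq, s, 200))
    spans <- dplyr::mutate(gen$spans, start = start + 4, end = end + 4)
    expect_equal(substr(orient_topology(seq, spans), 1, 1), "i")
  }
})

test_that("the composed predictor recovers planted helices and ignores decoys", {
  pred0 <- predict_topology_hydro(soluble_decoy(200, seed = 1))
  expect_equal(pred0$n_tm, 0)
  gen <- plant_tm_protein(1, "M", 100, seed = 7)
  pred1 <- predict_topology_hydro(gen$protein)
  expect_equal(pred1$n_tm, 1)
  expect_lt(abs(mean(unlist(pred1$spans[[1]][, 1:2])) -
                mean(unlist(gen$spans[1, 1:2]))), 3.01)
  gen2 <- plant_tm_protein(2, c("N", "C"), 300, seed = 8)
  pred2 <- predict_topology_hydro(gen2$protein)
  expect_equal(pred2$n_tm, 2)
  expect_true(all(pred2$spans[[1]]$start == sort(pred2$spans[[1]]$start)))
  expect_equal(pred2$predictor, "hydro-builtin")
})
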