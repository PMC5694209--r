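topo <- function(start, end, len = 60, id = "P", predictor = "x",
                 first_loop = "i") {
  spans <- if (is.null(start)) NULL else {
    tibble::tibble(start = start, end = end, certainty = "certain")
  }
  new_topology(id, predictor, spans = spans, length = len,
               first_loop = first_loop)
}

test_that("agreement needs matching span count, overlap and orientation", {
  a <- topo(10, 30)
  expect_true(topologies_agree(a, a))                      # reflexive
  expect_true(topologies_agree(a, topo(26, 46)))           # overlap 5
  expect_false(topologies_agree(a, topo(27, 47)))          # overlap 4
  expect_false(topologies_agree(a, topo(c(10, 40), c(30, 55))))  # 1 vs 2 spans
  expect_false(topologies_agree(a, topo(10, 30, first_loop = "o")))
  expect_true(topologies_agree(topo(NULL, NULL), topo(NULL, NULL)))
  expect_error(topologies_agree(a, topo(10, 30, len = 61)), "different lengths")
})

test_that("agreement is reflexive and symmetric on random prediction pairs", {
  withr::local_seed(88)
  random_spans_for <- function(len) {
    s <- random_topology()$spans[[1]]
    s[s$end <= len, ]
  }
  for (rep in 1:40) {
    len <- sample(80:150, 1)
    a <- new_topology("P", "a", spans = random_spans_for(len), length = len,
                      first_loop = sample(c("i", "o"), 1))
    b <- new_topology("P", "b", spans = random_spans_for(len), length = len,
                      first_loop = sample(c("i", "o"), 1))
    expect_true(topologies_agree(a, a))
    expect_true(topologies_agree(b, b))
    expect_equal(topologies_agree(a, b), topologies_agree(b, a))
  }
})

test_that("greedy consensus clusters, counts support and breaks ties", {
  # six identical predictions: support 6
  preds <- dplyr::bind_rows(lapply(1:6, function(k) {
    topo(10, 30, predictor = paste0("p", k))
  }))
  cons <- consensus_topology(preds)
  expect_equal(cons$support, 6L)
  expect_equal(cons$n_tm, 1L)

  # support n for every n (same prediction repeated)
  for (n in c(1, 3, 5)) {
    p <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
      topo(12, 32, predictor = paste0("p", k))
    }))
    expect_equal(consensus_topology(p)$support, as.integer(n))
  }

  # 4 agreeing 1-span vs 2 agreeing 0-span: membrane wins with support 4
  mixed <- dplyr::bind_rows(
    lapply(1:4, function(k) topo(10, 30, predictor = paste0("m", k))),
    lapply(1:2, function(k) topo(NULL, NULL, predictor = paste0("s", k)))
  )
  cons2 <- consensus_topology(mixed)
  expect_equal(cons2$support, 4L)
  expect_equal(cons2$n_tm, 1L)
  expect_equal(cons2$n_classes, 2L)

  # 3 vs 3 tie: the class founded by the highest-priority predictor wins
  tie <- dplyr::bind_rows(
    lapply(1:3, function(k) topo(10, 30, predictor = paste0("mem", k))),
    lapply(1:3, function(k) topo(NULL, NULL, predictor = paste0("sol", k)))
  )
  win_mem <- consensus_topology(tie, priority = c("mem1", "sol1"))
  expect_equal(win_mem$n_tm, 1L)
  win_sol <- consensus_topology(tie, priority = c("sol1", "mem1"))
  expect_equal(win_sol$n_tm, 0L)

  expect_error(consensus_topology(preds[0, ]), "at least one")
})

test_that("TMHMM posterior filter applies a strict span-mean threshold", {
  pred <- topo(10, 30, len = 40, predictor = "TMHMM")
  keep <- filter_tmhmm(pred, rep(0.95, 40))
  expect_equal(keep$n_tm, 1L)
  expect_equal(keep$span_conf[[1]], 0.95)
  # exactly at the threshold: dropped (strict inequality)
  expect_equal(filter_tmhmm(pred, rep(0.90, 40))$n_tm, 0L)
  # mean over the span decides: 0.99 over 11 residues, 0.50 over 10
  track <- rep(1, 40)
  track[10:30] <- c(rep(0.99, 11), rep(0.50, 10))
  expect_equal(mean(track[10:30]), 0.7566667, tolerance = 1e-6)
  expect_equal(filter_tmhmm(pred, track)$n_tm, 0L)
  # min statistic is stricter than mean
  track2 <- rep(0.95, 40); track2[15] <- 0.5
  expect_equal(filter_tmhmm(pred, track2, statistic = "mean")$n_tm, 1L)
  expect_equal(filter_tmhmm(pred, track2, statistic = "min")$n_tm, 0L)
  expect_error(filter_tmhmm(pred, rep(0.95, 39)), "does not match")
  expect_warning(out <- filter_tmhmm(pred, NULL), "unfiltered")
  expect_equal(out$n_tm, 1L)
})

test_that("branch merge is the union, with consensus spans preferred", {
  cons <- consensus_all(dplyr::bind_rows(
    topo(10, 30, id = "A", predictor = "p1"),
    topo(10, 30, id = "B", predictor = "p1"),
    topo(NULL, NULL, id = "C", predictor = "p1")
  ))
  tmhmm <- dplyr::bind_rows(
    topo(12, 32, id = "B", predictor = "TMHMM"),
    topo(20, 40, id = "D", predictor = "TMHMM")
  )
  merged <- merge_branches(cons, tmhmm)
  expect_setequal(merged$id, c("A", "B", "D"))
  expect_equal(merged$provenance[merged$id == "A"], "consensus")
  expect_equal(merged$provenance[merged$id == "B"], "consensus+tmhmm")
  expect_equal(merged$provenance[merged$id == "D"], "tmhmm")
  # doubly-called protein keeps the consensus spans
  expect_equal(merged$spans[merged$id == "B"][[1]]$start, 10L)
  # called by neither branch: absent
  expect_false("C" %in% merged$id)
})

test_that("merged set equals the union of branch calls on random inputs", {
  withr::local_seed(99)
  for (rep in 1:25) {
    ids <- sprintf("P%02d", 1:12)
    cons_rows <- lapply(ids, function(id) {
      t <- random_topology(id, "p1"); consensus_topology(t)
    })
    cons <- dplyr::bind_rows(cons_rows)
    tm <- dplyr::bind_rows(lapply(sample(ids, 6), function(id) {
      random_topology(id, "TMHMM")
    }))
    merged <- merge_branches(cons, tm)
    union_ids <- union(cons$protein_id[cons$n_tm >= 1],
                       tm$protein_id[tm$n_tm >= 1])
    expect_setequal(merged$id, union_ids)
    expect_gte(nrow(merged), max(sum(cons$n_tm >= 1), sum(tm$n_tm >= 1)))
    expect_true(all(merged$n_tm >= 1))
  }
})

test_that("consensus recovers planted labels from a noisy predictor panel", {
  fx <- genome_fixture(n_species = 1, n_tf_per_species = 60,
                       mtf_fraction = 0.3, seed = 21)
  panel <- simulate_predictor_panel(fx$truth, fx$proteins, seed = 4)
  cons <- consensus_all(panel)
  truth_label <- fx$truth$is_mtf[match(cons$protein_id, fx$truth$id)]
  agreement <- mean((cons$n_tm >= 1) == truth_label)
  expect_gte(agreement, 0.98)
  expect_true(all(cons$support == 5))  # 5 of 6 simulated predictors correct
})
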