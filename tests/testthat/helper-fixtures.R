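# Shared helpers: independent oracles and small in-code fixtures.

# Brute-force hydropathy profile: position-by-position truncated
# trapezoid-weighted mean, written without filter()/convolution so it is an
# independent oracle for hydropathy_profile().
brute_force_profile <- function(seq, params) {
  scale <- hydro_scale(params$scale)
  letters <- strsplit(toupper(seq), "")[[1]]
  vals <- unname(scale[letters])
  wedge <- params$wedge_len
  core <- params$core_len
  w <- if (wedge > 0) {
    c(rev((wedge:1) / (wedge + 1)), rep(1, core), (wedge:1) / (wedge + 1))
  } else {
    rep(1, core)
  }
  half <- (length(w) - 1) %/% 2
  n <- length(vals)
  out <- numeric(n)
  for (p in seq_len(n)) {
    num <- 0
    den <- 0
    for (off in -half:half) {
      q <- p + off
      if (q >= 1 && q <= n) {
        num <- num + w[off + half + 1] * vals[q]
        den <- den + w[off + half + 1]
      }
    }
    out[p] <- num / den
  }
  out
}

# Random amino-acid sequence over the 20 standard letters.
random_aa <- function(n) {
  paste(sample(setdiff(mtfscan:::the_amino_acids, "X"), n, replace = TRUE),
        collapse = "")
}

# Random valid topology: random span layout on a random length.
random_topology <- function(id = "P", predictor = "generic") {
  len <- sample(60:200, 1)
  n_spans <- sample(0:3, 1)
  spans <- NULL
  if (n_spans > 0) {
    pos <- 1L
    rows <- list()
    for (k in seq_len(n_spans)) {
      gap <- sample(2:15, 1)
      width <- sample(15:25, 1)
      start <- pos + gap
      end <- start + width - 1L
      if (end > len - 2L) break
      rows[[k]] <- tibble::tibble(start = start, end = end,
                                  certainty = "certain")
      pos <- end
    }
    spans <- dplyr::bind_rows(rows)
  }
  new_topology(id, predictor, spans = spans, length = len,
               first_loop = sample(c("i", "o"), 1))
}

# Exhaustive global-alignment score oracle: enumerate every monotone path of
# diagonal / gap-in-b / gap-in-a moves and score it with affine gaps
# (gap of length L scores gap_open + L * gap_extend). Independent of any
# dynamic-programming shortcut.
enumerate_best_score <- function(a, b, match = 2, mismatch = -1,
                                 gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, prev_move) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      recurse(i + 1, j + 1, score + s, "d")
    }
    if (i <= length(av)) { # gap in b
      open <- if (prev_move == "gb") 0 else gap_open
      recurse(i + 1, j, score + open + gap_extend, "gb")
    }
    if (j <= length(bv)) { # gap in a
      open <- if (prev_move == "ga") 0 else gap_open
      recurse(i, j + 1, score + open + gap_extend, "ga")
    }
  }
  recurse(1, 1, 0, "start")
  best
}
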