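# shared fixtures and independent oracles used across test files

make_table <- function(m, asv = NULL, samp = NULL) {
  asv <- asv %||% rownames(m) %||% sprintf("ASV%03d", seq_len(nrow(m)))
  samp <- samp %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(asv, samp)
  asv_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n_asv, n_samp, lambda = 20, seed = 1) {
  set.seed(seed)
  make_table(matrix(rpois(n_asv * n_samp, lambda), n_asv, n_samp))
}

# exhaustive-window oracle for local similarity: enumerate every contiguous
# aligned window at every offset |d| <= D. Reports the best positive and best
# negative window sums separately so tie-breaks between equal-magnitude
# chains of opposite sign do not enter the comparison.
brute_local_similarity <- function(zx, zy, D) {
  n <- length(zx)
  best_pos <- 0
  best_neg <- 0
  for (d in -D:D) {
    lo <- max(1L, 1L - d)
    hi <- min(n, n - d)
    for (i in lo:hi) {
      acc <- 0
      for (j in i:hi) {
        acc <- acc + zx[j] * zy[j + d]
        if (acc > best_pos) best_pos <- acc
        if (-acc > best_neg) best_neg <- -acc
      }
    }
  }
  list(ls = max(best_pos, best_neg) / n * (if (best_pos >= best_neg) 1 else -1),
       max_pos = best_pos / n, max_neg = best_neg / n)
}

# the DP's signed score must equal the oracle's best chain of that sign, and
# its magnitude the overall best
expect_matches_oracle <- function(dp, bf) {
  expect_equal(abs(dp$ls), max(bf$max_pos, bf$max_neg), tolerance = 1e-10)
  if (dp$ls >= 0) {
    expect_equal(dp$ls, bf$max_pos, tolerance = 1e-10)
  } else {
    expect_equal(-dp$ls, bf$max_neg, tolerance = 1e-10)
  }
}

# direct evaluation of the (min, max) relative-abundance partition, written
# independently of classify_asv
oracle_class <- function(p, u = 0.01, l = 1e-4) {
  lo <- min(p) < l
  hi <- max(p) >= u
  if (!lo && hi) return("AT")
  if (lo && hi) return("DT")
  if (lo && !hi) return("RT")
  "MT"
}
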