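#' Spearman correlation matrix of ASV abundance profiles
#'
#' Rank correlation (average ranks for ties) between all pairs of ASV rows,
#' the association measure used for molecular ecological network
#' construction on non-log-transformed abundances. ASVs with zero variance
#' across samples carry no rank information and are removed; their ids are
#' attached as attribute `dropped_zero_variance`.
#'
#' @param x an [asv_table()] or abundance matrix (ASVs x samples), usually
#'   after [filter_prevalence()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 4L) stop("need at least 4 samples for rank correlation")
  v <- apply(m, 1L, stats::var)
  dropped <- rownames(m)[v == 0]
  if (length(dropped)) m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 ASVs with non-zero variance")
  cc <- stats::cor(t(m), method = "spearman")
  attr(cc, "dropped_zero_variance") <- dropped
  cc
}

# Dedupe (exact within tolerance), unfold with a cubic smoothing spline on
# the cumulative spectral distribution, and test the nearest-neighbour
# spacing distribution against the Poisson (exponential) law by chi-square
# goodness of fit on equal-probability bins. Returns NA when too few
# distinct eigenvalues remain to form an NNSD.
nnsd_poisson_pvalue <- function(lambda, min_spacings = 20L, max_bins = 20L) {
  lam <- sort(lambda)
  # duplicate eigenvalues (degenerate after thresholding) carry spacing 0
  keep <- c(TRUE, diff(lam) > 1e-8)
  lam <- lam[keep]
  n <- length(lam)
  if (n < min_spacings + 1L) {
    return(list(p = NA_real_, chisq = NA_real_, n_spacings = n - 1L))
  }
  df_fit <- max(4, min(20, round(n / 5)))
  fit <- stats::smooth.spline(lam, seq_len(n), df = df_fit)
  e <- stats::predict(fit, lam)$y
  spac <- pmax(diff(e), 0)
  m <- length(spac)
  nbins <- max(5L, min(max_bins, floor(m / 5)))
  edges <- stats::qexp(seq(0, 1, length.out = nbins + 1L))
  edges[nbins + 1L] <- Inf
  obs <- table(cut(spac, edges, include.lowest = TRUE))
  expected <- m / nbins
  chisq <- sum((as.numeric(obs) - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = nbins - 1L, lower.tail = FALSE)
  list(p = p, chisq = chisq, n_spacings = m)
}

#' Scan correlation thresholds for the RMT transition
#'
#' For each candidate threshold s the correlation matrix is hard-thresholded
#' (entries with |r| < s set to zero), its eigenvalue spectrum unfolded, and
#' the nearest-neighbour spacing distribution (NNSD) tested against the
#' Poisson law exp(-d) expected for uncorrelated (random-matrix) structure.
#' Correlated signal produces Wigner-Dyson level repulsion instead, so the
#' transition to Poisson marks the noise floor.
#'
#' @param c_mat symmetric correlation matrix.
#' @param scan numeric length-2 range of thresholds.
#' @param step scan increment.
#' @return data.frame with one row per threshold: `s`, `n_edges`,
#'   `n_spacings`, `chisq`, `p_poisson`.
#' @export
rmt_scan <- function(c_mat, scan = c(0.30, 0.99), step = 0.01) {
  stopifnot(is.matrix(c_mat), nrow(c_mat) == ncol(c_mat))
  if (nrow(c_mat) < 50L) {
    warning("fewer than 50 nodes: the NNSD is based on a short spectrum")
  }
  ss <- seq(scan[1L], scan[2L], by = step)
  out <- lapply(ss, function(s) {
    a <- c_mat
    a[abs(a) < s] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    gof <- nnsd_poisson_pvalue(ev)
    off <- a
    diag(off) <- 0
    data.frame(s = s, n_edges = sum(off != 0) / 2,
               n_spacings = gof$n_spacings, chisq = gof$chisq,
               p_poisson = gof$p)
  })
  do.call(rbind, out)
}

#' Select the RMT correlation threshold
#'
#' The chosen threshold s_t is the smallest scanned value whose NNSD is
#' consistent with the Poisson law (goodness-of-fit p > `alpha`) and stays
#' consistent for the next `persistence` scan steps, guarding against
#' single-step false transitions.
#'
#' @inheritParams rmt_scan
#' @param alpha significance level for the Poisson goodness-of-fit.
#' @param persistence number of subsequent steps that must also be
#'   Poisson-consistent.
#' @return list of class `rmt_threshold`: `threshold`, `alpha`,
#'   `diagnostics` (the [rmt_scan()] table).
#' @export
rmt_threshold <- function(c_mat, scan = c(0.30, 0.99), step = 0.01,
                          alpha = 0.05, persistence = 2L) {
  diag_df <- rmt_scan(c_mat, scan = scan, step = step)
  ok <- !is.na(diag_df$p_poisson) & diag_df$p_poisson > alpha
  chosen <- NA_real_
  for (i in seq_along(ok)) {
    ahead <- seq(i, min(i + persistence, length(ok)))
    if (all(ok[ahead])) { chosen <- diag_df$s[i]; break }
  }
  if (is.na(chosen)) {
    cond <- structure(
      class = c("rmt_no_threshold", "error", "condition"),
      list(message = paste0(
             "no threshold in [", scan[1L], ", ", scan[2L],
             "] gives a Poisson-consistent NNSD; consider extending the scan"),
           call = sys.call(-1L), diagnostics = diag_df))
    stop(cond)
  }
  structure(list(threshold = chosen, alpha = alpha, diagnostics = diag_df),
            class = "rmt_threshold")
}

#' @export
print.rmt_threshold <- function(x, ...) {
  cat(sprintf("RMT threshold s_t = %.2f (Poisson GOF alpha = %g, %d thresholds scanned)\n",
              x$threshold, x$alpha, nrow(x$diagnostics)))
  invisible(x)
}
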