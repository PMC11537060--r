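perm_test_result <- function(statistic, observed, n_perm, p_value, seed,
                             extra = list()) {
  structure(c(list(statistic = statistic, observed = observed,
                   n_permutations = n_perm, p_value = p_value, seed = seed),
              extra),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$observed, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

check_groups <- function(d, groups) {
  n <- attr(stats::as.dist(d), "Size")
  if (length(groups) != n) stop("groups length does not match distance matrix")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two members")
  groups
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of between- versus within-group dissimilarity
#' ([vegan::anosim()]); R = (mean between-group rank - mean within-group
#' rank) / (M/2) with M = n(n-1)/2, p by permutation of group labels.
#'
#' @param d a `dist` object or symmetric matrix.
#' @param groups grouping factor over samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a `perm_test_result`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- check_groups(d, groups)
  set.seed(as.integer(seed))
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  perm_test_result("ANOSIM R", unname(fit$statistic), n_perm,
                   fit$signif, as.integer(seed))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from partitioned sums of squared dissimilarities (Anderson's
#' formulation, via [vegan::adonis2()]), with an R-squared effect size.
#'
#' @inheritParams anosim_test
#' @return a `perm_test_result` with `r_squared`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- check_groups(d, groups)
  df <- data.frame(group = groups)
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  perm_test_result("PERMANOVA pseudo-F", fit$F[1L], n_perm,
                   fit$`Pr(>F)`[1L], as.integer(seed),
                   extra = list(r_squared = fit$R2[1L]))
}

#' Multiple response permutation procedure (MRPP)
#'
#' delta is the group-size-weighted mean within-group dissimilarity; the
#' chance-corrected effect size A = 1 - delta / E(delta) under permutation
#' ([vegan::mrpp()]).
#'
#' @inheritParams anosim_test
#' @return a `perm_test_result` with `delta` and `A`.
#' @export
mrpp_test <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- check_groups(d, groups)
  set.seed(as.integer(seed))
  fit <- vegan::mrpp(d, groups, permutations = n_perm)
  perm_test_result("MRPP delta", fit$delta, n_perm, fit$Pvalue,
                   as.integer(seed), extra = list(delta = fit$delta,
                                                  A = fit$A))
}

#' Mantel test between two distance matrices
#'
#' Correlation over corresponding dissimilarities with significance by
#' row/column permutation of one matrix ([vegan::mantel()]). Spearman
#' correlation by default.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over the same samples.
#' @param method `"spearman"` or `"pearson"`.
#' @inheritParams anosim_test
#' @return a `perm_test_result`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size")) {
    stop("distance matrices have different sizes")
  }
  set.seed(as.integer(seed))
  fit <- vegan::mantel(d1, d2, method = method, permutations = n_perm)
  perm_test_result(paste0("Mantel r (", method, ")"), fit$statistic,
                   n_perm, fit$signif, as.integer(seed))
}

#' Variance-inflation screening of environmental variables
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing variable j on the remaining
#' variables; the highest-VIF variable is dropped iteratively while any VIF
#' exceeds the threshold (default 20), the usual collinearity screen before
#' constrained ordination. Constant variables have infinite VIF and are
#' dropped first.
#'
#' @param env numeric matrix or data.frame, samples x variables.
#' @param threshold drop variables while max VIF > threshold.
#' @return list with `retained` (variable names), `dropped` (in drop order)
#'   and `vif` (final VIFs of the retained set).
#' @export
vif_screen <- function(env, threshold = 20) {
  env <- as.data.frame(env)
  if (ncol(env) < 2L) stop("need at least two variables")
  if (anyNA(env)) stop("environmental matrix contains missing values")
  dropped <- character(0)
  repeat {
    v <- compute_vifs(env)
    if (all(is.finite(v)) && max(v) <= threshold) break
    worst <- names(v)[which.max(ifelse(is.finite(v), v, Inf))]
    # drop infinite-VIF (aliased or constant) variables before finite ones
    if (any(!is.finite(v))) worst <- names(v)[which(!is.finite(v))[1L]]
    dropped <- c(dropped, worst)
    env[[worst]] <- NULL
    if (ncol(env) < 2L) break
  }
  v <- if (ncol(env) >= 2L) compute_vifs(env) else
    stats::setNames(rep(1, ncol(env)), names(env))
  list(retained = names(env), dropped = dropped, vif = v)
}

compute_vifs <- function(env) {
  vars <- names(env)
  vapply(vars, function(j) {
    y <- env[[j]]
    if (stats::var(y) == 0) return(Inf)
    fit <- stats::lm(stats::reformulate(vars[vars != j], response = j),
                     data = env)
    # aliased predictors give a perfect fit; the Inf VIF below handles them
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}
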