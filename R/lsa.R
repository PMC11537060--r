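#' Standardize a time series for local similarity analysis
#'
#' Rank-based normal-score transform (Blom-type, average ranks for ties)
#' followed by centering and scaling to unit population standard deviation,
#' so that the LSA score of a series with itself is exactly 1.
#'
#' @param x time-ordered abundance vector (replicates already averaged),
#'   length >= 3.
#' @return standardized series with mean 0 and population sd 1.
#' @export
standardize_series <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 time points")
  if (anyNA(x)) stop("missing values in series")
  if (stats::var(x) == 0) stop("constant series cannot be standardized")
  z <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  z <- z - mean(z)
  s <- sqrt(mean(z^2))
  if (s == 0) stop("constant series cannot be standardized")
  z / s
}

#' Average replicate samples per time point
#'
#' @param x an [asv_table()] or abundance matrix (ASVs x samples).
#' @param timepoints vector (aligned with columns, or named by sample id)
#'   giving the time point of each sample.
#' @return matrix ASVs x time points (mean abundance), columns in time
#'   order.
#' @export
average_replicates <- function(x, timepoints) {
  m <- as.matrix(x)
  if (!is.null(names(timepoints))) timepoints <- timepoints[colnames(m)]
  if (length(timepoints) != ncol(m) || anyNA(timepoints)) {
    stop("every sample needs a time point")
  }
  tp <- sort(unique(timepoints))
  out <- vapply(tp, function(t) {
    rowMeans(m[, timepoints == t, drop = FALSE])
  }, numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), as.character(tp)))
}

#' Local similarity of two standardized series
#'
#' Dynamic program over partial sums of aligned products: for each offset
#' |d| <= D the positive chain P_i = max(0, P_(i-1) + zx_i * zy_(i+d)) and
#' the negative chain N_i = max(0, N_(i-1) - zx_i * zy_(i+d)) are
#' accumulated; the local similarity score is the largest chain divided by
#' the series length, signed by whether the positive or negative chain
#' attained it (positive preferred on exact ties). The reported delay d is
#' the offset at which the optimum occurred, i.e. `zy` shifted d steps
#' relative to `zx`.
#'
#' @param zx,zy standardized series of equal length (see
#'   [standardize_series()]).
#' @param D maximum alignment offset in time steps.
#' @return list with `ls` (signed score, |ls| <= 1) and `delay`.
#' @export
local_similarity <- function(zx, zy, D = 1L) {
  if (length(zx) != length(zy)) stop("series length mismatch")
  if (D < 0L || D >= length(zx)) stop("delay limit out of range")
  cpp_local_similarity(as.numeric(zx), as.numeric(zy), as.integer(D))
}

#' Local similarity analysis over all cross-table ASV pairs
#'
#' Standardizes every series, computes the LSA score and optimal delay for
#' every pair (one ASV from `a`, one from `b`), and attaches a two-sided
#' permutation p-value (fraction of time-permuted scores with |LS| at least
#' the observed |LS|, add-one corrected) and a Benjamini-Hochberg q-value
#' across all pairs. One shared set of seeded time permutations is used for
#' all pairs. ASVs with constant series are dropped with a message and
#' recorded in the `dropped_constant` attribute.
#'
#' @param a,b matrices of time series (ASVs x time points, replicates
#'   already averaged, shared ordered time axis), e.g. from
#'   [average_replicates()].
#' @param D maximum delay in time steps.
#' @param n_perm number of time permutations.
#' @param seed integer seed.
#' @param q_max significance threshold on the BH q-value.
#' @return data.frame of class `lsa_result` (asv_a, asv_b, ls, delay, p, q,
#'   significant).
#' @export
lsa_all_pairs <- function(a, b, D = 1L, n_perm = 999L, seed = 1L,
                          q_max = 0.05) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("tables must share the time axis")
  n <- ncol(a)
  drop_const <- c(rownames(a)[apply(a, 1L, stats::var) == 0],
                  rownames(b)[apply(b, 1L, stats::var) == 0])
  if (length(drop_const)) {
    message(length(drop_const), " constant series dropped from LSA")
  }
  a <- a[apply(a, 1L, stats::var) > 0, , drop = FALSE]
  b <- b[apply(b, 1L, stats::var) > 0, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("no non-constant series left")
  za <- t(apply(a, 1L, standardize_series))
  zb <- t(apply(b, 1L, standardize_series))
  set.seed(as.integer(seed))
  perms <- t(replicate(n_perm, sample.int(n)))
  res <- cpp_lsa_batch(za, zb, as.integer(D), perms)
  out <- data.frame(
    asv_a = rep(rownames(a), times = nrow(b)),
    asv_b = rep(rownames(b), each = nrow(a)),
    ls = as.vector(res$ls), delay = as.vector(res$delay),
    p = (as.vector(res$exceed) + 1) / (n_perm + 1),
    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_max
  attr(out, "dropped_constant") <- drop_const
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("lsa_result", class(out))
  out
}

#' Summarize a bipartite association network
#'
#' Positive/negative edge fractions over the significant LSA pairs, broken
#' down into within-habitat and between-habitat (sponge vs seawater) edges,
#' and optionally per-phylum edge counts.
#'
#' @param results an `lsa_result` from [lsa_all_pairs()] (or any data.frame
#'   with asv_a, asv_b, ls, significant).
#' @param groups named vector mapping every ASV id to `"sponge"` or
#'   `"seawater"`.
#' @param taxonomy optional named vector mapping ASV ids to phyla.
#' @return list with `n_edges`, `frac_positive`, `frac_negative`,
#'   `breakdown` (within/between habitat data.frame), and `per_phylum`
#'   (when taxonomy given).
#' @export
bipartite_summary <- function(results, groups, taxonomy = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  nodes <- unique(c(results$asv_a, results$asv_b))
  unmapped <- setdiff(nodes, names(groups))
  if (length(unmapped)) {
    stop("nodes without habitat mapping: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  n <- nrow(sig)
  if (n == 0L) {
    return(list(n_edges = 0L, frac_positive = 0, frac_negative = 0,
                breakdown = data.frame(), per_phylum = NULL))
  }
  pos <- sig$ls > 0
  ha <- groups[sig$asv_a]
  hb <- groups[sig$asv_b]
  scope <- ifelse(ha == hb, "within", "between")
  breakdown <- do.call(rbind, lapply(unique(scope), function(sc) {
    sel <- scope == sc
    data.frame(scope = sc, n_edges = sum(sel),
               frac_positive = mean(pos[sel]),
               frac_negative = mean(!pos[sel]),
               stringsAsFactors = FALSE)
  }))
  per_phylum <- NULL
  if (!is.null(taxonomy)) {
    phy <- c(taxonomy[sig$asv_a], taxonomy[sig$asv_b])
    per_phylum <- as.data.frame(table(phylum = phy),
                                stringsAsFactors = FALSE)
    names(per_phylum)[2L] <- "n_edge_ends"
  }
  list(n_edges = n, frac_positive = mean(pos), frac_negative = mean(!pos),
       breakdown = breakdown, per_phylum = per_phylum)
}

#' Write significant LSA edges to TSV
#'
#' @param results an `lsa_result`.
#' @param groups named habitat vector as in [bipartite_summary()].
#' @param path output TSV.
#' @export
write_lsa_edges <- function(results, groups, path) {
  sig <- results[results$significant, , drop = FALSE]
  sig$habitat_a <- unname(groups[sig$asv_a])
  sig$habitat_b <- unname(groups[sig$asv_b])
  utils::write.table(sig, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
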