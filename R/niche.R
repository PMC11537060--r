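#' Levins niche breadth of one ASV
#'
#' B = 1 / sum(P_j^2) where P_j is the proportion of the ASV's abundance
#' found in resource state j (the vector is renormalized internally). B
#' ranges from 1 (complete specialist, one state) to r (uniform generalist
#' over r states).
#'
#' @param p non-negative abundance (or proportion) vector over resource
#'   states.
#' @return the niche breadth B.
#' @export
levins_width <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("empty state vector")
  if (anyNA(p) || any(p < 0)) stop("state abundances must be non-negative")
  tot <- sum(p)
  if (tot <= 0) stop("ASV absent from every state")
  p <- p / tot
  1 / sum(p^2)
}

#' Community-level Levins niche breadth
#'
#' Computes B for every ASV from its distribution across resource states and
#' averages over the included ASVs. By default each sample is its own
#' resource state (replicates kept separate); `states` can map samples to
#' coarser states, in which case P_ij derives from the mean relative
#' abundance of ASV i over the samples of state j, renormalized across
#' states.
#'
#' @param x an [asv_table()].
#' @param states optional character/factor vector mapping each sample (in
#'   column order, or named by sample id) to a state; default: one state per
#'   sample.
#' @param min_occupancy include ASVs present in at least this many states.
#' @return list of class `niche_width_result`: `per_asv` (data.frame asv_id,
#'   B, n_states_occupied), `community_mean_B`, `community_se_B`, `r`.
#' @export
community_niche_width <- function(x, states = NULL, min_occupancy = 1L) {
  m <- to_relative(x)
  if (is.null(states)) {
    states <- colnames(m)
  } else {
    if (!is.null(names(states))) {
      missing <- setdiff(colnames(m), names(states))
      if (length(missing)) {
        stop("samples without a state mapping: ",
             paste(missing, collapse = ", "))
      }
      states <- states[colnames(m)]
    } else if (length(states) != ncol(m)) {
      stop("states must cover every sample")
    }
    if (anyNA(states)) stop("samples without a state mapping")
  }
  states <- as.factor(as.character(states))
  r <- nlevels(states)
  # mean relative abundance of each ASV within each state
  agg <- vapply(levels(states), function(s) {
    rowMeans(m[, states == s, drop = FALSE])
  }, numeric(nrow(m)))
  agg <- matrix(agg, nrow = nrow(m),
                dimnames = list(rownames(m), levels(states)))
  occupied <- rowSums(agg > 0)
  keep <- occupied >= min_occupancy & rowSums(agg) > 0
  B <- apply(agg[keep, , drop = FALSE], 1L, levins_width)
  per_asv <- data.frame(asv_id = rownames(agg)[keep], B = unname(B),
                        n_states_occupied = unname(occupied[keep]),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_asv = per_asv,
                 community_mean_B = mean(per_asv$B),
                 community_se_B = stats::sd(per_asv$B) /
                   sqrt(max(1L, nrow(per_asv))),
                 r = r),
            class = "niche_width_result")
}

#' @export
print.niche_width_result <- function(x, ...) {
  cat(sprintf("Levins niche breadth over %d states: mean B = %.3f (SE %.3f, %d ASVs)\n",
              x$r, x$community_mean_B, x$community_se_B, nrow(x$per_asv)))
  invisible(x)
}
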