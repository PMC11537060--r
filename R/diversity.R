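#' Alpha diversity of one sample
#'
#' Shannon uses natural logarithms; Pielou evenness is H / ln(richness);
#' inverse Simpson is 1 / sum(p^2), also the effective number of species.
#' Index computation is delegated to vegan.
#'
#' @param counts non-negative count (or abundance) vector for one sample.
#' @param index one of `"richness"`, `"shannon"`, `"simpson"`,
#'   `"invsimpson"`, `"pielou"`.
#' @return the index value.
#' @export
alpha_diversity <- function(counts,
                            index = c("richness", "shannon", "simpson",
                                      "invsimpson", "pielou")) {
  index <- match.arg(index)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("sample has zero total count")
  switch(index,
    richness = sum(counts > 0),
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    simpson = unname(vegan::diversity(counts, index = "simpson")),
    invsimpson = unname(vegan::diversity(counts, index = "invsimpson")),
    pielou = {
      s <- sum(counts > 0)
      if (s < 2L) 0 else
        unname(vegan::diversity(counts, index = "shannon")) / log(s)
    })
}

#' Alpha diversity for every sample of a table
#'
#' @param x an [asv_table()] or count matrix (ASVs x samples).
#' @param indices character vector of indices (see [alpha_diversity()]).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(x, indices = c("richness", "shannon",
                                                 "invsimpson", "pielou")) {
  m <- as.matrix(x)
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (idx in indices) {
    out[[idx]] <- apply(m, 2L, alpha_diversity, index = idx)
  }
  out
}

#' Effective number of species (neff)
#'
#' The inverse Simpson index, used to judge whether a composition is
#' high-diversity in the correlation-method selection heuristic.
#'
#' @param counts count vector for one sample.
#' @return neff value.
#' @export
effective_species <- function(counts) {
  alpha_diversity(counts, "invsimpson")
}

#' Choose a pairwise-association method for a data set
#'
#' Encodes the published heuristic for picking among correlation-type methods:
#' local similarity analysis (LSA) is appropriate when the composition is not
#' high-diversity (median neff below 13 fails), the table is less than 50%
#' sparse, and the samples form a time series. When any criterion fails, the
#' failing criteria are reported instead.
#'
#' @param neff effective number of species (scalar, e.g. the median across
#'   samples).
#' @param sparsity_frac fraction of zero cells in the ASV table.
#' @param is_time_series logical.
#' @param neff_min,sparsity_max heuristic cutoffs (defaults 13 and 0.5).
#' @return list with `method` (`"LSA"` or `NA`) and `failed_criteria`
#'   (character vector, empty when LSA is selected).
#' @export
choose_correlation_method <- function(neff, sparsity_frac, is_time_series,
                                      neff_min = 13, sparsity_max = 0.5) {
  failed <- character(0)
  if (neff < neff_min) failed <- c(failed, sprintf("neff < %g", neff_min))
  if (sparsity_frac >= sparsity_max) {
    failed <- c(failed, sprintf("sparsity >= %g", sparsity_max))
  }
  if (!is_time_series) failed <- c(failed, "not a time series")
  list(method = if (length(failed)) NA_character_ else "LSA",
       failed_criteria = failed)
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum(|x - y|) / sum(x + y) over ASVs, computed with
#' [vegan::vegdist()]. Works on counts or relative abundances; on
#' relative-abundance input values lie in \[0, 1\].
#'
#' @param x an [asv_table()] or abundance matrix (ASVs x samples).
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two samples")
  if (any(colSums(m) <= 0)) {
    stop("sample(s) with zero total: ",
         paste(colnames(m)[colSums(m) <= 0], collapse = ", "))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomerative clustering; the tree is returned as an ape
#' `phylo` object whose branch lengths place each merge at half its
#' cophenetic distance.
#'
#' @param d a `dist` object (e.g. from [bray_curtis()]).
#' @return a `phylo` tree; write with [ape::write.tree()].
#' @export
upgma_tree <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("need at least two samples to cluster")
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Cophenetic distances of a dendrogram
#'
#' @param tree a `phylo` tree from [upgma_tree()].
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
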