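#' Classify one ASV by its relative-abundance profile
#'
#' Partition of the (min, max) relative-abundance plane with an upper
#' threshold `u` (default 1%) and a lower threshold `l` (default 0.01%):
#' \describe{
#'   \item{AT}{abundant taxa — at or above `l` in every sample and reaching
#'     `u` in at least one (includes ASVs above `u` everywhere).}
#'   \item{DT}{dominant taxa — below `l` in some samples yet at or above `u`
#'     in others.}
#'   \item{RT}{rare taxa — below `l` somewhere and never reaching `u`
#'     (includes ASVs below `l` everywhere).}
#'   \item{MT}{moderate taxa — always at or above `l` but never reaching `u`;
#'     this cell of the partition is unnamed in the three-class scheme and is
#'     reported explicitly rather than forced into a class.}
#' }
#' Thresholds are inclusive at `l` and `u` ("at least"), strict below.
#'
#' @param p numeric vector of per-sample relative abundances in \[0, 1\].
#' @param u,l upper (abundant) and lower (rare) thresholds.
#' @return one of `"AT"`, `"DT"`, `"RT"`, `"MT"`.
#' @export
classify_asv <- function(p, u = 0.01, l = 1e-4) {
  if (length(p) == 0L) stop("empty abundance profile")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("relative abundances must lie in [0, 1]")
  }
  m <- min(p)
  M <- max(p)
  if (m >= l) {
    if (M >= u) "AT" else "MT"
  } else {
    if (M >= u) "DT" else "RT"
  }
}

#' Classify every ASV of a relative-abundance table
#'
#' @param r relative-abundance matrix from [to_relative()] (ASVs x samples).
#' @param u,l thresholds passed to [classify_asv()].
#' @return an object of class `abundance_classes`: a list with
#'   `classes` (data.frame: asv_id, min_relabund, max_relabund, label) and
#'   `summary` (per-label counts, fraction of ASVs, fraction of reads).
#' @export
classify_table <- function(r, u = 0.01, l = 1e-4) {
  m <- as.matrix(r)
  if (nrow(m) < 1L) stop("empty table")
  mins <- apply(m, 1L, min)
  maxs <- apply(m, 1L, max)
  label <- ifelse(mins >= l, ifelse(maxs >= u, "AT", "MT"),
                  ifelse(maxs >= u, "DT", "RT"))
  classes <- data.frame(asv_id = rownames(m), min_relabund = mins,
                        max_relabund = maxs, label = label,
                        row.names = NULL, stringsAsFactors = FALSE)
  lev <- c("AT", "DT", "MT", "RT")
  n <- table(factor(label, levels = lev))
  reads <- vapply(lev, function(cl) {
    sum(m[label == cl, , drop = FALSE])
  }, numeric(1))
  summary <- data.frame(label = lev, n_asv = as.integer(n),
                        frac_asvs = as.numeric(n) / nrow(m),
                        frac_reads = reads / sum(m),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(classes = classes, summary = summary, u = u, l = l),
            class = "abundance_classes")
}

#' @export
print.abundance_classes <- function(x, ...) {
  cat(sprintf("Abundance classes (u = %g, l = %g) over %d ASVs:\n",
              x$u, x$l, nrow(x$classes)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write abundance class assignments to TSV
#'
#' @param x an `abundance_classes` object.
#' @param path output TSV (asv_id, min_relabund, max_relabund, label).
#' @export
write_abundance_classes <- function(x, path) {
  stopifnot(inherits(x, "abundance_classes"))
  utils::write.table(x$classes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
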