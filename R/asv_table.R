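#' Construct a validated ASV count table
#'
#' An `asv_table` is an integer count matrix with ASVs as rows and samples as
#' columns, the universal input of the workflow. Row and column names are the
#' ASV and sample identifiers and must be unique.
#'
#' @param counts numeric matrix of non-negative whole numbers (ASV x sample).
#' @param asv_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return an object of class `asv_table` (a named integer matrix).
#' @export
asv_table <- function(counts, asv_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("ASV table format error: counts must be numeric")
  }
  if (is.null(asv_ids) || is.null(sample_ids)) {
    stop("ASV table requires ASV and sample identifiers")
  }
  asv_ids <- as.character(asv_ids)
  sample_ids <- as.character(sample_ids)
  if (length(asv_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop("identifier lengths do not match the count matrix")
  }
  if (anyDuplicated(asv_ids)) {
    stop("ASV table format error: duplicate ASV ids: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("ASV table format error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("ASV table format error: non-finite or missing counts")
  }
  if (any(counts < 0)) {
    stop("ASV table format error: negative counts")
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("ASV table format error: counts must be whole numbers")
  }
  if (nrow(counts) < 1L) stop("ASV table needs at least one ASV")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(asv_ids, sample_ids)
  class(counts) <- c("asv_table", class(matrix()))
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d ASVs x %d samples, %s reads\n",
              nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

is_asv_table <- function(x) inherits(x, "asv_table")

as_plain_matrix <- function(x) {
  class(x) <- "matrix"
  attr(x, "rel_abundance") <- NULL
  x
}

#' Read an ASV table from TSV or BIOM-JSON
#'
#' TSV layout: header row of sample ids, first column `asv_id`, tab-separated
#' counts. BIOM-JSON v1.0 is parsed with the biomformat package.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("ASV table format error: no sample columns")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("ASV table format error: non-numeric counts")
    rownames(m) <- ids
    asv_table(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    asv_table(m)
  }
}

#' Write an ASV table to TSV or BIOM-JSON
#'
#' @param x an [asv_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_asv_table <- function(x, path, format = c("tsv", "biom")) {
  stopifnot(is_asv_table(x))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(asv_id = rownames(x), as_plain_matrix(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(as_plain_matrix(x))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample column is divided by its total so that columns sum to one.
#'
#' @param x an [asv_table()] or plain count matrix.
#' @return a numeric matrix of proportions with attribute
#'   `rel_abundance = TRUE`.
#' @export
to_relative <- function(x) {
  m <- if (is_asv_table(x)) as_plain_matrix(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[tot <= 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  r <- sweep(m, 2L, tot, "/")
  attr(r, "rel_abundance") <- TRUE
  r
}

#' Rarefy an ASV table to even depth
#'
#' Subsamples every sample without replacement to `depth` reads
#' (via [vegan::rrarefy()]), the usual normalization step that makes richness
#' and relative-abundance thresholds comparable across libraries.
#'
#' @param x an [asv_table()].
#' @param depth target reads per sample; must not exceed any sample total.
#' @param seed integer seed for reproducibility.
#' @return a rarefied [asv_table()].
#' @export
rarefy_table <- function(x, depth, seed = 1L) {
  stopifnot(is_asv_table(x))
  tot <- colSums(as_plain_matrix(x))
  if (any(tot < depth)) {
    bad <- colnames(x)[tot < depth]
    stop("rarefaction depth ", depth, " exceeds total of sample(s): ",
         paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  m <- as_plain_matrix(x)
  if (nrow(m) == 1L) {
    # degenerate single-ASV community: every draw is that ASV
    sub <- matrix(as.integer(depth), 1L, ncol(m), dimnames = dimnames(m))
    return(asv_table(sub))
  }
  # vegan warns when a table has no singleton counts; synthetic and
  # pre-filtered tables legitimately lack them
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  asv_table(sub)
}

#' Filter ASVs by prevalence
#'
#' Keeps ASVs detected (count > 0) in strictly more than `min_sample_frac` of
#' the samples; the default retains ASVs present in more than half of the
#' samples, the usual inclusion rule before network construction.
#'
#' @param x an [asv_table()].
#' @param min_sample_frac prevalence cutoff in (0, 1); strict inequality.
#' @return the filtered [asv_table()] (possibly with zero rows).
#' @export
filter_prevalence <- function(x, min_sample_frac = 0.5) {
  stopifnot(is_asv_table(x))
  m <- as_plain_matrix(x)
  keep <- rowMeans(m > 0) > min_sample_frac
  out <- m[keep, , drop = FALSE]
  class(out) <- c("asv_table", "matrix", "array")
  out
}

#' Unique and shared ASVs between two communities
#'
#' Counts ASVs detected (nonzero total) in each table and in both, the numbers
#' behind a two-set Venn diagram of host versus seawater communities.
#'
#' @param a,b [asv_table()] objects.
#' @return list with `n_a`, `n_b`, `n_shared`, `frac_of_a`, `frac_of_b`.
#' @export
shared_asv_summary <- function(a, b) {
  det_a <- rownames(a)[rowSums(as_plain_matrix(a)) > 0]
  det_b <- rownames(b)[rowSums(as_plain_matrix(b)) > 0]
  shared <- intersect(det_a, det_b)
  list(n_a = length(det_a), n_b = length(det_b), n_shared = length(shared),
       frac_of_a = if (length(det_a)) length(shared) / length(det_a) else 0,
       frac_of_b = if (length(det_b)) length(shared) / length(det_b) else 0)
}

#' Merge ASV tables over the union of their ASV ids
#'
#' Missing ASV/sample combinations are filled with zero counts. Sample ids
#' must be disjoint.
#'
#' @param ... [asv_table()] objects.
#' @return an [asv_table()] on the union of ASV ids.
#' @export
merge_asv_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is_asv_table(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, is_asv_table, logical(1))))
  ids <- unique(unlist(lapply(tabs, rownames)))
  samp <- unlist(lapply(tabs, colnames))
  if (anyDuplicated(samp)) stop("sample ids overlap between tables")
  out <- matrix(0L, length(ids), length(samp), dimnames = list(ids, samp))
  for (t in tabs) out[rownames(t), colnames(t)] <- as_plain_matrix(t)
  asv_table(out)
}

#' Read a sample metadata table
#'
#' TSV keyed by `sample_id` with the design factors (host, phenotype,
#' habitat, month, replicate) and any environmental columns.
#'
#' @param path TSV file.
#' @return a data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' Check that metadata covers an ASV table
#'
#' @param x an [asv_table()].
#' @param metadata data.frame with a `sample_id` column.
#' @return invisibly TRUE; errors listing uncovered samples otherwise.
#' @export
validate_metadata <- function(x, metadata) {
  missing <- setdiff(colnames(x), metadata$sample_id)
  if (length(missing)) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
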