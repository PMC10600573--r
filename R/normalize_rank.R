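#' Read a gene-level count matrix from a TSV file
#'
#' Reads an htseq-count style table: first column gene identifiers, remaining
#' columns integer counts, one column per sample. Summary rows emitted by
#' htseq-count (ids beginning with `"__"`, e.g. `__no_feature`) are dropped.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param sample_groups Optional named character vector (or path to a
#'   two-column TSV `sample_id<TAB>group`) assigning each sample to a group
#'   such as `"main"`, `"stress"` or `"reference"`. Stored as the
#'   `"sample_groups"` attribute of the returned matrix.
#' @return Integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_counts <- function(path, sample_groups = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("count table needs a gene-id column and at least 2 sample columns")
  ids <- as.character(df[[1L]])
  keep <- !startsWith(ids, "__")
  df <- df[keep, , drop = FALSE]
  ids <- ids[keep]
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (!is.null(sample_groups)) {
    if (is.character(sample_groups) && length(sample_groups) == 1L &&
        file.exists(sample_groups)) {
      g <- utils::read.delim(sample_groups, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      sample_groups <- stats::setNames(as.character(g[[2L]]), as.character(g[[1L]]))
    }
    missing <- setdiff(colnames(m), names(sample_groups))
    if (length(missing))
      stop("samples without a group label: ", paste(missing, collapse = ", "))
    attr(m, "sample_groups") <- sample_groups[colnames(m)]
  }
  m
}

#' Write a count matrix to TSV (inverse of [read_counts()])
#'
#' @param counts Integer matrix with gene-id rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name for the gene-id column.
#' @export
write_counts <- function(counts, path, id_column = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample by the median-of-ratios
#' method: a pseudo-reference is the per-gene geometric mean of counts across
#' samples (genes with any zero count are excluded from the reference set),
#' and each sample's size factor is the median over reference genes of the
#' ratio of that sample's count to the pseudo-reference.
#'
#' For two samples whose counts satisfy `B = c * A` elementwise the factors
#' are exactly `(1/sqrt(c), sqrt(c))`.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @seealso [normalize_counts()]
#' @export
estimate_size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos))
    stop("no gene with all-positive counts; cannot form the pseudo-reference")
  k <- counts[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(k))
  sf <- apply(k, 2L, function(col) exp(stats::median(log(col) - log_ref)))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Named numeric vector as returned by
#'   [estimate_size_factors()]; names must match the sample columns.
#' @return Numeric matrix of normalized counts, same dimensions.
#' @export
normalize_counts <- function(counts, size_factors) {
  if (is.null(names(size_factors))) {
    if (length(size_factors) != ncol(counts))
      stop("size factor / sample mismatch")
  } else {
    if (!setequal(names(size_factors), colnames(counts)))
      stop("size factor names do not match sample ids")
    size_factors <- size_factors[colnames(counts)]
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, size_factors, "/")
}

#' Genes expressed in every sample
#'
#' A gene passes when its *raw* count is strictly positive in every sample.
#'
#' @param counts Count matrix, genes x samples.
#' @return Character vector of passing gene ids, in input order.
#' @export
filter_expressed_all <- function(counts) {
  rownames(counts)[rowSums(counts <= 0) == 0L]
}

#' Per-gene expression-stability statistics
#'
#' Normalizes the matrix (median-of-ratios unless `size_factors` is given)
#' and computes, for each gene, the geometric mean of normalized counts and
#' the coefficient of variation CV = sd/mean, using the sample (n-1)
#' standard deviation. CV is `NA` for genes not expressed in all samples;
#' the geometric mean is only reported for expressed-in-all genes.
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Optional precomputed size factors.
#' @return `data.frame` with columns `gene_id`, `geometric_mean`, `cv`,
#'   `expressed_in_all`, plus the normalized matrix as attribute
#'   `"normalized"` and the size factors as attribute `"size_factors"`.
#' @export
gene_stats <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- normalize_counts(counts, size_factors)
  expressed <- rowSums(counts <= 0) == 0L
  mu <- rowMeans(norm)
  sdev <- apply(norm, 1L, stats::sd)
  cv <- ifelse(expressed, sdev / mu, NA_real_)
  gm <- ifelse(expressed, exp(rowMeans(log(pmax(norm, .Machine$double.xmin)))),
               NA_real_)
  out <- data.frame(gene_id = rownames(counts),
                    geometric_mean = gm,
                    cv = cv,
                    expressed_in_all = expressed,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "normalized") <- norm
  attr(out, "size_factors") <- size_factors
  out
}

#' Retain the lowest-CV fraction of genes
#'
#' Keeps the `n = ceiling(fraction * N)` expressed-in-all genes with the
#' smallest CV, where `N` is the number of expressed-in-all genes with a
#' defined CV. Ties at the cutoff are broken lexicographically by gene id.
#' The implied CV cutoff (largest retained CV) is reported.
#'
#' With `N = 10096` genes and the default 3% fraction this retains 303 genes.
#'
#' @param stats `data.frame` from [gene_stats()] (needs `gene_id` and `cv`).
#' @param fraction Fraction of genes to retain, in (0, 1). Default 0.03.
#' @return `data.frame` of retained genes sorted by ascending CV, with the
#'   cutoff as attribute `"cv_cutoff"` and `n` as attribute `"n_retained"`.
#' @export
select_low_cv <- function(stats, fraction = 0.03) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  ok <- stats[!is.na(stats$cv), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no genes with a defined CV")
  n <- as.integer(ceiling(fraction * nrow(ok)))
  ord <- order(ok$cv, ok$gene_id)
  out <- ok[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cv_cutoff") <- max(out$cv)
  attr(out, "n_retained") <- n
  out
}

#' Stress-condition CV against a dedicated reference sample
#'
#' Re-normalizes the submatrix of stress samples plus one reference sample by
#' median-of-ratios on that submatrix alone, then computes each gene's CV
#' across the *stress* samples of the normalized submatrix. This annotation
#' mirrors normalizing a stress dataset against a single reference tissue,
#' kept separate from the main stability ranking; it is never used for the
#' main retention filter.
#'
#' @param counts Full count matrix.
#' @param stress_samples Character vector of stress sample ids (>= 2).
#' @param reference_sample Single reference sample id.
#' @return Named numeric vector of per-gene stress CVs (`NA` where any count
#'   in the submatrix is zero).
#' @export
stress_cv <- function(counts, stress_samples, reference_sample) {
  missing <- setdiff(c(stress_samples, reference_sample), colnames(counts))
  if (length(missing)) stop("missing sample ids: ", paste(missing, collapse = ", "))
  if (length(stress_samples) < 2L)
    stop("need at least 2 stress samples for a CV")
  sub <- counts[, unique(c(stress_samples, reference_sample)), drop = FALSE]
  sf <- estimate_size_factors(sub)
  norm <- normalize_counts(sub, sf)[, stress_samples, drop = FALSE]
  expressed <- rowSums(sub <= 0) == 0L
  cv <- apply(norm, 1L, stats::sd) / rowMeans(norm)
  cv[!expressed] <- NA_real_
  stats::setNames(cv, rownames(counts))
}

#' Rank genes by expression stability (one-call wrapper)
#'
#' Runs the expressed-in-all filter, median-of-ratios normalization, CV
#' computation and lowest-CV retention in one call, optionally adding a
#' stress-CV annotation column.
#'
#' @inheritParams gene_stats
#' @inheritParams select_low_cv
#' @param stress_samples,reference_sample Optional: see [stress_cv()].
#' @return `data.frame` of [gene_stats()] plus a logical `retained` column
#'   (and `stress_cv` when requested); attributes `"cv_cutoff"`,
#'   `"n_retained"`, `"size_factors"`.
#' @export
rank_stability <- function(counts, fraction = 0.03,
                           stress_samples = NULL, reference_sample = NULL) {
  groups <- attr(counts, "sample_groups")
  if (!is.null(groups)) {
    main <- colnames(counts)[groups != "stress"]
    if (is.null(stress_samples) && any(groups == "stress"))
      stress_samples <- colnames(counts)[groups == "stress"]
    if (is.null(reference_sample) && any(groups == "reference"))
      reference_sample <- colnames(counts)[groups == "reference"][1L]
  } else {
    main <- colnames(counts)
  }
  main_counts <- counts[, main, drop = FALSE]
  st <- gene_stats(main_counts)
  kept <- select_low_cv(st, fraction)
  st$retained <- st$gene_id %in% kept$gene_id
  if (!is.null(stress_samples) && !is.null(reference_sample))
    st$stress_cv <- stress_cv(counts, stress_samples, reference_sample)[st$gene_id]
  attr(st, "cv_cutoff") <- attr(kept, "cv_cutoff")
  attr(st, "n_retained") <- attr(kept, "n_retained")
  st
}
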