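# Family-level aggregation and the four-step pre-processing chain used before
# network construction: minimum-gene filter, scaling to the median sample sum,
# inter-quartile-range variable filtering, regularised log transform. The
# stages are order-fixed; a stage tag on the matrix enforces the order.

.fm_stages <- c("raw_sum", "scaled", "filtered", "rlog")

.new_family_matrix <- function(values, stage, gene_counts) {
  stopifnot(stage %in% .fm_stages)
  structure(values, stage = stage,
            gene_counts = gene_counts[rownames(values)],
            class = c("family_matrix", class(values)))
}

#' Build a family matrix directly
#'
#' Mainly useful for worked examples and tests; [aggregate_by_family()] is the
#' usual entry point.
#'
#' @param values Numeric family x sample matrix with dimnames.
#' @param stage One of `"raw_sum"`, `"scaled"`, `"filtered"`, `"rlog"`.
#' @param gene_counts Optional named per-family expressed-gene counts; defaults
#'   to `NA` for each family.
#' @return A `family_matrix`.
#' @export
family_matrix <- function(values, stage = "raw_sum", gene_counts = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("family_matrix: values must carry family and sample names")
  }
  if (any(values < 0)) stop("family_matrix: negative values")
  if (is.null(gene_counts)) {
    gene_counts <- stats::setNames(rep(NA_integer_, nrow(values)),
                                   rownames(values))
  }
  .new_family_matrix(values, stage, gene_counts)
}

.check_stage <- function(fm, expected, op) {
  if (!inherits(fm, "family_matrix")) {
    stop(op, ": input is not a family_matrix")
  }
  st <- attr(fm, "stage")
  if (!st %in% expected) {
    stop(op, ": expects stage ", paste(expected, collapse = "/"),
         ", got '", st, "' (stages run in order: ",
         paste(.fm_stages, collapse = " -> "), ")")
  }
  invisible(fm)
}

#' Sum gene counts to the taxonomic-family level
#'
#' @param table An `expression_table`.
#' @param design A `sample_design`; needed to drop baseline (0 h) samples.
#' @param exclude_baseline Drop samples with `timepoint_h == 0` (the default,
#'   matching the exclusion of the pre-incubation epiphyte sample).
#' @return A `family_matrix` at stage `"raw_sum"`, with the number of expressed
#'   genes per family (>= 1 read in >= 1 retained sample) stored in attribute
#'   `"gene_counts"`.
#' @export
aggregate_by_family <- function(table, design, exclude_baseline = TRUE) {
  stopifnot(inherits(table, "expression_table"))
  design <- sample_design(design, table)
  keep <- design$sample_id[!exclude_baseline | design$timepoint_h > 0]
  counts <- table$counts[, keep, drop = FALSE]
  fam <- table$gene_meta$family
  sums <- rowsum(counts, fam)
  sums <- sums[order(rownames(sums)), , drop = FALSE]
  expressed <- rowSums(counts) > 0
  gene_counts <- table(factor(fam[expressed], levels = rownames(sums)))
  .new_family_matrix(sums, "raw_sum",
                     stats::setNames(as.integer(gene_counts),
                                     rownames(sums)))
}

#' Remove families with too few expressed genes
#'
#' A gene counts as expressed if it has at least one read in at least one
#' retained sample; families with fewer than `min_genes` expressed genes are
#' dropped.
#'
#' @param fm A `family_matrix` at stage `"raw_sum"`.
#' @param min_genes Minimum number of expressed genes (default 10).
#' @return The filtered `family_matrix`, still at stage `"raw_sum"`.
#' @export
filter_min_genes <- function(fm, min_genes = 10) {
  .check_stage(fm, "raw_sum", "filter_min_genes")
  gc <- attr(fm, "gene_counts")
  keep <- names(gc)[gc >= min_genes]
  .new_family_matrix(fm[keep, , drop = FALSE], "raw_sum", gc)
}

.scale_columns <- function(mat) {
  s <- colSums(mat)
  if (any(s == 0)) {
    stop("scale_by_sample_sum: zero column sum for sample ",
         colnames(mat)[which(s == 0)[1]])
  }
  sweep(mat, 2, stats::median(s) / s, `*`)
}

#' Scale each sample to the median sample sum
#'
#' Each value is divided by its sample's total and multiplied by the median of
#' all sample totals, so that all column sums equal the median after scaling.
#'
#' @param fm A `family_matrix` at stage `"raw_sum"` (after the min-gene
#'   filter).
#' @return A `family_matrix` at stage `"scaled"`.
#' @export
scale_by_sample_sum <- function(fm) {
  .check_stage(fm, "raw_sum", "scale_by_sample_sum")
  .new_family_matrix(.scale_columns(unclass(fm)), "scaled",
                     attr(fm, "gene_counts"))
}

#' Variable filtering of low-information families
#'
#' Default (`mode = "iqr"`): compute each family's inter-quartile range across
#' samples (type-7 quantiles) and remove families whose IQR is strictly below
#' the `quantile_cut` quantile of all family IQRs. `mode = "total"` instead
#' removes families whose total expression is strictly below the
#' `quantile_cut` quantile of family totals.
#'
#' @param fm A `family_matrix` at stage `"scaled"`.
#' @param quantile_cut Quantile defining the removal threshold (default 0.25,
#'   the first quartile); 0 disables the filter.
#' @param mode `"iqr"` or `"total"`.
#' @return A `family_matrix` at stage `"filtered"`.
#' @export
iqr_filter <- function(fm, quantile_cut = 0.25, mode = c("iqr", "total")) {
  .check_stage(fm, "scaled", "iqr_filter")
  mode <- match.arg(mode)
  if (ncol(fm) < 2) stop("iqr_filter: IQR undefined with fewer than 2 samples")
  stat <- if (mode == "iqr") {
    apply(unclass(fm), 1, stats::IQR, type = 7)
  } else {
    rowSums(unclass(fm))
  }
  cut <- stats::quantile(stat, quantile_cut, type = 7, names = FALSE)
  keep <- names(stat)[stat >= cut]
  .new_family_matrix(fm[keep, , drop = FALSE], "filtered",
                     attr(fm, "gene_counts"))
}

#' Regularised log transform
#'
#' `log2(x + pseudocount)` on the scaled values. This is a monotone,
#' rank-preserving surrogate for shrinkage-based variance-stabilising
#' transforms; because the only downstream consumer is a rank-based
#' correlation, the choice cannot change the network's edge set (asserted by a
#' cross-module test).
#'
#' @param fm A `family_matrix` at stage `"filtered"`.
#' @param pseudocount Added before taking logs (default 1).
#' @return A `family_matrix` at stage `"rlog"`.
#' @export
regularized_log <- function(fm, pseudocount = 1) {
  .check_stage(fm, "filtered", "regularized_log")
  if (any(fm < 0)) stop("regularized_log: negative input value")
  .new_family_matrix(log2(unclass(fm) + pseudocount), "rlog",
                     attr(fm, "gene_counts"))
}

#' Run the full pre-processing chain
#'
#' aggregate -> min-gene filter -> scale -> IQR filter -> regularised log.
#'
#' @inheritParams aggregate_by_family
#' @inheritParams filter_min_genes
#' @inheritParams iqr_filter
#' @inheritParams regularized_log
#' @param iqr_mode Passed to [iqr_filter()] as `mode`.
#' @return List of the matrices at each stage: `raw`, `scaled`, `filtered`,
#'   `rlog`.
#' @export
preprocess_counts <- function(table, design, exclude_baseline = TRUE,
                              min_genes = 10, quantile_cut = 0.25,
                              iqr_mode = "iqr", pseudocount = 1) {
  raw <- aggregate_by_family(table, design, exclude_baseline)
  raw <- filter_min_genes(raw, min_genes)
  scaled <- scale_by_sample_sum(raw)
  filtered <- iqr_filter(scaled, quantile_cut, mode = iqr_mode)
  rlog <- regularized_log(filtered, pseudocount)
  list(raw = raw, scaled = scaled, filtered = filtered, rlog = rlog)
}
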