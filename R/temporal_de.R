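# Temporal differential-expression stage: summarisation by (taxonomic family x
# functional cluster), screening for time and animal effects, all pairwise
# timepoint contrasts at BH 0.1, compact-letter significance groups from
# maximal cliques of the non-significance graph, and grouping of features by
# their canonical DE pattern restricted to the top share of expression.

#' Sum counts by (taxonomic family, functional cluster)
#'
#' Every gene maps to exactly one feature, so column sums are preserved. Genes
#' without a functional cluster go to a reserved `"unclustered"` id with a
#' warning.
#'
#' @param table An `expression_table`.
#' @return A `feature_table`: list with `values` (feature x sample matrix) and
#'   `feature_meta` (`feature`, `family`, `functional_cluster`).
#' @export
summarize_features <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  fc <- table$gene_meta$functional_cluster
  if (anyNA(fc) || any(fc == "")) {
    warning("summarize_features: ", sum(is.na(fc) | fc == ""),
            " gene(s) lack a functional cluster; assigned to 'unclustered'")
    fc[is.na(fc) | fc == ""] <- "unclustered"
  }
  feature <- paste(table$gene_meta$family, fc, sep = "|")
  values <- rowsum(table$counts, feature)
  values <- values[order(rownames(values)), , drop = FALSE]
  meta <- unique(data.frame(feature = feature,
                            family = table$gene_meta$family,
                            functional_cluster = fc,
                            stringsAsFactors = FALSE))
  meta <- meta[match(rownames(values), meta$feature), ]
  rownames(meta) <- NULL
  structure(list(values = values, feature_meta = meta),
            class = "feature_table")
}

# Regularised-log feature values used by the surrogate linear-model engine:
# per-sample scaling to the median sum, then log2(x + 1).
.rlog_features <- function(ft, design) {
  keep <- design$sample_id[design$timepoint_h > 0]
  mat <- ft$values[, keep, drop = FALSE]
  log2(.scale_columns(mat) + 1)
}

.check_replication <- function(design) {
  d <- design[design$timepoint_h > 0, ]
  if (length(unique(d$animal_id)) < 2 || length(unique(d$timepoint_h)) < 2) {
    stop("need at least 2 animals and 2 timepoints")
  }
  reps <- table(d$timepoint_h)
  if (any(reps < 2)) {
    stop("timepoint ", names(reps)[which(reps < 2)[1]],
         " is not replicated across animals")
  }
  invisible(d)
}

#' Screen features for time and animal effects
#'
#' Default surrogate engine: per feature, a linear model on regularised-log
#' values with additive animal and timepoint factors. The time p-value is the
#' F-test of `animal + time` against `animal`; the animal p-value of
#' `animal + time` against `time`. Both are BH-adjusted across features. An
#' externally computed p-value table (e.g. from a negative-binomial
#' likelihood-ratio engine) can be supplied instead via `external_pvals`
#' (columns `feature`, `p_time`, `p_animal`).
#'
#' @param ft A `feature_table`.
#' @param design A `sample_design` (baseline samples are excluded).
#' @param external_pvals Optional replacement p-value table.
#' @return Data frame: `feature`, `p_time`, `p_animal`, `padj_time`,
#'   `padj_animal`.
#' @export
test_time_effect <- function(ft, design, external_pvals = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.null(external_pvals)) {
    stopifnot(all(c("feature", "p_time", "p_animal") %in%
                    names(external_pvals)))
    out <- external_pvals[, c("feature", "p_time", "p_animal")]
  } else {
    d <- .check_replication(design)
    y <- .rlog_features(ft, design)
    d <- d[match(colnames(y), d$sample_id), ]
    animal <- factor(d$animal_id)
    time <- factor(d$timepoint_h)
    pv <- t(apply(y, 1, function(row) {
      # a numerically constant feature carries no evidence for either factor
      if (stats::var(row) <= 1e-20 * (mean(row)^2 + 1e-300)) {
        return(c(p_time = 1, p_animal = 1))
      }
      full <- stats::lm(row ~ animal + time)
      p_time <- stats::anova(stats::lm(row ~ animal), full)[2, "Pr(>F)"]
      p_animal <- stats::anova(stats::lm(row ~ time), full)[2, "Pr(>F)"]
      c(p_time = p_time, p_animal = p_animal)
    }))
    # a feature with no residual variation left carries no evidence
    pv[is.na(pv)] <- 1
    out <- data.frame(feature = rownames(y), pv, stringsAsFactors = FALSE)
  }
  out$padj_time <- stats::p.adjust(out$p_time, method = "BH")
  out$padj_animal <- stats::p.adjust(out$p_animal, method = "BH")
  rownames(out) <- NULL
  out
}

#' All pairwise timepoint contrasts for selected features
#'
#' One contrast per unordered timepoint pair (10 for five timepoints), from
#' the surrogate model: the contrast estimate is the difference of timepoint
#' means, its standard error `sqrt(MSE * (1/n_i + 1/n_j))` with the residual
#' degrees of freedom of the `animal + time` fit (exact for the balanced
#' design this stage requires). P-values are BH-adjusted within feature.
#'
#' @param ft A `feature_table`.
#' @param design A `sample_design`.
#' @param features Features to test (default: all).
#' @return Long data frame: `feature`, `t1`, `t2` (hours), `estimate`, `p`,
#'   `padj`.
#' @export
pairwise_timepoints <- function(ft, design, features = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  d <- .check_replication(design)
  y <- .rlog_features(ft, design)
  if (is.null(features)) features <- rownames(y)
  stopifnot(all(features %in% rownames(y)))
  d <- d[match(colnames(y), d$sample_id), ]
  animal <- factor(d$animal_id)
  time <- factor(d$timepoint_h)
  tps <- sort(unique(d$timepoint_h))
  pairs <- t(utils::combn(tps, 2))
  res <- lapply(features, function(f) {
    row <- y[f, ]
    fit <- stats::lm(row ~ animal + time)
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    means <- tapply(row, time, mean)
    ns <- tapply(row, time, length)
    est <- means[as.character(pairs[, 2])] - means[as.character(pairs[, 1])]
    se <- sqrt(mse * (1 / ns[as.character(pairs[, 1])] +
                        1 / ns[as.character(pairs[, 2])]))
    tstat <- ifelse(est == 0, 0, est / se)
    p <- ifelse(se == 0,
                ifelse(est == 0, 1, 0),
                2 * stats::pt(abs(tstat), df = stats::df.residual(fit),
                              lower.tail = FALSE))
    data.frame(feature = f, t1 = pairs[, 1], t2 = pairs[, 2],
               estimate = unname(est), p = unname(p),
               padj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compact-letter significance groups from maximal cliques
#'
#' Builds the graph on timepoints whose edges join pairs that are *not*
#' significantly different (`adjusted p >= alpha`), enumerates its maximal
#' cliques, assigns one letter per clique in order of the clique's earliest
#' timepoint, and labels each timepoint with the letters of every clique that
#' contains it. Two timepoints share a letter iff they lie in a common maximal
#' clique.
#'
#' @param pairs Data frame with `t1`, `t2`, `padj` covering all unordered
#'   timepoint pairs.
#' @param alpha Significance threshold on adjusted p (default 0.1).
#' @return List: `letters` (named character vector per timepoint, in time
#'   order), `key` (canonical pattern key, invariant to letter naming) and
#'   `cliques` (list of timepoint vectors).
#' @export
significance_letters <- function(pairs, alpha = 0.1) {
  stopifnot(all(c("t1", "t2", "padj") %in% names(pairs)))
  tps <- sort(unique(c(pairs$t1, pairs$t2)))
  lab <- sprintf("T%g", tps)
  ns <- pairs[pairs$padj >= alpha, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sprintf("T%g", ns$t1), to = sprintf("T%g", ns$t2)),
    directed = FALSE,
    vertices = data.frame(name = lab)
  )
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(cl) {
    sort(match(igraph::V(g)$name[cl], lab))
  })
  cliques <- cliques[order(vapply(cliques, min, numeric(1)),
                           vapply(cliques, paste, collapse = ",",
                                  character(1)))]
  letters_per_tp <- vapply(seq_along(tps), function(i) {
    member <- vapply(cliques, function(cl) i %in% cl, logical(1))
    paste(letters[which(member)], collapse = "")
  }, character(1))
  names(letters_per_tp) <- lab
  list(letters = letters_per_tp,
       key = canonical_pattern_key(letters_per_tp),
       cliques = cliques)
}

#' Canonical DE-pattern key
#'
#' Re-indexes letters by first appearance scanning timepoints in time order,
#' so keys are equal iff letter assignments are identical up to renaming.
#'
#' @param letter_labels Character vector of per-timepoint letter labels in
#'   time order.
#' @return A single string, e.g. `"a|ab|b|b|c"`.
#' @export
canonical_pattern_key <- function(letter_labels) {
  seen <- character(0)
  for (labx in letter_labels) {
    for (ch in strsplit(labx, "")[[1]]) {
      if (!ch %in% seen) seen <- c(seen, ch)
    }
  }
  remap <- stats::setNames(letters[seq_along(seen)], seen)
  paste(vapply(letter_labels, function(labx) {
    paste(sort(unname(remap[strsplit(labx, "")[[1]]])), collapse = "")
  }, character(1)), collapse = "|")
}

#' Group features by DE pattern within the top expression share
#'
#' Features are sorted by total expression (baseline excluded) and the minimal
#' prefix reaching `top_fraction` of the cumulative total is retained
#' (`top_fraction = 1` keeps everything). Retained features are grouped by
#' canonical pattern key; each pattern reports its feature count, summed
#' per-timepoint expression (mean over animals of the summed feature counts)
#' and the per-family contribution proportions.
#'
#' @param sig Named list of [significance_letters()] results, one per feature.
#' @param ft The `feature_table`.
#' @param design A `sample_design`.
#' @param top_fraction Cumulative expression share retained (default 0.9).
#' @return List: `patterns` (data frame `pattern`, `n_features`, total
#'   expression), `timepoint_expression` (pattern x timepoint matrix),
#'   `family_contributions` (long data frame of proportions) and `features`
#'   (feature -> pattern map).
#' @export
pattern_grouping <- function(sig, ft, design, top_fraction = 0.9) {
  stopifnot(inherits(ft, "feature_table"))
  feats <- names(sig)
  stopifnot(all(feats %in% rownames(ft$values)))
  keep_samples <- design$sample_id[design$timepoint_h > 0]
  vals <- ft$values[feats, keep_samples, drop = FALSE]
  totals <- rowSums(vals)
  ord <- order(-totals)
  cum <- cumsum(totals[ord]) / sum(totals)
  n_keep <- if (top_fraction >= 1) length(ord) else
    min(which(cum >= top_fraction))
  kept <- feats[ord[seq_len(n_keep)]]

  keys <- vapply(sig[kept], `[[`, character(1), "key")
  tps <- sort(unique(design$timepoint_h[design$timepoint_h > 0]))
  tp_of <- design$timepoint_h[match(keep_samples, design$sample_id)]
  # mean across animals of the per-sample feature sums, per timepoint
  tp_means <- t(apply(vals[kept, , drop = FALSE], 1, function(row) {
    tapply(row, tp_of, mean)
  }))
  colnames(tp_means) <- sprintf("T%g", as.numeric(colnames(tp_means)))

  pat <- sort(unique(keys))
  patterns <- data.frame(
    pattern = pat,
    n_features = as.integer(table(keys)[pat]),
    total_expression = as.numeric(tapply(totals[kept], keys, sum)[pat]),
    stringsAsFactors = FALSE
  )
  tp_expr <- rowsum(tp_means, keys)[pat, , drop = FALSE]

  fam <- ft$feature_meta$family[match(kept, ft$feature_meta$feature)]
  fam_tot <- tapply(totals[kept], list(keys, fam), sum)
  contrib <- do.call(rbind, lapply(pat, function(p) {
    v <- stats::setNames(fam_tot[p, ], colnames(fam_tot))
    v <- v[!is.na(v)]
    data.frame(pattern = p, family = names(v),
               proportion = as.numeric(v) / sum(v),
               stringsAsFactors = FALSE)
  }))
  rownames(contrib) <- NULL
  list(patterns = patterns,
       timepoint_expression = tp_expr,
       family_contributions = contrib,
       features = stats::setNames(keys, kept))
}

#' Full temporal DE stage
#'
#' Screens features for a time effect (BH-adjusted p below `alpha`), excludes
#' features with an animal effect at the same threshold, runs all pairwise
#' timepoint contrasts on the survivors, assigns letter groups, and groups the
#' top `top_fraction` of expression by DE pattern.
#'
#' @inheritParams test_time_effect
#' @inheritParams pattern_grouping
#' @param alpha BH threshold for the screens and the pairwise contrasts.
#' @return List: `screen`, `pairwise`, `letters` (per feature), `patterns`
#'   and the retained `features`.
#' @export
temporal_de <- function(ft, design, alpha = 0.1, top_fraction = 0.9,
                        external_pvals = NULL) {
  screen <- test_time_effect(ft, design, external_pvals)
  keep <- screen$feature[screen$padj_time < alpha &
                           screen$padj_animal >= alpha]
  if (length(keep) == 0) {
    return(list(screen = screen, pairwise = NULL, letters = list(),
                patterns = NULL, features = character(0)))
  }
  pw <- pairwise_timepoints(ft, design, keep)
  sig <- lapply(split(pw, pw$feature), significance_letters, alpha = alpha)
  sig <- sig[keep]
  patterns <- pattern_grouping(sig, ft, design, top_fraction)
  list(screen = screen, pairwise = pw, letters = sig, patterns = patterns,
       features = keep)
}
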