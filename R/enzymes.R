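# TPM-based temporal profiling of glycoside hydrolase (GH), peptidase and
# LuxS quorum-sensing gene families: per-family TPM sums, 95%-of-expression
# filter per enzyme type, two-way fixed-effect ANOVA (time + animal) with BH
# correction, Tukey HSD letter groups, and per-taxon contribution
# decomposition.

#' Transcripts per million
#'
#' `rate(g, s) = count / length_kb`, `TPM(g, s) = rate / sum_g rate * 1e6`,
#' normalised over every gene in the table, so each sample column sums to one
#' million.
#'
#' @param table An `expression_table` with positive gene lengths.
#' @return A gene x sample matrix of TPM values.
#' @export
compute_tpm <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  rate <- table$counts / (table$gene_meta$length_bp / 1000)
  s <- colSums(rate)
  if (any(s == 0)) {
    stop("compute_tpm: all-zero sample ", colnames(rate)[which(s == 0)[1]])
  }
  sweep(rate, 2, 1e6 / s, `*`)
}

.enzyme_type <- function(tag) {
  ifelse(startsWith(tag, "GH"), "GH",
         ifelse(tag == "LuxS", "luxs", "peptidase"))
}

#' Sum TPM by enzyme family
#'
#' Genes sharing an enzyme tag are summed per sample; untagged genes
#' contribute to no enzyme family. LuxS genes are summed per taxonomic family
#' (profile rows `"LuxS|<family>"`), mirroring a per-taxon quorum-sensing
#' analysis.
#'
#' @param tpm Gene x sample TPM matrix from [compute_tpm()].
#' @param gene_meta The `gene_meta` of the same table.
#' @return List: `profile` (enzyme family x sample summed TPM) and `meta`
#'   (`enzyme_family`, `type` in GH/peptidase/luxs).
#' @export
sum_by_enzyme_family <- function(tpm, gene_meta) {
  tagged <- !is.na(gene_meta$enzyme_tag) & gene_meta$enzyme_tag != ""
  tag <- gene_meta$enzyme_tag[tagged]
  fam <- gene_meta$family[tagged]
  id <- ifelse(tag == "LuxS", paste0("LuxS|", fam), tag)
  profile <- rowsum(tpm[tagged, , drop = FALSE], id)
  profile <- profile[order(rownames(profile)), , drop = FALSE]
  meta <- data.frame(
    enzyme_family = rownames(profile),
    type = .enzyme_type(sub("\\|.*$", "", rownames(profile))),
    stringsAsFactors = FALSE
  )
  list(profile = profile, meta = meta)
}

#' Retain the most highly expressed enzyme families per type
#'
#' Within each of GH and peptidase separately, enzyme families are sorted by
#' total TPM and the minimal prefix whose cumulative share reaches `fraction`
#' is kept. LuxS rows are never filtered.
#'
#' @param profiles Output of [sum_by_enzyme_family()].
#' @param fraction Cumulative expression share to retain (default 0.95).
#' @return The filtered `profiles` list.
#' @export
top_expression_filter <- function(profiles, fraction = 0.95) {
  keep <- character(0)
  for (ty in unique(profiles$meta$type)) {
    fams <- profiles$meta$enzyme_family[profiles$meta$type == ty]
    if (ty == "luxs") {
      keep <- c(keep, fams)
      next
    }
    totals <- rowSums(profiles$profile[fams, , drop = FALSE])
    ord <- order(-totals)
    cum <- cumsum(totals[ord]) / sum(totals)
    n_keep <- if (fraction >= 1) length(ord) else min(which(cum >= fraction))
    keep <- c(keep, fams[ord[seq_len(n_keep)]])
  }
  keep <- rownames(profiles$profile)[rownames(profiles$profile) %in% keep]
  list(profile = profiles$profile[keep, , drop = FALSE],
       meta = profiles$meta[match(keep, profiles$meta$enzyme_family), ])
}

.anova_fit <- function(values, design) {
  d <- design[design$timepoint_h > 0, ]
  v <- values[d$sample_id]
  stats::lm(v ~ factor(d$animal_id) + factor(d$timepoint_h))
}

#' Two-way fixed-effect ANOVA for a time effect
#'
#' Per enzyme family, `summed TPM ~ animal + time` (no interaction; balanced
#' design required), reporting the time F statistic and p-value, BH-adjusted
#' across enzyme families. A profile with no time-attributable variation
#' reports F = 0, p = 1.
#'
#' @param profiles Output of [sum_by_enzyme_family()] (possibly filtered).
#' @param design A `sample_design` (baseline excluded).
#' @return Data frame: `enzyme_family`, `type`, `F`, `p`, `padj`.
#' @export
anova_time <- function(profiles, design) {
  .check_replication(design)
  d <- design[design$timepoint_h > 0, ]
  res <- t(vapply(rownames(profiles$profile), function(f) {
    v <- profiles$profile[f, d$sample_id]
    # a profile with no variation carries no evidence of a time effect
    if (stats::var(v) <= 1e-20 * (mean(v)^2 + 1e-300)) return(c(0, 1))
    fit <- .anova_fit(profiles$profile[f, ], design)
    an <- stats::anova(fit)
    Fv <- an["factor(d$timepoint_h)", "F value"]
    p <- an["factor(d$timepoint_h)", "Pr(>F)"]
    if (is.na(Fv) || is.nan(Fv)) {
      Fv <- 0
      p <- 1
    }
    c(Fv, p)
  }, numeric(2)))
  out <- data.frame(
    enzyme_family = rownames(profiles$profile),
    type = profiles$meta$type[match(rownames(profiles$profile),
                                    profiles$meta$enzyme_family)],
    F = res[, 1], p = res[, 2],
    padj = stats::p.adjust(res[, 2], method = "BH"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Tukey HSD pairwise p-values from a fitted time + animal model
#'
#' Tukey-Kramer statistic `q = |m_i - m_j| / sqrt((MSE / 2) (1/n_i + 1/n_j))`
#' referred to the studentized range distribution with the number of
#' timepoints and the model's residual degrees of freedom. With two groups
#' this reduces exactly to the pooled two-sided t-test.
#'
#' @param values Named per-sample response vector.
#' @param design A `sample_design`.
#' @return Data frame `t1`, `t2`, `estimate`, `q`, `padj` (the Tukey p-value,
#'   which is already family-wise adjusted).
#' @export
tukey_pairwise <- function(values, design) {
  d <- design[design$timepoint_h > 0, ]
  fit <- .anova_fit(values, design)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  v <- values[d$sample_id]
  time <- factor(d$timepoint_h)
  means <- tapply(v, time, mean)
  ns <- tapply(v, time, length)
  tps <- sort(unique(d$timepoint_h))
  pairs <- t(utils::combn(tps, 2))
  est <- means[as.character(pairs[, 2])] - means[as.character(pairs[, 1])]
  se_q <- sqrt((mse / 2) * (1 / ns[as.character(pairs[, 1])] +
                              1 / ns[as.character(pairs[, 2])]))
  q <- ifelse(est == 0, 0, abs(est) / se_q)
  p <- if (length(tps) == 2) {
    # with two groups the studentized range reduces exactly to the pooled
    # two-sided t-test; use the closed form (stats::ptukey is only
    # approximate)
    ifelse(se_q == 0, ifelse(est == 0, 1, 0),
           2 * stats::pt(q / sqrt(2), df = stats::df.residual(fit),
                         lower.tail = FALSE))
  } else {
    ifelse(se_q == 0,
           ifelse(est == 0, 1, 0),
           stats::ptukey(q, nmeans = length(tps),
                         df = stats::df.residual(fit),
                         lower.tail = FALSE))
  }
  data.frame(t1 = pairs[, 1], t2 = pairs[, 2], estimate = unname(est),
             q = unname(q), padj = unname(p), stringsAsFactors = FALSE)
}

#' Tukey HSD letter groups for one enzyme family
#'
#' Pairwise Tukey p-values feed the same maximal-clique letter routine as the
#' DE stage.
#'
#' @param profiles Output of [sum_by_enzyme_family()].
#' @param design A `sample_design`.
#' @param family Enzyme family id (profile row name).
#' @param alpha Significance threshold on the Tukey p-value (default 0.1,
#'   matching the study-wide threshold).
#' @return As [significance_letters()], plus the pairwise table in `$pairs`.
#' @export
tukey_letters <- function(profiles, design, family, alpha = 0.1) {
  stopifnot(family %in% rownames(profiles$profile))
  pairs <- tukey_pairwise(profiles$profile[family, ], design)
  out <- significance_letters(pairs, alpha = alpha)
  out$pairs <- pairs
  out
}

#' Per-taxon contributions to enzyme-family expression
#'
#' For each (enzyme family, timepoint): the share of each taxonomic family in
#' the summed TPM, averaged over animals. Shares sum to one where defined; a
#' zero-expression (enzyme family, timepoint) cell yields `NA` proportions.
#'
#' @param tpm Gene x sample TPM matrix.
#' @param gene_meta Matching `gene_meta`.
#' @param design A `sample_design`.
#' @return Long data frame: `enzyme_family`, `taxonomic_family`,
#'   `timepoint_h`, `mean_tpm`, `proportion`.
#' @export
taxon_contributions <- function(tpm, gene_meta, design) {
  tagged <- !is.na(gene_meta$enzyme_tag) & gene_meta$enzyme_tag != ""
  if (!any(tagged)) {
    return(data.frame(enzyme_family = character(0),
                      taxonomic_family = character(0),
                      timepoint_h = numeric(0), mean_tpm = numeric(0),
                      proportion = numeric(0)))
  }
  d <- design[design$timepoint_h > 0, ]
  tag <- gene_meta$enzyme_tag[tagged]
  fam <- gene_meta$family[tagged]
  enz <- ifelse(tag == "LuxS", paste0("LuxS|", fam), tag)
  key <- paste(enz, fam, sep = "\r")
  sums <- rowsum(tpm[tagged, d$sample_id, drop = FALSE], key)
  tp_of <- d$timepoint_h
  tps <- sort(unique(tp_of))
  tp_means <- matrix(0, nrow(sums), length(tps),
                     dimnames = list(rownames(sums), tps))
  for (j in seq_along(tps)) {
    tp_means[, j] <- rowMeans(sums[, tp_of == tps[j], drop = FALSE])
  }
  parts <- do.call(rbind, strsplit(rownames(tp_means), "\r", fixed = TRUE))
  out <- do.call(rbind, lapply(seq_along(tps), function(j) {
    data.frame(enzyme_family = parts[, 1], taxonomic_family = parts[, 2],
               timepoint_h = tps[j],
               mean_tpm = tp_means[, j], stringsAsFactors = FALSE)
  }))
  tot <- stats::ave(out$mean_tpm,
                    paste(out$enzyme_family, out$timepoint_h), FUN = sum)
  out$proportion <- ifelse(tot > 0, out$mean_tpm / tot, NA_real_)
  out <- out[order(out$enzyme_family, out$timepoint_h,
                   out$taxonomic_family), ]
  rownames(out) <- NULL
  out
}

#' Full enzyme-profiling stage
#'
#' TPM -> per-enzyme-family sums -> 95% expression filter (GH and peptidase
#' separately) -> time ANOVA with BH correction -> Tukey letter groups for the
#' significant families -> per-taxon contributions.
#'
#' @param table An `expression_table`.
#' @param design A `sample_design`.
#' @param fraction Cumulative expression share retained per type.
#' @param alpha BH threshold declaring a significant time effect.
#' @return List: `profiles`, `anova`, `letters` (per significant family),
#'   `contributions`.
#' @export
enzyme_analysis <- function(table, design, fraction = 0.95, alpha = 0.1) {
  tpm <- compute_tpm(table)
  profiles <- sum_by_enzyme_family(tpm, table$gene_meta)
  if (nrow(profiles$profile) == 0) {
    return(list(profiles = profiles, anova = NULL, letters = list(),
                contributions = NULL))
  }
  profiles <- top_expression_filter(profiles, fraction)
  an <- anova_time(profiles, design)
  sig_fams <- an$enzyme_family[an$padj < alpha]
  lets <- lapply(stats::setNames(sig_fams, sig_fams), function(f) {
    tukey_letters(profiles, design, f, alpha = alpha)
  })
  contrib <- taxon_contributions(tpm, table$gene_meta, design)
  contrib <- contrib[contrib$enzyme_family %in%
                       rownames(profiles$profile), ]
  list(profiles = profiles, anova = an, letters = lets,
       contributions = contrib)
}
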