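# TPM normalisation, enzyme-family sums, 95% filter, time ANOVA, Tukey HSD
# letters and per-taxon contributions.

test_that("TPM matches the direct formula and normalises each sample", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  meta <- data.frame(gene_id = c("g1", "g2"), family = "F", genus = "g",
                     functional_cluster = "FC1", enzyme_tag = NA,
                     length_bp = c(500L, 1000L))
  tpm <- compute_tpm(expression_table(counts, meta))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3))

  # equal lengths and counts: 1e6 / n each
  counts2 <- matrix(5L, 4, 2, dimnames = list(sprintf("g%d", 1:4),
                                              c("s1", "s2")))
  meta2 <- data.frame(gene_id = sprintf("g%d", 1:4), family = "F",
                      genus = "g", functional_cluster = "FC1",
                      enzyme_tag = NA, length_bp = 800L)
  tpm2 <- compute_tpm(expression_table(counts2, meta2))
  expect_true(all(tpm2 == 2.5e5))

  # column sums are one million
  b <- simulate_bundle(small_config())
  tpm3 <- compute_tpm(b$table)
  expect_equal(unname(colSums(tpm3)), rep(1e6, ncol(tpm3)), tolerance = 1e-9)

  # TPM is invariant to uniform scaling of a sample's counts
  tab4 <- b$table
  tab4$counts[, 1] <- tab4$counts[, 1] * 3L
  expect_equal(compute_tpm(tab4)[, 1], tpm3[, 1])

  counts0 <- counts2
  counts0[, 2] <- 0L
  expect_error(compute_tpm(expression_table(counts0, meta2)), "s2")
})

test_that("enzyme-family sums aggregate tags, LuxS per taxonomic family", {
  tab <- toy_table()
  tpm <- compute_tpm(tab)
  prof <- sum_by_enzyme_family(tpm, tab$gene_meta)
  # GH5 = g1 + g3; untagged g2/g5 contribute nowhere
  expect_equal(prof$profile["GH5", ], tpm["g1", ] + tpm["g3", ])
  expect_equal(prof$profile["M24b", ], tpm["g4", ])
  expect_setequal(prof$meta$type, c("GH", "peptidase"))

  # LuxS rows are per taxonomic family
  tab2 <- toy_table()
  tab2$gene_meta$enzyme_tag <- c("LuxS", NA, "LuxS", NA, "LuxS")
  prof2 <- sum_by_enzyme_family(compute_tpm(tab2), tab2$gene_meta)
  expect_setequal(rownames(prof2$profile),
                  c("LuxS|FamA", "LuxS|FamB"))
  expect_true(all(prof2$meta$type == "luxs"))

  # group-by oracle on a simulated bundle
  b <- simulate_bundle(small_config())
  tpmb <- compute_tpm(b$table)
  profb <- sum_by_enzyme_family(tpmb, b$table$gene_meta)
  gm <- b$table$gene_meta
  for (fam in setdiff(rownames(profb$profile), grep("^LuxS", rownames(profb$profile), value = TRUE))) {
    idx <- !is.na(gm$enzyme_tag) & gm$enzyme_tag == fam
    expect_equal(profb$profile[fam, ], colSums(tpmb[idx, , drop = FALSE]))
  }
})

test_that("the 95% filter keeps the minimal prefix per enzyme type", {
  profile <- matrix(c(70, 20, 6, 4), 4, 1,
                    dimnames = list(c("GH1", "GH2", "GH3", "GH4"), "s1"))
  profiles <- list(profile = profile,
                   meta = data.frame(enzyme_family = rownames(profile),
                                     type = "GH"))
  kept <- top_expression_filter(profiles, 0.95)
  expect_setequal(rownames(kept$profile), c("GH1", "GH2", "GH3"))

  # a single family is always kept; fraction 1 keeps everything
  one <- list(profile = profile[1, , drop = FALSE],
              meta = data.frame(enzyme_family = "GH1", type = "GH"))
  expect_equal(nrow(top_expression_filter(one, 0.95)$profile), 1L)
  expect_equal(nrow(top_expression_filter(profiles, 1)$profile), 4L)

  # types are filtered separately and LuxS rows are never dropped
  profile2 <- rbind(profile,
                    M1 = 97, M2 = 3,
                    `LuxS|FamA` = 0.01)
  profiles2 <- list(profile = profile2,
                    meta = data.frame(
                      enzyme_family = rownames(profile2),
                      type = c(rep("GH", 4), "peptidase", "peptidase", "luxs")
                    ))
  kept2 <- top_expression_filter(profiles2, 0.95)
  # M1 alone already reaches 95% of the peptidase total; LuxS is never cut
  expect_true(all(c("M1", "LuxS|FamA") %in% rownames(kept2$profile)))
  expect_false("M2" %in% rownames(kept2$profile))
  expect_true(all(c("GH1", "GH2", "GH3") %in% rownames(kept2$profile)))
})

test_that("time ANOVA is null on constants and matches aov on real data", {
  design <- balanced_design()
  flat <- matrix(7, 1, nrow(design),
                 dimnames = list("GH1", design$sample_id))
  profiles <- list(profile = flat,
                   meta = data.frame(enzyme_family = "GH1", type = "GH"))
  an <- anova_time(profiles, design)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)

  # independent oracle: stats::aov on the same data
  set.seed(31)
  m <- matrix(rlnorm(3 * nrow(design), 5, 0.5), 3,
              dimnames = list(c("GH1", "GH2", "M1"), design$sample_id))
  m[2, design$timepoint_h >= 4] <- m[2, design$timepoint_h >= 4] * 4
  profiles2 <- list(profile = m,
                    meta = data.frame(enzyme_family = rownames(m),
                                      type = c("GH", "GH", "peptidase")))
  an2 <- anova_time(profiles2, design)
  for (f in rownames(m)) {
    df <- data.frame(v = m[f, design$sample_id],
                     animal = factor(design$animal_id),
                     time = factor(design$timepoint_h))
    ref <- summary(stats::aov(v ~ animal + time, df))[[1]]
    expect_equal(an2$p[an2$enzyme_family == f], ref["time", "Pr(>F)"],
                 tolerance = 1e-10)
  }
  # the planted 4 h step is BH-significant at 0.1
  expect_lt(an2$padj[an2$enzyme_family == "GH2"], 0.1)
})

test_that("the balanced ANOVA decomposition is exact", {
  design <- balanced_design()
  set.seed(32)
  v <- stats::setNames(rlnorm(nrow(design), 3, 0.4), design$sample_id)
  animal <- factor(design$animal_id)
  time <- factor(design$timepoint_h)
  fit <- stats::lm(v ~ animal + time)
  an <- stats::anova(fit)
  ss_total <- sum((v - mean(v))^2)
  expect_equal(sum(an[, "Sum Sq"]), ss_total, tolerance = 1e-9)
})

test_that("Tukey with two groups equals the pooled t-test", {
  design <- balanced_design(timepoints = c(1, 8))
  set.seed(33)
  v <- stats::setNames(rlnorm(nrow(design), 4, 0.3), design$sample_id)
  pt_pair <- tukey_pairwise(v, design)
  # same contrast via the pooled t statistic on the same model's MSE
  d <- design
  fit <- stats::lm(v[d$sample_id] ~ factor(d$animal_id) +
                     factor(d$timepoint_h))
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(v[d$sample_id], d$timepoint_h, mean)
  tstat <- (means[2] - means[1]) / sqrt(mse * (2 / 3))
  p_t <- 2 * stats::pt(abs(tstat), df = stats::df.residual(fit),
                       lower.tail = FALSE)
  expect_equal(pt_pair$padj, unname(p_t), tolerance = 1e-6)
})

test_that("Tukey p-values match TukeyHSD and are conservative", {
  design <- balanced_design()
  set.seed(34)
  v <- stats::setNames(rlnorm(nrow(design), 4, 0.3), design$sample_id)
  v[design$timepoint_h >= 6] <- v[design$timepoint_h >= 6] * 2
  mine <- tukey_pairwise(v, design)

  d <- data.frame(v = v[design$sample_id],
                  animal = factor(design$animal_id),
                  time = factor(design$timepoint_h))
  ref <- stats::TukeyHSD(stats::aov(v ~ animal + time, d))$time
  ref_key <- rownames(ref)
  mine_key <- paste0(mine$t2, "-", mine$t1)
  expect_equal(mine$padj, unname(ref[match(mine_key, ref_key), "p adj"]),
               tolerance = 1e-8)

  # conservativeness: Tukey p >= unadjusted pairwise t p
  fit <- stats::lm(v ~ animal + time, d)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(d$v, d$time, mean)
  for (i in seq_len(nrow(mine))) {
    tt <- abs(means[as.character(mine$t2[i])] -
                means[as.character(mine$t1[i])]) / sqrt(mse * 2 / 3)
    p_t <- 2 * stats::pt(tt, stats::df.residual(fit), lower.tail = FALSE)
    expect_gte(mine$padj[i] + 1e-12, p_t)
  }
})

test_that("Tukey letter groups collapse when means are equal", {
  design <- balanced_design()
  set.seed(35)
  flat <- matrix(100 * exp(rnorm(nrow(design), 0, 1e-4)), 1,
                 dimnames = list("GH1", design$sample_id))
  profiles <- list(profile = flat,
                   meta = data.frame(enzyme_family = "GH1", type = "GH"))
  lets <- tukey_letters(profiles, design, "GH1")
  expect_true(all(lets$letters == "a"))
})

test_that("taxon contributions are proportions that sum to one", {
  tab <- toy_table()
  tpm <- compute_tpm(tab)
  contrib <- taxon_contributions(tpm, tab$gene_meta, toy_design())
  # GH5 is expressed by FamA (g1) and FamB (g3)
  gh5 <- contrib[contrib$enzyme_family == "GH5", ]
  for (tp in unique(gh5$timepoint_h)) {
    expect_equal(sum(gh5$proportion[gh5$timepoint_h == tp]), 1)
  }
  # a single-taxon enzyme family has share 1
  m24 <- contrib[contrib$enzyme_family == "M24b", ]
  expect_true(all(m24$proportion == 1))

  # direct ratio: 30 vs 10 gives 0.75 / 0.25
  counts <- matrix(c(30L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "A1_T1"))
  meta <- data.frame(gene_id = c("g1", "g2"), family = c("FamA", "FamB"),
                     genus = "g", functional_cluster = "FC1",
                     enzyme_tag = "GH5", length_bp = 1000L)
  des <- sample_design(data.frame(sample_id = "A1_T1", animal_id = "A1",
                                  timepoint_h = 1))
  con2 <- taxon_contributions(compute_tpm(expression_table(counts, meta)),
                              meta, des)
  expect_equal(sort(con2$proportion), c(0.25, 0.75))
})

test_that("the full enzyme stage runs on a simulated bundle", {
  b <- simulate_bundle(generator_config(seed = 4))
  res <- enzyme_analysis(b$table, b$design)
  expect_true(nrow(res$anova) > 0)
  expect_true(all(res$anova$padj >= res$anova$p - 1e-12))
  expect_true(all(names(res$letters) %in%
                    res$anova$enzyme_family[res$anova$padj < 0.1]))
  # contributions restricted to retained enzyme families
  expect_true(all(res$contributions$enzyme_family %in%
                    rownames(res$profiles$profile)))
})
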