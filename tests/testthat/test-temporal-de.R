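# Feature summarisation, time/animal screening, pairwise contrasts and
# maximal-clique significance letters.

make_feature_table <- function(values, design,
                               family = "FamA", fc = "FC1") {
  # values: feature x sample matrix
  structure(list(
    values = values,
    feature_meta = data.frame(
      feature = rownames(values),
      family = rep_len(family, nrow(values)),
      functional_cluster = rep_len(fc, nrow(values)),
      stringsAsFactors = FALSE
    )
  ), class = "feature_table")
}

test_that("feature summarisation sums by (family, functional cluster)", {
  tab <- toy_table()
  ft <- summarize_features(tab)
  # FamB|FC1 = g3 + g4
  expect_equal(unname(ft$values["FamB|FC1", "A1_T1"]), 1 + 0)
  expect_equal(unname(ft$values["FamB|FC1", "A2_T1"]), 3 + 2)
  # disjoint features preserve column sums
  expect_equal(colSums(ft$values), colSums(tab$counts))

  # brute-force group-by oracle on a simulated bundle
  b <- simulate_bundle(small_config())
  ft2 <- summarize_features(b$table)
  key <- paste(b$table$gene_meta$family, b$table$gene_meta$functional_cluster,
               sep = "|")
  oracle <- rowsum(b$table$counts, key)
  expect_equal(unclass(ft2$values), oracle[rownames(ft2$values), ],
               ignore_attr = TRUE)
})

test_that("genes without a functional cluster go to a reserved id with warning", {
  tab <- toy_table()
  tab$gene_meta$functional_cluster[2] <- NA
  expect_warning(ft <- summarize_features(tab), "unclustered")
  expect_true("FamA|unclustered" %in% rownames(ft$values))
})

test_that("time screen is null-calibrated and powered for planted steps", {
  design <- balanced_design()
  set.seed(21)
  n_samp <- nrow(design)
  # null features: animal effect only; stepped features: jump at 4 h. The
  # stepped features are kept small so sample-sum scaling (a whole-table
  # normalisation) does not leak their signal into the nulls.
  base <- matrix(1000 * exp(rnorm(30 * n_samp, 0, 0.05)), nrow = 30)
  colnames(base) <- design$sample_id
  rownames(base) <- sprintf("null%02d", 1:30)
  # feature-specific animal effects (a shared effect would be removed by the
  # sample-sum scaling step)
  animal_eff <- matrix(rnorm(30 * 3, 0, 0.4), 30,
                       dimnames = list(rownames(base), sprintf("A%d", 1:3)))
  base <- base * exp(animal_eff[, design$animal_id])
  step <- matrix(20 * exp(rnorm(5 * n_samp, 0, 0.05)), nrow = 5)
  colnames(step) <- design$sample_id
  rownames(step) <- sprintf("step%02d", 1:5)
  step[, design$timepoint_h >= 4] <- step[, design$timepoint_h >= 4] * 6
  ft <- make_feature_table(round(rbind(base, step)), design)
  screen <- test_time_effect(ft, design)
  expect_true(all(screen$padj_time[grepl("step", screen$feature)] < 0.1))
  # null time p-values are roughly uniform: BH keeps them out at 0.1
  expect_lt(mean(screen$padj_time[grepl("null", screen$feature)] < 0.1), 0.2)
  # the animal signal is picked up by the animal screen
  expect_lt(stats::median(screen$p_animal[grepl("null", screen$feature)]),
            0.05)
})

test_that("a feature identical at all timepoints within animal is never significant", {
  design <- balanced_design()
  v <- stats::setNames(rep(c(10, 20, 30), times = 5)[
    match(design$animal_id, sprintf("A%d", 1:3))], design$sample_id)
  ft <- make_feature_table(matrix(v, 1, dimnames = list("flat", names(v))),
                           design)
  screen <- test_time_effect(ft, design)
  expect_gte(screen$p_time[1], 0.99)
})

test_that("replication across animals is required", {
  d <- balanced_design(n_animals = 1)
  ft <- make_feature_table(
    matrix(1:5, 1, dimnames = list("f", d$sample_id)), d
  )
  expect_error(test_time_effect(ft, d), "2 animals")
})

test_that("pairwise contrasts enumerate all timepoint pairs", {
  design <- balanced_design()
  set.seed(22)
  m <- matrix(rpois(2 * nrow(design), 100), 2,
              dimnames = list(c("f1", "f2"), design$sample_id))
  pw <- pairwise_timepoints(make_feature_table(m, design), design)
  expect_equal(nrow(pw), 2 * choose(5, 2))
  expect_equal(nrow(unique(pw[pw$feature == "f1", c("t1", "t2")])), 10L)

  d3 <- balanced_design(timepoints = c(1, 4, 8))
  m3 <- matrix(rpois(nrow(d3), 100), 1, dimnames = list("f", d3$sample_id))
  pw3 <- pairwise_timepoints(make_feature_table(m3, d3), d3)
  expect_equal(nrow(pw3), 3L)

  # all-equal feature: every adjusted p is 1
  flat <- matrix(50, 1, nrow(design),
                 dimnames = list("flat", design$sample_id))
  pwf <- pairwise_timepoints(make_feature_table(flat, design), design)
  expect_true(all(pwf$padj == 1))
})

test_that("BH within feature is monotone in the raw p-values", {
  design <- balanced_design()
  set.seed(23)
  m <- matrix(rpois(nrow(design), 100) *
                rep(c(1, 1, 2, 2, 3), each = 3), 1,
              dimnames = list("f", design$sample_id))
  pw <- pairwise_timepoints(make_feature_table(m, design), design)
  ord <- order(pw$p)
  expect_true(all(diff(pw$padj[ord]) >= -1e-12))
  expect_equal(pw$padj, oracle_bh(pw$p))
})

test_that("letters come from maximal cliques of the non-significance graph", {
  mk_pairs <- function(sig_pairs, tps = c(1, 2, 4, 6, 8)) {
    pr <- t(combn(tps, 2))
    data.frame(t1 = pr[, 1], t2 = pr[, 2],
               padj = ifelse(paste(pr[, 1], pr[, 2]) %in% sig_pairs, 0, 1))
  }
  # nothing significant: one clique, all "a"
  all_a <- significance_letters(mk_pairs(character(0)))
  expect_true(all(all_a$letters == "a"))
  expect_equal(all_a$key, "a|a|a|a|a")

  # everything significant: five distinct letters
  pr <- t(combn(c(1, 2, 4, 6, 8), 2))
  all_diff <- significance_letters(mk_pairs(paste(pr[, 1], pr[, 2])))
  expect_equal(unname(all_diff$letters), c("a", "b", "c", "d", "e"))

  # chain on three timepoints: T1-T2 and T2-T4 not significant, T1 vs T4 is
  chain <- significance_letters(data.frame(
    t1 = c(1, 1, 2), t2 = c(2, 4, 4), padj = c(1, 0, 1)
  ))
  expect_equal(unname(chain$letters), c("a", "ab", "b"))
})

test_that("with two timepoints the display reduces to a/a or a/b", {
  two_ns <- significance_letters(data.frame(t1 = 1, t2 = 8, padj = 0.5))
  expect_equal(unname(two_ns$letters), c("a", "a"))
  two_s <- significance_letters(data.frame(t1 = 1, t2 = 8, padj = 0.01))
  expect_equal(unname(two_s$letters), c("a", "b"))
})

test_that("pattern keys are invariant to letter renaming", {
  expect_equal(canonical_pattern_key(c("b", "ba", "a")),
               canonical_pattern_key(c("a", "ab", "b")))
  expect_false(canonical_pattern_key(c("a", "a", "b")) ==
                 canonical_pattern_key(c("a", "b", "b")))
})

test_that("letters satisfy the maximal-clique biconditional on many graphs", {
  # subset here; the exhaustive 1024-graph sweep runs in the acceptance suite
  pr <- t(combn(1:5, 2))
  set.seed(24)
  for (code in sample(0:1023, 128)) {
    nonsig <- as.logical(bitwAnd(code, 2^(0:9)))
    pairs <- data.frame(t1 = pr[, 1], t2 = pr[, 2],
                        padj = ifelse(nonsig, 1, 0))
    res <- significance_letters(pairs)
    adj <- matrix(FALSE, 5, 5)
    adj[as.matrix(pr)] <- nonsig
    adj <- adj | t(adj)
    diag(adj) <- TRUE
    share <- function(i, j) {
      any(mapply(grepl, strsplit(res$letters[i], "")[[1]],
                 MoreArgs = list(x = res$letters[j])))
    }
    # oracle: maximal cliques by exhaustive subset search
    subsets <- lapply(1:31, function(s) which(as.logical(bitwAnd(s, 2^(0:4)))))
    is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
    maximal <- vapply(seq_along(subsets), function(k) {
      if (!is_clique[k]) return(FALSE)
      !any(vapply(seq_along(subsets), function(j) {
        is_clique[j] && length(subsets[[j]]) > length(subsets[[k]]) &&
          all(subsets[[k]] %in% subsets[[j]])
      }, logical(1)))
    }, logical(1))
    max_cliques <- subsets[maximal]
    for (i in 1:4) for (j in (i + 1):5) {
      joint <- any(vapply(max_cliques, function(s) all(c(i, j) %in% s),
                          logical(1)))
      expect_equal(share(i, j), joint)
    }
  }
})

test_that("pattern grouping restricts to the top expression share", {
  design <- balanced_design()
  set.seed(25)
  vals <- matrix(rpois(4 * nrow(design), 10), 4,
                 dimnames = list(sprintf("f%d", 1:4), design$sample_id))
  vals[1, ] <- vals[1, ] * 1000   # f1 dominates expression
  ft <- make_feature_table(vals, design,
                           family = c("FamA", "FamA", "FamB", "FamB"))
  rownames(ft$values) <- ft$feature_meta$feature <- sprintf("f%d", 1:4)
  sig <- lapply(stats::setNames(rownames(vals), rownames(vals)), function(f) {
    list(letters = c(T1 = "a", T2 = "a", T4 = "a", T6 = "a", T8 = "a"),
         key = "a|a|a|a|a")
  })
  top <- pattern_grouping(sig, ft, design, top_fraction = 0.5)
  expect_equal(names(top$features), "f1")
  all_kept <- pattern_grouping(sig, ft, design, top_fraction = 1)
  expect_equal(length(all_kept$features), 4L)
  expect_equal(all_kept$patterns$n_features, 4L)
  # contributions are proportions summing to one
  expect_equal(sum(all_kept$family_contributions$proportion), 1)
})

test_that("planted temporal archetypes are recovered as dominant patterns", {
  b <- simulate_bundle(generator_config(seed = 2))
  ft <- summarize_features(b$table)
  de <- temporal_de(ft, b$design)
  expect_gt(length(de$features), 0)
  pat <- de$patterns
  ord <- order(-pat$patterns$total_expression)
  top5 <- pat$patterns$pattern[utils::head(ord, 5)]
  blk <- stats::setNames(b$profiles$families$block,
                         b$profiles$families$family)
  archetype <- vapply(top5, function(p) {
    te <- pat$timepoint_expression[p, ]
    fc <- pat$family_contributions
    fc <- fc[fc$pattern == p, ]
    dom <- unname(blk[fc$family[which.max(fc$proportion)]])
    dir <- te[["T8"]] - te[["T1"]]
    if (dir < 0 && dom == "primary") "early" else
      if (dir > 0 && dom == "secondary") "late" else "other"
  }, character(1))
  # both planted archetypes appear among the dominant patterns: an
  # early-high pattern led by a primary family and a late-high pattern led
  # by a secondary family
  expect_true("early" %in% archetype)
  expect_true("late" %in% archetype)
})
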