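# End-to-end orchestration: simulate (or load) a bundle, preprocess, build
# and cluster the network, run the keystone analysis, the temporal DE stage
# and the enzyme profiling, and optionally write the result tables plus a
# summary.json.

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulate -> preprocess -> network -> keystone ->
#' temporal DE -> enzymes. All thresholds default to the study settings:
#' min-gene filter 10, IQR quantile 0.25, rho threshold 0.7, BH alpha 0.1 for
#' edges, DE and enzyme screens, top expression fractions 0.9 (DE patterns)
#' and 0.95 (enzyme families), two keystones flagged per cluster.
#'
#' @param config A [generator_config()] used to simulate the input bundle;
#'   ignored when `bundle` is given.
#' @param bundle Optional list with `table` (`expression_table`) and `design`
#'   (`sample_design`) to analyse instead of simulating.
#' @param out_dir Optional output directory; when set, writes the input
#'   bundle, `edges.tsv`/`nodes.tsv`/`network.graphml`, `keystones.tsv`,
#'   `de_patterns.tsv`, `pattern_summary.tsv`, `enzyme_profiles.tsv`,
#'   `enzyme_letters.tsv`, the effective configuration and `summary.json`.
#' @param min_genes,iqr_quantile,pseudocount Pre-processing settings.
#' @param rho_min,alpha Network edge thresholds.
#' @param top_k Keystones flagged per cluster.
#' @param de_alpha,top_fraction Temporal DE settings.
#' @param enzyme_fraction,enzyme_alpha Enzyme-profiling settings.
#' @param min_cluster_size Minimum module size counted as a cluster in the
#'   summary (default 5): the analysis is about the large colonisation-phase
#'   clusters, and tiny modules are typically chance-correlation artifacts.
#'   All modules regardless of size are reported under `n_modules_total`.
#' @param skip_enzymes,skip_de Skip the corresponding stage.
#' @param overwrite Allow writing into an existing non-empty `out_dir`.
#' @return List with `bundle`, `matrices` (pre-processing stages), `network`,
#'   `keystones`, `de`, `enzymes` and `summary`.
#' @export
run_pipeline <- function(config = generator_config(), bundle = NULL,
                         out_dir = NULL, min_genes = 10, iqr_quantile = 0.25,
                         pseudocount = 1, rho_min = 0.7, alpha = 0.1,
                         top_k = 2, de_alpha = 0.1, top_fraction = 0.9,
                         enzyme_fraction = 0.95, enzyme_alpha = 0.1,
                         min_cluster_size = 5,
                         skip_enzymes = FALSE, skip_de = FALSE,
                         overwrite = FALSE) {
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
      stop("run_pipeline: output directory ", out_dir,
           " is not empty (use overwrite = TRUE)")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(bundle)) {
    bundle <- stage("simulate", simulate_bundle(config))
  } else {
    stopifnot(inherits(bundle$table, "expression_table"))
    bundle$design <- sample_design(bundle$design, bundle$table)
  }

  matrices <- stage("preprocess", preprocess_counts(
    bundle$table, bundle$design, min_genes = min_genes,
    quantile_cut = iqr_quantile, pseudocount = pseudocount
  ))

  net <- stage("network", {
    cm <- spearman_correlations(matrices$rlog)
    weights <- rowSums(unclass(matrices$scaled))[rownames(matrices$rlog)]
    detect_clusters(build_network(cm, weights, rho_min = rho_min,
                                  alpha = alpha))
  })

  keystones <- stage("keystone", keystone_analysis(net, top_k = top_k))

  de <- if (skip_de) NULL else stage("de", {
    ft <- summarize_features(bundle$table)
    temporal_de(ft, bundle$design, alpha = de_alpha,
                top_fraction = top_fraction)
  })

  enzymes <- if (skip_enzymes) NULL else stage("enzymes", enzyme_analysis(
    bundle$table, bundle$design, fraction = enzyme_fraction,
    alpha = enzyme_alpha
  ))

  labels <- net$membership[!is.na(net$membership)]
  # "clusters" are the large modules; small modules (below min_cluster_size)
  # are chance-correlation artifacts and only counted in n_modules_total
  module_sizes <- table(labels)
  keystone_list <- if (nrow(keystones) > 0) {
    split(keystones$node[keystones$keystone],
          keystones$cluster[keystones$keystone])
  } else {
    list()
  }
  summary <- list(
    n_samples = nrow(bundle$design),
    n_genes = nrow(bundle$table$counts),
    n_families = length(unique(bundle$table$gene_meta$family)),
    n_families_network = nrow(matrices$rlog),
    n_edges = nrow(net$edges),
    n_negative_edges = sum(net$edges$sign == "-"),
    n_clusters = sum(module_sizes >= min_cluster_size),
    n_modules_total = length(module_sizes),
    modularity = net$modularity,
    keystones = keystone_list,
    n_de_features = if (is.null(de)) NA_integer_ else length(de$features),
    n_de_patterns = if (is.null(de) || is.null(de$patterns)) NA_integer_ else
      nrow(de$patterns$patterns),
    n_enzyme_families = if (is.null(enzymes) || is.null(enzymes$anova))
      NA_integer_ else nrow(enzymes$anova),
    n_significant_enzyme_families = if (is.null(enzymes) ||
                                        is.null(enzymes$anova))
      NA_integer_ else sum(enzymes$anova$padj < enzyme_alpha)
  )

  result <- list(bundle = bundle, matrices = matrices, network = net,
                 keystones = keystones, de = de, enzymes = enzymes,
                 summary = summary)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir, config)
  result
}

.write_pipeline_outputs <- function(result, out_dir, config) {
  write_bundle(result$bundle$table, result$bundle$design,
               file.path(out_dir, "bundle"))
  write_network(result$network, out_dir)
  .write_tsv(as.data.frame(result$keystones),
             file.path(out_dir, "keystones.tsv"))
  if (!is.null(result$de) && length(result$de$features) > 0) {
    lets <- result$de$letters
    de_df <- data.frame(
      feature = names(lets),
      pattern = vapply(lets, `[[`, character(1), "key"),
      letters = vapply(lets, function(x) paste(x$letters, collapse = "|"),
                       character(1)),
      stringsAsFactors = FALSE
    )
    .write_tsv(de_df, file.path(out_dir, "de_patterns.tsv"))
    .write_tsv(result$de$patterns$patterns,
               file.path(out_dir, "pattern_summary.tsv"))
  }
  if (!is.null(result$enzymes) && !is.null(result$enzymes$anova)) {
    .write_tsv(result$enzymes$anova,
               file.path(out_dir, "enzyme_profiles.tsv"))
    if (length(result$enzymes$letters) > 0) {
      el <- data.frame(
        enzyme_family = names(result$enzymes$letters),
        letters = vapply(result$enzymes$letters,
                         function(x) paste(x$letters, collapse = "|"),
                         character(1)),
        stringsAsFactors = FALSE
      )
      .write_tsv(el, file.path(out_dir, "enzyme_letters.tsv"))
    }
  }
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
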