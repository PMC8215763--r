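# Readers/writers for the annotated count-table bundle and all result tables.
# Single authority for column naming: counts.tsv (gene_id + one column per
# sample), gene_meta.tsv (gene_id, family, genus, functional_cluster,
# enzyme_tag, length_bp), design.tsv (sample_id, animal_id, timepoint_h).
# All files are tab-separated UTF-8 with a header row; timepoints are stored
# as hours and labelled "T{h}" in reports.

#' Construct and validate an expression table
#'
#' @param counts Non-negative integer gene x sample matrix with gene ids as
#'   row names and sample ids as column names.
#' @param gene_meta Data frame with columns `gene_id`, `family`, `genus`,
#'   `functional_cluster`, `enzyme_tag` (NA where untagged), `length_bp`.
#' @param check_orf_floor Warn about genes shorter than 300 bp (the 100-aa ORF
#'   floor of typical CDS prediction); never an error.
#' @return An `expression_table` (list with `counts` and `gene_meta`).
#' @export
expression_table <- function(counts, gene_meta, check_orf_floor = FALSE) {
  meta_cols <- c("gene_id", "family", "genus", "functional_cluster",
                 "enzyme_tag", "length_bp")
  missing <- setdiff(meta_cols, names(gene_meta))
  if (length(missing) > 0) {
    stop("expression_table: gene_meta missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(gene_meta$gene_id)) {
    dup <- gene_meta$gene_id[duplicated(gene_meta$gene_id)][1]
    stop("expression_table: duplicate gene id: ", dup)
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("expression_table: counts must carry gene and sample names")
  }
  if (!setequal(rownames(counts), gene_meta$gene_id)) {
    off <- c(setdiff(rownames(counts), gene_meta$gene_id),
             setdiff(gene_meta$gene_id, rownames(counts)))[1]
    stop("expression_table: counts/gene_meta gene mismatch: ", off)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("expression_table: negative count for gene ",
         rownames(counts)[bad[1]], " in sample ", colnames(counts)[bad[2]])
  }
  if (any(counts != round(counts))) {
    stop("expression_table: counts must be integers")
  }
  if (any(gene_meta$length_bp <= 0)) {
    stop("expression_table: non-positive gene length for gene ",
         gene_meta$gene_id[which(gene_meta$length_bp <= 0)[1]])
  }
  if (check_orf_floor && any(gene_meta$length_bp < 300)) {
    warning("expression_table: ", sum(gene_meta$length_bp < 300),
            " gene(s) shorter than the 300 bp (100 aa) ORF floor")
  }
  storage.mode(counts) <- "integer"
  gene_meta <- gene_meta[match(rownames(counts), gene_meta$gene_id), meta_cols]
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, gene_meta = gene_meta),
            class = "expression_table")
}

#' Validate a sample design against an expression table
#'
#' @param design Data frame with `sample_id`, `animal_id`, `timepoint_h`.
#' @param table Optional `expression_table` whose samples must all appear in
#'   the design (and vice versa).
#' @return The design with class `sample_design`; baseline samples are those
#'   with `timepoint_h == 0`.
#' @export
sample_design <- function(design, table = NULL) {
  need <- c("sample_id", "animal_id", "timepoint_h")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0) {
    stop("sample_design: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("sample_design: duplicate sample id: ",
         design$sample_id[duplicated(design$sample_id)][1])
  }
  key <- paste(design$animal_id, design$timepoint_h)
  if (anyDuplicated(key)) {
    stop("sample_design: duplicate (animal, timepoint) pair: ",
         key[duplicated(key)][1])
  }
  if (any(design$timepoint_h < 0)) stop("sample_design: negative timepoint")
  if (!is.null(table)) {
    extra <- setdiff(colnames(table$counts), design$sample_id)
    if (length(extra) > 0) {
      stop("sample_design: sample absent from design: ", extra[1])
    }
    extra2 <- setdiff(design$sample_id, colnames(table$counts))
    if (length(extra2) > 0) {
      stop("sample_design: design sample absent from counts: ", extra2[1])
    }
  }
  design <- as.data.frame(design)[, need]
  rownames(design) <- NULL
  class(design) <- c("sample_design", "data.frame")
  design
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Write the three-file TSV bundle
#'
#' @param table An `expression_table`.
#' @param design A `sample_design`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`counts.tsv`, `gene_meta.tsv`,
#'   `design.tsv`).
#' @export
write_bundle <- function(table, design, dir) {
  stopifnot(inherits(table, "expression_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(table$counts),
                          table$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  paths <- c(
    counts = .write_tsv(counts_df, file.path(dir, "counts.tsv")),
    gene_meta = .write_tsv(table$gene_meta, file.path(dir, "gene_meta.tsv")),
    design = .write_tsv(as.data.frame(design), file.path(dir, "design.tsv"))
  )
  invisible(paths)
}

#' Read and validate a count-table bundle
#'
#' @param dir Directory holding `counts.tsv`, `gene_meta.tsv`, `design.tsv`.
#' @return List with `table` (`expression_table`) and `design`
#'   (`sample_design`). Errors name the offending column, gene or sample.
#' @export
read_bundle <- function(dir) {
  counts_df <- .read_tsv(file.path(dir, "counts.tsv"))
  if (!"gene_id" %in% names(counts_df)) {
    stop("read_bundle: counts.tsv missing column: gene_id")
  }
  counts <- as.matrix(counts_df[, setdiff(names(counts_df), "gene_id"),
                                drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  gene_meta <- .read_tsv(file.path(dir, "gene_meta.tsv"))
  design <- .read_tsv(file.path(dir, "design.tsv"))
  table <- expression_table(counts, gene_meta)
  design <- sample_design(design, table)
  list(table = table, design = design)
}

#' Write a family network as edge list, node table and GraphML
#'
#' Edge records carry `rho`, raw and BH-adjusted p and the sign; node records
#' carry total expression and cluster label. GraphML preserves all typed
#' attributes so that re-reading reproduces the graph exactly.
#'
#' @param net A `family_network` (see [build_network()]).
#' @param dir Output directory.
#' @return Invisibly, the written paths (`edges.tsv`, `nodes.tsv`,
#'   `network.graphml`).
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "family_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(
    family = igraph::V(net$graph)$name,
    total_expression = igraph::V(net$graph)$total_expression,
    cluster = igraph::V(net$graph)$cluster,
    stringsAsFactors = FALSE
  )
  paths <- c(
    edges = .write_tsv(net$edges, file.path(dir, "edges.tsv")),
    nodes = .write_tsv(nodes, file.path(dir, "nodes.tsv")),
    graphml = {
      p <- file.path(dir, "network.graphml")
      igraph::write_graph(net$graph, p, format = "graphml")
      p
    }
  )
  invisible(paths)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to a GraphML file.
#' @return An igraph graph with the stored node and edge attributes.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
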