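#' Read a tab-separated count matrix
#'
#' Expects a header line (first cell a feature-ID column name, the rest
#' sample IDs) and one row per feature with non-negative integer counts.
#' Ragged rows, non-integer entries and duplicate feature IDs are
#' rejected with the offending line number.
#'
#' @param path TSV file path.
#' @return Integer matrix (features x samples) with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort("counts file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1) abort("counts file is empty: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2) abort("line 1: header must name a feature column and >= 1 sample")
  samples <- header[-1]
  n_feat <- length(lines) - 1L
  mat <- matrix(0L, nrow = n_feat, ncol = n_col - 1L,
                dimnames = list(NULL, samples))
  ids <- character(n_feat)
  for (i in seq_len(n_feat)) {
    row <- fields[[i + 1L]]
    line_no <- i + 1L
    if (length(row) != n_col)
      abort("line %d: expected %d fields, found %d", line_no, n_col, length(row))
    vals <- row[-1]
    bad <- !grepl("^[0-9]+$", vals)
    if (any(bad))
      abort("line %d: non-integer count '%s'", line_no, vals[which(bad)[1]])
    ids[i] <- row[1]
    mat[i, ] <- as.integer(vals)
  }
  dup <- duplicated(ids)
  if (any(dup))
    abort("line %d: duplicate feature ID '%s'", which(dup)[1] + 1L,
          ids[which(dup)[1]])
  rownames(mat) <- ids
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with feature rownames and sample
#'   colnames.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target table
#'
#' @param path TSV with columns `mirna`, `target`, `target_class`
#'   (`mRNA`/`lncRNA`) and `mre_count` (integer >= 1); duplicate
#'   (`mirna`, `target`) pairs are rejected.
#' @return The validated data frame.
#' @export
read_target_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "target", "target_class", "mre_count")
  if (!all(need %in% names(tab)))
    abort("target table must have columns: %s", paste(need, collapse = ", "))
  if (!all(tab$target_class %in% c("mRNA", "lncRNA")))
    abort("target_class must be 'mRNA' or 'lncRNA'")
  if (any(tab$mre_count < 1) || any(tab$mre_count != round(tab$mre_count)))
    abort("mre_count must be an integer >= 1")
  if (anyDuplicated(tab[, c("mirna", "target")]))
    abort("duplicate (mirna, target) pairs in target table")
  tab
}

#' Write a miRNA-target table as TSV
#' @param targets target table data frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_target_table <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a DE table as TSV
#' @param table DE table from [de_test()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(format(table, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE table written by [write_de_table()]
#' @param path TSV file path.
#' @return The DE table data frame.
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

network_edge_table <- function(network) {
  e <- network$edges
  if (inherits(network, "coexpression_network")) {
    data.frame(from = e$lncrna, to = e$mrna, type = rep("pp", nrow(e)),
               weight = e$weight, p = e$p, stringsAsFactors = FALSE)
  } else {
    e[, c("from", "to", "type", "weight", "p")]
  }
}

#' Export a network for Cytoscape
#'
#' Writes the network in one of three formats: `"sif"`
#' (`source<TAB>edgetype<TAB>target` lines; edge types `pp` for
#' co-expression networks, `targets`/`coexp` for ceRNA networks),
#' `"tsv"` (edge table with weights and p-values; a companion
#' `<path>.nodes.tsv` node-attribute table), or `"graphml"` (nodes with
#' `class`, `direction`, `degree` attributes). Node and edge ordering is
#' deterministic.
#'
#' @param network a `cerna_network` or `coexpression_network`.
#' @param path output file.
#' @param format one of `"sif"`, `"tsv"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("sif", "tsv", "graphml")) {
  if (length(format) == 1 && !format %in% c("sif", "tsv", "graphml"))
    abort("unknown network format '%s'", format)
  format <- match.arg(format)
  edges <- network_edge_table(network)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  nodes <- network$nodes[order(network$nodes$class, network$nodes$node), ,
                         drop = FALSE]
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to), path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    writeLines(graphml_string(nodes, edges), path)
  }
  invisible(path)
}

graphml_string <- function(nodes, edges) {
  has_dir <- "direction" %in% names(nodes)
  keys <- c(
    '  <key id="class" for="node" attr.name="class" attr.type="string"/>',
    if (has_dir) '  <key id="direction" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="degree" for="node" attr.name="degree" attr.type="int"/>',
    '  <key id="type" for="edge" attr.name="type" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>'
  )
  node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
    paste0('    <node id="', xml_escape(nodes$node[i]), '">\n',
           '      <data key="class">', nodes$class[i], "</data>\n",
           if (has_dir) paste0('      <data key="direction">',
                               nodes$direction[i], "</data>\n") else "",
           '      <data key="degree">', nodes$degree[i], "</data>\n",
           "    </node>")
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(edges)), function(i) {
    w <- if (is.na(edges$weight[i])) "" else
      paste0('      <data key="weight">', format(edges$weight[i], digits = 10),
             "</data>\n")
    paste0('    <edge source="', xml_escape(edges$from[i]), '" target="',
           xml_escape(edges$to[i]), '">\n',
           '      <data key="type">', edges$type[i], "</data>\n", w,
           "    </edge>")
  }, character(1))
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    '  <graph id="G" edgedefault="undirected">',
    node_xml, edge_xml,
    "  </graph>", "</graphml>")
}
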