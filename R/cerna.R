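#' Pearson correlation with t-based significance
#'
#' Returns the Pearson coefficient and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, both
#'   non-constant.
#' @return A list with elements `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4) abort("pearson_test needs n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n)[1])
}

#' Screen lncRNA-mRNA candidate pairs by correlation
#'
#' Evaluates every lncRNA x mRNA pair among the differentially expressed
#' features and keeps those with a signed Pearson correlation strictly
#' above `pcc_min` and correlation p-value below `alpha`. The signed rule
#' (not `|PCC|`) reflects the ceRNA hypothesis: transcripts competing for
#' the same miRNAs co-vary positively.
#'
#' @param expr_lnc,expr_mrna log-normalized expression matrices
#'   (features x samples, shared samples).
#' @param de_lnc,de_mrna character vectors of differentially expressed
#'   feature IDs (rows are restricted to these; IDs absent from the
#'   matrices are ignored).
#' @param pcc_min,alpha thresholds (defaults 0.8 and 0.05, both strict).
#' @return Data frame of candidate pairs: `lncrna`, `mrna`, `pcc`,
#'   `pcc_p`, sorted by (`lncrna`, `mrna`).
#' @export
candidate_pairs <- function(expr_lnc, expr_mrna, de_lnc, de_mrna,
                            pcc_min = 0.8, alpha = 0.05) {
  de_lnc <- intersect(de_lnc, rownames(expr_lnc))
  de_mrna <- intersect(de_mrna, rownames(expr_mrna))
  empty <- data.frame(lncrna = character(0), mrna = character(0),
                      pcc = numeric(0), pcc_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(de_lnc) == 0 || length(de_mrna) == 0) {
    warnf("empty differential-expression set: no candidate pairs")
    return(empty)
  }
  net <- build_lnc_mrna_network(expr_lnc[de_lnc, , drop = FALSE],
                                expr_mrna[de_mrna, , drop = FALSE],
                                pcc_min = pcc_min, alpha = alpha)
  out <- net$edges
  names(out) <- c("lncrna", "mrna", "pcc", "pcc_p")
  out
}

#' Shared differentially expressed miRNAs of a lncRNA-mRNA pair
#'
#' Intersects the differentially expressed miRNAs targeting the lncRNA
#' with those targeting the mRNA, and sums MRE (miRNA response element)
#' counts per member.
#'
#' @param lncrna_id,mrna_id the pair's feature IDs.
#' @param targets target table (`mirna`, `target`, `target_class`,
#'   `mre_count`).
#' @param de_mirnas character vector of differentially expressed miRNA
#'   IDs (the universe of miRNAs under consideration).
#' @return List with `shared` (sorted miRNA IDs), `mre_lncrna` and
#'   `mre_mrna` (total MRE counts of the shared miRNAs on each member).
#' @export
shared_mirnas <- function(lncrna_id, mrna_id, targets, de_mirnas) {
  tl <- targets[targets$target == lncrna_id & targets$mirna %in% de_mirnas, ]
  tm <- targets[targets$target == mrna_id & targets$mirna %in% de_mirnas, ]
  shared <- sort(intersect(tl$mirna, tm$mirna))
  list(
    shared = shared,
    mre_lncrna = sum(tl$mre_count[tl$mirna %in% shared]),
    mre_mrna = sum(tm$mre_count[tm$mirna %in% shared])
  )
}

#' Hypergeometric test for shared miRNAs
#'
#' Upper-tail probability of observing at least `n_shared` miRNAs in
#' common between the `n_target_lnc` miRNAs targeting the lncRNA and the
#' `n_target_mrna` miRNAs targeting the mRNA, when both sets are drawn
#' from a universe of `n_universe` miRNAs:
#' `p = sum_{i >= x} C(K, i) C(N - K, n - i) / C(N, n)`.
#'
#' @param n_universe universe size N (e.g. number of differentially
#'   expressed miRNAs).
#' @param n_target_lnc,n_target_mrna set sizes K and n.
#' @param n_shared observed overlap x.
#' @return The upper-tail p-value (1 when `n_shared = 0`).
#' @export
#' @examples
#' hypergeom_shared_test(10, 5, 4, 4)  # 5/210
hypergeom_shared_test <- function(n_universe, n_target_lnc, n_target_mrna,
                                  n_shared) {
  for (v in c(n_universe, n_target_lnc, n_target_mrna, n_shared))
    if (!is_count_scalar(v)) abort("all arguments must be non-negative integers")
  if (n_target_lnc > n_universe || n_target_mrna > n_universe)
    abort("target-set sizes cannot exceed the universe")
  if (n_shared > min(n_target_lnc, n_target_mrna))
    abort("'n_shared' cannot exceed either target-set size")
  stats::phyper(n_shared - 1, n_target_lnc, n_universe - n_target_lnc,
                n_target_mrna, lower.tail = FALSE)
}

#' Assemble the lncRNA-miRNA-mRNA ceRNA network
#'
#' Retains a candidate lncRNA-mRNA pair when (i) the two members share at
#' least `min_shared` differentially expressed miRNAs in the target table
#' and (ii) the hypergeometric test on that overlap is significant at
#' `alpha` (`alpha = 1` disables the gate). Retained pairs contribute a
#' co-expression edge; every shared miRNA contributes target edges to
#' both members. Node regulation direction is looked up in the DE tables.
#'
#' @param de_tables named list of DE tables from [de_test()], with
#'   elements `mrna`, `lncrna`, `mirna` (calls determine the DE sets and
#'   directions).
#' @param pairs candidate pairs from [candidate_pairs()].
#' @param targets miRNA-target table.
#' @param alpha hypergeometric significance threshold (default 0.05,
#'   strict; `>= 1` keeps every pair).
#' @param min_shared minimum number of shared DE miRNAs (default 2: the
#'   strict reading of "more than 1").
#' @param universe hypergeometric universe size N; defaults to the
#'   number of differentially expressed miRNAs.
#' @return An object of class `cerna_network`: list with `nodes`
#'   (`node`, `class`, `direction`, `degree`), `edges` (`from`, `to`,
#'   `type` in `targets`/`coexp`, `weight`, `p`) and `pairs` (retained
#'   pairs with `n_shared` and `hypergeom_p`).
#' @export
assemble_cerna <- function(de_tables, pairs, targets, alpha = 0.05,
                           min_shared = 2, universe = NULL) {
  stopifnot(all(c("mrna", "lncrna", "mirna") %in% names(de_tables)))
  mir_tab <- de_tables$mirna
  de_mir <- mir_tab$feature[mir_tab$call != "ns"]
  N <- universe %||% length(de_mir)
  if (N < 1 && nrow(pairs) > 0) {
    warnf("empty miRNA universe: no pair can be retained")
    return(new_cerna_network(empty_pairs(), de_tables))
  }
  tg <- targets[targets$mirna %in% de_mir, , drop = FALSE]

  res <- empty_pairs()
  if (nrow(pairs) > 0) {
    recs <- lapply(seq_len(nrow(pairs)), function(i) {
      lnc <- pairs$lncrna[i]; mr <- pairs$mrna[i]
      sh <- shared_mirnas(lnc, mr, tg, de_mir)
      K <- length(unique(tg$mirna[tg$target == lnc]))
      n <- length(unique(tg$mirna[tg$target == mr]))
      p <- if (K > N || n > N) 1 else
        hypergeom_shared_test(N, K, n, length(sh$shared))
      data.frame(lncrna = lnc, mrna = mr, pcc = pairs$pcc[i],
                 pcc_p = pairs$pcc_p[i], n_shared = length(sh$shared),
                 hypergeom_p = p,
                 shared = paste(sh$shared, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, recs)
    keep <- res$n_shared >= min_shared & (alpha >= 1 | res$hypergeom_p < alpha)
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
  }
  new_cerna_network(res, de_tables)
}

empty_pairs <- function() {
  data.frame(lncrna = character(0), mrna = character(0), pcc = numeric(0),
             pcc_p = numeric(0), n_shared = integer(0),
             hypergeom_p = numeric(0), shared = character(0),
             stringsAsFactors = FALSE)
}

new_cerna_network <- function(retained, de_tables) {
  coexp <- data.frame(from = retained$lncrna, to = retained$mrna,
                      type = rep("coexp", nrow(retained)),
                      weight = retained$pcc, p = retained$pcc_p,
                      stringsAsFactors = FALSE)
  tgt <- data.frame(from = character(0), to = character(0),
                    type = character(0), weight = numeric(0), p = numeric(0),
                    stringsAsFactors = FALSE)
  if (nrow(retained) > 0) {
    lst <- lapply(seq_len(nrow(retained)), function(i) {
      sh <- strsplit(retained$shared[i], ",", fixed = TRUE)[[1]]
      sh <- sh[nzchar(sh)]
      if (!length(sh)) return(NULL)
      data.frame(from = rep(sh, 2),
                 to = rep(c(retained$lncrna[i], retained$mrna[i]),
                          each = length(sh)),
                 type = "targets", weight = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    })
    got <- do.call(rbind, lst)
    if (!is.null(got)) tgt <- unique(got)
  }
  edges <- rbind(tgt, coexp)
  if (nrow(edges))
    edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  node_class <- c(
    stats::setNames(rep("lncRNA", length(unique(retained$lncrna))),
                    unique(retained$lncrna)),
    stats::setNames(rep("mRNA", length(unique(retained$mrna))),
                    unique(retained$mrna)),
    stats::setNames(rep("miRNA", length(unique(tgt$from))), unique(tgt$from))
  )
  if (is.null(names(node_class))) names(node_class) <- character(0)
  direction <- vapply(names(node_class), function(id) {
    for (tab in de_tables) {
      hit <- which(tab$feature == id)
      if (length(hit)) return(tab$call[hit[1]])
    }
    "ns"
  }, character(1))
  deg <- table(c(edges$from, edges$to))
  nodes <- data.frame(
    node = names(node_class),
    class = unname(node_class),
    direction = as.character(direction),
    degree = as.integer(ifelse(names(node_class) %in% names(deg),
                               deg[names(node_class)], 0L)),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$class, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = retained),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d lncRNAs, %d miRNAs, %d mRNAs | %d edges (%d targeting, %d co-expression)\n",
              sum(x$nodes$class == "lncRNA"), sum(x$nodes$class == "miRNA"),
              sum(x$nodes$class == "mRNA"), nrow(x$edges),
              sum(x$edges$type == "targets"), sum(x$edges$type == "coexp")))
  invisible(x)
}

#' Degree-centrality report
#'
#' Ranks network nodes by degree (descending), ties broken by node ID, so
#' hub RNAs — the molecules contributing most interactions — top the
#' table.
#'
#' @param network a `cerna_network` (or `coexpression_network`).
#' @return Data frame with columns `node`, `class`, `direction` (when
#'   available) and `degree`.
#' @export
degree_report <- function(network) {
  nodes <- network$nodes
  nodes <- nodes[order(-nodes$degree, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Extract the sub-network around one miRNA
#'
#' Keeps the named miRNA, every target it has in the network, and the
#' retained lncRNA-mRNA co-expression edges among those targets.
#'
#' @param network a `cerna_network`.
#' @param mirna_id miRNA node ID (error if absent).
#' @return A `cerna_network` restricted to the miRNA's neighborhood.
#' @export
extract_mirna_subnetwork <- function(network, mirna_id) {
  stopifnot(inherits(network, "cerna_network"))
  mir_nodes <- network$nodes$node[network$nodes$class == "miRNA"]
  if (!(mirna_id %in% mir_nodes))
    abort("miRNA '%s' is not in the network", mirna_id)
  tgt_edges <- network$edges[network$edges$type == "targets" &
                               network$edges$from == mirna_id, , drop = FALSE]
  members <- tgt_edges$to
  coexp <- network$edges[network$edges$type == "coexp" &
                           network$edges$from %in% members &
                           network$edges$to %in% members, , drop = FALSE]
  edges <- rbind(tgt_edges, coexp)
  rownames(edges) <- NULL
  keep <- c(mirna_id, members)
  nodes <- network$nodes[network$nodes$node %in% keep, , drop = FALSE]
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(ifelse(nodes$node %in% names(deg),
                                    deg[nodes$node], 0L))
  rownames(nodes) <- NULL
  pairs <- network$pairs[network$pairs$lncrna %in% members &
                           network$pairs$mrna %in% members, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = pairs),
            class = "cerna_network")
}
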