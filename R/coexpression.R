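#' Co-expression similarity matrix
#'
#' The similarity between two features is the absolute value of the
#' Pearson correlation of their expression profiles across samples,
#' `S_ij = |cor(i, j)|`, with unit diagonal. Zero-variance features are
#' excluded with a warning (their correlation is undefined).
#'
#' @param expr numeric matrix, features x samples (typically
#'   log2-normalized expression), >= 3 samples.
#' @return Symmetric matrix with entries in `[0, 1]`, diagonal 1; the
#'   excluded feature IDs are recorded in attribute `"excluded"`.
#' @export
similarity <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) abort("similarity needs >= 3 samples")
  v <- row_vars(expr)
  excluded <- rownames(expr)[v == 0] %||% character(0)
  if (length(excluded)) {
    warnf("excluding %d zero-variance feature(s): %s", length(excluded),
          paste(utils::head(excluded, 5), collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  S <- abs(stats::cor(t(expr)))
  diag(S) <- 1
  attr(S, "excluded") <- excluded
  S
}

#' Soft-threshold adjacency
#'
#' Raises the similarity matrix elementwise to the power `beta`
#' (`a_ij = S_ij^beta`), the soft-thresholding step that sharpens strong
#' correlations relative to weak ones. The diagonal is set to 0 so a
#' node's connectivity excludes self-similarity.
#'
#' @param S similarity matrix from [similarity()].
#' @param beta positive integer soft-threshold exponent.
#' @return Adjacency matrix with zero diagonal; `beta` stored as an
#'   attribute.
#' @export
soft_adjacency <- function(S, beta) {
  if (!is_scalar_number(beta) || beta < 1 || abs(beta - round(beta)) > 1e-8)
    abort("'beta' must be a positive integer")
  A <- S^beta
  diag(A) <- 0
  attr(A, "beta") <- as.integer(beta)
  attr(A, "excluded") <- NULL
  A
}

#' Weighted connectivity
#'
#' The connectivity of node i is the sum of its adjacency weights to all
#' other nodes, `k_i = sum_j a_ij`; in a binarized network this is the
#' neighbor count.
#'
#' @param A adjacency matrix (zero diagonal).
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(A) {
  A <- as.matrix(A)
  rowSums(A) - diag(A)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the (positive) connectivities into `n_bins` equal-width bins,
#' regresses `log10` of the per-bin frequency `p(k)` on `log10` of the
#' per-bin mean connectivity over non-empty bins, and reports the signed
#' fit index `-sign(slope) * R^2` so that only decaying (power-law-like,
#' `p(k) ~ k^-gamma`) distributions can score highly. The slope estimates
#' `-gamma`.
#'
#' @param k connectivity vector.
#' @param n_bins number of equal-width bins (default 10).
#' @return A list of class `scale_free_fit` with `signed_r2`, `slope`,
#'   `mean_k` (mean of the input connectivities), `n_bins` (non-empty
#'   bins used) and `beta` (NA here; filled by [pick_beta()]).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k_all <- k
  k <- k[k > 0]
  if (length(k) == 0 || min(k) == max(k))
    abort("scale-free fit needs >= 3 non-empty connectivity bins")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- as.integer(table(bin))
  keep <- cnt > 0
  if (sum(keep) < 3)
    abort("scale-free fit needs >= 3 non-empty connectivity bins")
  pk <- cnt[keep] / sum(cnt)
  km <- as.numeric(tapply(k, bin, mean))[keep]
  fit <- stats::lm(log10(pk) ~ log10(km))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(beta = NA_integer_,
                 signed_r2 = -sign(slope) * r2,
                 slope = slope,
                 mean_k = mean(k_all),
                 n_bins = sum(keep)),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: beta=%s signed_r2=%.3f slope=%.3f mean_k=%.2f\n",
              ifelse(is.na(x$beta), "?", x$beta), x$signed_r2, x$slope,
              x$mean_k))
  invisible(x)
}

#' Select the soft threshold by the scale-free topology criterion
#'
#' Sweeps `beta` over `beta_range`, fitting the scale-free index of the
#' resulting connectivity distribution at each value, and chooses the
#' smallest `beta` whose signed R-squared reaches `r2_target` while the
#' mean connectivity stays at or above `min_mean_k` (so the network is
#' not thresholded into dust). If no `beta` qualifies the one maximizing
#' the signed R-squared is returned with `criterion_met = FALSE` and a
#' warning.
#'
#' @param expr features x samples expression matrix (a similarity matrix
#'   is computed internally).
#' @param beta_range candidate integer exponents (default `1:30`).
#' @param r2_target signed R-squared required (default 0.8).
#' @param min_mean_k minimum acceptable mean connectivity (default 1).
#' @param n_bins bins passed to [scale_free_fit()].
#' @return A list of class `beta_sweep`: `beta` (chosen), `fit` (its
#'   `scale_free_fit`), `criterion_met`, and `sweep` (data frame with one
#'   row per candidate: `beta`, `signed_r2`, `slope`, `mean_k`).
#' @export
pick_beta <- function(expr, beta_range = 1:30, r2_target = 0.8,
                      min_mean_k = 1, n_bins = 10) {
  if (length(beta_range) == 0) abort("'beta_range' must be non-empty")
  S <- similarity(expr)
  rows <- lapply(beta_range, function(b) {
    f <- tryCatch(scale_free_fit(connectivity(soft_adjacency(S, b)), n_bins),
                  error = function(e) {
                    warnf("beta=%d skipped: %s", b, conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) {
      data.frame(beta = b, signed_r2 = NA_real_, slope = NA_real_,
                 mean_k = NA_real_)
    } else {
      data.frame(beta = b, signed_r2 = f$signed_r2, slope = f$slope,
                 mean_k = f$mean_k)
    }
  })
  sweep_df <- do.call(rbind, rows)
  ok <- !is.na(sweep_df$signed_r2)
  qual <- ok & sweep_df$signed_r2 >= r2_target & sweep_df$mean_k >= min_mean_k
  if (any(qual)) {
    beta <- sweep_df$beta[which(qual)[1]]
    met <- TRUE
  } else {
    if (!any(ok)) abort("no beta produced a valid scale-free fit")
    beta <- sweep_df$beta[which.max(ifelse(ok, sweep_df$signed_r2, -Inf))]
    met <- FALSE
    warnf("no beta reached signed R^2 >= %.2f with mean k >= %.2f; using beta=%d (max R^2)",
          r2_target, min_mean_k, beta)
  }
  fit <- scale_free_fit(connectivity(soft_adjacency(S, beta)), n_bins)
  fit$beta <- as.integer(beta)
  structure(list(beta = as.integer(beta), fit = fit, criterion_met = met,
                 sweep = sweep_df),
            class = "beta_sweep")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` counts shared weighted neighbors (the unsigned
#' WGCNA form); `TOM_ii = 1` by convention. `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param A adjacency matrix: symmetric, entries in `[0, 1]`, zero
#'   diagonal.
#' @return The TOM matrix (entries in `[0, 1]`, unit diagonal).
#' @export
tom <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-10)
    abort("adjacency must be square and symmetric")
  if (any(A < 0 | A > 1)) abort("adjacency entries must be in [0, 1]")
  if (any(diag(A) != 0)) abort("adjacency diagonal must be zero")
  k <- rowSums(A)
  L <- A %*% A  # zero diagonal of A removes u = i and u = j terms
  den <- outer(k, k, pmin) + 1 - A
  stopifnot(all(den > 0))
  TOM <- (L + A) / den
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Module detection by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' (`1 - TOM`), cut statically at `cut_height`; clusters smaller than
#' `min_module_size` are labelled `"unassigned"`. Modules are renamed
#' `M1, M2, ...` by decreasing size (ties broken by first occurrence) so
#' labels are deterministic.
#'
#' @param dissimilarity square dissimilarity matrix (e.g. `1 - tom(A)`).
#' @param cut_height static cut height in `(0, 1]`.
#' @param min_module_size minimum cluster size to be called a module.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return Character vector of module labels, named by feature.
#' @export
cluster_modules <- function(dissimilarity, cut_height = 0.95,
                            min_module_size = 3, linkage = "average") {
  if (!is_scalar_number(cut_height) || cut_height <= 0 || cut_height > 1)
    abort("'cut_height' must be in (0, 1]")
  D <- as.matrix(dissimilarity)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  # average linkage is monotone up to floating error; cutree() insists on
  # exactly non-decreasing heights
  hc$height <- cummax(round(hc$height, 12))
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  ord <- big[order(-sizes[big], as.integer(big))]
  labels <- rep("unassigned", length(cl))
  for (i in seq_along(ord)) labels[cl == ord[i]] <- sprintf("M%d", i)
  stats::setNames(labels, rownames(D) %||% names(cl))
}

#' Build the lncRNA-mRNA co-expression network
#'
#' Connects a lncRNA and an mRNA when their expression profiles satisfy
#' `PCC > pcc_min` (signed, strict) with a correlation-test p-value below
#' `alpha` (two-sided t with n - 2 degrees of freedom). Node degrees are
#' edge-incidence counts; only connected features appear as nodes.
#'
#' @param expr_lnc,expr_mrna features x samples expression matrices over
#'   the same samples (>= 4).
#' @param pcc_min correlation threshold (default 0.8, strict).
#' @param alpha p-value threshold (default 0.05).
#' @param modules optional named module-label vector to attach to nodes.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (`lncrna`, `mrna`, `weight`, `p`), `nodes` (`node`, `class`,
#'   `degree`, optionally `module`) and the thresholds used.
#' @export
build_lnc_mrna_network <- function(expr_lnc, expr_mrna, pcc_min = 0.8,
                                   alpha = 0.05, modules = NULL) {
  expr_lnc <- as.matrix(expr_lnc); expr_mrna <- as.matrix(expr_mrna)
  if (!is.null(colnames(expr_lnc)) && !is.null(colnames(expr_mrna))) {
    shared <- intersect(colnames(expr_lnc), colnames(expr_mrna))
    if (length(shared) == 0) abort("the two matrices share no sample columns")
    expr_lnc <- expr_lnc[, shared, drop = FALSE]
    expr_mrna <- expr_mrna[, shared, drop = FALSE]
  } else if (ncol(expr_lnc) != ncol(expr_mrna)) {
    abort("unnamed expression matrices must have the same sample columns")
  }
  n <- ncol(expr_lnc)
  if (n < 4) abort("network construction needs >= 4 shared samples")
  R <- suppressWarnings(stats::cor(t(expr_lnc), t(expr_mrna)))
  P <- cor_pvalue(R, n)
  pass <- !is.na(R) & R > pcc_min & P < alpha
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    lncrna = rownames(expr_lnc)[idx[, 1]],
    mrna = rownames(expr_mrna)[idx[, 2]],
    weight = R[idx],
    p = P[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$lncrna, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  new_coexpression_network(edges, pcc_min, alpha, modules)
}

# two-sided p of a Pearson correlation via t = r * sqrt((n-2)/(1-r^2))
cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-t, n - 2)
  p[r2 >= 1] <- 0
  p
}

new_coexpression_network <- function(edges, pcc_min, alpha, modules = NULL) {
  nodes <- data.frame(
    node = c(unique(edges$lncrna), unique(edges$mrna)),
    class = rep(c("lncRNA", "mRNA"),
                c(length(unique(edges$lncrna)), length(unique(edges$mrna)))),
    stringsAsFactors = FALSE
  )
  deg <- table(c(edges$lncrna, edges$mrna))
  nodes$degree <- as.integer(deg[nodes$node])
  if (!is.null(modules)) nodes$module <- unname(modules[nodes$node])
  nodes <- nodes[order(nodes$class, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes, pcc_min = pcc_min,
                 alpha = alpha),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d lncRNAs, %d mRNAs, %d edges (PCC > %g, p < %g)\n",
              sum(x$nodes$class == "lncRNA"), sum(x$nodes$class == "mRNA"),
              nrow(x$edges), x$pcc_min, x$alpha))
  invisible(x)
}

#' Extract the hub lncRNA sub-network
#'
#' Keeps the lncRNAs whose degree is at least `min_degree`, all their
#' mRNA neighbors, and the incident edges; degrees are recomputed within
#' the sub-network.
#'
#' @param network a `coexpression_network`.
#' @param min_degree minimum lncRNA degree (>= 0).
#' @return A `coexpression_network` restricted to hubs and neighbors.
#' @export
extract_hub_subnetwork <- function(network, min_degree) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!is_scalar_number(min_degree) || min_degree < 0)
    abort("'min_degree' must be >= 0")
  hubs <- network$nodes$node[network$nodes$class == "lncRNA" &
                               network$nodes$degree >= min_degree]
  edges <- network$edges[network$edges$lncrna %in% hubs, , drop = FALSE]
  rownames(edges) <- NULL
  new_coexpression_network(edges, network$pcc_min, network$alpha)
}
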