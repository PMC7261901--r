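#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample in the DESeq lineage:
#' for each feature with all-positive counts, compute the ratio of its
#' count to its geometric mean across samples; the sample's factor is the
#' median of those ratios.
#'
#' @param counts integer matrix, features x samples.
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 20, 40, 30, 60), nrow = 3, byrow = TRUE)
#' estimate_size_factors(m)  # proportional to (1, 2)
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    abort(paste("no feature has positive counts in every sample;",
                "pre-filter all-zero/sparse features before normalization"))
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(col) stats::median(exp(log(col) - loggeo)))
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order, each in `[0, 1]`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort("p-values must be numeric in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Two-group differential expression test
#'
#' Normalizes counts by median-of-ratios size factors, computes the fold
#' change on the normalized scale as
#' `(mean_condition + pc) / (mean_control + pc)` with pseudocount `pc`,
#' and tests each feature with Welch's t on `log2(normalized + 1)`.
#' FDR is Benjamini-Hochberg; the up/down/ns call applies the strict
#' fold-change and raw-p thresholds (`fold_change > up` and `p < alpha`
#' for "up"; `fold_change < down` and `p < alpha` for "down").
#'
#' @param study an `expression_study` (simulated or read from disk).
#' @param class feature class to test: `"mrna"`, `"lncrna"` or `"mirna"`.
#' @param up,down,alpha call thresholds (defaults 1.2 / 0.83 / 0.05).
#' @param pseudocount pseudocount on the normalized scale for fold-change
#'   stability at zeros.
#' @param method only `"welch"` is implemented.
#' @return A `data.frame` (one row per feature) with columns `feature`,
#'   `class`, `base_mean`, `fold_change`, `log2fc`, `p_value`, `fdr`,
#'   `call`.
#' @export
de_test <- function(study, class = c("mrna", "lncrna", "mirna"),
                    up = 1.2, down = 0.83, alpha = 0.05,
                    pseudocount = 1, method = "welch") {
  class <- match.arg(class)
  method <- match.arg(method)
  counts <- study$counts[[class]]
  if (is.null(counts)) abort("study has no counts for class '%s'", class)
  groups <- study$samples$group[match(colnames(counts), study$samples$sample)]
  ctrl <- which(groups == "control")
  cond <- which(groups == "condition")
  if (length(ctrl) < 2 || length(cond) < 2)
    abort("each group needs >= 2 samples (variance undefined otherwise)")

  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ln <- log2(norm + 1)

  m_ctrl <- rowMeans(norm[, ctrl, drop = FALSE])
  m_cond <- rowMeans(norm[, cond, drop = FALSE])
  fold_change <- (m_cond + pseudocount) / (m_ctrl + pseudocount)

  n1 <- length(ctrl); n2 <- length(cond)
  mu1 <- rowMeans(ln[, ctrl, drop = FALSE])
  mu2 <- rowMeans(ln[, cond, drop = FALSE])
  v1 <- row_vars(ln[, ctrl, drop = FALSE])
  v2 <- row_vars(ln[, cond, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  tt <- (mu2 - mu1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate features (zero variance in both groups)
  degen <- se2 == 0
  p[degen] <- ifelse(mu2[degen] == mu1[degen], 1, 0)

  out <- data.frame(
    feature = rownames(counts) %||% sprintf("f%04d", seq_len(nrow(counts))),
    class = class_label(class),
    base_mean = rowMeans(norm),
    fold_change = fold_change,
    log2fc = log2(fold_change),
    p_value = p,
    fdr = benjamini_hochberg(p),
    stringsAsFactors = FALSE
  )
  out$call <- de_call(out$fold_change, out$p_value, up, down, alpha)
  rownames(out) <- NULL
  out
}

de_call <- function(fold_change, p, up, down, alpha) {
  ifelse(fold_change > up & p < alpha, "up",
         ifelse(fold_change < down & p < alpha, "down", "ns"))
}

#' Apply the fold-change / p-value differential-expression filter
#'
#' Retains exactly the features with `fold_change > up` (up-regulated) or
#' `fold_change < down` (down-regulated) and raw `p_value < alpha`, all
#' inequalities strict. Calls are recomputed at the supplied thresholds.
#'
#' @param table a DE table from [de_test()].
#' @param up,down,alpha thresholds; must satisfy `down < 1 < up`,
#'   `0 < alpha < 1`.
#' @return The filtered table (calls all `"up"` or `"down"`), with an
#'   attribute `n_up`/`n_down` recording the partition.
#' @export
apply_de_filter <- function(table, up = 1.2, down = 0.83, alpha = 0.05) {
  if (!(down < 1 && 1 < up)) abort("thresholds must satisfy down < 1 < up")
  if (!(alpha > 0 && alpha < 1)) abort("'alpha' must be in (0, 1)")
  call <- de_call(table$fold_change, table$p_value, up, down, alpha)
  out <- table[call != "ns", , drop = FALSE]
  out$call <- call[call != "ns"]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$call == "up")
  attr(out, "n_down") <- sum(out$call == "down")
  out
}

#' Relative expression by the delta-delta Ct method
#'
#' Computes `2^-((ct_target_cond - ct_ref_cond) - (ct_target_ctrl -
#' ct_ref_ctrl))`, the standard qPCR fold-change estimate of a target
#' transcript in condition vs control, normalized to a reference gene.
#'
#' @param ct_target_cond,ct_ref_cond,ct_target_ctrl,ct_ref_ctrl finite Ct
#'   values (cycles).
#' @return The relative expression fold.
#' @export
#' @examples
#' ddct_relative_expression(25, 20, 24, 20)  # 0.5
ddct_relative_expression <- function(ct_target_cond, ct_ref_cond,
                                     ct_target_ctrl, ct_ref_ctrl) {
  ct <- c(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(ct))) abort("Ct values must be finite")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
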