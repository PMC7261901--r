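#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count_scalar <- function(x) {
  is_scalar_number(x) && x >= 0 && abs(x - round(x)) < .Machine$double.eps^0.5
}

# row variances of a numeric matrix (denominator n - 1)
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# map internal class keys to display labels used in tables/exports
class_label <- function(key) {
  c(mrna = "mRNA", lncrna = "lncRNA", mirna = "miRNA")[[key]]
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}
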