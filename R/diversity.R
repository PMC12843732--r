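#' Shannon diversity of an abundance vector
#'
#' H = -sum p_i log(p_i) over taxa with positive abundance, where p_i are
#' the relative abundances. Scale-invariant, so counts and relative
#' abundances give the same value.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @param base logarithm base; natural log by default.
#' @return Shannon diversity (numeric scalar).
#' @export
shannon_diversity <- function(x, base = exp(1)) {
  if (anyNA(x) || any(x < 0)) stop("shannon_diversity: abundances must be non-negative")
  s <- sum(x)
  if (s == 0) stop("shannon_diversity: undefined for an all-zero vector")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Per-sample Shannon diversity of a taxa table
#'
#' @param table a [taxa_table()].
#' @param base logarithm base.
#' @return data frame with `sample_id` and `shannon`; all-zero samples get
#'   `NA` (they are flagged on the table, not dropped).
#' @export
shannon_table <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "taxa_table"))
  h <- vapply(seq_along(table$sample_ids), function(j) {
    x <- table$values[, j]
    if (sum(x) == 0) NA_real_ else shannon_diversity(x, base = base)
  }, numeric(1))
  data.frame(sample_id = table$sample_ids, shannon = h,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed between all sample
#' pairs of a taxa table. Values lie in [0, 1]; identical profiles give 0
#' and disjoint supports give 1. The measure is a semi-metric: the triangle
#' inequality does not hold in general. A pair of all-zero samples has an
#' undefined dissimilarity, returned as `NA` and listed in the
#' `"undefined_pairs"` attribute.
#'
#' @param table a [taxa_table()] with >= 2 samples (counts or relative).
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (length(table$sample_ids) < 2) stop("bray_curtis_matrix: need >= 2 samples")
  m <- t(table$values)
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  diag(d) <- 0
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(undef)) {
    attr(d, "undefined_pairs") <- data.frame(
      a = table$sample_ids[undef[, 1]],
      b = table$sample_ids[undef[, 2]],
      stringsAsFactors = FALSE)
  }
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  d
}
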