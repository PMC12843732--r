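#' Pairwise Spearman correlations between taxa
#'
#' Ranks each taxon's abundance profile across samples (average ranks for
#' ties) and computes the Pearson correlation of the rank vectors for every
#' taxon pair. Two-sided p-values come from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, with
#' |rho| = 1 mapped to p = 0; for n <= 9 an exact permutation p-value is
#' available (tie-free profiles only; ties fall back to the t
#' approximation). A constant taxon has no defined correlation: its rows and
#' columns are `NA` and it is listed in the `constant_taxa` attribute.
#'
#' @param table a [taxa_table()] with >= 2 taxa and >= 4 samples.
#' @param p_method `"t"` or `"exact"` (exact only for n <= 9).
#' @return list with `rho` and `p` (symmetric taxa x taxa matrices, unit
#'   diagonal on `rho`), `n` (sample count) and `constant_taxa`.
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact")) {
  stopifnot(inherits(table, "taxa_table"))
  p_method <- match.arg(p_method)
  v <- table$values
  n <- ncol(v)
  if (nrow(v) < 2) stop("spearman_matrix: need >= 2 taxa")
  if (n < 4) stop("spearman_matrix: need >= 4 samples")
  if (p_method == "exact" && n > 9) {
    stop("spearman_matrix: exact p-values are limited to n <= 9")
  }
  ranks <- t(apply(v, 1, rank))          # taxa x samples, average ranks
  constant <- apply(v, 1, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(t(ranks)))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  rho <- pmin(pmax(rho, -1), 1)
  p <- matrix(NA_real_, nrow(v), nrow(v), dimnames = dimnames(rho))
  ok <- !constant
  if (p_method == "t") {
    p[ok, ok] <- spearman_p(rho[ok, ok, drop = FALSE], n)
  } else {
    has_ties <- apply(ranks, 1, anyDuplicated) > 0
    null_abs <- .spearman_exact_null(n)
    for (i in which(ok)) {
      for (j in which(ok)) {
        if (j <= i) next
        r_ij <- rho[i, j]
        p[i, j] <- p[j, i] <- if (has_ties[i] || has_ties[j]) {
          spearman_p(r_ij, n)
        } else {
          mean(null_abs >= abs(r_ij) - 1e-12)
        }
      }
    }
  }
  diag(p) <- ifelse(constant, NA, 0)
  list(rho = rho, p = p, n = n,
       constant_taxa = table$taxon_ids[constant])
}

#' Two-sided Spearman p-value via the t approximation
#'
#' @param rho correlation(s) in [-1, 1]; |rho| = 1 gives p = 0.
#' @param n sample count (> 2).
#' @return p-value(s), same shape as `rho`.
#' @export
spearman_p <- function(rho, n) {
  out <- rho
  perfect <- !is.na(rho) & abs(rho) >= 1
  mid <- !is.na(rho) & !perfect
  tt <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  out[mid] <- 2 * pt(-abs(tt), n - 2)
  out[perfect] <- 0
  out
}

# |rho| values over all permutations of 1..n vs identity (cached per n).
.spearman_null_cache <- new.env(parent = emptyenv())
.spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]])) return(.spearman_null_cache[[key]])
  perms <- .all_perms(n)
  id <- seq_len(n)
  d2 <- colSums((perms - id)^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  .spearman_null_cache[[key]] <- abs(rho)
  abs(rho)
}

# all permutations of 1..n as an n x n! matrix
.all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0
  for (k in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      col <- col + 1
      rest <- sub[, j]
      rest[rest >= k] <- rest[rest >= k] + 1L
      out[, col] <- c(k, rest)
    }
  }
  out
}
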