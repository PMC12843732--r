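#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression with the two-sided t test for the slope on
#' n - 2 degrees of freedom, as used for the per-fraction relationships
#' between multifunctionality and microbial predictors.
#'
#' @param x,y numeric vectors of equal length (n >= 3); `x` non-constant.
#' @return object of class `linear_fit`: `slope`, `intercept`, `r`, `r2`,
#'   `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("linear_fit: length mismatch")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("linear_fit: need >= 3 complete observations")
  if (sd(x) == 0) stop("linear_fit: x is constant")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  r <- cor(x, y)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = r, r2 = r^2, p = unname(sm$coefficients[2, 4]), n = n),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g + %.4g x, r2 = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r2, x$p, x$n))
  invisible(x)
}

#' Hierarchical partitioning of variance over two factors
#'
#' Attributes the explained variance of a response to two design factors
#' and their interaction by fixed-effects hierarchical partitioning: OLS
#' models are fitted for every admissible subset of the terms
#' {A, B, A:B} (the interaction is only admitted alongside both main
#' effects), each term's contribution is the average of its incremental R^2
#' over all orderings of entry that respect that hierarchy, and the
#' contributions are rescaled to percent of the full model's explained
#' variance. In a balanced orthogonal design the shares reduce exactly to
#' the classical ANOVA sums-of-squares fractions.
#'
#' @param response numeric response vector.
#' @param factor_a,factor_b factors (or coercible); the interaction term
#'   requires >= 1 replicate per occupied cell.
#' @param names optional length-2 character vector naming the factors.
#' @return object of class `variance_partition`: `shares` (named percent of
#'   explained variance for A, B and the interaction, summing to 100),
#'   `increments` (average incremental R^2 per term), `full_r2`, `n`.
#' @export
hierarchical_partition <- function(response, factor_a, factor_b,
                                   names = c("A", "B")) {
  a <- droplevels(factor(factor_a))
  b <- droplevels(factor(factor_b))
  y <- as.numeric(response)
  if (length(y) != length(a) || length(y) != length(b)) {
    stop("hierarchical_partition: length mismatch")
  }
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("hierarchical_partition: both factors need >= 2 levels")
  }
  if (var(y) == 0) stop("hierarchical_partition: constant response")
  r2_of <- function(terms) {
    if (!length(terms)) return(0)
    f <- stats::reformulate(terms, response = "y")
    # noiseless designs fit perfectly; only the R^2 is needed
    suppressWarnings(
      summary(lm(f, data = data.frame(y = y, A = a, B = b)))$r.squared)
  }
  r2 <- list(none = 0, A = r2_of("A"), B = r2_of("B"),
             AB = r2_of(c("A", "B")), full = r2_of(c("A", "B", "A:B")))
  # admissible orderings of {A, B, A:B}: the interaction enters last
  inc_a <- mean(c(r2$A - r2$none, r2$AB - r2$B))
  inc_b <- mean(c(r2$B - r2$none, r2$AB - r2$A))
  inc_ab <- r2$full - r2$AB
  inc <- c(inc_a, inc_b, inc_ab)
  term_names <- c(names[1], names[2], paste(names, collapse = ":"))
  if (r2$full <= 0) stop("hierarchical_partition: model explains no variance")
  shares <- 100 * inc / sum(inc)
  structure(
    list(shares = setNames(shares, term_names),
         increments = setNames(inc, term_names),
         full_r2 = r2$full, n = length(y)),
    class = "variance_partition"
  )
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> full R2 = %.4f (n = %d)\n", x$full_r2, x$n))
  for (i in seq_along(x$shares)) {
    cat(sprintf("  %s: %.2f%%\n", names(x$shares)[i], x$shares[i]))
  }
  invisible(x)
}

#' First principal-coordinate axis of a dissimilarity matrix
#'
#' Classical metric scaling: the squared dissimilarities are double-centered
#' and eigen-decomposed; the first axis (largest positive eigenvalue) is the
#' standard one-number summary of community composition used as a manifest
#' variable in path models.
#'
#' @param d symmetric dissimilarity matrix (e.g. [bray_curtis_matrix()]).
#' @param k number of axes to return.
#' @return samples x k matrix of principal coordinates.
#' @export
pcoa_axes <- function(d, k = 1) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("pcoa_axes: missing dissimilarities are not supported")
  pts <- cmdscale(d, k = k)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pts
}
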