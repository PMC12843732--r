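#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose inter-point distances best
#' preserve the rank order of the input dissimilarities, by minimizing
#' Kruskal's stress-1:
#' `sqrt( sum( (dhat_ij - shat_ij)^2 ) / sum( dhat_ij^2 ) )`,
#' where `dhat` are configuration distances and `shat` the isotonic
#' (pool-adjacent-violators) fit to them in the rank order of the input.
#' Each iteration alternates the isotonic fit with a Guttman (SMACOF)
#' configuration update; a backtracking step ensures that stress never
#' increases within a run. Ties in the dissimilarities are handled by
#' Kruskal's primary approach (tied values may receive unequal fitted
#' values). The best of `restarts` random starts is returned; the first
#' start is the classical-scaling (principal coordinates) configuration.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k embedding dimension (>= 1, < number of samples).
#' @param restarts number of starts (first is classical scaling).
#' @param seed integer seed for the random starts.
#' @param max_iter,tol iteration cap and stress-improvement tolerance.
#' @return object of class `nmds_result`: `points` (centered coordinates,
#'   principal-axis orientation), `stress`, `stress_trace` (per-iteration
#'   stress of the winning run, non-increasing), `converged`, `restarts`,
#'   `seed`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = 1L, max_iter = 200,
                 tol = 1e-7) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
    stop("nmds: dissimilarity matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("nmds: diagonal must be zero")
  if (anyNA(d)) stop("nmds: missing dissimilarities are not supported")
  if (k < 1 || k >= n) stop("nmds: need 1 <= k < number of samples")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper.tri(d)]
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    X0 <- if (r == 1) {
      cm <- tryCatch(suppressWarnings(cmdscale(d, k = k)), error = function(e) NULL)
      if (is.null(cm) || ncol(cm) < k) {
        matrix(rnorm(n * k), n, k)
      } else {
        cm + matrix(rnorm(n * k, sd = 1e-6), n, k)  # break exact degeneracies
      }
    } else {
      matrix(rnorm(n * k), n, k)
    }
    run <- .nmds_run(X0, dv, pairs, n, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  # rotate to principal axes; stress is rotation-invariant
  if (k > 1) X <- X %*% svd(X)$v
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(
    list(points = X, stress = best$stress, stress_trace = best$trace,
         converged = best$converged, restarts = restarts, seed = seed,
         k = k),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> k = %d, stress = %.6g (%s, best of %d starts)\n",
              x$k, x$stress, if (x$converged) "converged" else "iteration cap",
              x$restarts))
  invisible(x)
}

# Stress-1 and the isotonic disparities of a configuration.
.nmds_eval <- function(X, dv, pairs, ord) {
  dhat <- sqrt(rowSums((X[pairs[, 1], , drop = FALSE] -
                        X[pairs[, 2], , drop = FALSE])^2))
  denom <- sum(dhat^2)
  if (denom == 0) return(list(stress = Inf, dhat = dhat, shat = dhat))
  shat <- numeric(length(dhat))
  shat[ord] <- isoreg(dhat[ord])$yf
  list(stress = sqrt(sum((dhat - shat)^2) / denom), dhat = dhat, shat = shat)
}

.nmds_run <- function(X, dv, pairs, n, k, max_iter, tol) {
  # primary tie treatment: within tied dissimilarities order by current
  # distance is not needed for correctness; a fixed secondary order keeps
  # the fit deterministic while allowing unequal values within ties
  ord <- order(dv, method = "radix")
  ev <- .nmds_eval(X, dv, pairs, ord)
  trace <- ev$stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (!is.finite(ev$stress)) break
    # Guttman transform with disparities shat
    ratio <- ifelse(ev$dhat > 0, ev$shat / ev$dhat, 0)
    B <- matrix(0, n, n)
    idx <- cbind(pairs[, 1], pairs[, 2])
    B[idx] <- -ratio
    B[idx[, c(2, 1), drop = FALSE]] <- -ratio
    diag(B) <- -rowSums(B)
    Xprop <- (B %*% X) / n
    step <- 1
    repeat {
      Xnew <- X + step * (Xprop - X)
      ev_new <- .nmds_eval(Xnew, dv, pairs, ord)
      if (ev_new$stress <= ev$stress || step < 1e-4) break
      step <- step / 2
    }
    if (ev_new$stress > ev$stress) { converged <- TRUE; break }
    improvement <- ev$stress - ev_new$stress
    X <- Xnew
    ev <- ev_new
    trace <- c(trace, ev$stress)
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = ev$stress, trace = trace, converged = converged)
}
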