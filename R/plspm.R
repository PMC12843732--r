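#' Partial least squares path modeling (mode A)
#'
#' Estimates a recursive system of latent variables, each measured
#' reflectively (mode A) by a block of manifest variables. The algorithm is
#' the classical Lohmoeller/Wold iteration: manifest variables are
#' standardized; outer weights start at unit values; then the loop
#' alternates (a) latent scores as standardized weighted sums of their
#' block, (b) inner weights between adjacent latents per the chosen scheme
#' (centroid: sign of the score correlation; factorial: the correlation;
#' path: regression coefficients for predecessors, correlations for
#' successors), (c) inner estimates as weighted sums of adjacent scores,
#' and (d) mode-A outer weights as the covariance of each manifest with its
#' block's inner estimate, until the largest absolute weight change falls
#' below `tol`. Path coefficients are then OLS regressions of each
#' endogenous latent score on its predecessors; fit is summarized by block
#' communalities, per-latent R^2 and the goodness of fit
#' `GoF = sqrt(mean(communality) * mean(R^2))`. Total effects are sums of
#' path products over all directed paths (powers of the path-coefficient
#' matrix); indirect = total - direct.
#'
#' @param data data frame or matrix (samples x manifest variables).
#' @param blocks named list: latent name -> character vector of manifest
#'   column names; every block non-empty.
#' @param paths square 0/1 matrix with latent names on both dimnames;
#'   `paths[i, j] = 1` means latent j -> latent i. Must be acyclic
#'   (lower-triangular under some ordering of the latents).
#' @param scheme inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @param tol convergence tolerance on the outer weights.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   weight-change trace.
#' @return object of class `pls_path_model`: `scores` (unit-variance latent
#'   scores), `path_coefficients` (matrix, same shape as `paths`),
#'   `outer_weights`, `loadings`, `communalities`, `r2` (per endogenous
#'   latent), `gof`, `effects` (data frame: from, to, direct, indirect,
#'   total), `inner_model` (per-latent regression detail), `iterations`,
#'   `scheme`.
#' @export
plspm_fit <- function(data, blocks, paths, scheme = c("centroid", "factorial", "path"),
                      tol = 1e-7, max_iter = 300) {
  scheme <- match.arg(scheme)
  data <- as.data.frame(data)
  lat <- names(blocks)
  if (is.null(lat) || anyDuplicated(lat)) {
    stop("plspm_fit: blocks must be a uniquely named list")
  }
  if (any(lengths(blocks) == 0)) {
    stop("plspm_fit: empty block(s): ",
         paste(lat[lengths(blocks) == 0], collapse = ", "))
  }
  mv <- unlist(blocks, use.names = FALSE)
  missing <- setdiff(mv, colnames(data))
  if (length(missing)) {
    stop("plspm_fit: manifest variable(s) absent from data: ",
         paste(missing, collapse = ", "))
  }
  paths <- as.matrix(paths)
  if (!all(dim(paths) == length(lat)) ||
      !identical(rownames(paths), lat) || !identical(colnames(paths), lat)) {
    stop("plspm_fit: paths must be a square matrix with the latent names as dimnames")
  }
  if (any(paths != 0 & paths != 1) || any(diag(paths) != 0)) {
    stop("plspm_fit: paths must be 0/1 with a zero diagonal")
  }
  if (!.is_acyclic(paths)) stop("plspm_fit: path matrix contains a cycle")
  adjacency <- (paths + t(paths)) > 0
  n <- nrow(data)
  n_pred <- max(rowSums(paths))
  if (n <= n_pred + 1) stop("plspm_fit: too few rows for the inner regressions")

  X <- lapply(blocks, function(cols) {
    m <- scale(as.matrix(data[, cols, drop = FALSE]))
    if (any(!is.finite(m))) stop("plspm_fit: constant or missing manifest variable")
    m
  })
  w <- lapply(blocks, function(cols) rep(1, length(cols)))
  scores_of <- function(w) {
    Y <- sapply(lat, function(l) as.numeric(scale(X[[l]] %*% w[[l]])))
    colnames(Y) <- lat
    Y
  }
  trace <- numeric(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    Y <- scores_of(w)
    R <- cor(Y)
    Z <- matrix(0, n, length(lat), dimnames = list(NULL, lat))
    for (l in seq_along(lat)) {
      adj <- which(adjacency[l, ])
      if (!length(adj)) stop("plspm_fit: latent '", lat[l], "' is isolated")
      e <- switch(scheme,
        centroid = sign(R[l, adj]),
        factorial = R[l, adj],
        path = {
          pred <- which(paths[l, ] > 0)
          succ <- setdiff(adj, pred)
          ee <- numeric(length(adj))
          if (length(pred)) {
            ee[match(pred, adj)] <- coef(lm(Y[, l] ~ Y[, pred, drop = FALSE] - 1))
          }
          if (length(succ)) ee[match(succ, adj)] <- R[l, succ]
          ee
        })
      Z[, l] <- Y[, adj, drop = FALSE] %*% e
    }
    w_new <- lapply(seq_along(lat), function(l) {
      as.numeric(cov(X[[lat[l]]], Z[, l]))
    })
    names(w_new) <- lat
    delta <- max(abs(abs(unlist(w_new) / .w_norm(w_new, X)) -
                     abs(unlist(w) / .w_norm(w, X))))
    trace <- c(trace, delta)
    w <- w_new
    if (delta < tol) break
    if (iterations >= max_iter) {
      err <- simpleError(sprintf(
        "plspm_fit: no convergence in %d iterations (last weight change %.3g)",
        max_iter, delta))
      err$trace <- trace
      stop(err)
    }
  }
  Y <- scores_of(w)
  # orient each latent with its own block (positive mean loading)
  for (l in lat) {
    ld <- cor(X[[l]], Y[, l])
    if (sum(ld) < 0) {
      Y[, l] <- -Y[, l]
      w[[l]] <- -w[[l]]
    }
  }
  # normalize reported weights so the weighted sum has unit variance
  for (l in lat) {
    s <- sd(X[[l]] %*% w[[l]])
    w[[l]] <- w[[l]] / s
  }

  B <- paths * 0
  inner <- list()
  r2 <- c()
  for (l in lat) {
    pred <- lat[paths[l, ] > 0]
    if (!length(pred)) next
    fit <- lm(Y[, l] ~ Y[, pred, drop = FALSE])
    cf <- coef(fit)[-1]
    B[l, pred] <- cf
    r2[l] <- summary(fit)$r.squared
    inner[[l]] <- data.frame(predictor = pred, coefficient = unname(cf),
                             stringsAsFactors = FALSE)
  }
  loadings <- lapply(lat, function(l) {
    setNames(as.numeric(cor(X[[l]], Y[, l])), blocks[[l]])
  })
  names(loadings) <- lat
  communality <- unlist(loadings)^2
  gof <- sqrt(mean(communality) * mean(r2))
  # total effects: sum over path products of every length
  total <- B
  Bk <- B
  for (step in seq_len(length(lat) - 1)) {
    Bk <- Bk %*% B
    total <- total + Bk
  }
  eff_idx <- which(total != 0 | B != 0, arr.ind = TRUE)
  effects <- data.frame(
    from = lat[eff_idx[, 2]], to = lat[eff_idx[, 1]],
    direct = B[eff_idx], indirect = total[eff_idx] - B[eff_idx],
    total = total[eff_idx], stringsAsFactors = FALSE)
  effects <- effects[order(effects$to, effects$from), ]
  rownames(effects) <- NULL
  structure(
    list(scores = Y, path_coefficients = B, outer_weights = w,
         loadings = loadings, communalities = communality, r2 = r2,
         gof = gof, effects = effects, inner_model = inner,
         iterations = iterations, scheme = scheme, blocks = blocks,
         paths = paths, weight_trace = trace),
    class = "pls_path_model"
  )
}

#' @export
print.pls_path_model <- function(x, ...) {
  cat(sprintf("<pls_path_model> %d latent(s), scheme = %s, %d iteration(s)\n",
              length(x$blocks), x$scheme, x$iterations))
  cat(sprintf("  GoF = %.4f; R2: %s\n", x$gof,
              paste(sprintf("%s=%.3f", names(x$r2), x$r2), collapse = ", ")))
  invisible(x)
}

# unit-variance normalizer used for the convergence criterion
.w_norm <- function(w, X) {
  rep(vapply(names(w), function(l) sd(X[[l]] %*% w[[l]]), numeric(1)),
      times = lengths(w))
}

.is_acyclic <- function(paths) {
  m <- paths
  remaining <- seq_len(nrow(m))
  while (length(remaining)) {
    sinks <- remaining[colSums(m[remaining, remaining, drop = FALSE]) == 0]
    if (!length(sinks)) return(FALSE)
    remaining <- setdiff(remaining, sinks)
  }
  TRUE
}

#' Rank microbial predictors of multifunctionality across strata
#'
#' Collects the standardized total effects on a response latent (SMF by
#' default) from one or more fitted PLS path models and ranks the
#' predictors by absolute total effect within each stratum. The maximal
#' predictor per stratum is identified; exact ties are broken
#' lexicographically and flagged.
#'
#' @param fits a named list of [plspm_fit()] objects (names = stratum
#'   labels) or a single fit.
#' @param response name of the response latent (default `"SMF"`).
#' @param predictors optional subset of predictor latents to rank (e.g.
#'   only the microbial ones); default: all latents with a path into the
#'   response.
#' @return object of class `predictor_ranking`: `table` (stratum,
#'   predictor, direct, indirect, total, rank), `top` (data frame with the
#'   winning predictor per stratum and a `tie` flag).
#' @export
rank_predictors <- function(fits, response = "SMF", predictors = NULL) {
  if (inherits(fits, "pls_path_model")) fits <- list(model = fits)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  rows <- list()
  top <- list()
  ref <- NULL
  for (s in names(fits)) {
    fit <- fits[[s]]
    stopifnot(inherits(fit, "pls_path_model"))
    eff <- fit$effects[fit$effects$to == response, , drop = FALSE]
    if (!nrow(eff)) stop("rank_predictors: no effects on '", response,
                         "' in stratum ", s)
    if (!is.null(predictors)) {
      missing <- setdiff(predictors, eff$from)
      if (length(missing)) {
        stop("rank_predictors: predictor(s) absent in stratum ", s, ": ",
             paste(missing, collapse = ", "))
      }
      eff <- eff[eff$from %in% predictors, , drop = FALSE]
    }
    if (is.null(ref)) {
      ref <- sort(eff$from)
    } else if (!identical(sort(eff$from), ref)) {
      stop("rank_predictors: predictor sets differ across strata")
    }
    ord <- order(-abs(eff$total), eff$from)
    eff <- eff[ord, , drop = FALSE]
    eff$rank <- seq_len(nrow(eff))
    eff$stratum <- s
    rows[[s]] <- eff
    tie <- nrow(eff) > 1 && abs(eff$total[1]) == abs(eff$total[2])
    top[[s]] <- data.frame(stratum = s, predictor = eff$from[1],
                           total = eff$total[1], tie = tie,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(table = tab[, c("stratum", "from", "direct", "indirect", "total", "rank")],
         top = do.call(rbind, c(top, list(make.row.names = FALSE)))),
    class = "predictor_ranking"
  )
}

#' @export
print.predictor_ranking <- function(x, ...) {
  cat("<predictor_ranking>\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}
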