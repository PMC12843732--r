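#' Min-max standardize a vector to [0, 1]
#'
#' STD = (X - Xmin) / (Xmax - Xmin), where Xmin and Xmax are taken across
#' all supplied values: the minimum maps to 0 and the maximum to 1. This is
#' the standardization applied to every soil variable before averaging into
#' the multifunctionality index, and to every network topology metric
#' before averaging into the complexity index.
#'
#' @param x numeric vector, length >= 2, no missing values unless
#'   `na_ok = TRUE` (missing values are then passed through).
#' @param degenerate policy for a constant vector: `"error"` (default) or
#'   `"zero"` to return all zeros.
#' @param na_ok allow NA cells (excluded from min/max).
#' @return numeric vector in [0, 1].
#' @export
minmax_standardize <- function(x, degenerate = c("error", "zero"),
                               na_ok = FALSE) {
  degenerate <- match.arg(degenerate)
  if (!na_ok && anyNA(x)) stop("minmax_standardize: NA in input")
  if (sum(!is.na(x)) < 2) stop("minmax_standardize: need >= 2 values")
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    if (degenerate == "zero") return(replace(rep(0, length(x)), is.na(x), NA))
    stop("minmax_standardize: degenerate range (all values equal)")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Soil multifunctionality from a soil-variable table
#'
#' Each variable is min-max standardized to [0, 1] across all samples
#' jointly (one global min and max per variable), then averaged: the
#' per-sample mean over all variables is the soil multifunctionality (SMF),
#' and the mean over each cycle's variables gives the C, N and P cycling
#' functions. With the default 15-variable schema (5 C, 6 N, 4 P) the
#' identity SMF = (5 C + 6 N + 4 P) / 15 holds exactly.
#'
#' @param soil a [soil_table()] with >= 2 samples.
#' @param degenerate policy for constant variables, see
#'   [minmax_standardize()]; errors name the variable.
#' @param mask optional logical matrix (same shape as `soil$values`), `TRUE`
#'   marking cells to exclude; an excluded variable drops out of that
#'   sample's mean and the divisor adjusts.
#' @return object of class `multifunctionality`, a list with
#'   `scores` (data frame: sample_id, SMF, C_function, N_function,
#'   P_function), `standardized` (samples x variables matrix in [0, 1]),
#'   `variable_range` (per-variable min/max) and `n_per_cycle`.
#' @export
compute_multifunctionality <- function(soil, degenerate = c("error", "zero"),
                                       mask = NULL) {
  stopifnot(inherits(soil, "soil_table"))
  degenerate <- match.arg(degenerate)
  v <- soil$values
  if (nrow(v) < 2) stop("compute_multifunctionality: need >= 2 samples")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(v)))
    v[mask] <- NA
  }
  std <- v
  for (j in seq_len(ncol(v))) {
    std[, j] <- tryCatch(
      minmax_standardize(v[, j], degenerate = degenerate, na_ok = !is.null(mask)),
      error = function(e) {
        stop(sprintf("variable '%s': %s", soil$variables[j], conditionMessage(e)),
             call. = FALSE)
      })
  }
  cyc <- soil$cycles
  cycle_mean <- function(tag) {
    cols <- std[, cyc == tag, drop = FALSE]
    rowMeans(cols, na.rm = !is.null(mask))
  }
  scores <- data.frame(
    sample_id = soil$sample_ids,
    SMF = rowMeans(std, na.rm = !is.null(mask)),
    C_function = cycle_mean("C"),
    N_function = cycle_mean("N"),
    P_function = cycle_mean("P"),
    stringsAsFactors = FALSE
  )
  rownames(scores) <- NULL
  structure(
    list(scores = scores,
         standardized = std,
         variable_range = data.frame(
           variable = soil$variables,
           cycle = unname(cyc),
           min = apply(v, 2, min, na.rm = TRUE),
           max = apply(v, 2, max, na.rm = TRUE),
           row.names = NULL, stringsAsFactors = FALSE),
         n_per_cycle = c(C = sum(cyc == "C"), N = sum(cyc == "N"),
                         P = sum(cyc == "P"))),
    class = "multifunctionality"
  )
}

#' @export
print.multifunctionality <- function(x, ...) {
  cat(sprintf("<multifunctionality> %d samples, %d variables (C:%d N:%d P:%d)\n",
              nrow(x$scores), nrow(x$variable_range),
              x$n_per_cycle[["C"]], x$n_per_cycle[["N"]], x$n_per_cycle[["P"]]))
  cat(sprintf("  SMF range: %.3f - %.3f\n",
              min(x$scores$SMF), max(x$scores$SMF)))
  invisible(x)
}
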