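#' One-way ANOVA with Fisher's LSD test and compact letters
#'
#' Fits a one-way ANOVA and, when the omnibus F test is significant at
#' `alpha` (protected LSD; override with `protected = FALSE`), performs all
#' pairwise least-significant-difference comparisons: t tests on group mean
#' differences using the pooled residual mean square and its degrees of
#' freedom. Group letters are assembled by the insert-and-absorb procedure,
#' so groups sharing no letter differ at `alpha` and groups sharing a letter
#' do not. No correction beyond the protection step is applied — that is the
#' definition of the LSD test.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) of group labels; >= 2 groups with
#'   >= 2 observations each.
#' @param alpha significance level.
#' @param protected if `TRUE` (default) pairwise tests are only run when the
#'   omnibus F is significant; otherwise all groups share one letter.
#' @return object of class `group_comparison`: `f_statistic`, `p_value`,
#'   `df`, `means` (data frame with group, n, mean, letters), `pairwise_p`
#'   (symmetric matrix), `alpha`, `protected`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, protected = TRUE) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("anova_lsd: need >= 2 groups")
  n_g <- table(groups)
  if (any(n_g < 2)) {
    stop("anova_lsd: group(s) with fewer than 2 observations: ",
         paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  if (length(values) != length(groups)) stop("anova_lsd: length mismatch")
  lv <- levels(groups)
  k <- length(lv)
  if (var(values) == 0) {
    # a perfectly constant response carries no evidence at all
    pw <- matrix(1, k, k, dimnames = list(lv, lv))
    return(structure(
      list(f_statistic = 0, p_value = 1,
           df = c(between = k - 1L, within = length(values) - k),
           means = data.frame(group = lv, n = as.integer(n_g),
                              mean = as.numeric(tapply(values, groups, mean)),
                              letters = "a", stringsAsFactors = FALSE),
           pairwise_p = pw, alpha = alpha, protected = protected),
      class = "group_comparison"))
  }
  fit <- aov(values ~ groups)
  at <- anova(fit)
  f_stat <- at$`F value`[1]
  p_val <- at$`Pr(>F)`[1]
  mse <- at$`Mean Sq`[2]
  df_e <- at$Df[2]
  if (is.nan(f_stat) && mse == 0) {
    # zero variance everywhere: no evidence of group differences
    f_stat <- 0
    p_val <- 1
  }
  means <- tapply(values, groups, mean)
  pw <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  diag(pw) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (mse == 0) {
        p_ij <- if (means[i] == means[j]) 1 else 0
      } else {
        se <- sqrt(mse * (1 / n_g[i] + 1 / n_g[j]))
        t_ij <- (means[i] - means[j]) / se
        p_ij <- 2 * pt(-abs(t_ij), df_e)
      }
      pw[i, j] <- pw[j, i] <- p_ij
    }
  }
  run_pairwise <- !protected || (!is.na(p_val) && p_val < alpha)
  letters_vec <- if (run_pairwise) {
    .compact_letters(pw < alpha, order(means, decreasing = TRUE))
  } else {
    setNames(rep("a", k), lv)
  }
  structure(
    list(f_statistic = f_stat, p_value = p_val,
         df = c(between = at$Df[1], within = df_e),
         means = data.frame(group = lv, n = as.integer(n_g),
                            mean = as.numeric(means),
                            letters = unname(letters_vec[lv]),
                            stringsAsFactors = FALSE),
         pairwise_p = pw, alpha = alpha, protected = protected),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$f_statistic, x$p_value))
  print(x$means, row.names = FALSE)
  invisible(x)
}

# Insert-and-absorb compact letter display. `signif_mat` is a logical
# matrix marking significantly different pairs; `ord` orders groups
# (typically by decreasing mean) for letter assignment.
.compact_letters <- function(signif_mat, ord = seq_len(nrow(signif_mat))) {
  lv <- rownames(signif_mat)
  k <- length(lv)
  # letter sets as logical membership vectors; start with one set of all
  sets <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!isTRUE(signif_mat[i, j])) next
      for (s in seq_along(sets)) {
        if (sets[[s]][i] && sets[[s]][j]) {
          a <- sets[[s]]; a[i] <- FALSE
          b <- sets[[s]]; b[j] <- FALSE
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && all(sets[[s]] <= sets[[t]]) &&
              !identical(sets[[s]], sets[[t]])) {
            keep[s] <- FALSE
            break
          }
        }
      }
      # drop duplicates that survive the containment check
      sets <- unique(sets[keep])
    }
  }
  # order letter sets by the best-ranked member so "a" goes to high means
  first_member <- vapply(sets, function(s) min(match(which(s), ord)), numeric(1))
  sets <- sets[order(first_member)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) s[g], logical(1)))],
          collapse = "")
  }, character(1))
  setNames(out, lv)
}
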