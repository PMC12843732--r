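test_that("linear fit: exact line, closed-form coefficients, null p-values", {
  x <- c(1, 2, 3, 4)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)

  # 5-point toy vs the normal equations computed by hand
  x5 <- c(0.5, 1.3, 2.2, 3.1, 4.7); y5 <- c(2.1, 1.7, 3.4, 2.9, 5.0)
  f5 <- linear_fit(x5, y5)
  sxx <- sum((x5 - mean(x5))^2); sxy <- sum((x5 - mean(x5)) * (y5 - mean(y5)))
  expect_equal(f5$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(f5$intercept, mean(y5) - mean(x5) * sxy / sxx, tolerance = 1e-12)
  expect_equal(f5$r2, f5$r^2)
  expect_equal(sign(f5$r), sign(f5$slope))

  # y independent of x: slope p-values uniform on [0, 1]
  set.seed(71)
  ps <- vapply(1:500, function(i) linear_fit(rnorm(12), rnorm(12))$p, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("variance partition: pure factor-A designs give 100/0/0", {
  g <- expand.grid(A = factor(paste0("a", 1:3)), B = factor(paste0("b", 1:2)),
                   rep = 1:4)
  y <- c(1, 5, 9)[as.integer(g$A)]
  vp <- hierarchical_partition(y, g$A, g$B, names = c("veg", "agg"))
  expect_equal(unname(vp$shares), c(100, 0, 0), tolerance = 1e-9)
  expect_equal(vp$full_r2, 1)
  expect_equal(sum(vp$shares), 100, tolerance = 1e-9)
})

test_that("variance partition matches ANOVA fractions on balanced designs", {
  set.seed(83)
  g <- expand.grid(A = factor(paste0("a", 1:3)), B = factor(paste0("b", 1:4)),
                   rep = 1:3)
  y <- rnorm(nrow(g)) + as.integer(g$A) + 0.5 * as.integer(g$B) +
    0.3 * as.integer(g$A) * as.integer(g$B)
  vp <- hierarchical_partition(y, g$A, g$B)
  ss <- anova(lm(y ~ A * B, data = g))$`Sum Sq`
  explained <- sum(ss[1:3])
  expect_equal(unname(vp$shares), 100 * ss[1:3] / explained, tolerance = 1e-9)
  expect_equal(vp$full_r2, explained / sum(ss), tolerance = 1e-12)
})

test_that("variance partition matches literal ordering enumeration when unbalanced", {
  set.seed(89)
  for (rep in 1:5) {
    n <- 60
    a <- factor(sample(paste0("a", 1:3), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)))
    b <- factor(sample(paste0("b", 1:2), n, replace = TRUE, prob = c(0.7, 0.3)))
    y <- rnorm(n) + as.integer(a) * 0.8 + (a == "a2") * (b == "b2") * 1.5
    vp <- hierarchical_partition(y, a, b)
    want <- oracle_partition(y, a, b)
    expect_equal(unname(vp$shares), unname(want$shares), tolerance = 1e-9)
    expect_equal(vp$full_r2, want$full_r2, tolerance = 1e-12)
    expect_equal(sum(vp$shares), 100, tolerance = 1e-9)
  }
})

test_that("PCoA first axis reproduces classical scaling of Bray-Curtis data", {
  set.seed(97)
  v <- matrix(rexp(8 * 10), 8, 10,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  d <- bray_curtis_matrix(taxa_table(v, mode = "counts"))
  ax <- pcoa_axes(d, k = 2)
  ref <- cmdscale(as.dist(d), k = 2)
  expect_equal(abs(cor(ax[, 1], ref[, 1])), 1, tolerance = 1e-9)
})

.toy_path_setup <- function(n = 200, seed = 101) {
  set.seed(seed)
  x <- rnorm(n)
  m <- 0.6 * x + rnorm(n, 0, 0.8)
  y <- 0.5 * m + 0.3 * x + rnorm(n, 0, 0.7)
  dat <- data.frame(X = x, M = m, Y = y)
  lat <- c("X", "M", "Y")
  paths <- matrix(0, 3, 3, dimnames = list(lat, lat))
  paths["M", "X"] <- 1
  paths["Y", c("X", "M")] <- 1
  list(dat = dat, paths = paths,
       blocks = list(X = "X", M = "M", Y = "Y"))
}

test_that("single-indicator PLS-PM equals closed-form path analysis", {
  s <- .toy_path_setup()
  fit <- plspm_fit(s$dat, s$blocks, s$paths)
  B_ref <- oracle_path_analysis(s$dat, s$paths)
  expect_equal(fit$path_coefficients, B_ref, tolerance = 1e-8)
  # latent scores are the standardized manifests, unit variance
  expect_equal(abs(cor(fit$scores[, "X"], scale(s$dat$X))[1]), 1,
               tolerance = 1e-12)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("PLS-PM identities: GoF, effect decomposition, chain algebra", {
  s <- .toy_path_setup(seed = 103)
  for (scheme in c("centroid", "factorial", "path")) {
    fit <- plspm_fit(s$dat, s$blocks, s$paths, scheme = scheme)
    expect_equal(fit$gof, sqrt(mean(fit$communalities) * mean(fit$r2)),
                 tolerance = 1e-12)
    eff <- fit$effects
    expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
    # chain X -> M -> Y plus direct X -> Y: total = direct + product
    xy <- eff[eff$from == "X" & eff$to == "Y", ]
    expect_equal(xy$total,
                 fit$path_coefficients["Y", "X"] +
                   fit$path_coefficients["M", "X"] *
                   fit$path_coefficients["Y", "M"],
                 tolerance = 1e-12)
    expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  }
})

test_that("PLS-PM recovers planted paths within the pre-simulated bias band", {
  lat <- c("L1", "L2", "L3")
  paths <- matrix(0, 3, 3, dimnames = list(lat, lat))
  paths["L2", "L1"] <- 1
  paths["L3", "L2"] <- 1
  blocks <- list(L1 = paste0("a", 1:3), L2 = paste0("b", 1:3),
                 L3 = paste0("c", 1:3))
  bias <- vapply(1:50, function(s) {
    set.seed(300 + s)
    n <- 500
    x1 <- rnorm(n)
    x2 <- 0.5 * x1 + rnorm(n, 0, sqrt(1 - 0.25))
    x3 <- 0.4 * x2 + rnorm(n, 0, sqrt(1 - 0.16))
    mk <- function(xi) sapply(1:3, function(i) 0.8 * xi + rnorm(n, 0, 0.6))
    dat <- cbind(mk(x1), mk(x2), mk(x3))
    colnames(dat) <- unlist(blocks)
    fit <- plspm_fit(as.data.frame(dat), blocks, paths)
    mean(abs(c(fit$path_coefficients["L2", "L1"] - 0.5,
               fit$path_coefficients["L3", "L2"] - 0.4)))
  }, numeric(1))
  # composite attenuation band pre-simulated with an independent
  # equal-weight composite oracle: mean abs bias ~0.075, always < 0.12
  expect_lt(mean(bias), 0.12)
})

test_that("PLS-PM bias shrinks as the sample grows", {
  lat <- c("A", "B")
  paths <- matrix(0, 2, 2, dimnames = list(lat, lat))
  paths["B", "A"] <- 1
  blocks <- list(A = "xa", B = "xb")
  bias_at <- vapply(c(100, 500, 2000), function(n) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 * n + s)
      xa <- rnorm(n)
      xb <- 0.5 * xa + rnorm(n, 0, sqrt(0.75))
      fit <- plspm_fit(data.frame(xa = xa, xb = xb), blocks, paths)
      abs(fit$path_coefficients["B", "A"] - 0.5)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(bias_at[3], bias_at[1])
  expect_lt(bias_at[3], 0.02)
})

test_that("PLS-PM rejects cyclic models and reports non-convergence traces", {
  s <- .toy_path_setup()
  cyc <- s$paths
  cyc["X", "Y"] <- 1
  expect_error(plspm_fit(s$dat, s$blocks, cyc), "cycle")
  err <- tryCatch(plspm_fit(s$dat, s$blocks, s$paths, tol = 0, max_iter = 3),
                  error = function(e) e)
  expect_match(conditionMessage(err), "convergence")
  expect_true(length(err$trace) >= 1)
  expect_error(plspm_fit(s$dat, list(X = "X", M = character(0), Y = "Y"),
                         s$paths), "empty block")
})

test_that("predictor ranking orders by absolute total effect and flags ties", {
  s <- .toy_path_setup(seed = 107)
  fit <- plspm_fit(s$dat, s$blocks, s$paths)
  rk <- rank_predictors(fit, response = "Y")
  eff <- fit$effects[fit$effects$to == "Y", ]
  expect_equal(rk$top$predictor, eff$from[which.max(abs(eff$total))])
  expect_equal(rk$table$rank, order(-abs(rk$table$total)))

  rk1 <- rank_predictors(fit, response = "M")
  expect_equal(rk1$top$predictor, "X")  # single predictor ranks first
  expect_error(rank_predictors(fit, response = "Y", predictors = "nope"),
               "absent")
})
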