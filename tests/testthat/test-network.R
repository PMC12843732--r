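test_that("taxa filter applies the abundance AND prevalence rule", {
  # taxon in 2 of 10 samples at high abundance -> removed (prevalence)
  # taxon in all samples at mean 0.005% -> removed (abundance)
  v <- rbind(
    common = rep(0.3, 10),
    rare_prev = c(0.4, 0.4, rep(0, 8)),
    rare_abund = rep(5e-5, 10),
    mid = c(rep(0.2, 6), rep(0, 4))
  )
  v <- rbind(v, filler = 1 - colSums(v))
  colnames(v) <- paste0("s", 1:10)
  tab <- taxa_table(v, mode = "relative")
  kept <- filter_taxa(tab, min_rel_abund = 1e-4, min_prevalence = 3)$taxon_ids
  expect_setequal(kept, c("common", "mid", "filler"))

  # brute-force rule check on a random toy table
  set.seed(19)
  for (rep in 1:10) {
    w <- matrix(rexp(5 * 8) * rbinom(40, 1, 0.6), 5, 8,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:8)))
    tw <- as_relative(taxa_table(w, mode = "counts"))
    got <- filter_taxa(tw, min_rel_abund = 0.05, min_prevalence = 3)$taxon_ids
    expected <- rownames(w)[rowMeans(tw$values) >= 0.05 &
                              rowSums(tw$values > 0) >= 3]
    expect_identical(got, expected)
  }

  # empty result is a valid empty table
  e <- filter_taxa(tab, min_rel_abund = 0.99, min_prevalence = 3)
  expect_equal(nrow(e$values), 0L)
})

test_that("Spearman correlations match first-principles rank computation", {
  mk <- function(rows) taxa_table(rows, mode = "relative")
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  v <- rbind(a = x / sum(x), b = y / sum(y))
  v <- rbind(v, c = 1 - colSums(v))
  colnames(v) <- paste0("s", 1:5)
  sp <- spearman_matrix(mk(v))
  # sum d^2 = 4 at n = 5 -> rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(sp$rho["a", "b"], 0.8)
  expect_equal(sp$rho["a", "a"], 1)
  # and a sum d^2 = 6 case: y = (3,1,2,4,5) -> rho = 0.7
  v7 <- rbind(a = x / sum(x), b = c(3, 1, 2, 4, 5) / 15)
  v7 <- rbind(v7, c = 1 - colSums(v7)); colnames(v7) <- paste0("s", 1:5)
  expect_equal(spearman_matrix(mk(v7))$rho["a", "b"], 1 - 6 * 6 / (5 * 24))

  # strictly decreasing vs increasing -> -1, p = 0 under the convention
  v2 <- rbind(up = (1:5) / 15, down = (5:1) / 15)
  v2 <- rbind(v2, rest = 1 - colSums(v2)); colnames(v2) <- paste0("s", 1:5)
  sp2 <- spearman_matrix(mk(v2))
  expect_equal(sp2$rho["up", "down"], -1)
  expect_equal(sp2$p["up", "down"], 0)

  # tie handling vs brute-force rank correlation on random vectors
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(6:15, 1)
    a <- sample(0:4, n, replace = TRUE) + runif(n) * rbinom(n, 1, 0.5)
    b <- sample(0:4, n, replace = TRUE) + runif(n) * rbinom(n, 1, 0.5)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    m <- rbind(p = a, q = b) + 0.01
    colnames(m) <- paste0("s", seq_len(n))
    sp3 <- spearman_matrix(taxa_table(m, mode = "counts"))
    expect_equal(sp3$rho["p", "q"], oracle_spearman(a, b), tolerance = 1e-12)
    # t-approximation p agrees with the reference implementation
    if (abs(sp3$rho["p", "q"]) < 1) {
      ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
      expect_equal(sp3$p["p", "q"], ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Spearman is invariant under monotone transforms and flags constants", {
  set.seed(29)
  v <- matrix(rexp(4 * 12), 4, 12,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:12)))
  t1 <- taxa_table(v, mode = "counts")
  w <- v; w[2, ] <- exp(3 * w[2, ]); w[3, ] <- log(w[3, ] + 1)
  t2 <- taxa_table(w, mode = "counts")
  expect_equal(spearman_matrix(t1)$rho, spearman_matrix(t2)$rho,
               tolerance = 1e-12)

  vc <- v; vc[1, ] <- 0.25
  spc <- spearman_matrix(taxa_table(vc, mode = "counts"))
  expect_identical(spc$constant_taxa, "t1")
  expect_true(all(is.na(spc$rho["t1", ])))
})

test_that("exact permutation p-values match the reference for small n", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(5:7, 1)
    a <- sample(seq_len(50), n); b <- sample(seq_len(50), n)  # tie-free
    m <- rbind(p = a, q = b)
    colnames(m) <- paste0("s", seq_len(n))
    spe <- spearman_matrix(taxa_table(m, mode = "counts"), p_method = "exact")
    ref <- cor.test(a, b, method = "spearman", exact = TRUE)
    expect_equal(spe$p["p", "q"], ref$p.value, tolerance = 1e-12)
  }
})

test_that("edge rule is the exact conjunction with an inclusive threshold", {
  set.seed(43)
  for (rep in 1:20) {
    k <- sample(4:8, 1)
    rho <- matrix(0, k, k)
    rho[upper.tri(rho)] <- runif(choose(k, 2), -1, 1)
    rho <- rho + t(rho); diag(rho) <- 1
    p <- matrix(0, k, k)
    p[upper.tri(p)] <- runif(choose(k, 2))
    p <- p + t(p)
    net <- build_network(rho, p, paste0("t", 1:k))
    expected <- oracle_edges(rho, p)
    expect_equal(nrow(net$edges), if (is.null(expected)) 0L else nrow(expected))
    if (!is.null(expected)) {
      got <- net$edges[order(net$edges$from, net$edges$to), c("from", "to")]
      exp_df <- data.frame(from = paste0("t", expected[, 1]),
                           to = paste0("t", expected[, 2]))
      exp_df <- exp_df[order(exp_df$from, exp_df$to), ]
      expect_equal(got, exp_df, ignore_attr = TRUE)
    }
  }

  # boundary: rho = 0.8 exactly with p < alpha forms an edge (>= inclusive)
  rho <- matrix(c(1, 0.8, 0.8, 1), 2)
  p <- matrix(c(0, 0.01, 0.01, 0), 2)
  expect_equal(nrow(build_network(rho, p, c("a", "b"))$edges), 1L)
  p_ns <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(nrow(build_network(rho, p_ns, c("a", "b"))$edges), 0L)
  rho_lo <- matrix(c(1, 0.7999, 0.7999, 1), 2)
  expect_equal(nrow(build_network(rho_lo, p, c("a", "b"))$edges), 0L)
  expect_error(build_network(rho, p, c("a", "b"), rho_star = 1.5), "rho_star")
})

test_that("topology metrics: closed forms and brute-force agreement", {
  tri <- cooccurrence_network(c("a", "b", "c"),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               rho = 0.9, p = 0))
  tt <- topology(tri)
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$graph_density, 1)
  expect_equal(tt$average_degree, 2)
  expect_equal(tt$average_path_length, 1)

  path3 <- cooccurrence_network(c("a", "b", "c"),
    data.frame(from = c("a", "b"), to = c("b", "c"), rho = 0.9, p = 0))
  tp <- topology(path3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$graph_density, 2 / 3)
  expect_equal(tp$average_degree, 4 / 3)
  expect_equal(tp$average_path_length, 4 / 3)

  set.seed(47)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    g <- random_graph(n, p_edge = runif(1, 0.1, 0.8))
    got <- topology(graph_to_network(g))
    want <- oracle_topology(g$adj)
    for (metric in names(want)) {
      expect_equal(got[[metric]], want[[metric]], tolerance = 1e-12,
                   label = paste(metric, "rep", rep))
    }
    m <- got$n_edges
    if (m > 0) {
      expect_equal(got$negative_edge_proportion * m,
                   round(got$negative_edge_proportion * m))
    }
  }

  # all-positive -> 0; all-negative -> 1
  gpos <- random_graph(6, p_edge = 0.9, p_negative = 0)
  expect_equal(topology(graph_to_network(gpos))$negative_edge_proportion, 0)
  gneg <- random_graph(6, p_edge = 0.9, p_negative = 1)
  expect_equal(topology(graph_to_network(gneg))$negative_edge_proportion, 1)

  # edgeless network: undefined path length flagged as NA
  t0 <- topology(cooccurrence_network(c("a", "b")))
  expect_true(is.na(t0$average_path_length))
  expect_equal(t0$unreachable_pairs, 1L)
})

test_that("complexity index: forced extremes, hand toy and affine invariance", {
  mk <- function(nn, ne, cc, apl, dens) {
    list(stratum = NA_character_, community = NA_character_, n_nodes = nn,
         n_edges = ne, edges_per_node = ne / nn, average_degree = 2 * ne / nn,
         clustering_coefficient = cc, average_path_length = apl,
         unreachable_pairs = 0L, graph_density = dens,
         negative_edge_proportion = 0)
  }
  a <- structure(mk(10, 20, 0.5, 1.2, 0.4), class = "topology_summary")
  b <- structure(mk(8, 10, 0.3, 2.0, 0.3), class = "topology_summary")
  c_ <- structure(mk(6, 5, 0.1, 3.0, 0.1), class = "topology_summary")
  ci <- complexity_index(list(a, b, c_))
  # `a` is maximal in every metric (and has the shortest path length) -> 1
  expect_equal(ci$index$complexity[1], 1)
  expect_equal(ci$index$complexity[3], 0)
  # hand computation of the middle network via the min-max formula
  hand <- mean(c((8 - 6) / (10 - 6), (10 - 5) / (20 - 5),
                 (2 * 10 / 8 - 2 * 5 / 6) / (2 * 20 / 10 - 2 * 5 / 6),
                 (0.3 - 0.1) / (0.5 - 0.1),
                 (1 / 2 - 1 / 3) / (1 / 1.2 - 1 / 3),
                 (0.3 - 0.1) / (0.4 - 0.1)))
  expect_equal(ci$index$complexity[2], hand)

  # increasing affine rescale of one raw metric leaves all indices unchanged
  resc <- lapply(list(a, b, c_), function(s) {
    s$clustering_coefficient <- 5 * s$clustering_coefficient + 2
    s
  })
  expect_equal(complexity_index(resc)$index$complexity, ci$index$complexity,
               tolerance = 1e-12)

  # strictly increasing in any single metric, others fixed
  b_up <- b; b_up$n_edges <- 15; b_up$average_degree <- 2 * 15 / 8
  ci_up <- complexity_index(list(a, b_up, c_))
  expect_gt(ci_up$index$complexity[2], ci$index$complexity[2])

  # constant metrics are excluded and listed
  same_nodes <- lapply(list(a, b, c_), function(s) { s$n_nodes <- 9; s })
  ci2 <- complexity_index(same_nodes)
  expect_true("n_nodes" %in% ci2$excluded_metrics)
  expect_error(complexity_index(list(a)), ">= 2")
})

test_that("per-stratum ensemble yields 28 aggregate networks and skips small strata", {
  des <- simulation_design(replicates = 4, taxa = 12, block_size = 3,
                           complexity_profile = list(
                             bacteria = list(base = 1,
                               vegetation = c(AL = 0, NL = 0, MS = 0, HR = 0,
                                              CK = 0, PA = 0, AV = 0),
                               fraction = c(bulk = 0, LM = 0, SM = 0, MI = 0,
                                            SC = 0)),
                             fungi = list(base = 1,
                               vegetation = c(AL = 0, NL = 0, MS = 0, HR = 0,
                                              CK = 0, PA = 0, AV = 0),
                               fraction = c(bulk = 0, LM = 0, SM = 0, MI = 0,
                                            SC = 0))),
                           seed = 10)
  g <- generate_taxa_table(des, "bacteria")
  ens <- build_all_networks(g$table, g$metadata, run_config(), "bacteria")
  expect_length(ens$networks, 28L)
  expect_false(any(grepl("bulk", names(ens$networks))))
  with_bulk <- build_all_networks(g$table, g$metadata,
                                  run_config(include_bulk = TRUE), "bacteria")
  expect_length(with_bulk$networks, 35L)

  # a stratum reduced below 4 samples is skipped with a warning
  keep <- g$table$sample_ids[!(g$metadata$vegetation == "AL" &
                                 g$metadata$fraction == "LM" &
                                 g$metadata$plot != "AL-1")]
  sub <- subset_samples(g$table, keep)
  md <- g$metadata[g$metadata$sample_id %in% keep, ]
  expect_warning(ens2 <- build_all_networks(sub, md, run_config(), "bacteria"),
                 "AL.LM")
  expect_equal(ens2$skipped$stratum, "AL.LM")
  expect_length(ens2$networks, 27L)
})

test_that("planted blocks raise stratum edge counts above blockless strata", {
  hits <- vapply(1:10, function(s) {
    des <- simulation_design(replicates = 20, taxa = 12, block_size = 6,
                             within_correlation = 0.95,
                             anti_pair_fraction = 0,
                             complexity_profile = list(
                               bacteria = list(base = 0,
                                 vegetation = c(AL = 0, NL = 1, MS = 0, HR = 0,
                                                CK = 0, PA = 0, AV = 0),
                                 fraction = c(bulk = 0, LM = 1, SM = 0, MI = 0,
                                              SC = 0)),
                               fungi = list(base = 1,
                                 vegetation = c(AL = 0, NL = 0, MS = 0, HR = 0,
                                                CK = 0, PA = 0, AV = 0),
                                 fraction = c(bulk = 0, LM = 0, SM = 0, MI = 0,
                                              SC = 0))),
                             seed = 100 + s)
    g <- generate_taxa_table(des, "bacteria", seed = 100 + s)
    ens <- build_all_networks(g$table, g$metadata, run_config(), "bacteria")
    tab <- ens$topology
    planted <- tab$n_edges[tab$stratum == "NL.LM"]
    others <- tab$n_edges[tab$stratum != "NL.LM"]
    planted > max(others)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
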