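# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: explicit loops, Floyd-Warshall, literal
# enumeration.

# random simple undirected graph on n nodes as a symmetric logical adjacency
random_graph <- function(n, p_edge = 0.4, p_negative = 0.3) {
  adj <- matrix(FALSE, n, n)
  sign <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        adj[i, j] <- adj[j, i] <- TRUE
        s <- if (runif(1) < p_negative) -1L else 1L
        sign[i, j] <- sign[j, i] <- s
      }
    }
  }
  list(adj = adj, sign = sign)
}

graph_to_network <- function(g, taxa = paste0("t", seq_len(nrow(g$adj)))) {
  idx <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
               rho = 0.9 * g$sign[idx], p = 0.001,
               stringsAsFactors = FALSE)
  } else NULL
  cooccurrence_network(taxa, edges)
}

# exhaustive topology metrics: triangle enumeration + Floyd-Warshall
oracle_topology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  cc <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(adj[v, ])
    pairs <- combn(nb, 2)
    linked <- sum(apply(pairs, 2, function(pr) adj[pr[1], pr[2]]))
    linked / choose(deg[v], 2)
  }, numeric(1))
  D <- ifelse(adj, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  list(n_nodes = n, n_edges = m, average_degree = 2 * m / n,
       clustering_coefficient = mean(cc),
       average_path_length = if (length(finite)) mean(finite) else NA_real_,
       graph_density = if (n >= 2) 2 * m / (n * (n - 1)) else NA_real_,
       unreachable_pairs = choose(n, 2) - length(finite))
}

# Spearman rho of one pair from first principles (explicit rank-Pearson)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# literal edge-rule evaluation
oracle_edges <- function(rho, p, rho_star = 0.8, alpha = 0.05) {
  n <- nrow(rho)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(rho[i, j]) && !is.na(p[i, j]) &&
          abs(rho[i, j]) >= rho_star && p[i, j] < alpha) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# hierarchical partitioning by literal enumeration of admissible orderings
oracle_partition <- function(y, a, b) {
  df <- data.frame(y = y, A = factor(a), B = factor(b))
  r2 <- function(terms) {
    if (!length(terms)) return(0)
    summary(lm(reformulate(terms, "y"), data = df))$r.squared
  }
  # admissible orderings: every permutation of the three terms in which the
  # interaction never precedes either main effect
  perms <- list(c("A", "B", "A:B"), c("B", "A", "A:B"))
  inc <- c(A = 0, B = 0, `A:B` = 0)
  for (ord in perms) {
    sofar <- character(0)
    for (term in ord) {
      inc[term] <- inc[term] + (r2(c(sofar, term)) - r2(sofar))
      sofar <- c(sofar, term)
    }
  }
  inc <- inc / length(perms)
  list(shares = 100 * inc / sum(inc), full_r2 = r2(c("A", "B", "A:B")))
}

# closed-form standardized path analysis (single-indicator oracle)
oracle_path_analysis <- function(data, paths) {
  Z <- scale(as.matrix(data))
  B <- paths * 0
  for (to in rownames(paths)) {
    pred <- colnames(paths)[paths[to, ] > 0]
    if (!length(pred)) next
    B[to, pred] <- solve(crossprod(Z[, pred, drop = FALSE]),
                         crossprod(Z[, pred, drop = FALSE], Z[, to]))
  }
  B
}

# Kruskal stress-1 of a configuration, recomputed from scratch
oracle_stress <- function(X, d) {
  dv <- d[upper.tri(d)]
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dhat <- sqrt(rowSums((X[pairs[, 1], , drop = FALSE] -
                        X[pairs[, 2], , drop = FALSE])^2))
  ord <- order(dv)
  shat <- numeric(length(dhat))
  shat[ord] <- isoreg(dhat[ord])$yf
  sqrt(sum((dhat - shat)^2) / sum(dhat^2))
}

# small random soil table with the default schema
random_soil_table <- function(n = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  schema <- default_soil_schema()
  v <- matrix(rnorm(n * length(schema), mean = 10, sd = 3), n,
              dimnames = list(paste0("s", seq_len(n)), names(schema)))
  soil_table(v, schema = schema)
}

null_design <- function(seed, replicates = 20) {
  simulation_design(replicates = replicates, seed = seed,
                    path_coefficients = c(bacterial_diversity = 0,
                                          fungal_diversity = 0,
                                          bacterial_complexity = 0,
                                          fungal_complexity = 0))
}
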