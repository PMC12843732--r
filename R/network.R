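#' Abundance and prevalence filter for network taxa
#'
#' Removes rare taxa before network inference: a taxon is kept only if its
#' summarized relative abundance across the stratum's samples is at least
#' `min_rel_abund` (default 1e-4, i.e. 0.01%) AND it is present (positive)
#' in at least `min_prevalence` samples (default 3). Removal is the OR of
#' the two failures. A counts table is converted to relative abundance
#' first. An empty result is a valid empty table, not an error.
#'
#' @param table a [taxa_table()].
#' @param min_rel_abund minimum summarized relative abundance (proportion).
#' @param min_prevalence minimum number of samples with positive abundance.
#' @param summary how abundance is summarized across samples: `"mean"`
#'   (default), `"max"`, or `"overall"` (pooled abundance share).
#' @return a filtered `taxa_table` in relative mode.
#' @export
filter_taxa <- function(table, min_rel_abund = 1e-4, min_prevalence = 3,
                        summary = c("mean", "max", "overall")) {
  stopifnot(inherits(table, "taxa_table"))
  summary <- match.arg(summary)
  table <- as_relative(table)
  v <- table$values
  abund <- switch(summary,
    mean = rowMeans(v),
    max = apply(v, 1, max),
    overall = if (sum(v) > 0) rowSums(v) / sum(v) else rowSums(v))
  prevalence <- rowSums(v > 0)
  keep <- abund >= min_rel_abund & prevalence >= min_prevalence
  out <- table
  out$values <- v[keep, , drop = FALSE]
  out$taxon_ids <- table$taxon_ids[keep]
  # values stay fractions of the ORIGINAL community (no renormalization):
  # renormalizing would rescale each sample by a different factor and
  # perturb the cross-sample ranks the Spearman step depends on, so
  # filtered columns deliberately sum to < 1
  out$zero_samples <- out$sample_ids[colSums(out$values) == 0]
  out
}

#' Threshold correlation matrices into a co-occurrence network
#'
#' An edge joins taxa i and j iff `|rho_ij| >= rho_star` (inclusive) and
#' `p_ij < alpha`. Undefined correlations (`NA`, e.g. from constant taxa)
#' never form edges. All filtered taxa stay in the node set, so isolated
#' nodes are preserved.
#'
#' @param rho,p symmetric taxa x taxa matrices from [spearman_matrix()].
#' @param taxa node ids matching the matrix order.
#' @param rho_star correlation threshold in (0, 1).
#' @param alpha significance level in (0, 1).
#' @param p_adjust optional [stats::p.adjust()] method applied to the
#'   upper-triangle p-values before thresholding (`"none"` by default).
#' @param stratum,community labels carried on the network.
#' @return a [cooccurrence_network()].
#' @export
build_network <- function(rho, p, taxa = rownames(rho), rho_star = 0.8,
                          alpha = 0.05, p_adjust = "none",
                          stratum = NA_character_, community = NA_character_) {
  if (!(rho_star > 0 && rho_star < 1)) stop("build_network: rho_star must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("build_network: alpha must be in (0, 1)")
  rho <- as.matrix(rho); p <- as.matrix(p)
  if (!all(dim(rho) == dim(p)) || nrow(rho) != ncol(rho)) {
    stop("build_network: rho and p must be square matrices of equal size")
  }
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(rho)))
  if (length(taxa) != nrow(rho)) stop("build_network: taxa ids do not match matrices")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  if (p_adjust != "none") pv <- stats::p.adjust(pv, method = p_adjust)
  hit <- !is.na(rho[ut]) & !is.na(pv) & abs(rho[ut]) >= rho_star & pv < alpha
  edges <- if (any(hit)) {
    data.frame(from = taxa[ut[hit, 1]], to = taxa[ut[hit, 2]],
               rho = rho[ut][hit], p = pv[hit], stringsAsFactors = FALSE)
  } else NULL
  cooccurrence_network(taxa, edges, stratum = stratum, community = community)
}

#' Topological parameters of a co-occurrence network
#'
#' Computes the six standard topological parameters — node count, edge
#' count, average degree (2E/N), average local clustering coefficient
#' (nodes with degree < 2 contribute 0), average shortest path length and
#' graph density (2E/(N(N-1))) — plus the edges-per-node ratio and the
#' proportion of negative edges. Path lengths ignore edge signs and
#' weights; on a disconnected graph the average is taken over connected
#' pairs only (the number of unreachable pairs is reported), and it is `NA`
#' when no connected pair exists.
#'
#' @param network a [cooccurrence_network()].
#' @return object of class `topology_summary` (a named list).
#' @export
topology <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  g <- as_igraph(network)
  n <- length(network$taxa)
  if (n < 1) stop("topology: need >= 1 node")
  m <- nrow(network$edges)
  cc <- if (n >= 1) igraph::transitivity(g, type = "localaverage",
                                         isolates = "zero") else NA_real_
  if (is.nan(cc)) cc <- 0
  comp <- igraph::components(g)
  connected_pairs <- sum(choose(comp$csize, 2))
  apl <- if (connected_pairs > 0) {
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  } else NA_real_
  structure(
    list(stratum = network$stratum,
         community = network$community,
         n_nodes = n,
         n_edges = m,
         edges_per_node = if (n > 0) m / n else NA_real_,
         average_degree = if (n > 0) 2 * m / n else NA_real_,
         clustering_coefficient = cc,
         average_path_length = apl,
         unreachable_pairs = as.integer(choose(n, 2) - connected_pairs),
         graph_density = if (n >= 2) 2 * m / (n * (n - 1)) else NA_real_,
         negative_edge_proportion = if (m > 0) sum(network$edges$sign < 0) / m
                                    else NA_real_),
    class = "topology_summary"
  )
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary> %s: N=%d E=%d deg=%.3g cc=%.3g apl=%s dens=%.3g\n",
              ifelse(is.na(x$stratum), "network", x$stratum),
              x$n_nodes, x$n_edges, x$average_degree, x$clustering_coefficient,
              ifelse(is.na(x$average_path_length), "NA",
                     sprintf("%.3g", x$average_path_length)),
              x$graph_density))
  invisible(x)
}

#' Collect an ensemble of topology summaries into a data frame
#'
#' @param ensemble list of `topology_summary` objects.
#' @return data frame, one row per network.
#' @export
topology_table <- function(ensemble) {
  stopifnot(length(ensemble) >= 1)
  do.call(rbind, lapply(ensemble, function(s) {
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  }))
}

#' Network complexity index over an ensemble of networks
#'
#' Standardizes each topological metric across the networks of an ensemble
#' and averages them into a single complexity index per network. The metric
#' set is node count, edge count, average degree, clustering coefficient,
#' the reciprocal of the average path length (inverted first so that all
#' metrics point in the "more complex" direction) and graph density. The
#' default standardization is min-max to [0, 1], so a network maximal in
#' every metric within its ensemble scores 1 and a minimal one scores 0.
#' Metrics constant across the ensemble carry no information and are
#' excluded (and listed); a network with an undefined path length has that
#' metric treated as missing with the averaging divisor adjusted.
#'
#' @param ensemble list of `topology_summary` objects (>= 2), or the data
#'   frame from [topology_table()].
#' @param metrics metric columns to standardize; the default is the
#'   six-parameter set with `inv_average_path_length` derived as
#'   `1 / average_path_length`.
#' @param standardization `"minmax"` (default) or `"zscore"`.
#' @return object of class `complexity_index`: `index` (data frame with
#'   stratum, community, complexity), `standardized` (networks x metrics),
#'   `metrics_used`, `excluded_metrics`, `bounds` (per-metric min/max).
#' @export
complexity_index <- function(ensemble,
                             metrics = c("n_nodes", "n_edges",
                                         "average_degree",
                                         "clustering_coefficient",
                                         "inv_average_path_length",
                                         "graph_density"),
                             standardization = c("minmax", "zscore")) {
  standardization <- match.arg(standardization)
  tab <- if (is.data.frame(ensemble)) ensemble else topology_table(ensemble)
  if (nrow(tab) < 2) {
    stop("complexity_index: ensemble standardization needs >= 2 networks")
  }
  tab$inv_average_path_length <- 1 / tab$average_path_length
  missing <- setdiff(metrics, names(tab))
  if (length(missing)) {
    stop("complexity_index: unknown metric(s): ", paste(missing, collapse = ", "))
  }
  raw <- as.matrix(tab[, metrics, drop = FALSE])
  constant <- apply(raw, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || min(x) == max(x)
  })
  used <- metrics[!constant]
  if (!length(used)) stop("complexity_index: all metrics are constant across the ensemble")
  std <- raw[, used, drop = FALSE]
  for (j in seq_along(used)) {
    std[, j] <- if (standardization == "minmax") {
      minmax_standardize(raw[, used[j]], na_ok = TRUE)
    } else {
      as.numeric(scale(raw[, used[j]]))
    }
  }
  idx <- rowMeans(std, na.rm = TRUE)
  out <- data.frame(
    stratum = if ("stratum" %in% names(tab)) tab$stratum else NA_character_,
    community = if ("community" %in% names(tab)) tab$community else NA_character_,
    complexity = idx, stringsAsFactors = FALSE)
  structure(
    list(index = out, standardized = std, metrics_used = used,
         excluded_metrics = metrics[constant],
         standardization = standardization,
         bounds = data.frame(metric = used,
                             min = apply(raw[, used, drop = FALSE], 2, min, na.rm = TRUE),
                             max = apply(raw[, used, drop = FALSE], 2, max, na.rm = TRUE),
                             row.names = NULL, stringsAsFactors = FALSE)),
    class = "complexity_index"
  )
}

#' @export
print.complexity_index <- function(x, ...) {
  cat(sprintf("<complexity_index> %d networks, %d metric(s) [%s]\n",
              nrow(x$index), length(x$metrics_used), x$standardization))
  if (length(x$excluded_metrics)) {
    cat("  excluded constant metric(s):",
        paste(x$excluded_metrics, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Infer one co-occurrence network per vegetation-by-fraction stratum
#'
#' Splits the samples by vegetation type and aggregate fraction, applies
#' the abundance/prevalence filter within each stratum, computes Spearman
#' correlations and thresholds them into a network. The default 7
#' vegetation x 4 aggregate-fraction design yields 28 networks per
#' community type; bulk-soil samples are excluded from the aggregate-scale
#' ensemble unless `include_bulk` is set in the configuration. Strata with
#' fewer than 4 samples cannot support the correlation test and are skipped
#' with a warning (and recorded); a stratum whose taxa are all filtered out
#' yields an empty network, not an error.
#'
#' @param table a [taxa_table()].
#' @param metadata a [sample_metadata()] data frame covering all samples.
#' @param config a [run_config()].
#' @param community community type label stored on each network.
#' @return object of class `network_ensemble`: `networks` (list of
#'   [cooccurrence_network()]), `topology` (data frame via
#'   [topology_table()]), `skipped` (data frame of skipped strata),
#'   `config`.
#' @export
build_all_networks <- function(table, metadata, config = run_config(),
                               community = NA_character_) {
  stopifnot(inherits(table, "taxa_table"))
  .check_metadata_cover(metadata, table$sample_ids)
  fr_levels <- fraction_levels()
  if (!config$include_bulk) fr_levels <- setdiff(fr_levels, "bulk")
  meta <- metadata[match(table$sample_ids, metadata$sample_id), ]
  networks <- list()
  summaries <- list()
  skipped <- data.frame(stratum = character(), n_samples = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  for (veg in vegetation_levels()) {
    for (fr in fr_levels) {
      ids <- table$sample_ids[meta$vegetation == veg & meta$fraction == fr]
      label <- paste(veg, fr, sep = ".")
      if (length(ids) == 0) next
      if (length(ids) < 4) {
        warning(sprintf("stratum %s has %d sample(s) (< 4); skipped",
                        label, length(ids)))
        skipped <- rbind(skipped, data.frame(
          stratum = label, n_samples = length(ids),
          reason = "fewer than 4 samples", stringsAsFactors = FALSE))
        next
      }
      sub <- filter_taxa(subset_samples(table, ids),
                         min_rel_abund = config$min_rel_abund,
                         min_prevalence = config$min_prevalence,
                         summary = config$abundance_summary)
      net <- if (nrow(sub$values) < 2) {
        cooccurrence_network(sub$taxon_ids, NULL, stratum = label,
                             community = community)
      } else {
        sp <- spearman_matrix(sub, p_method = config$p_method)
        build_network(sp$rho, sp$p, sub$taxon_ids,
                      rho_star = config$rho_star, alpha = config$alpha,
                      p_adjust = config$p_adjust, stratum = label,
                      community = community)
      }
      networks[[label]] <- net
      summaries[[label]] <- topology(net)
    }
  }
  structure(
    list(networks = networks,
         topology = if (length(summaries)) topology_table(summaries) else NULL,
         skipped = skipped, config = config, community = community),
    class = "network_ensemble"
  )
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat(sprintf("<network_ensemble> %d network(s)%s, %d skipped stratum(a)\n",
              length(x$networks),
              ifelse(is.na(x$community), "", paste0(" [", x$community, "]")),
              nrow(x$skipped)))
  invisible(x)
}
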