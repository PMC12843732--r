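#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline so that a run is reproducible from
#' its configuration alone. The defaults follow the analysis conventions of
#' aggregate-scale co-occurrence studies: edges require |Spearman rho| >= 0.8
#' at p < 0.05; taxa enter a stratum's network only if their mean relative
#' abundance is >= 0.01% and they occur in >= 3 samples.
#'
#' @param min_rel_abund minimum mean relative abundance for the taxa filter
#'   (proportion; 1e-4 = 0.01%).
#' @param min_prevalence minimum number of samples a taxon must occur in.
#' @param rho_star correlation threshold for network edges, in (0, 1).
#' @param alpha significance level for edges and group tests, in (0, 1).
#' @param abundance_summary summary statistic the abundance filter applies
#'   across a stratum's samples: `"mean"`, `"max"` or `"overall"`.
#' @param complexity_metrics metric set of the network complexity index.
#' @param standardization `"minmax"` (default) or `"zscore"` scheme for the
#'   complexity index.
#' @param p_method `"t"` for the t approximation of Spearman p-values, or
#'   `"exact"` for the exact permutation distribution (n <= 9 only).
#' @param p_adjust multiplicity correction applied to edge p-values
#'   (`"none"` by default; any [stats::p.adjust()] method).
#' @param nmds_k,nmds_restarts NMDS embedding dimension and random restarts.
#' @param plspm_scheme,plspm_tol inner estimation scheme and convergence
#'   tolerance of the PLS path model.
#' @param include_bulk include bulk-soil samples as a network stratum.
#' @param seed integer random seed recorded in all outputs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(min_rel_abund = 1e-4,
                       min_prevalence = 3,
                       rho_star = 0.8,
                       alpha = 0.05,
                       abundance_summary = c("mean", "max", "overall"),
                       complexity_metrics = c("n_nodes", "n_edges",
                                              "average_degree",
                                              "clustering_coefficient",
                                              "inv_average_path_length",
                                              "graph_density"),
                       standardization = c("minmax", "zscore"),
                       p_method = c("t", "exact"),
                       p_adjust = "none",
                       nmds_k = 2,
                       nmds_restarts = 20,
                       plspm_scheme = c("centroid", "factorial", "path"),
                       plspm_tol = 1e-7,
                       include_bulk = FALSE,
                       seed = 1L) {
  if (!(rho_star > 0 && rho_star < 1)) stop("run_config: rho_star must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("run_config: alpha must be in (0, 1)")
  structure(
    list(min_rel_abund = min_rel_abund,
         min_prevalence = as.integer(min_prevalence),
         rho_star = rho_star,
         alpha = alpha,
         abundance_summary = match.arg(abundance_summary),
         complexity_metrics = complexity_metrics,
         standardization = match.arg(standardization),
         p_method = match.arg(p_method),
         p_adjust = p_adjust,
         nmds_k = as.integer(nmds_k),
         nmds_restarts = as.integer(nmds_restarts),
         plspm_scheme = match.arg(plspm_scheme),
         plspm_tol = plspm_tol,
         include_bulk = isTRUE(include_bulk),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys fall back to the defaults of
#' [run_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write result bundles as JSON, embedding the run configuration
#'
#' Every numeric result artifact the pipeline writes carries the
#' configuration (including the seed) that produced it.
#'
#' @param x a list (or coercible) of results.
#' @param path output `.json` path.
#' @param config the [run_config()] used for the run, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, config = NULL) {
  payload <- list(results = x)
  if (!is.null(config)) payload$run_config <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
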