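#' Assemble the per-sample predictor table for driver analysis
#'
#' Joins soil multifunctionality, per-sample Shannon diversity of both
#' communities, and the per-stratum network complexity indices (each
#' aggregate sample inherits the complexity of its vegetation x fraction
#' network) into one table. Samples from strata without a network (e.g.
#' bulk soil when excluded) get `NA` complexity.
#'
#' @param dataset a [generate_dataset()] result, or any list with elements
#'   `bacteria`, `fungi` ([taxa_table()]s), `soil` ([soil_table()]) and
#'   `metadata`.
#' @param config a [run_config()].
#' @return list of class `smf_analysis`: `predictors` (per-sample data
#'   frame), `smf` ([compute_multifunctionality()] result), `ensembles`
#'   (per-community [build_all_networks()] results), `complexity`
#'   (per-community [complexity_index()] results), `config`.
#' @export
analyze_dataset <- function(dataset, config = run_config()) {
  smf <- compute_multifunctionality(dataset$soil)
  sh_b <- shannon_table(dataset$bacteria)
  sh_f <- shannon_table(dataset$fungi)
  ens <- list(
    bacteria = build_all_networks(dataset$bacteria, dataset$metadata,
                                  config, community = "bacteria"),
    fungi = build_all_networks(dataset$fungi, dataset$metadata,
                               config, community = "fungi"))
  cx <- lapply(ens, function(e) complexity_index(
    e$topology, metrics = config$complexity_metrics,
    standardization = config$standardization))
  md <- dataset$metadata
  stratum <- paste(md$vegetation, md$fraction, sep = ".")
  cx_of <- function(ci) {
    setNames(ci$index$complexity, ci$index$stratum)[stratum]
  }
  predictors <- data.frame(
    sample_id = md$sample_id,
    vegetation = md$vegetation,
    fraction = md$fraction,
    stratum = stratum,
    SMF = smf$scores$SMF[match(md$sample_id, smf$scores$sample_id)],
    bacterial_diversity = sh_b$shannon[match(md$sample_id, sh_b$sample_id)],
    fungal_diversity = sh_f$shannon[match(md$sample_id, sh_f$sample_id)],
    bacterial_complexity = unname(cx_of(cx$bacteria)),
    fungal_complexity = unname(cx_of(cx$fungi)),
    stringsAsFactors = FALSE)
  structure(
    list(predictors = predictors, smf = smf, ensembles = ens,
         complexity = cx, config = config),
    class = "smf_analysis"
  )
}

#' Fit the SMF driver path model
#'
#' Fits a PLS path model with the four microbial predictors (bacterial and
#' fungal diversity, bacterial and fungal network complexity) as
#' single-indicator exogenous latents, each with a direct path into SMF —
#' either pooled over all aggregate samples or separately per aggregate
#' fraction.
#'
#' @param predictors the predictor table from [analyze_dataset()].
#' @param by_fraction fit one model per aggregate fraction instead of a
#'   pooled model.
#' @param scheme,tol passed to [plspm_fit()].
#' @return a named list of [plspm_fit()] objects (one entry, `"pooled"`,
#'   unless `by_fraction`).
#' @export
fit_smf_drivers <- function(predictors, by_fraction = FALSE,
                            scheme = "centroid", tol = 1e-7) {
  vars <- c("bacterial_diversity", "fungal_diversity",
            "bacterial_complexity", "fungal_complexity")
  dat <- predictors[complete.cases(predictors[, c(vars, "SMF")]), ]
  blocks <- c(setNames(as.list(vars), vars), list(SMF = "SMF"))
  lat <- names(blocks)
  paths <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  paths["SMF", vars] <- 1
  fit_one <- function(d) plspm_fit(d, blocks, paths, scheme = scheme, tol = tol)
  if (by_fraction) {
    frs <- intersect(fraction_levels(), unique(as.character(dat$fraction)))
    setNames(lapply(frs, function(fr) fit_one(dat[dat$fraction == fr, ])), frs)
  } else {
    list(pooled = fit_one(dat))
  }
}

#' Run the full pipeline on a synthetic dataset
#'
#' Convenience wrapper: [analyze_dataset()], then [fit_smf_drivers()] and
#' [rank_predictors()].
#'
#' @param dataset a [generate_dataset()] result.
#' @param config a [run_config()].
#' @param by_fraction fit driver models per aggregate fraction.
#' @return the [analyze_dataset()] list, extended with `drivers` (the
#'   fitted path models) and `ranking` (a [rank_predictors()] result).
#' @export
run_pipeline <- function(dataset, config = run_config(), by_fraction = FALSE) {
  out <- analyze_dataset(dataset, config)
  out$drivers <- fit_smf_drivers(out$predictors, by_fraction = by_fraction,
                                 scheme = config$plspm_scheme,
                                 tol = config$plspm_tol)
  out$ranking <- rank_predictors(out$drivers, response = "SMF")
  out
}
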