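#' Specify a factorial simulation design
#'
#' Describes a vegetation x aggregate-fraction factorial community survey
#' with planted, recoverable structure: correlated taxa blocks that control
#' the expected co-occurrence network complexity of each stratum,
#' vegetation/fraction effects on community evenness (hence Shannon
#' diversity), and a latent soil-fertility variable, wired to the planted
#' stratum properties by standardized path coefficients, from which the
#' soil variables (and therefore multifunctionality) are generated.
#'
#' The default factorial is 7 vegetation types x 5 fractions (bulk plus
#' four aggregate classes) x 4 replicate plots = 140 samples. Replicates
#' are configurable because the Spearman edge rule (|rho| >= 0.8, p < 0.05)
#' is essentially unsatisfiable at n = 4; network-recovery studies should
#' use >= 20 replicates per stratum.
#'
#' Block counts per stratum follow built-in vegetation and fraction
#' profiles per community (restoration raises fungal block counts, most in
#' AV, and fungal counts grow as aggregate size shrinks; bacterial counts
#' rise under NL/PA/AV and fall under HR/CK), overridable via
#' `complexity_profile`.
#'
#' @param replicates replicate plots per vegetation x fraction cell (>= 2).
#' @param taxa number of taxa per community table.
#' @param block_size taxa per correlated block.
#' @param within_correlation latent (copula) correlation inside a block,
#'   |r| < 1.
#' @param anti_pair_fraction fraction of blocks whose last member is
#'   anti-correlated with the rest (plants negative edges).
#' @param abundance_spread spread of the log-abundance means; larger values
#'   mean a less even community (lower Shannon diversity).
#' @param log_sd standard deviation of the log-normal abundance noise.
#' @param complexity_profile,diversity_profile optional overrides: a list
#'   with per-community `vegetation` and `fraction` named numeric vectors
#'   of additive effects (block-count offsets, evenness effects).
#' @param path_coefficients named standardized effects of the planted
#'   stratum properties on the latent fertility driving the soil variables.
#' @param latent_noise_sd noise on the latent fertility (per sample).
#' @param soil_noise_sd noise on each generated soil variable.
#' @param seed integer seed (< 2^31).
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(replicates = 4,
                              taxa = 50,
                              block_size = 6,
                              within_correlation = 0.9,
                              anti_pair_fraction = 0.3,
                              abundance_spread = 4,
                              log_sd = 1,
                              complexity_profile = NULL,
                              diversity_profile = NULL,
                              path_coefficients = c(bacterial_diversity = 0.3,
                                                    fungal_diversity = 0.1,
                                                    bacterial_complexity = 0.1,
                                                    fungal_complexity = 0.6),
                              latent_noise_sd = 0.5,
                              soil_noise_sd = 0.5,
                              seed = 1L) {
  if (replicates < 2) stop("simulation_design: replicates must be >= 2")
  if (abs(within_correlation) >= 1) {
    stop("simulation_design: |within_correlation| must be < 1")
  }
  if (is.null(complexity_profile)) {
    complexity_profile <- list(
      bacteria = list(
        base = 1,
        vegetation = c(AL = 1, NL = 3, MS = 2, HR = 0, CK = 0, PA = 3, AV = 3),
        fraction = c(bulk = 0, LM = 0, SM = 0, MI = 0, SC = 0)),
      fungi = list(
        base = 1,
        vegetation = c(AL = 0, NL = 1, MS = 1, HR = 1, CK = 1, PA = 1, AV = 2),
        fraction = c(bulk = 0, LM = 0, SM = 1, MI = 2, SC = 3)))
  }
  if (is.null(diversity_profile)) {
    diversity_profile <- list(
      bacteria = list(
        vegetation = c(AL = 0, NL = 0.2, MS = 0.2, HR = 0.2, CK = 0.2,
                       PA = 0.25, AV = 0.3),
        fraction = c(bulk = 0.1, LM = 0, SM = 0.1, MI = 0.2, SC = 0.2)),
      fungi = list(
        vegetation = c(AL = 0, NL = 0, MS = 0.3, HR = -0.3, CK = 0.25,
                       PA = -0.3, AV = -0.2),
        fraction = c(bulk = 0, LM = 0, SM = 0, MI = 0.25, SC = 0.1)))
  }
  max_blocks <- max(vapply(complexity_profile, function(p) {
    p$base + max(p$vegetation) + max(p$fraction)
  }, numeric(1)))
  if (max_blocks * block_size > taxa) {
    stop("simulation_design: block plan needs more taxa than available (",
         max_blocks, " blocks x ", block_size, " > ", taxa, ")")
  }
  structure(
    list(replicates = as.integer(replicates), taxa = as.integer(taxa),
         block_size = as.integer(block_size),
         within_correlation = within_correlation,
         anti_pair_fraction = anti_pair_fraction,
         abundance_spread = abundance_spread, log_sd = log_sd,
         complexity_profile = complexity_profile,
         diversity_profile = diversity_profile,
         path_coefficients = path_coefficients,
         latent_noise_sd = latent_noise_sd, soil_noise_sd = soil_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# stratum grid and planted per-stratum properties for one community
.stratum_plan <- function(design, community) {
  grid <- expand.grid(fraction = fraction_levels(),
                      vegetation = vegetation_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("vegetation", "fraction")]
  cp <- design$complexity_profile[[community]]
  dp <- design$diversity_profile[[community]]
  grid$stratum <- paste(grid$vegetation, grid$fraction, sep = ".")
  grid$n_blocks <- cp$base + cp$vegetation[grid$vegetation] +
    cp$fraction[grid$fraction]
  grid$evenness_effect <- dp$vegetation[grid$vegetation] +
    dp$fraction[grid$fraction]
  rownames(grid) <- NULL
  grid
}

# block-structured correlation matrix; anti-members are sign-flipped
.block_correlation <- function(taxa, n_blocks, block_size, r, anti_blocks) {
  S <- diag(taxa)
  membership <- rep(NA_integer_, taxa)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    S[idx, idx] <- r
    diag(S)[idx] <- 1
    if (b <= anti_blocks) {
      k <- idx[length(idx)]
      S[k, setdiff(idx, k)] <- -r
      S[setdiff(idx, k), k] <- -r
    }
    membership[idx] <- b
  }
  L <- tryCatch(chol(S), error = function(e) {
    stop(sprintf("requested correlation matrix is not positive definite (block of size %d at r = %g)",
                 block_size, r), call. = FALSE)
  })
  list(chol = L, membership = membership)
}

#' Generate a taxa table with planted correlation blocks
#'
#' Per vegetation x fraction stratum, taxa abundances are exponentiated
#' correlated Gaussians (a log-normal marginal with a Gaussian copula):
#' the copula correlation matrix carries the stratum's planted blocks, so
#' strata with more blocks yield Spearman networks with more edges in
#' expectation. Rank-based statistics see only the copula, which is why no
#' attempt is made at marginal realism. A configurable fraction of blocks
#' carries one anti-correlated member to plant negative edges. The result
#' is converted to per-sample relative abundance.
#'
#' @param design a [simulation_design()].
#' @param community `"bacteria"` or `"fungi"`.
#' @param seed integer seed (defaults to the design's).
#' @return list with `table` (a relative-mode [taxa_table()]), `metadata`
#'   (a [sample_metadata()]), and `truth` (per-stratum block counts, block
#'   membership, evenness effects).
#' @export
generate_taxa_table <- function(design, community = c("bacteria", "fungi"),
                                seed = design$seed) {
  community <- match.arg(community)
  set.seed(seed)
  plan <- .stratum_plan(design, community)
  nt <- design$taxa
  reps <- design$replicates
  prefix <- substr(community, 1, 1)
  cols <- list(); ids <- character(0)
  meta <- list()
  membership <- list()
  for (s in seq_len(nrow(plan))) {
    bc <- .block_correlation(nt, plan$n_blocks[s], design$block_size,
                             design$within_correlation,
                             anti_blocks = round(design$anti_pair_fraction *
                                                 plan$n_blocks[s]))
    spread <- design$abundance_spread * exp(-plan$evenness_effect[s])
    # abundance ranks are assigned to taxa in random order: correlated
    # guilds span the whole abundance range, which also keeps the planted
    # copula visible after closure (a block of uniformly dominant taxa
    # would distort every taxon's relative abundance through the total)
    mu <- sample(-spread * (seq_len(nt) - 1) / (nt - 1))
    Z <- matrix(rnorm(reps * nt), reps, nt) %*% bc$chol
    ab <- exp(sweep(design$log_sd * t(Z), 1, mu, "+"))   # taxa x reps
    sample_ids <- paste(plan$stratum[s], paste0("r", seq_len(reps)), sep = ".")
    ids <- c(ids, sample_ids)
    cols[[s]] <- ab
    meta[[s]] <- data.frame(sample_id = sample_ids,
                            vegetation = plan$vegetation[s],
                            fraction = plan$fraction[s],
                            plot = paste0(plan$vegetation[s], "-", seq_len(reps)),
                            stringsAsFactors = FALSE)
    membership[[plan$stratum[s]]] <- bc$membership
  }
  values <- do.call(cbind, cols)
  rownames(values) <- paste0(prefix, "_taxon", seq_len(nt))
  colnames(values) <- ids
  md <- do.call(rbind, meta)
  tab <- as_relative(taxa_table(values, mode = "counts"))
  list(table = tab,
       metadata = sample_metadata(md$sample_id, md$vegetation, md$fraction,
                                  md$plot),
       truth = list(plan = plan, block_membership = membership,
                    community = community))
}

#' Generate soil variables from a per-sample latent fertility
#'
#' Each of the 15 schema variables is `loading * latent + noise`, with
#' positive loadings so that min-max averaging into SMF is monotone in the
#' latent: at zero noise the SMF ranking equals the latent ranking exactly.
#'
#' @param design a [simulation_design()] (supplies `soil_noise_sd`).
#' @param latent named numeric vector of per-sample latent fertility values
#'   (names = sample ids).
#' @param schema cycle-tag schema, see [soil_table()].
#' @param seed integer seed.
#' @return list with `table` (a [soil_table()]) and `loadings`.
#' @export
generate_soil_table <- function(design, latent,
                                schema = default_soil_schema(),
                                seed = design$seed) {
  if (is.null(names(latent))) stop("generate_soil_table: latent values must be named by sample id")
  set.seed(seed)
  nv <- length(schema)
  n <- length(latent)
  loadings <- runif(nv, 0.7, 1)
  values <- sapply(seq_len(nv), function(j) {
    loadings[j] * latent + rnorm(n, 0, design$soil_noise_sd)
  })
  colnames(values) <- names(schema)
  rownames(values) <- names(latent)
  list(table = soil_table(values, sample_ids = names(latent), schema = schema),
       loadings = setNames(loadings, names(schema)))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Assembles both community taxa tables, the metadata and the soil table
#' under the planted generative chain: the stratum determines the planted
#' network complexity (block counts) and community evenness; those
#' per-stratum properties, standardized across strata, feed a per-sample
#' latent fertility through the design's path coefficients; the soil
#' variables (and hence SMF) are generated from that latent. The returned
#' ground truth is sufficient to score recovery of every planted quantity.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed (defaults to the design's; component seeds are
#'   derived by fixed offsets).
#' @return object of class `synthetic_dataset`: `bacteria`, `fungi` (taxa
#'   tables), `soil` (soil table), `metadata`, and `truth` (per-stratum
#'   planted values, path coefficients, per-sample latent fertility, block
#'   memberships).
#' @export
generate_dataset <- function(design, seed = design$seed) {
  bac <- generate_taxa_table(design, "bacteria", seed = seed + 1L)
  fun <- generate_taxa_table(design, "fungi", seed = seed + 2L)
  metadata <- bac$metadata
  stopifnot(identical(bac$metadata$sample_id, fun$metadata$sample_id))
  stratum_of <- paste(metadata$vegetation, metadata$fraction, sep = ".")
  z <- function(plan, col) {
    v <- plan[[col]]
    setNames(as.numeric(scale(v)), plan$stratum)
  }
  zb <- z(bac$truth$plan, "n_blocks"); zf <- z(fun$truth$plan, "n_blocks")
  db <- z(bac$truth$plan, "evenness_effect"); df <- z(fun$truth$plan, "evenness_effect")
  beta <- design$path_coefficients
  set.seed(seed + 3L)
  latent <- beta[["bacterial_diversity"]] * db[stratum_of] +
    beta[["fungal_diversity"]] * df[stratum_of] +
    beta[["bacterial_complexity"]] * zb[stratum_of] +
    beta[["fungal_complexity"]] * zf[stratum_of] +
    rnorm(nrow(metadata), 0, design$latent_noise_sd)
  names(latent) <- metadata$sample_id
  soil <- generate_soil_table(design, latent, seed = seed + 4L)
  structure(
    list(bacteria = bac$table, fungi = fun$table, soil = soil$table,
         metadata = metadata,
         truth = list(
           design = design,
           path_coefficients = beta,
           latent_fertility = latent,
           soil_loadings = soil$loadings,
           stratum = setNames(stratum_of, metadata$sample_id),
           complexity_target = list(bacteria = zb, fungi = zf),
           diversity_target = list(bacteria = db, fungi = df),
           block_membership = list(bacteria = bac$truth$block_membership,
                                   fungi = fun$truth$block_membership),
           plan = list(bacteria = bac$truth$plan, fungi = fun$truth$plan))),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples; bacteria %d taxa, fungi %d taxa, %d soil variables\n",
              nrow(x$metadata), length(x$bacteria$taxon_ids),
              length(x$fungi$taxon_ids), length(x$soil$variables)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Writes `bacteria.tsv`, `fungi.tsv`, `soil.tsv`, `metadata.tsv` and a
#' `ground_truth.json` capturing the planted values.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxa_table(dataset$bacteria, file.path(dir, "bacteria.tsv"))
  write_taxa_table(dataset$fungi, file.path(dir, "fungi.tsv"))
  write_soil_table(dataset$soil, file.path(dir, "soil.tsv"))
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- dataset$truth
  truth$design <- unclass(truth$design)
  truth$path_coefficients <- as.list(truth$path_coefficients)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
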