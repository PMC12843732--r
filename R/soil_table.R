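#' Default soil-variable schema
#'
#' The default indicator set covers fifteen variables tied to soil carbon
#' (organic C, dissolved organic C, easily oxidizable organic C, microbial
#' biomass C, beta-glucosidase), nitrogen (total N, nitrate N, ammonium N,
#' microbial biomass N, N-acetylglucosaminidase, leucine aminopeptidase) and
#' phosphorus (total P, available P, microbial biomass P, alkaline
#' phosphatase) cycling: 5 C, 6 N and 4 P indicators.
#'
#' @return named character vector mapping variable name to cycle tag
#'   (`"C"`, `"N"` or `"P"`).
#' @export
default_soil_schema <- function() {
  c(SOC = "C", DOC = "C", EOC = "C", MBC = "C", BG = "C",
    TN = "N", NO3 = "N", NH4 = "N", MBN = "N", NAG = "N", LAP = "N",
    TP = "P", AP = "P", MBP = "P", ALP = "P")
}

#' Construct a soil-variable table
#'
#' Samples in rows, soil variables in columns, each variable tagged with the
#' nutrient cycle (C, N or P) it belongs to. This is the substrate of the
#' soil multifunctionality computation.
#'
#' @param values numeric matrix, samples x variables.
#' @param sample_ids unique sample identifiers (default rownames).
#' @param schema named character vector mapping every column of `values` to
#'   a cycle tag in `c("C","N","P")`; defaults to [default_soil_schema()].
#' @return object of class `soil_table` with fields `values`, `sample_ids`,
#'   `variables`, `cycles`.
#' @export
soil_table <- function(values, sample_ids = rownames(values),
                       schema = default_soil_schema()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) stop("soil_table: sample ids are required")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("soil_table: duplicated sample id(s)")
  vars <- colnames(values)
  if (is.null(vars)) stop("soil_table: variable names are required")
  missing <- setdiff(vars, names(schema))
  if (length(missing)) {
    stop("soil_table: variable(s) absent from the schema: ",
         paste(missing, collapse = ", "))
  }
  absent <- setdiff(names(schema), vars)
  if (length(absent)) {
    stop("soil_table: schema variable(s) missing from the table: ",
         paste(absent, collapse = ", "))
  }
  cycles <- schema[vars]
  if (!all(cycles %in% c("C", "N", "P"))) {
    stop("soil_table: cycle tags must be C, N or P")
  }
  if (anyNA(values)) stop("soil_table: missing values must be masked explicitly")
  rownames(values) <- sample_ids
  structure(
    list(values = values, sample_ids = sample_ids, variables = vars,
         cycles = cycles),
    class = "soil_table"
  )
}

#' @export
print.soil_table <- function(x, ...) {
  tab <- table(factor(x$cycles, levels = c("C", "N", "P")))
  cat(sprintf("<soil_table> %d samples x %d variables (C:%d N:%d P:%d)\n",
              length(x$sample_ids), length(x$variables),
              tab[["C"]], tab[["N"]], tab[["P"]]))
  invisible(x)
}

#' Read a soil-variable table from tab-separated text
#'
#' Samples in rows (first column = sample id), one column per soil variable.
#' Every column must be covered by the schema and vice versa; a missing or
#' extra variable is an error naming it.
#'
#' @param path file path.
#' @param schema named cycle-tag mapping, see [soil_table()].
#' @return a [soil_table()].
#' @export
read_soil_table <- function(path, schema = default_soil_schema()) {
  raw <- .read_tsv_strict(path)
  if (ncol(raw) < 2) stop("read_soil_table: need a sample id column plus >= 1 variable")
  ids <- as.character(raw[[1]])
  num <- raw[, -1, drop = FALSE]
  nonnum <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop("read_soil_table: non-numeric cell(s) in column(s): ",
         paste(nonnum, collapse = ", "))
  }
  soil_table(as.matrix(num), sample_ids = ids, schema = schema)
}

#' Write a soil-variable table as tab-separated text
#'
#' @param x a [soil_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_soil_table <- function(x, path) {
  stopifnot(inherits(x, "soil_table"))
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

## ---- sample metadata ----

#' Vegetation and aggregate-fraction levels of the factorial design
#'
#' Seven vegetation types — abandoned cropland (AL), natural grassland (NL),
#' Medicago sativa (MS), Hippophae rhamnoides (HR), Caragana korshinskii
#' (CK), Populus alba (PA) and Armeniaca vulgaris (AV) — crossed with bulk
#' soil plus four aggregate size fractions: large macro-aggregates (LM),
#' small macro-aggregates (SM), micro-aggregates (MI) and silt/clay (SC).
#'
#' @name design-levels
#' @return character vector of factor levels.
#' @export
vegetation_levels <- function() c("AL", "NL", "MS", "HR", "CK", "PA", "AV")

#' @rdname design-levels
#' @export
fraction_levels <- function() c("bulk", "LM", "SM", "MI", "SC")

#' Construct sample metadata
#'
#' One record per sample mapping it to a vegetation type, an aggregate
#' fraction and a replicate plot.
#'
#' @param sample_id,vegetation,fraction,plot equal-length vectors;
#'   `vegetation` and `fraction` are restricted to [vegetation_levels()] and
#'   [fraction_levels()].
#' @return a `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, vegetation, fraction, plot) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_metadata: duplicated sample id(s)")
  bad_v <- setdiff(unique(as.character(vegetation)), vegetation_levels())
  if (length(bad_v)) {
    stop("sample_metadata: unknown vegetation level(s): ",
         paste(bad_v, collapse = ", "))
  }
  bad_f <- setdiff(unique(as.character(fraction)), fraction_levels())
  if (length(bad_f)) {
    stop("sample_metadata: unknown fraction level(s): ",
         paste(bad_f, collapse = ", "))
  }
  out <- data.frame(
    sample_id = sample_id,
    vegetation = factor(vegetation, levels = vegetation_levels()),
    fraction = factor(fraction, levels = fraction_levels()),
    plot = as.character(plot),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Read sample metadata from tab-separated text
#'
#' Requires columns `sample_id`, `vegetation`, `fraction`, `plot`.
#'
#' @param path file path.
#' @return a [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path) {
  raw <- .read_tsv_strict(path)
  need <- c("sample_id", "vegetation", "fraction", "plot")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("read_sample_metadata: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  sample_metadata(raw$sample_id, raw$vegetation, raw$fraction, raw$plot)
}

#' Write sample metadata as tab-separated text
#'
#' @param x a [sample_metadata()] data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Check that every sample id in `ids` has exactly one metadata record.
.check_metadata_cover <- function(metadata, ids) {
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing)) {
    stop("metadata does not cover sample(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
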