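#' Construct a taxa abundance table
#'
#' A taxa table holds a taxa-by-samples matrix of non-negative abundances,
#' either raw counts or per-sample relative abundances. It is the substrate
#' for diversity, ordination and co-occurrence network inference.
#'
#' @param values numeric matrix, taxa in rows, samples in columns.
#' @param taxon_ids character vector of unique taxon identifiers
#'   (default: rownames of `values`).
#' @param sample_ids character vector of unique sample identifiers
#'   (default: colnames of `values`).
#' @param mode `"counts"` or `"relative"`. In relative mode every non-empty
#'   sample column must sum to 1 (tolerance 1e-9); all-zero columns are
#'   retained but flagged in the `zero_samples` field.
#' @return an object of class `taxa_table` with fields `values`,
#'   `taxon_ids`, `sample_ids`, `mode`, `zero_samples`.
#' @seealso [read_taxa_table()], [as_relative()]
#' @export
taxa_table <- function(values, taxon_ids = rownames(values),
                       sample_ids = colnames(values),
                       mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(taxon_ids) || is.null(sample_ids)) {
    stop("taxa_table: taxon and sample identifiers are required")
  }
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(taxon_ids)) {
    stop("taxa_table: duplicated taxon id(s): ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("taxa_table: duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (nrow(values) != length(taxon_ids) || ncol(values) != length(sample_ids)) {
    stop("taxa_table: dimensions do not match the identifier vectors")
  }
  if (anyNA(values)) stop("taxa_table: missing values are not allowed")
  if (any(values < 0)) stop("taxa_table: negative abundances found")
  dimnames(values) <- list(taxon_ids, sample_ids)
  csum <- colSums(values)
  zero_samples <- sample_ids[csum == 0]
  if (mode == "relative") {
    bad <- csum != 0 & abs(csum - 1) > 1e-9
    if (any(bad)) {
      stop("taxa_table: relative-abundance columns must sum to 1; offending sample(s): ",
           paste(sample_ids[bad], collapse = ", "))
    }
  }
  structure(
    list(values = values, taxon_ids = taxon_ids, sample_ids = sample_ids,
         mode = mode, zero_samples = zero_samples),
    class = "taxa_table"
  )
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table> %d taxa x %d samples (%s mode)\n",
              length(x$taxon_ids), length(x$sample_ids), x$mode))
  if (length(x$zero_samples)) {
    cat("  all-zero samples:", paste(x$zero_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$values)

#' Convert a taxa table to relative abundance
#'
#' Divides every sample column by its sum. The canonical internal form of
#' the pipeline is relative abundance: the taxa filter and the downstream
#' rules are stated on relative abundances. All-zero columns stay zero and
#' remain flagged.
#'
#' @param x a [taxa_table()].
#' @return a `taxa_table` in `"relative"` mode.
#' @export
as_relative <- function(x) {
  stopifnot(inherits(x, "taxa_table"))
  if (x$mode == "relative") return(x)
  v <- x$values
  csum <- colSums(v)
  pos <- csum > 0
  v[, pos] <- sweep(v[, pos, drop = FALSE], 2, csum[pos], "/")
  taxa_table(v, x$taxon_ids, x$sample_ids, mode = "relative")
}

#' Subset the samples of a taxa table
#'
#' @param x a [taxa_table()].
#' @param samples character vector of sample ids to keep (order preserved).
#' @return a `taxa_table` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "taxa_table"))
  missing <- setdiff(samples, x$sample_ids)
  if (length(missing)) {
    stop("subset_samples: unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  taxa_table(x$values[, samples, drop = FALSE], x$taxon_ids, samples, mode = x$mode)
}

#' Read a taxa abundance table from tab-separated text
#'
#' Expects a UTF-8, tab-separated file with a header row of sample ids and
#' the taxon id in the first column ("." decimal separator, no thousands
#' separators). Ragged rows are reported with their line number.
#'
#' @param path file path.
#' @param mode `"counts"` or `"relative"`: how the stored values are to be
#'   interpreted.
#' @param to_relative if `TRUE` (default) a counts table is converted to
#'   per-sample relative abundance after validation.
#' @return a [taxa_table()].
#' @export
read_taxa_table <- function(path, mode = c("counts", "relative"),
                            to_relative = TRUE) {
  mode <- match.arg(mode)
  raw <- .read_tsv_strict(path)
  if (ncol(raw) < 2) stop("read_taxa_table: need a taxon id column plus >= 1 sample")
  ids <- as.character(raw[[1]])
  num <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(num)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))
    stop("read_taxa_table: non-numeric abundance column(s): ",
         paste(names(raw)[-1][bad], collapse = ", "))
  }
  tab <- taxa_table(num, taxon_ids = ids, sample_ids = colnames(num), mode = mode)
  if (mode == "counts" && to_relative) tab <- as_relative(tab) else tab
}

#' Write a taxa table as tab-separated text
#'
#' @param x a [taxa_table()].
#' @param path output file path.
#' @param id_column header name for the taxon id column.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(x, path, id_column = "taxon_id") {
  stopifnot(inherits(x, "taxa_table"))
  df <- data.frame(x$taxon_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# Strict TSV reader: refuses ragged rows and reports the first bad line.
.read_tsv_strict <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in %s: line %d has %d field(s), expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  read.delim(text = lines, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
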