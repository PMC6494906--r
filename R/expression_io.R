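#' Expression matrix container
#'
#' Holds a genes-or-probes x samples matrix of expression values E, the
#' per-sample annotations, the measurement scale (`log2` or `linear`) and the
#' unit (`intensity`, `FPKM` or `counts`). All downstream operations consume
#' and produce this container.
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples.
#' @param samples data.frame of sample annotations; must have `sample_id`,
#'   and may carry `subject_id`, `substructure`, `hemisphere`, `age`, `sex`.
#'   Row order matches the columns of `values`.
#' @param scale `"log2"` or `"linear"`.
#' @param unit `"intensity"`, `"FPKM"` or `"counts"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples, scale = c("log2", "linear"),
                              unit = c("intensity", "FPKM", "counts")) {
  scale <- match.arg(scale)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale == "linear" && any(values < 0))
    stop("negative value on linear scale")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique row identifiers")
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) stop("samples need a sample_id column")
  if (nrow(samples) != ncol(values))
    stop(sprintf("annotation rows (%d) do not match expression columns (%d)",
                 nrow(samples), ncol(values)))
  colnames(values) <- as.character(samples$sample_id)
  structure(list(values = values, samples = samples,
                 scale = scale, unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d rows x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

.dialects <- list(
  allen_microarray = list(scale = "log2",   unit = "intensity", header = FALSE),
  adtbi_fpkm       = list(scale = "linear", unit = "FPKM",      header = TRUE),
  nuclei_counts    = list(scale = "linear", unit = "counts",    header = TRUE)
)

#' Read an expression table with its sample annotations
#'
#' Parses the three supported file dialects into an [expression_matrix()]:
#' * `allen_microarray`: headerless CSV, first column probe id, one column
#'   per sample; values are log2 intensities. Annotation CSV row order
#'   defines sample order.
#' * `adtbi_fpkm`: CSV with a header row, first column gene id; linear FPKM.
#' * `nuclei_counts`: CSV with a header row, first column gene id; linear
#'   counts, one column per nucleus.
#'
#' Parsing is header-tolerant: a leading header row in a nominally headerless
#' file is detected (non-numeric data cells) and skipped.
#'
#' @param path expression CSV.
#' @param annotation_path sample annotation CSV (one row per sample; must
#'   contain `sample_id` or the first column is taken as the id).
#' @param dialect one of `"allen_microarray"`, `"adtbi_fpkm"`,
#'   `"nuclei_counts"`.
#' @return An `ExpressionMatrix` with scale/unit set by the dialect.
#' @export
read_expression_table <- function(path, annotation_path,
                                  dialect = c("allen_microarray",
                                              "adtbi_fpkm",
                                              "nuclei_counts")) {
  dialect <- match.arg(dialect)
  for (p in c(path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)
  spec <- .dialects[[dialect]]

  raw <- data.table::fread(path, header = spec$header, data.table = FALSE,
                           colClasses = list(character = 1))
  if (!spec$header) {
    # tolerate an unexpected header row: every data cell non-numeric
    first_data <- suppressWarnings(as.numeric(unlist(raw[1, -1])))
    if (all(is.na(first_data)) && ncol(raw) > 1) raw <- raw[-1, , drop = FALSE]
  }
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2] + 1L, path))
  }
  if (anyNA(num)) stop("missing value in expression table ", path)
  rownames(num) <- ids

  ann <- data.table::fread(annotation_path, header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(ann)) names(ann)[1] <- "sample_id"
  if (nrow(ann) != ncol(num))
    stop(sprintf("annotation rows (%d) do not match expression columns (%d)",
                 nrow(ann), ncol(num)))
  expression_matrix(num, ann, scale = spec$scale, unit = spec$unit)
}

#' Write an expression table and its annotations
#'
#' Inverse of [read_expression_table()]: a round-trip through write/read
#' reproduces the values bit-identically for every dialect.
#'
#' @param m an `ExpressionMatrix`.
#' @param path expression CSV output path.
#' @param annotation_path annotation CSV output path.
#' @param dialect target dialect (controls header convention).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, annotation_path,
                                   dialect = c("allen_microarray",
                                               "adtbi_fpkm",
                                               "nuclei_counts")) {
  dialect <- match.arg(dialect)
  spec <- .dialects[[dialect]]
  df <- data.frame(id = rownames(m$values), m$values,
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path, col.names = spec$header)
  data.table::fwrite(m$samples, annotation_path)
  invisible(path)
}

#' Average samples to substructure level for one subject
#'
#' Collapses all samples of one subject that map to the same substructure to
#' their arithmetic mean, pooling left and right hemisphere samples. The mean
#' is taken on the stored scale (log2 for microarray data, matching how the
#' atlas reports region averages).
#'
#' @param m an `ExpressionMatrix` restricted to a single subject.
#' @param ontology an `OntologyMap`; every sample's substructure must resolve.
#' @param subject optional subject id; if given, `m` is first restricted to
#'   that subject's samples.
#' @param drop_white_matter drop samples whose substructure is flagged
#'   white-matter (the microarray-run default upstream of this call).
#' @return An `ExpressionMatrix` with one column per observed substructure;
#'   sample annotations carry `substructure` as `sample_id`.
#' @export
aggregate_substructures <- function(m, ontology, subject = NULL,
                                    drop_white_matter = FALSE) {
  samp <- m$samples
  keep <- rep(TRUE, nrow(samp))
  if (!is.null(subject)) {
    if (!"subject_id" %in% names(samp)) stop("samples lack subject_id")
    keep <- samp$subject_id == subject
    if (!any(keep)) stop("no samples for subject ", subject)
  } else if ("subject_id" %in% names(samp) &&
             length(unique(samp$subject_id)) > 1) {
    stop("matrix spans multiple subjects; pass `subject`")
  }
  samp <- samp[keep, , drop = FALSE]
  vals <- m$values[, keep, drop = FALSE]
  if (!"substructure" %in% names(samp)) stop("samples lack substructure")
  onto <- ontology_lookup(samp$substructure, ontology)
  if (drop_white_matter) {
    gm <- !onto$white_matter
    samp <- samp[gm, , drop = FALSE]
    vals <- vals[, gm, drop = FALSE]
  }
  subs <- unique(samp$substructure)
  out <- vapply(subs, function(s)
    rowMeans(vals[, samp$substructure == s, drop = FALSE]),
    numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(rownames(vals), subs))
  ann <- data.frame(sample_id = subs, substructure = subs,
                    hemisphere = "none")
  if ("subject_id" %in% names(samp) && nrow(samp))
    ann$subject_id <- samp$subject_id[1]
  if ("age" %in% names(samp) && nrow(samp)) ann$age <- samp$age[1]
  expression_matrix(out, ann, scale = m$scale, unit = m$unit)
}

#' Convert an expression matrix to the linear scale
#'
#' Log2 values v are replaced by 2^v; an already-linear matrix is returned
#' unchanged (the operation is idempotent and strictly monotone per cell).
#'
#' @param m an `ExpressionMatrix`.
#' @return An `ExpressionMatrix` on the linear scale.
#' @export
to_linear <- function(m) {
  if (m$scale == "linear") return(m)
  m$values <- 2 ^ m$values
  m$scale <- "linear"
  m
}
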