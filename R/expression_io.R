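#' Expression matrix container
#'
#' Light S3 container for a features x samples matrix of read counts or
#' normalized expression values. Carries the feature level (`"transcript"` or
#' `"gene"`) and, once normalized, the method used, so every downstream table
#' records how its numbers were produced.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids). All values must be
#'   finite and non-negative; ids must be unique.
#' @param level `"transcript"` or `"gene"`.
#' @param normalized Logical; `TRUE` if values are library-size normalized.
#' @param norm_method Character tag recording the normalization method
#'   (e.g. `"cpm"`); `NULL` for raw counts.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, level = c("transcript", "gene"),
                        normalized = FALSE, norm_method = NULL) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (missing cells are not allowed)")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (normalized && is.null(norm_method))
    stop("normalized matrices must record the method used")
  structure(list(values = values, level = level,
                 normalized = normalized, norm_method = norm_method),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d %s features x %d samples (%s)\n",
              nrow(x$values), x$level, ncol(x$values),
              if (x$normalized) paste0("normalized: ", x$norm_method)
              else "raw counts"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines
# ignored, no quoting.
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, encoding = "UTF-8", ...)
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a count matrix from TSV
#'
#' First column feature ids, header row sample ids, numeric body. Rejects
#' duplicate ids, negative values, non-numeric or missing cells.
#'
#' @param path Path to a tab-separated file.
#' @param level Feature level of the file, `"transcript"` (default) or
#'   `"gene"`.
#' @param normalized,norm_method Passed to [expr_matrix()]; use when reading
#'   back a normalized matrix written by [write_counts()].
#' @return An [expr_matrix()].
#' @export
read_counts <- function(path, level = c("transcript", "gene"),
                        normalized = FALSE, norm_method = NULL) {
  level <- match.arg(level)
  df <- read_tsv_strict(path)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("count file '", path,
         "' is empty or has no sample columns; expected feature ids in ",
         "column 1 and one column per sample")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  num <- vapply(body, function(col) {
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    as.numeric(col)
  }, numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(body)))
  if (any(is.na(num)))
    stop("non-numeric or missing cells in count file: ", path)
  expr_matrix(num, level = level, normalized = normalized,
              norm_method = norm_method)
}

#' Write a count matrix to TSV
#'
#' Mirrors [read_counts()]: integer matrices round-trip bit-identically.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = feature_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  invisible(path)
}

#' Read and validate a sample design table
#'
#' Expects columns `sample_id`, `cultivar`, `pair_id`, `tolerance_class`
#' (`tolerant`/`sensitive`), `day` (non-negative integer) and `replicate`.
#' Each pair must contain exactly one tolerant and one sensitive cultivar, and
#' each (cultivar, day) cell at least two replicates so group variances are
#' estimable.
#'
#' @param path Path to a TSV file, or a data.frame with the same columns.
#' @return A validated data.frame of class `sample_design`.
#' @export
read_design <- function(path) {
  df <- if (is.data.frame(path)) path else read_tsv_strict(path)
  as_sample_design(df)
}

#' @rdname read_design
#' @param df Data frame with the design columns.
#' @export
as_sample_design <- function(df) {
  req <- c("sample_id", "cultivar", "pair_id", "tolerance_class", "day",
           "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, req]
  df$sample_id <- as.character(df$sample_id)
  df$cultivar <- as.character(df$cultivar)
  df$pair_id <- as.character(df$pair_id)
  df$tolerance_class <- as.character(df$tolerance_class)
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in design")
  bad <- setdiff(unique(df$tolerance_class), c("tolerant", "sensitive"))
  if (length(bad))
    stop("unknown tolerance_class: ", paste(bad, collapse = ", "))
  if (any(is.na(df$day)) || any(df$day < 0L))
    stop("'day' must be a non-negative integer")
  for (p in unique(df$pair_id)) {
    sub <- unique(df[df$pair_id == p, c("cultivar", "tolerance_class")])
    n_tol <- sum(sub$tolerance_class == "tolerant")
    n_sen <- sum(sub$tolerance_class == "sensitive")
    if (n_tol != 1L || n_sen != 1L)
      stop("pair '", p, "' must contain exactly one tolerant and one ",
           "sensitive cultivar (found ", n_tol, " tolerant, ", n_sen,
           " sensitive)")
  }
  cell <- table(df$cultivar, df$day)
  if (any(cell > 0 & cell < 2))
    stop("each (cultivar, day) cell needs >= 2 replicates for variance ",
         "estimation")
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d samples, %d pair(s), days %s\n",
              nrow(x), length(unique(x$pair_id)),
              paste(sort(unique(x$day)), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write a sample design table
#' @param design A `sample_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  write_tsv_strict(as.data.frame(design), path)
  invisible(path)
}

#' Read a transcript-to-gene map
#'
#' Two-column TSV (`transcript_id`, `gene_id`), many-to-one: every transcript
#' maps to exactly one gene.
#'
#' @param path TSV path or a two-column data.frame.
#' @return Data frame with columns `transcript_id`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  df <- if (is.data.frame(path)) path else read_tsv_strict(path)
  if (ncol(df) < 2L) stop("gene map needs columns transcript_id, gene_id")
  df <- data.frame(transcript_id = as.character(df[[1L]]),
                   gene_id = as.character(df[[2L]]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$transcript_id))
    stop("transcripts mapping to more than one gene: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
               collapse = ", "))
  df
}

#' Write a transcript-to-gene map
#' @param map Data frame from [read_gene_map()].
#' @param path Output path.
#' @export
write_gene_map <- function(map, path) {
  write_tsv_strict(map, path)
  invisible(path)
}

#' Sum isoform values to gene level
#'
#' Per sample, the gene value is the sum of the values of all its splicing
#' isoforms; per-sample totals are conserved exactly. Works on raw counts or
#' on normalized values (the container records which).
#'
#' @param x A transcript-level [expr_matrix()].
#' @param map Transcript-to-gene map from [read_gene_map()].
#' @return A gene-level [expr_matrix()] with the same normalization state.
#' @export
aggregate_isoforms <- function(x, map) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$level != "transcript")
    stop("aggregate_isoforms() expects a transcript-level matrix")
  missing_tx <- setdiff(feature_ids(x), map$transcript_id)
  if (length(missing_tx))
    stop("transcripts absent from the gene map: ",
         paste(missing_tx, collapse = ", "))
  gene <- map$gene_id[match(feature_ids(x), map$transcript_id)]
  agg <- rowsum(x$values, group = gene, reorder = TRUE)
  expr_matrix(agg, level = "gene", normalized = x$normalized,
              norm_method = x$norm_method)
}

#' Library-size normalization
#'
#' `cpm` scales each sample to counts per million. `median_of_ratios`
#' estimates per-sample size factors as the median, over genes, of the ratio
#' of the sample's count to the gene's geometric-mean reference; genes with a
#' zero count in any sample are excluded from factor estimation.
#'
#' @param x A raw-count [expr_matrix()].
#' @param method `"cpm"` (default) or `"median_of_ratios"`.
#' @return A normalized [expr_matrix()] with the per-sample size factors in
#'   attribute `"size_factors"` (for cpm, library size / 1e6).
#' @export
normalize_counts <- function(x, method = c("cpm", "median_of_ratios")) {
  stopifnot(inherits(x, "expr_matrix"))
  method <- match.arg(method)
  if (x$normalized)
    stop("matrix is already normalized (", x$norm_method, ")")
  sf <- size_factors(x$values, method)
  out <- sweep(x$values, 2L, sf, "/")
  res <- expr_matrix(out, level = x$level, normalized = TRUE,
                     norm_method = method)
  attr(res, "size_factors") <- sf
  res
}

#' Per-sample size factors
#'
#' @param values Raw count matrix (features x samples).
#' @param method `"cpm"` or `"median_of_ratios"`.
#' @return Named numeric vector of size factors; dividing each sample by its
#'   factor yields the normalized matrix.
#' @export
size_factors <- function(values, method = c("cpm", "median_of_ratios")) {
  method <- match.arg(method)
  lib <- colSums(values)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(values)[lib == 0], collapse = ", "))
  if (method == "cpm") return(lib / 1e6)
  keep <- rowSums(values > 0) == ncol(values)
  if (!any(keep))
    stop("median-of-ratios needs at least one gene with nonzero counts in ",
         "every sample")
  log_ref <- rowMeans(log(values[keep, , drop = FALSE]))
  sf <- apply(values[keep, , drop = FALSE], 2L,
              function(col) exp(stats::median(log(col) - log_ref)))
  sf
}
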