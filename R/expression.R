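#' Construct a probe-by-sample expression matrix
#'
#' The central container of the package: a non-negative intensity matrix with
#' probes in rows and samples in columns, plus a sample metadata table giving
#' each sample's patient, tissue (normal/cancer) and priming method
#' (oligo_dT/random). Missing values are explicit `NA`s, never silent zeros.
#'
#' @param values numeric matrix, probes x samples, with rownames = probe ids
#'   and colnames = sample ids. All finite values must be >= 0.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `tissue` (one of "normal", "cancer") and `priming` (one of "oligo_dT",
#'   "random"). Column order of `values` must follow `samples$sample_id`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` and `samples`.
#' @seealso [read_expression_table()] to build one from TSV files.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_input("expression_matrix(): 'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_input("expression_matrix(): 'values' needs probe rownames and sample colnames")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "tissue", "priming")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort_input("sample metadata is missing column(s): %s", paste(miss, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$patient_id <- as.integer(samples$patient_id)
  samples$tissue <- as.character(samples$tissue)
  samples$priming <- as.character(samples$priming)
  if (anyNA(samples$patient_id) || any(samples$patient_id < 1L)) {
    abort_input("patient_id must be integers >= 1")
  }
  bad_t <- setdiff(unique(samples$tissue), TISSUES)
  if (length(bad_t)) abort_input("unknown tissue value(s): %s", paste(bad_t, collapse = ", "))
  bad_p <- setdiff(unique(samples$priming), PRIMINGS)
  if (length(bad_p)) abort_input("unknown priming value(s): %s", paste(bad_p, collapse = ", "))

  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) abort_input("duplicate probe id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(samples$sample_id)) {
    abort_input("duplicate sample id(s): %s",
                paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  key <- paste(samples$patient_id, samples$tissue, samples$priming)
  if (anyDuplicated(key)) {
    abort_input("duplicate sample key (patient, tissue, priming): %s",
                key[duplicated(key)][1L])
  }
  if (!identical(colnames(values), samples$sample_id)) {
    if (!setequal(colnames(values), samples$sample_id)) {
      abort_input("matrix columns and metadata sample_id do not match")
    }
    values <- values[, samples$sample_id, drop = FALSE]
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort_input("negative intensity at probe '%s', sample '%s'",
                rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]])
  }
  structure(list(values = values, samples = samples), class = "expression_matrix")
}

# Internal fast constructor used in permutation loops: skips validation.
new_expression_matrix <- function(values, samples) {
  structure(list(values = values, samples = samples), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d patients)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$patient_id))))
  tb <- table(x$samples$tissue, x$samples$priming)
  print(tb)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Is the paired design complete?
#'
#' TRUE when every patient has all four (tissue, priming) sample combinations.
#'
#' @param x an `expression_matrix`.
#' @return logical scalar.
#' @export
is_complete_design <- function(x) {
  s <- x$samples
  all(vapply(split(paste(s$tissue, s$priming), s$patient_id),
             function(k) length(unique(k)) == 4L, logical(1)))
}

# Column index for one (patient, tissue, priming) combination; NA if absent.
sample_col <- function(x, patient, tissue, priming) {
  s <- x$samples
  i <- which(s$patient_id == patient & s$tissue == tissue & s$priming == priming)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

# Columns for all patients (ascending) of one (tissue, priming) group.
group_cols <- function(x, tissue, priming, patients = NULL) {
  s <- x$samples
  patients <- patients %||% sort(unique(s$patient_id))
  vapply(patients, function(p) sample_col(x, p, tissue, priming), integer(1))
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has a header row `probe_id` followed by sample ids, one
#' probe per row. The metadata file has columns `sample_id`, `patient_id`,
#' `tissue`, `priming`. Sample order in the returned object follows the
#' metadata row order. Empty cells in the matrix become `NA` (explicitly
#' missing); non-numeric cells and negative intensities are reported with
#' their probe/sample context.
#'
#' @param matrix_path path to the intensity TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return an `expression_matrix`.
#' @export
read_expression_table <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) abort_input("matrix file not found: %s", matrix_path)
  if (!file.exists(metadata_path)) abort_input("metadata file not found: %s", metadata_path)
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2L) abort_input("matrix file has no sample columns: %s", matrix_path)
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(raw[[1L]])
  header_samples <- colnames(raw)[-1L]
  unknown <- setdiff(header_samples, as.character(meta$sample_id))
  if (length(unknown)) {
    abort_input("sample id(s) in matrix header not present in metadata: %s",
                paste(unknown, collapse = ", "))
  }
  absent <- setdiff(as.character(meta$sample_id), header_samples)
  if (length(absent)) {
    abort_input("metadata sample id(s) absent from matrix header: %s",
                paste(absent, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(header_samples),
                 dimnames = list(probe_ids, header_samples))
  for (j in seq_along(header_samples)) {
    col <- trimws(raw[[j + 1L]])
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & nzchar(col) & col != "NA")
    if (length(bad)) {
      abort_input("non-numeric cell '%s' at probe '%s', sample '%s'",
                  col[bad[1L]], probe_ids[bad[1L]], header_samples[j])
    }
    vals[, j] <- x
  }
  expression_matrix(vals, meta)
}

#' Read / validate a probe annotation table
#'
#' Columns: `probe_id`, `gene_id`, `probe_class` ("sense" or "afas"),
#' `afas_index` (ordinal of the antisense probe along its gene; NA for sense
#' probes) and `truncated` (logical; probes spanning an exon-exon junction).
#'
#' @param annotation a data.frame, or a path to a TSV with those columns.
#' @return a validated data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    if (!file.exists(annotation)) abort_input("annotation file not found: %s", annotation)
    annotation <- utils::read.delim(annotation, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  }
  a <- as.data.frame(annotation, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_id", "probe_class", "afas_index", "truncated")
  miss <- setdiff(req, names(a))
  if (length(miss)) abort_input("annotation missing column(s): %s", paste(miss, collapse = ", "))
  a$probe_id <- as.character(a$probe_id)
  a$gene_id <- as.character(a$gene_id)
  a$probe_class <- as.character(a$probe_class)
  a$afas_index <- suppressWarnings(as.integer(a$afas_index))
  a$truncated <- as.logical(a$truncated)
  if (anyDuplicated(a$probe_id)) {
    abort_input("duplicate probe id(s) in annotation: %s",
                paste(unique(a$probe_id[duplicated(a$probe_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(a$probe_class), c("sense", "afas"))
  if (length(bad)) abort_input("unknown probe_class value(s): %s", paste(bad, collapse = ", "))
  sense <- a$probe_class == "sense"
  if (any(!is.na(a$afas_index[sense]))) {
    abort_input("sense probes must have empty afas_index")
  }
  if (any(a$truncated[sense])) abort_input("sense probes cannot be truncated")
  if (any(is.na(a$afas_index[!sense]))) {
    abort_input("afas probe(s) without afas_index: %s",
                paste(a$probe_id[!sense & is.na(a$afas_index)][1L]))
  }
  if (anyNA(a$truncated)) abort_input("truncated must be TRUE/FALSE")
  for (g in unique(a$gene_id[!sense])) {
    ix <- a$afas_index[!sense & a$gene_id == g]
    if (anyDuplicated(ix)) abort_input("duplicate afas_index within gene '%s'", g)
  }
  class(a) <- c("probe_annotation", "data.frame")
  a
}

#' Write result tables as deterministic TSV files
#'
#' Each named table is written to `<out_dir>/<name>.tsv` with tab separation,
#' LF line endings, UTF-8 encoding and all numeric columns formatted to 6
#' significant digits, so identical inputs give byte-identical files. Empty
#' tables produce a header-only file.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a manifest data.frame with columns `name`, `file`,
#'   `n_rows`, `md5`.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort_input("write_results(): 'tables' must be a fully named list")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) abort_input("cannot create output directory: %s", out_dir)
  }
  files <- character(length(tables))
  nr <- integer(length(tables))
  for (i in seq_along(tables)) {
    tab <- as.data.frame(tables[[i]], stringsAsFactors = FALSE)
    for (j in seq_along(tab)) {
      if (is.numeric(tab[[j]]) && !is.integer(tab[[j]])) tab[[j]] <- format_num(tab[[j]])
    }
    path <- file.path(out_dir, paste0(names(tables)[i], ".tsv"))
    con <- file(path, open = "wb")
    lines <- c(paste(names(tab), collapse = "\t"),
               if (nrow(tab)) do.call(paste, c(lapply(tab, as.character), sep = "\t")))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    files[i] <- path
    nr[i] <- nrow(tab)
  }
  manifest <- data.frame(name = names(tables), file = files, n_rows = nr,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Export an expression matrix (and metadata) to the package TSV format
#'
#' Inverse of [read_expression_table()]; the round trip is lossless at 6
#' significant digits.
#'
#' @param x an `expression_matrix`.
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression_table <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(probe_id = rownames(x$values), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$values))) tab[[x$samples$sample_id[j]]] <- format_num(x$values[, j])
  con <- file(matrix_path, open = "wb")
  writeLines(c(paste(names(tab), collapse = "\t"),
               do.call(paste, c(lapply(tab, as.character), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(c(matrix_path, metadata_path))
}
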