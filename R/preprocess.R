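#' Global mean scaling normalization
#'
#' Multiplies every sample's intensities by `mean(reference) / mean(sample)`
#' so all arrays share the reference array's mean intensity. The reference
#' sample itself is unchanged.
#'
#' @param x an `expression_matrix`.
#' @param reference a sample id present in `x` (default: the first
#'   oligo-dT-primed normal sample in metadata order).
#' @return the normalized `expression_matrix`, with the per-sample scale
#'   factors attached as attribute `"scale_factors"`.
#' @export
global_mean_scale <- function(x, reference = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  s <- x$samples
  if (is.null(reference)) {
    i <- which(s$tissue == "normal" & s$priming == "oligo_dT")
    if (!length(i)) i <- 1L
    reference <- s$sample_id[i[1L]]
  }
  if (!reference %in% s$sample_id) {
    abort_input("reference sample '%s' not found", reference)
  }
  means <- colMeans(x$values, na.rm = TRUE)
  if (any(!is.finite(means)) || any(means == 0)) {
    abort_input("sample '%s' has zero or undefined mean intensity",
                names(means)[which(!is.finite(means) | means == 0)[1L]])
  }
  factors <- means[reference] / means
  out <- new_expression_matrix(sweep(x$values, 2L, factors, `*`), s)
  attr(out, "scale_factors") <- factors
  out
}

#' Detection call for normalized intensities
#'
#' A probe intensity is called expressed when it is at or above the
#' conservative detection threshold (inclusive; the default threshold is 100).
#'
#' @param intensity numeric vector of normalized intensities (>= 0).
#' @param params a `screen_params`.
#' @return logical vector (NA where intensity is missing).
#' @export
detection_call <- function(intensity, params = screen_params()) {
  if (any(intensity < 0, na.rm = TRUE)) abort_input("negative intensity in detection_call()")
  intensity >= params$detection_threshold
}

# Per-probe medians across patients for one (tissue, priming) group.
# Probes with any missing value in the required samples are returned as NA.
probe_medians <- function(x, tissue, priming) {
  cols <- group_cols(x, tissue, priming)
  if (anyNA(cols)) {
    abort_input("no %s / %s sample for patient(s): %s", tissue, priming,
                paste(sort(unique(x$samples$patient_id))[is.na(cols)], collapse = ", "))
  }
  row_medians(x$values[, cols, drop = FALSE])
}

#' Fraction of probes called expressed
#'
#' Summarizes detection over one probe class in one (tissue, priming) group.
#' By default each probe is scored on its median intensity across patients
#' (the "median expression level" rule); with `per_sample = TRUE` the
#' fraction is instead computed per sample and averaged, the style used for
#' per-tissue percentage tables. Truncated probes are excluded from the
#' evaluated set; probes with missing values in the required samples are
#' excluded and counted in the summary.
#'
#' @param x a normalized `expression_matrix`.
#' @param annotation a `probe_annotation`.
#' @param probe_class "sense" or "afas".
#' @param tissue "normal" or "cancer".
#' @param priming "oligo_dT" or "random".
#' @param params a `screen_params`.
#' @param per_sample compute per-sample fractions and average them.
#' @return one-row data.frame: `probe_class`, `tissue`, `priming`,
#'   `n_probes_evaluated`, `n_positive`, `percent_positive`, `n_missing`.
#' @export
positive_fraction <- function(x, annotation, probe_class, tissue, priming,
                              params = screen_params(), per_sample = FALSE) {
  probe_class <- match.arg(probe_class, c("sense", "afas"))
  tissue <- match.arg(tissue, TISSUES)
  priming <- match.arg(priming, PRIMINGS)
  keep <- annotation$probe_class == probe_class & !annotation$truncated
  ids <- intersect(annotation$probe_id[keep], rownames(x$values))
  if (!length(ids)) abort_input("no probes evaluated: class '%s' is empty after exclusions", probe_class)
  cols <- group_cols(x, tissue, priming)
  v <- x$values[ids, cols, drop = FALSE]
  miss <- rowSums(is.na(v)) > 0L
  v <- v[!miss, , drop = FALSE]
  if (!nrow(v)) abort_input("no probes evaluated: all '%s' probes have missing values", probe_class)
  if (per_sample) {
    fr <- colMeans(detection_call(v, params))
    n_pos <- mean(colSums(detection_call(v, params)))
    pct <- 100 * mean(fr)
  } else {
    med <- row_medians(v)
    n_pos <- sum(detection_call(med, params))
    pct <- 100 * n_pos / nrow(v)
  }
  data.frame(probe_class = probe_class, tissue = tissue, priming = priming,
             n_probes_evaluated = nrow(v), n_positive = n_pos,
             percent_positive = pct, n_missing = sum(miss),
             stringsAsFactors = FALSE)
}

#' Gene-level antisense detection call
#'
#' A gene is antisense-positive when at least one of its non-truncated AFAS
#' probes has a median expression level (across patients of the given tissue
#' and priming) at or above the detection threshold.
#'
#' @param gene_id gene identifier.
#' @inheritParams positive_fraction
#' @return logical scalar.
#' @export
gene_positive <- function(gene_id, x, annotation, tissue, priming,
                          params = screen_params()) {
  keep <- annotation$gene_id == gene_id & annotation$probe_class == "afas" &
    !annotation$truncated
  ids <- intersect(annotation$probe_id[keep], rownames(x$values))
  if (!length(ids)) abort_input("gene '%s' has no evaluable afas probes", gene_id)
  cols <- group_cols(x, tissue, priming)
  med <- row_medians(x$values[ids, cols, drop = FALSE])
  any(detection_call(med, params), na.rm = TRUE)
}

#' Detection summary over all probe classes and conditions
#'
#' Builds a summary table over both probe classes, tissues and primings,
#' plus gene-level antisense positivity per tissue (random priming), the
#' layout used for headline detection tables.
#'
#' @inheritParams positive_fraction
#' @return list with `probes` (8-row probe-level summary) and `genes`
#'   (gene-level positive fractions per tissue/priming).
#' @export
detection_summary <- function(x, annotation, params = screen_params(),
                              per_sample = FALSE) {
  grid <- expand.grid(probe_class = c("sense", "afas"), tissue = TISSUES,
                      priming = PRIMINGS, stringsAsFactors = FALSE)
  probes <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    positive_fraction(x, annotation, grid$probe_class[i], grid$tissue[i],
                      grid$priming[i], params, per_sample = per_sample)
  }))
  genes_with <- unique(annotation$gene_id[annotation$probe_class == "afas" &
                                            !annotation$truncated])
  gene_grid <- expand.grid(tissue = TISSUES, priming = PRIMINGS,
                           stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(seq_len(nrow(gene_grid)), function(i) {
    pos <- vapply(genes_with, gene_positive, logical(1), x = x,
                  annotation = annotation, tissue = gene_grid$tissue[i],
                  priming = gene_grid$priming[i], params = params)
    data.frame(tissue = gene_grid$tissue[i], priming = gene_grid$priming[i],
               n_genes = length(pos), n_positive = sum(pos),
               percent_positive = 100 * mean(pos), stringsAsFactors = FALSE)
  }))
  list(probes = probes, genes = genes)
}
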