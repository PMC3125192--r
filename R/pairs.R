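#' Build sense-antisense pair profiles
#'
#' Pairs every antisense (AFAS) probe with its gene's single sense probe and
#' extracts, for each patient, the four intensities the balance screens need:
#' sense and antisense in cancer and in normal tissue. Three priming modes
#' are supported: `"random"` (both members from random priming, the default
#' for antisense work), `"dt"` (both from oligo-dT), and `"mixed"` (sense
#' from oligo-dT, antisense from random priming, rationalized by the better
#' detection of polyadenylated mRNA under oligo-dT and of total RNA under
#' random priming).
#'
#' Pairs with any missing value in a required sample are dropped (a message
#' reports how many), so downstream screens always see complete profiles.
#'
#' @param x a normalized `expression_matrix`.
#' @param annotation a `probe_annotation`.
#' @param params a `screen_params`.
#' @param mode priming mode, one of "random", "dt", "mixed".
#' @return object of class `pair_profiles`: list with `pairs` (data.frame
#'   `gene_id`, `sense_probe_id`, `afas_probe_id`) and four
#'   pairs-by-patients matrices `sense_cancer`, `sense_normal`,
#'   `afas_cancer`, `afas_normal`, plus `patients` and `mode`.
#' @export
pair_profiles <- function(x, annotation, params = screen_params(),
                          mode = c("random", "dt", "mixed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expression_matrix"))
  sense_priming <- if (mode == "random") "random" else "oligo_dT"
  afas_priming <- if (mode == "dt") "oligo_dT" else "random"

  sense <- annotation[annotation$probe_class == "sense", , drop = FALSE]
  afas <- annotation[annotation$probe_class == "afas", , drop = FALSE]
  if (anyDuplicated(sense$gene_id)) {
    abort_input("gene(s) with more than one sense probe: %s",
                paste(unique(sense$gene_id[duplicated(sense$gene_id)]), collapse = ", "))
  }
  smap <- stats::setNames(sense$probe_id, sense$gene_id)
  keep <- afas$gene_id %in% names(smap) &
    afas$probe_id %in% rownames(x$values) &
    smap[afas$gene_id] %in% rownames(x$values)
  afas <- afas[keep, , drop = FALSE]
  if (!nrow(afas)) abort_input("no sense-afas pairs can be formed")
  pairs <- data.frame(gene_id = afas$gene_id,
                      sense_probe_id = unname(smap[afas$gene_id]),
                      afas_probe_id = afas$probe_id,
                      stringsAsFactors = FALSE)

  patients <- sort(unique(x$samples$patient_id))
  if (length(patients) != params$n_patients) {
    abort_input("matrix has %d patient(s) but params$n_patients = %d",
                length(patients), params$n_patients)
  }
  grab <- function(probe_ids, tissue, priming) {
    cols <- group_cols(x, tissue, priming, patients)
    if (anyNA(cols)) {
      abort_input("incomplete design: missing %s / %s sample", tissue, priming)
    }
    m <- x$values[probe_ids, cols, drop = FALSE]
    dimnames(m) <- list(pairs$afas_probe_id, paste0("P", patients))
    m
  }
  prof <- list(
    pairs = pairs,
    sense_cancer = grab(pairs$sense_probe_id, "cancer", sense_priming),
    sense_normal = grab(pairs$sense_probe_id, "normal", sense_priming),
    afas_cancer = grab(pairs$afas_probe_id, "cancer", afas_priming),
    afas_normal = grab(pairs$afas_probe_id, "normal", afas_priming),
    patients = patients,
    mode = mode
  )
  complete <- !(rowSums(is.na(prof$sense_cancer)) | rowSums(is.na(prof$sense_normal)) |
                  rowSums(is.na(prof$afas_cancer)) | rowSums(is.na(prof$afas_normal)))
  if (any(!complete)) {
    message(sprintf("pair_profiles: dropped %d pair(s) with missing values", sum(!complete)))
    prof$pairs <- prof$pairs[complete, , drop = FALSE]
    for (k in c("sense_cancer", "sense_normal", "afas_cancer", "afas_normal")) {
      prof[[k]] <- prof[[k]][complete, , drop = FALSE]
    }
  }
  structure(prof, class = "pair_profiles")
}

#' @export
print.pair_profiles <- function(x, ...) {
  cat(sprintf("pair_profiles: %d sense-afas pairs, %d patients, mode '%s'\n",
              nrow(x$pairs), length(x$patients), x$mode))
  invisible(x)
}
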