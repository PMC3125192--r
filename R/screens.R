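# All screening statistics: cancer/normal fold-change screens, the
# balance-reversal screens, antisense dominance, concerted change, priming
# correlation and direction concordance.

floored_ratio <- function(num, den, floor) {
  pmax(num, floor) / pmax(den, floor)
}

#' Cancer-to-normal ratio of a probe
#'
#' Ratio of the probe's median expression across patients in cancer tissue to
#' that in normal tissue, under one priming method. Both medians are floored
#' at `params$intensity_floor` so the ratio is always finite.
#'
#' @param probe_id probe identifier.
#' @param x a normalized `expression_matrix`.
#' @param params a `screen_params`.
#' @param priming "random" (default) or "oligo_dT".
#' @return numeric ratio.
#' @export
cancer_normal_ratio <- function(probe_id, x, params = screen_params(),
                                priming = "random") {
  if (!probe_id %in% rownames(x$values)) abort_input("probe '%s' not in matrix", probe_id)
  r <- cn_ratios(x, probe_id, params, priming)
  unname(r)
}

# Vectorized cancer/normal median ratios for many probes.
cn_ratios <- function(x, probe_ids, params, priming) {
  cc <- group_cols(x, "cancer", priming)
  cn <- group_cols(x, "normal", priming)
  med_c <- row_medians(x$values[probe_ids, cc, drop = FALSE])
  med_n <- row_medians(x$values[probe_ids, cn, drop = FALSE])
  stats::setNames(floored_ratio(med_c, med_n, params$intensity_floor), probe_ids)
}

#' Twofold cancer/normal screen
#'
#' Identifies probes whose cancer-to-normal median ratio is strictly more
#' than `fold_change` (up in cancer) or strictly less than `1/fold_change`
#' (down in cancer). The boundary is strict, matching the "more than twofold"
#' reading; probes with missing values in any required sample are skipped.
#'
#' @param x a normalized `expression_matrix`.
#' @param annotation a `probe_annotation`.
#' @param params a `screen_params`.
#' @param priming priming method of the data used (default "random").
#' @param probe_class which probes to screen (default "afas").
#' @return list with data.frames `up` and `down`, each with columns
#'   `probe_id`, `gene_id`, `ratio`.
#' @export
fold_change_screen <- function(x, annotation, params = screen_params(),
                               priming = "random", probe_class = "afas") {
  keep <- annotation$probe_class == probe_class
  ids <- intersect(annotation$probe_id[keep], rownames(x$values))
  if (!length(ids)) abort_input("no '%s' probes present in matrix", probe_class)
  cc <- group_cols(x, "cancer", priming)
  cn <- group_cols(x, "normal", priming)
  v <- x$values[ids, c(cc, cn), drop = FALSE]
  ok <- rowSums(is.na(v)) == 0L
  ids <- ids[ok]
  r <- cn_ratios(x, ids, params, priming)
  gmap <- stats::setNames(annotation$gene_id, annotation$probe_id)
  mk <- function(sel) data.frame(probe_id = ids[sel],
                                 gene_id = unname(gmap[ids[sel]]),
                                 ratio = unname(r[sel]),
                                 stringsAsFactors = FALSE)
  list(up = mk(r > params$fold_change), down = mk(r < 1 / params$fold_change))
}

# Inclusive margin comparison x >= (1+m) * y, with a relative epsilon so an
# exactly-m% difference passes despite (1+m) not being representable in
# binary floating point (e.g. 110 vs 1.1 * 100).
margin_ge <- function(x, y, m) {
  x >= (1 + m) * y * (1 - 1e-9)
}

# Per-patient support matrix for the four reversal conditions in the
# sense-up / antisense-down direction; the opposite direction swaps the
# sense and antisense arguments. m is the relative margin.
reversal_support <- function(S_c, S_n, A_c, A_n, m) {
  margin_ge(S_c, A_c, m) &   # sense dominant in cancer, >= m apart
    margin_ge(A_n, S_n, m) & # balance reversed in normal
    margin_ge(S_c, S_n, m) & # sense up >= m in cancer
    margin_ge(A_n, A_c, m)   # antisense down >= m in cancer
}

#' Balance-reversal screen
#'
#' Reports sense-antisense pairs whose expression balance flips between
#' tissues. For the sense-up/antisense-down direction a patient supports a
#' pair when all four hold (with margin `m = params$margin`):
#' sense_cancer >= (1+m) x afas_cancer; afas_normal >= (1+m) x sense_normal;
#' sense_cancer >= (1+m) x sense_normal; afas_normal >= (1+m) x afas_cancer.
#' A pair is reported when at least `min_support` patients support it. The
#' opposite direction swaps the roles of sense and antisense. A pair
#' reported in both directions (possible only in degenerate data) is
#' returned twice with `conflict = TRUE`.
#'
#' @param pp a [pair_profiles()] object.
#' @param params a `screen_params`.
#' @param direction "both" (default), "sense_up_afas_down" or
#'   "sense_down_afas_up".
#' @param margin optional override of `params$margin`.
#' @return data.frame with columns `afas_probe_id`, `gene_id`, `direction`,
#'   `support`, `margin`, `mode`, `conflict`.
#' @export
balance_reversal_screen <- function(pp, params = screen_params(),
                                    direction = c("both", "sense_up_afas_down",
                                                  "sense_down_afas_up"),
                                    margin = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(pp, "pair_profiles"))
  m <- margin %||% params$margin
  sup_up <- rowSums(reversal_support(pp$sense_cancer, pp$sense_normal,
                                     pp$afas_cancer, pp$afas_normal, m))
  sup_dn <- rowSums(reversal_support(pp$afas_cancer, pp$afas_normal,
                                     pp$sense_cancer, pp$sense_normal, m))
  hit_up <- sup_up >= params$min_support
  hit_dn <- sup_dn >= params$min_support
  conflict <- hit_up & hit_dn
  rows <- function(hit, sup, dir) {
    k <- sum(hit)
    data.frame(afas_probe_id = pp$pairs$afas_probe_id[hit],
               gene_id = pp$pairs$gene_id[hit],
               direction = rep(dir, k), support = as.integer(sup[hit]),
               margin = rep(m, k), mode = rep(pp$mode, k),
               conflict = conflict[hit], stringsAsFactors = FALSE)
  }
  out <- switch(direction,
    both = rbind(rows(hit_up, sup_up, "sense_up_afas_down"),
                 rows(hit_dn, sup_dn, "sense_down_afas_up")),
    sense_up_afas_down = rows(hit_up, sup_up, "sense_up_afas_down"),
    sense_down_afas_up = rows(hit_dn, sup_dn, "sense_down_afas_up")
  )
  rownames(out) <- NULL
  out
}

#' Change-only pair screen (cDNA-pair preset)
#'
#' The relaxed screen used for cDNA-identified sense-antisense pairs: a
#' patient supports a pair when the sense transcript changes by at least the
#' margin in one direction between tissues while the antisense transcript
#' shows a similar change in the opposite direction (no within-tissue
#' dominance reversal is required). Both directions are screened and the
#' union returned, deduplicated per pair and direction.
#'
#' @inheritParams balance_reversal_screen
#' @return data.frame as in [balance_reversal_screen()] (without `conflict`).
#' @export
cdna_pair_screen <- function(pp, params = screen_params(), margin = NULL) {
  stopifnot(inherits(pp, "pair_profiles"))
  m <- margin %||% params$margin
  sup_up <- rowSums(margin_ge(pp$sense_cancer, pp$sense_normal, m) &
                      margin_ge(pp$afas_normal, pp$afas_cancer, m))
  sup_dn <- rowSums(margin_ge(pp$sense_normal, pp$sense_cancer, m) &
                      margin_ge(pp$afas_cancer, pp$afas_normal, m))
  rows <- function(sup, dir) {
    hit <- sup >= params$min_support
    k <- sum(hit)
    data.frame(afas_probe_id = pp$pairs$afas_probe_id[hit],
               gene_id = pp$pairs$gene_id[hit],
               direction = rep(dir, k), support = as.integer(sup[hit]),
               margin = rep(m, k), mode = rep(pp$mode, k),
               stringsAsFactors = FALSE)
  }
  out <- rbind(rows(sup_up, "sense_up_afas_down"),
               rows(sup_dn, "sense_down_afas_up"))
  out <- out[!duplicated(paste(out$afas_probe_id, out$direction)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Antisense-dominant pairs
#'
#' Pairs whose antisense probe median expression (across patients) is at
#' least `dominance_fold` times the sense probe median in BOTH tissues
#' (inclusive comparison).
#'
#' @inheritParams balance_reversal_screen
#' @return data.frame with columns `afas_probe_id`, `gene_id`,
#'   `afas_sense_ratio_normal`, `afas_sense_ratio_cancer`.
#' @export
afas_dominant_pairs <- function(pp, params = screen_params()) {
  stopifnot(inherits(pp, "pair_profiles"))
  fl <- params$intensity_floor
  r_n <- floored_ratio(row_medians(pp$afas_normal), row_medians(pp$sense_normal), fl)
  r_c <- floored_ratio(row_medians(pp$afas_cancer), row_medians(pp$sense_cancer), fl)
  hit <- r_n >= params$dominance_fold & r_c >= params$dominance_fold
  out <- data.frame(afas_probe_id = pp$pairs$afas_probe_id[hit],
                    gene_id = pp$pairs$gene_id[hit],
                    afas_sense_ratio_normal = r_n[hit],
                    afas_sense_ratio_cancer = r_c[hit],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Concerted change count and its independence expectation
#'
#' Counts sense-antisense pairs whose two transcripts move in the same
#' direction between normal and cancer tissue (both median ratios above 1,
#' or both below 1). Pairs where either ratio is exactly 1 after flooring
#' are excluded as ties. The expected count under independence is
#' `N * (p_up_sense * p_up_afas + p_down_sense * p_down_afas)` using the
#' marginal direction frequencies of the non-tied pairs.
#'
#' @inheritParams balance_reversal_screen
#' @return list with `observed`, `expected`, `n_pairs` (non-tied), `n_ties`,
#'   and the marginal up-fractions `p_up_sense`, `p_up_afas`.
#' @export
concerted_change_count <- function(pp, params = screen_params()) {
  stopifnot(inherits(pp, "pair_profiles"))
  fl <- params$intensity_floor
  rs <- floored_ratio(row_medians(pp$sense_cancer), row_medians(pp$sense_normal), fl)
  ra <- floored_ratio(row_medians(pp$afas_cancer), row_medians(pp$afas_normal), fl)
  keep <- rs != 1 & ra != 1
  n_ties <- sum(!keep)
  rs <- rs[keep]; ra <- ra[keep]
  N <- length(rs)
  observed <- sum((rs > 1) == (ra > 1))
  p_up_s <- mean(rs > 1)
  p_up_a <- mean(ra > 1)
  expected <- N * (p_up_s * p_up_a + (1 - p_up_s) * (1 - p_up_a))
  list(observed = observed, expected = expected, n_pairs = N, n_ties = n_ties,
       p_up_sense = p_up_s, p_up_afas = p_up_a)
}

#' Per-probe correlation between priming methods
#'
#' For each probe of one class, the Pearson correlation between its oligo-dT
#' and random-priming intensities across all (patient, tissue) samples. A low
#' average correlation for antisense probes relative to sense probes
#' indicates that the two priming methods capture different transcript
#' populations from antisense regions. Probes with zero variance in either
#' vector (correlation undefined) are skipped and counted.
#'
#' @param x a normalized `expression_matrix`.
#' @param annotation a `probe_annotation`.
#' @param probe_class "sense" or "afas".
#' @return list with `correlations` (data.frame `probe_id`, `r`), `mean_r`,
#'   and `n_skipped`.
#' @export
priming_correlation <- function(x, annotation, probe_class = c("afas", "sense")) {
  probe_class <- match.arg(probe_class)
  s <- x$samples
  patients <- sort(unique(s$patient_id))
  key <- expand.grid(tissue = TISSUES, patient = patients, stringsAsFactors = FALSE)
  cols_dt <- mapply(function(p, t) sample_col(x, p, t, "oligo_dT"), key$patient, key$tissue)
  cols_rd <- mapply(function(p, t) sample_col(x, p, t, "random"), key$patient, key$tissue)
  ok <- !is.na(cols_dt) & !is.na(cols_rd)
  if (sum(ok) < 3L) abort_input("fewer than 3 paired (patient, tissue) samples across primings")
  ids <- intersect(annotation$probe_id[annotation$probe_class == probe_class],
                   rownames(x$values))
  vd <- x$values[ids, cols_dt[ok], drop = FALSE]
  vr <- x$values[ids, cols_rd[ok], drop = FALSE]
  sd_d <- apply(vd, 1L, stats::sd)
  sd_r <- apply(vr, 1L, stats::sd)
  usable <- is.finite(sd_d) & is.finite(sd_r) & sd_d > 0 & sd_r > 0
  r <- rep(NA_real_, length(ids))
  r[usable] <- vapply(which(usable), function(i) stats::cor(vd[i, ], vr[i, ]),
                      numeric(1))
  list(correlations = data.frame(probe_id = ids[usable], r = r[usable],
                                 stringsAsFactors = FALSE),
       mean_r = mean(r[usable]),
       n_skipped = sum(!usable))
}

#' Direction concordance against a reference gene list
#'
#' Compares observed cancer-vs-normal change directions with a reference
#' table of genes known to be up- or down-regulated, counting agreement per
#' reference direction. Reference genes absent from the observed table are
#' reported separately as unmatched.
#'
#' @param reference data.frame with columns `gene_id` and `direction`
#'   ("up"/"down").
#' @param observed data.frame with the same columns.
#' @return list with `n_agree_up`, `n_total_up`, `n_agree_down`,
#'   `n_total_down`, `unmatched` (character vector of gene ids).
#' @export
direction_concordance <- function(reference, observed) {
  for (nm in list(reference, observed)) {
    if (!all(c("gene_id", "direction") %in% names(nm))) {
      abort_input("direction_concordance(): tables need columns gene_id, direction")
    }
  }
  bad <- setdiff(unique(c(reference$direction, observed$direction)), c("up", "down"))
  if (length(bad)) abort_input("unknown direction value(s): %s", paste(bad, collapse = ", "))
  obs <- stats::setNames(observed$direction, observed$gene_id)
  matched <- reference$gene_id %in% names(obs)
  agree <- matched & obs[reference$gene_id] == reference$direction
  list(
    n_agree_up = sum(agree & reference$direction == "up"),
    n_total_up = sum(matched & reference$direction == "up"),
    n_agree_down = sum(agree & reference$direction == "down"),
    n_total_down = sum(matched & reference$direction == "down"),
    unmatched = reference$gene_id[!matched]
  )
}

#' Counting function for a named screen
#'
#' Returns a `function(x, annotation, params) -> count` wrapper around one of
#' the package's screens, as required by [shuffle_expected_count()].
#'
#' @param name one of "fold_change", "fold_change_up", "fold_change_down",
#'   "balance_reversal", "cdna_pairs", "afas_dominant", "concerted_change".
#' @param mode priming mode passed to [pair_profiles()] where relevant.
#' @param direction direction passed to [balance_reversal_screen()].
#' @param priming priming used by the fold-change screen.
#' @return a counting function.
#' @export
screen_count_fun <- function(name = c("fold_change", "fold_change_up",
                                      "fold_change_down", "balance_reversal",
                                      "cdna_pairs", "afas_dominant",
                                      "concerted_change"),
                             mode = "random", direction = "both",
                             priming = "random") {
  name <- match.arg(name)
  switch(name,
    fold_change = function(x, annotation, params) {
      fc <- fold_change_screen(x, annotation, params, priming = priming)
      nrow(fc$up) + nrow(fc$down)
    },
    fold_change_up = function(x, annotation, params) {
      nrow(fold_change_screen(x, annotation, params, priming = priming)$up)
    },
    fold_change_down = function(x, annotation, params) {
      nrow(fold_change_screen(x, annotation, params, priming = priming)$down)
    },
    balance_reversal = function(x, annotation, params) {
      nrow(balance_reversal_screen(pair_profiles(x, annotation, params, mode),
                                   params, direction))
    },
    cdna_pairs = function(x, annotation, params) {
      nrow(cdna_pair_screen(pair_profiles(x, annotation, params, mode), params))
    },
    afas_dominant = function(x, annotation, params) {
      nrow(afas_dominant_pairs(pair_profiles(x, annotation, params, mode), params))
    },
    concerted_change = function(x, annotation, params) {
      concerted_change_count(pair_profiles(x, annotation, params, mode), params)$observed
    }
  )
}
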