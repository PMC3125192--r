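# Brute-force reference implementations, deliberately written as plain loops
# over probe/sample ids so they stay independent of the package's vectorized
# code paths.

o_median <- function(v) {
  v <- sort(v)
  k <- length(v)
  if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
}

o_value <- function(x, probe, patient, tissue, priming) {
  x$values[probe, sprintf("P%d_%s_%s", patient, tissue, priming)]
}

o_group_median <- function(x, probe, tissue, priming) {
  pats <- sort(unique(x$samples$patient_id))
  o_median(sapply(pats, function(p) o_value(x, probe, p, tissue, priming)))
}

o_cn_ratio <- function(x, probe, p, priming) {
  max(o_group_median(x, probe, "cancer", priming), p$intensity_floor) /
    max(o_group_median(x, probe, "normal", priming), p$intensity_floor)
}

o_fold_change <- function(x, ann, p, priming = "random") {
  ids <- ann$probe_id[ann$probe_class == "afas"]
  up <- down <- character(0)
  for (id in ids) {
    r <- o_cn_ratio(x, id, p, priming)
    if (r > p$fold_change) up <- c(up, id)
    if (r < 1 / p$fold_change) down <- c(down, id)
  }
  list(up = up, down = down)
}

o_pairs <- function(ann) {
  afas <- ann[ann$probe_class == "afas", ]
  data.frame(gene_id = afas$gene_id, afas_probe_id = afas$probe_id,
             sense_probe_id = paste0(afas$gene_id, "-S"),
             stringsAsFactors = FALSE)
}

o_pair_vals <- function(x, pair, patient, mode) {
  sp <- if (mode == "random") "random" else "oligo_dT"
  ap <- if (mode == "dt") "oligo_dT" else "random"
  list(sc = o_value(x, pair$sense_probe_id, patient, "cancer", sp),
       sn = o_value(x, pair$sense_probe_id, patient, "normal", sp),
       ac = o_value(x, pair$afas_probe_id, patient, "cancer", ap),
       an = o_value(x, pair$afas_probe_id, patient, "normal", ap))
}

# balance-reversal: both directions; returns data.frame(afas_probe_id,
# direction, support)
o_balance <- function(x, ann, p, mode = "random", margin = p$margin) {
  prs <- o_pairs(ann)
  pats <- sort(unique(x$samples$patient_id))
  out <- NULL
  for (i in seq_len(nrow(prs))) {
    sup_up <- sup_dn <- 0
    for (pt in pats) {
      v <- o_pair_vals(x, prs[i, ], pt, mode)
      m1 <- 1 + margin
      if (v$sc >= m1 * v$ac && v$an >= m1 * v$sn &&
          v$sc >= m1 * v$sn && v$an >= m1 * v$ac) sup_up <- sup_up + 1
      if (v$ac >= m1 * v$sc && v$sn >= m1 * v$an &&
          v$ac >= m1 * v$an && v$sn >= m1 * v$sc) sup_dn <- sup_dn + 1
    }
    if (sup_up >= p$min_support) {
      out <- rbind(out, data.frame(afas_probe_id = prs$afas_probe_id[i],
                                   direction = "sense_up_afas_down",
                                   support = sup_up, stringsAsFactors = FALSE))
    }
    if (sup_dn >= p$min_support) {
      out <- rbind(out, data.frame(afas_probe_id = prs$afas_probe_id[i],
                                   direction = "sense_down_afas_up",
                                   support = sup_dn, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(afas_probe_id = character(0),
                               direction = character(0), support = integer(0))
  else out
}

o_cdna <- function(x, ann, p, mode = "random") {
  prs <- o_pairs(ann)
  pats <- sort(unique(x$samples$patient_id))
  out <- NULL
  for (i in seq_len(nrow(prs))) {
    sup_up <- sup_dn <- 0
    for (pt in pats) {
      v <- o_pair_vals(x, prs[i, ], pt, mode)
      m1 <- 1 + p$margin
      if (v$sc >= m1 * v$sn && v$an >= m1 * v$ac) sup_up <- sup_up + 1
      if (v$sn >= m1 * v$sc && v$ac >= m1 * v$an) sup_dn <- sup_dn + 1
    }
    if (sup_up >= p$min_support) {
      out <- rbind(out, data.frame(afas_probe_id = prs$afas_probe_id[i],
                                   direction = "sense_up_afas_down",
                                   stringsAsFactors = FALSE))
    }
    if (sup_dn >= p$min_support) {
      out <- rbind(out, data.frame(afas_probe_id = prs$afas_probe_id[i],
                                   direction = "sense_down_afas_up",
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(afas_probe_id = character(0),
                               direction = character(0))
  else out
}

o_dominant <- function(x, ann, p, mode = "random") {
  prs <- o_pairs(ann)
  sp <- if (mode == "random") "random" else "oligo_dT"
  ap <- if (mode == "dt") "oligo_dT" else "random"
  hits <- character(0)
  for (i in seq_len(nrow(prs))) {
    rn <- max(o_group_median(x, prs$afas_probe_id[i], "normal", ap), p$intensity_floor) /
      max(o_group_median(x, prs$sense_probe_id[i], "normal", sp), p$intensity_floor)
    rc <- max(o_group_median(x, prs$afas_probe_id[i], "cancer", ap), p$intensity_floor) /
      max(o_group_median(x, prs$sense_probe_id[i], "cancer", sp), p$intensity_floor)
    if (rn >= p$dominance_fold && rc >= p$dominance_fold) {
      hits <- c(hits, prs$afas_probe_id[i])
    }
  }
  hits
}

o_concerted <- function(x, ann, p, mode = "random") {
  prs <- o_pairs(ann)
  sp <- if (mode == "random") "random" else "oligo_dT"
  ap <- if (mode == "dt") "oligo_dT" else "random"
  rs <- sapply(seq_len(nrow(prs)), function(i)
    max(o_group_median(x, prs$sense_probe_id[i], "cancer", sp), p$intensity_floor) /
      max(o_group_median(x, prs$sense_probe_id[i], "normal", sp), p$intensity_floor))
  ra <- sapply(seq_len(nrow(prs)), function(i)
    max(o_group_median(x, prs$afas_probe_id[i], "cancer", ap), p$intensity_floor) /
      max(o_group_median(x, prs$afas_probe_id[i], "normal", ap), p$intensity_floor))
  keep <- rs != 1 & ra != 1
  rs <- rs[keep]; ra <- ra[keep]
  N <- length(rs)
  pus <- mean(rs > 1); pua <- mean(ra > 1)
  list(observed = sum((rs > 1) == (ra > 1)),
       expected = N * (pus * pua + (1 - pus) * (1 - pua)))
}

o_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# exon-walk re-derivation of the tiling: window starts, sense windows and
# truncated flags, walking the genome base by base through the exons.
o_tile <- function(gene, step, plen) {
  ex <- gene$exons
  # per-transcript-position genomic coordinate and exon index
  pos <- integer(0); exi <- integer(0)
  if (gene$strand == "+") {
    for (i in seq_len(nrow(ex))) {
      pos <- c(pos, seq(ex[i, 1], ex[i, 2] - 1))
      exi <- c(exi, rep(i, ex[i, 2] - ex[i, 1]))
    }
  } else {
    for (i in rev(seq_len(nrow(ex)))) {
      pos <- c(pos, seq(ex[i, 2] - 1, ex[i, 1]))
      exi <- c(exi, rep(i, ex[i, 2] - ex[i, 1]))
    }
  }
  L <- length(pos)
  if (L < plen) return(NULL)
  starts <- seq(0, L - plen, by = step)
  data.frame(
    window_start = starts,
    truncated = sapply(starts, function(w) {
      length(unique(exi[(w + 1):(w + plen)])) > 1
    }),
    sense_window = sapply(starts, function(w) {
      substr(gene$spliced_sequence, w + 1, w + plen)
    }),
    stringsAsFactors = FALSE
  )
}

o_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# exact two-sided Mann-Whitney by enumerating group assignments of the pooled
# VALUES; U computed by pair counting, not ranks.
o_mwu <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a); N <- length(pooled)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  dev <- abs(u_obs - m * (N - m) / 2)
  combos <- combn(N, m)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(U = u_obs, p = mean(abs(us - m * (N - m) / 2) >= dev - 1e-9))
}
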