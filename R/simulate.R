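#' Simulation configuration
#'
#' Describes the synthetic world the generator emulates: a paired design of
#' `n_patients` patients, each contributing a normal and a cancer sample
#' labelled by both oligo-dT and random priming; one sense probe per gene plus
#' a uniform 1-12 antisense (AFAS) probes per gene; log-normal intensities
#' with multiplicative per-measurement noise and a per-array scale factor; a
#' majority of expressed antisense transcripts lacking poly(A) tails (visible
#' under random priming, near background under oligo-dT except for a small
#' leak); and planted sense/antisense balance-reversal pairs at a configurable
#' fold and prevalence.
#'
#' @param ... named overrides. Fields and defaults:
#' \describe{
#'   \item{n_patients}{6 patients, paired normal/cancer.}
#'   \item{n_genes}{number of genes (default 501, the platform scale).}
#'   \item{afas_min, afas_max}{uniform range of AFAS probes per gene (1, 12).}
#'   \item{baseline_log_mean, baseline_log_sd}{log-normal parameters of
#'     expressed probe base intensities (log(200), 1.5).}
#'   \item{noise_cv}{coefficient of variation of the multiplicative
#'     measurement noise (0.2).}
#'   \item{afas_expressed_fraction}{fraction of AFAS probes whose antisense
#'     region is transcribed at all (0.4; the remainder sit at background).}
#'   \item{polyA_minus_fraction}{fraction of expressed antisense transcripts
#'     lacking a poly(A) tail (0.9).}
#'   \item{dt_leak}{fraction of a poly(A)- transcript's random-priming signal
#'     still visible under oligo-dT (0.05).}
#'   \item{planted_reversal_fraction}{target fraction of sense-antisense
#'     pairs carrying a planted balance reversal (0.05). Reversals are
#'     gene-level events: every AFAS probe of a planted gene is a planted
#'     pair, and genes are drawn until the target fraction is reached.}
#'   \item{planted_fold}{per-transcript fold applied to planted pairs (3).}
#'   \item{planted_direction_mix}{fraction of planted pairs in the
#'     sense-up/antisense-down direction (0.5).}
#'   \item{background_log_mean, background_log_sd}{log-normal parameters of
#'     unexpressed-probe background (log(30), 0.7).}
#'   \item{array_effect_sd}{sd (log scale) of the per-array scale factor that
#'     global mean scaling is meant to remove (0.1).}
#'   \item{truncated_fraction}{fraction of AFAS probes flagged truncated and
#'     hence excluded from detection-fraction summaries (0.1).}
#'   \item{seed}{RNG seed (1).}
#' }
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  defaults <- list(
    n_patients = 6L,
    n_genes = 501L,
    afas_min = 1L,
    afas_max = 12L,
    baseline_log_mean = log(200),
    baseline_log_sd = 1.5,
    noise_cv = 0.2,
    afas_expressed_fraction = 0.4,
    polyA_minus_fraction = 0.9,
    dt_leak = 0.05,
    planted_reversal_fraction = 0.05,
    planted_fold = 3,
    planted_direction_mix = 0.5,
    background_log_mean = log(30),
    background_log_sd = 0.7,
    array_effect_sd = 0.1,
    truncated_fraction = 0.1,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort_input("simulation_config(): unknown parameter(s): %s",
                paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  for (k in c("n_patients", "n_genes", "afas_min", "afas_max", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (cfg$n_genes < 1L) abort_input("n_genes must be >= 1")
  if (cfg$n_patients < 1L) abort_input("n_patients must be >= 1")
  if (cfg$afas_min < 1L || cfg$afas_max < cfg$afas_min) {
    abort_input("need 1 <= afas_min <= afas_max")
  }
  for (k in c("afas_expressed_fraction", "polyA_minus_fraction", "dt_leak",
              "planted_reversal_fraction", "planted_direction_mix",
              "truncated_fraction")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      abort_input("simulation parameter '%s' must be a fraction in [0, 1]", k)
    }
  }
  if (cfg$planted_fold <= 1) abort_input("planted_fold must be > 1")
  if (cfg$noise_cv < 0) abort_input("noise_cv must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' Parse a simulation config from key = value text
#'
#' @param config path or character vector of `key = value` lines.
#' @return a `simulation_config`.
#' @export
parse_sim_config <- function(config) {
  lines <- if (length(config) == 1L && !grepl("=", config, fixed = TRUE)) {
    if (!file.exists(config)) abort_input("config file not found: %s", config)
    readLines(config, warn = FALSE)
  } else {
    as.character(config)
  }
  kv <- parse_kv_lines(lines)
  num <- lapply(kv, function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) abort_input("config value is not numeric: '%s'", v)
    x
  })
  do.call(simulation_config, num)
}

#' Simulate a paired two-tissue, two-priming expression dataset
#'
#' Generates a complete design: for every patient, four samples (normal and
#' cancer tissue, each labelled by oligo-dT and by random priming), named
#' `P<patient>_<tissue>_<priming>`. Each probe has a latent per-tissue,
#' per-priming mean intensity; observed intensities multiply that mean by a
#' per-array scale factor and per-measurement log-normal noise with the
#' configured coefficient of variation.
#'
#' Expressed antisense transcripts that are poly(A)- have their oligo-dT mean
#' set to `dt_leak` times the random-priming mean. Planted reversal pairs
#' split `planted_fold` symmetrically across tissues: in the
#' sense-up/antisense-down direction the sense probe mean is `B/sqrt(f)` in
#' normal and `B*sqrt(f)` in cancer while the antisense probe mean is the
#' mirror image, so the pair satisfies all four balance-reversal conditions
#' in expectation at margin up to `sqrt(f)^2 - 1`.
#'
#' @param cfg a `simulation_config`.
#' @return list of class `afas_simulation` with elements `matrix`
#'   (an [expression_matrix()]), `annotation` (a [probe_annotation()]) and
#'   `truth` (class `ground_truth`: `probes` status table and `planted`
#'   pair table).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    nG <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(nG))
    n_afas <- if (cfg$afas_max > cfg$afas_min) {
      sample(cfg$afas_min:cfg$afas_max, nG, replace = TRUE)
    } else {
      rep(cfg$afas_min, nG)
    }

    ann <- data.frame(
      probe_id = c(paste0(gene_ids, "-S"),
                   sprintf("%s-%02d", rep(gene_ids, n_afas),
                           unlist(lapply(n_afas, seq_len)))),
      gene_id = c(gene_ids, rep(gene_ids, n_afas)),
      probe_class = c(rep("sense", nG), rep("afas", sum(n_afas))),
      afas_index = c(rep(NA_integer_, nG), unlist(lapply(n_afas, seq_len))),
      truncated = FALSE,
      stringsAsFactors = FALSE
    )
    is_afas <- ann$probe_class == "afas"
    nA <- sum(is_afas)
    ann$truncated[is_afas] <- stats::runif(nA) < cfg$truncated_fraction
    nP <- nrow(ann)

    # latent base level per probe
    base <- stats::rlnorm(nP, cfg$baseline_log_mean, cfg$baseline_log_sd)
    bg <- stats::rlnorm(nP, cfg$background_log_mean, cfg$background_log_sd)
    expressed <- rep(TRUE, nP)
    expressed[is_afas] <- stats::runif(nA) < cfg$afas_expressed_fraction
    polyA_minus <- rep(FALSE, nP)
    polyA_minus[is_afas & expressed] <-
      stats::runif(sum(is_afas & expressed)) < cfg$polyA_minus_fraction

    # Planted balance reversals are gene-level events: the planted antisense
    # transcript spans the gene, so every AFAS probe tiling a planted gene
    # reports the reversal and is labelled as a planted pair. Genes are drawn
    # in random order until the target fraction of pairs is covered.
    target <- round(cfg$planted_reversal_fraction * nA)
    planted <- data.frame(gene_id = character(0), sense_probe_id = character(0),
                          afas_probe_id = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
    planted_genes <- character(0)
    if (target > 0L) {
      for (g in sample(gene_ids)) {
        if (length(planted_genes) &&
            sum(n_afas[match(planted_genes, gene_ids)]) >= target) break
        planted_genes <- c(planted_genes, g)
      }
      dir_up <- stats::runif(length(planted_genes)) < cfg$planted_direction_mix
      gdir <- ifelse(dir_up, "sense_up_afas_down", "sense_down_afas_up")
      names(gdir) <- planted_genes
      sel <- is_afas & ann$gene_id %in% planted_genes
      planted <- data.frame(
        gene_id = ann$gene_id[sel],
        sense_probe_id = paste0(ann$gene_id[sel], "-S"),
        afas_probe_id = ann$probe_id[sel],
        direction = unname(gdir[ann$gene_id[sel]]),
        stringsAsFactors = FALSE
      )
      # planted antisense transcripts are forced expressed
      expressed[match(planted$afas_probe_id, ann$probe_id)] <- TRUE
    }

    # mean intensity per probe x tissue (random-priming scale)
    mu <- matrix(ifelse(expressed, base, bg), nrow = nP, ncol = 2L,
                 dimnames = list(ann$probe_id, TISSUES))
    if (nrow(planted)) {
      f <- sqrt(cfg$planted_fold)
      si <- match(planted$sense_probe_id, ann$probe_id)
      ai <- match(planted$afas_probe_id, ann$probe_id)
      up <- planted$direction == "sense_up_afas_down"
      B <- base[si]
      # sense up in cancer, antisense the mirror image (flip for other class)
      mu[si[up], "normal"]  <- B[up] / f;  mu[si[up], "cancer"]  <- B[up] * f
      mu[ai[up], "normal"]  <- B[up] * f;  mu[ai[up], "cancer"]  <- B[up] / f
      mu[si[!up], "normal"] <- B[!up] * f; mu[si[!up], "cancer"] <- B[!up] / f
      mu[ai[!up], "normal"] <- B[!up] / f; mu[ai[!up], "cancer"] <- B[!up] * f
    }

    # priming visibility: oligo-dT sees poly(A)- transcripts only via a leak;
    # unexpressed probes sit at background under both primings
    dt_factor <- ifelse(polyA_minus, cfg$dt_leak, 1)
    mu_dt <- mu * dt_factor
    mu_dt[!expressed, ] <- mu[!expressed, ]   # background is priming-neutral

    patients <- seq_len(cfg$n_patients)
    grid <- expand.grid(priming = PRIMINGS, tissue = TISSUES, patient = patients,
                        stringsAsFactors = FALSE)
    sample_ids <- sprintf("P%d_%s_%s", grid$patient, grid$tissue, grid$priming)
    nS <- nrow(grid)
    array_factor <- exp(stats::rnorm(nS, 0, cfg$array_effect_sd))
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))

    vals <- matrix(0, nrow = nP, ncol = nS,
                   dimnames = list(ann$probe_id, sample_ids))
    for (j in seq_len(nS)) {
      m <- if (grid$priming[j] == "oligo_dT") mu_dt[, grid$tissue[j]] else mu[, grid$tissue[j]]
      noise <- if (cfg$noise_cv > 0) stats::rlnorm(nP, 0, sdlog) else 1
      vals[, j] <- m * array_factor[j] * noise
    }

    meta <- data.frame(sample_id = sample_ids, patient_id = grid$patient,
                       tissue = grid$tissue, priming = grid$priming,
                       stringsAsFactors = FALSE)
    truth <- structure(list(
      probes = data.frame(probe_id = ann$probe_id, gene_id = ann$gene_id,
                          probe_class = ann$probe_class,
                          expressed = expressed, polyA_minus = polyA_minus,
                          stringsAsFactors = FALSE),
      planted = planted
    ), class = "ground_truth")
    structure(list(matrix = expression_matrix(vals, meta),
                   annotation = probe_annotation(ann),
                   truth = truth),
              class = "afas_simulation")
  })
}

#' @export
print.afas_simulation <- function(x, ...) {
  cat(sprintf("afas_simulation: %d probes (%d sense, %d afas), %d samples, %d planted pair(s)\n",
              nrow(x$matrix$values), sum(x$annotation$probe_class == "sense"),
              sum(x$annotation$probe_class == "afas"), ncol(x$matrix$values),
              nrow(x$truth$planted)))
  invisible(x)
}

#' Tidy table of planted reversal pairs
#'
#' @param gt the `truth` element of a simulation (class `ground_truth`).
#' @return data.frame with columns `gene_id`, `sense_probe_id`,
#'   `afas_probe_id`, `direction`, joinable to screen output on
#'   (`gene_id`, `afas_probe_id`).
#' @export
truth_table <- function(gt) {
  if (!inherits(gt, "ground_truth")) {
    abort_input("truth_table(): expected a 'ground_truth' object")
  }
  gt$planted
}

#' Confusion counts of a screen result against planted truth
#'
#' Joins a balance screen result to the planted-pair table on
#' `afas_probe_id` and returns recovery statistics. Directions must agree for
#' a planted pair to count as recovered.
#'
#' @param result a screen result table with columns `afas_probe_id`,
#'   `gene_id` and `direction` (e.g. from [balance_reversal_screen()]).
#' @param truth a `ground_truth` or the table from [truth_table()].
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @export
score_recovery <- function(result, truth) {
  tt <- if (inherits(truth, "ground_truth")) truth_table(truth) else truth
  need <- c("afas_probe_id", "direction")
  if (!all(need %in% names(result)) || !all(need %in% names(tt))) {
    abort_input("score_recovery(): join keys %s missing from result or truth",
                paste(need, collapse = ", "))
  }
  key_res <- paste(result$afas_probe_id, result$direction)
  key_tru <- paste(tt$afas_probe_id, tt$direction)
  tp <- sum(key_tru %in% key_res)
  fp <- sum(!key_res %in% key_tru)
  fn <- sum(!key_tru %in% key_res)
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (nrow(tt)) tp / nrow(tt) else NA_real_,
       fdr = if (nrow(result)) fp / nrow(result) else 0)
}
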