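# Permutation null for screen counts, chi-square goodness of fit, and the
# Mann-Whitney rank-sum test.

#' Random-shuffling expected count for a screen
#'
#' Estimates the null distribution of a screen's hit count by repeatedly
#' destroying the cancer/normal association and recounting. The default
#' scheme (`"tissue_labels"`) independently and uniformly re-assigns the
#' normal/cancer labels of each patient's sample pair per probe row: with
#' probability 1/2 a probe's normal and cancer values for a patient are
#' swapped (coherently across both primings), preserving each probe's value
#' multiset and the patient pairing while removing exactly the tissue signal
#' the screens measure. The alternative scheme (`"pair_partners"`) leaves
#' intensities untouched and instead permutes the gene assignment of the
#' antisense probes, breaking the sense-antisense pairing.
#'
#' @param x a normalized `expression_matrix`.
#' @param annotation a `probe_annotation`.
#' @param screen a counting function `function(x, annotation, params)` (see
#'   [screen_count_fun()]) or the name of a built-in screen.
#' @param params a `screen_params`.
#' @param n_shuffles number of shuffles (>= 100; default `params$n_shuffles`).
#' @param seed RNG seed (default `params$seed`); recorded in the result.
#' @param null shuffling scheme, "tissue_labels" or "pair_partners".
#' @return object of class `permutation_result`: list with `observed`,
#'   `null_mean`, `null_sd` (population SD), `n_shuffles`, `seed`,
#'   `empirical_p` (fraction of shuffles with count >= observed, with +1
#'   smoothing) and the vector of shuffle `counts`.
#' @export
shuffle_expected_count <- function(x, annotation, screen,
                                   params = screen_params(),
                                   n_shuffles = params$n_shuffles,
                                   seed = params$seed,
                                   null = c("tissue_labels", "pair_partners")) {
  null <- match.arg(null)
  if (is.character(screen)) screen <- screen_count_fun(screen)
  if (!is.function(screen)) abort_input("'screen' must be a function or a screen name")
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 100L) abort_input("n_shuffles must be >= 100")
  observed <- screen(x, annotation, params)
  if (length(observed) != 1L || !is.numeric(observed)) {
    abort_input("screen is incompatible: it must return a single count")
  }
  patients <- sort(unique(x$samples$patient_id))
  nP <- nrow(x$values)
  counts <- numeric(n_shuffles)

  if (null == "tissue_labels") {
    # column pairs to swap: one (normal, cancer) pair per patient per priming
    swaps <- list()
    for (p in patients) {
      for (pr in PRIMINGS) {
        cn <- sample_col(x, p, "normal", pr)
        cc <- sample_col(x, p, "cancer", pr)
        if (!is.na(cn) && !is.na(cc)) {
          swaps[[length(swaps) + 1L]] <- c(patient = match(p, patients), n = cn, c = cc)
        }
      }
    }
    with_seed(seed, {
      for (s in seq_len(n_shuffles)) {
        flip <- matrix(stats::runif(nP * length(patients)) < 0.5,
                       nrow = nP, ncol = length(patients))
        V <- x$values
        for (sw in swaps) {
          idx <- which(flip[, sw[["patient"]]])
          if (length(idx)) {
            tmp <- V[idx, sw[["n"]]]
            V[idx, sw[["n"]]] <- V[idx, sw[["c"]]]
            V[idx, sw[["c"]]] <- tmp
          }
        }
        counts[s] <- screen(new_expression_matrix(V, x$samples), annotation, params)
      }
    })
  } else {
    afas_rows <- which(annotation$probe_class == "afas")
    with_seed(seed, {
      for (s in seq_len(n_shuffles)) {
        ann2 <- annotation
        perm <- sample(afas_rows)
        ann2$gene_id[afas_rows] <- annotation$gene_id[perm]
        ann2$afas_index[afas_rows] <- stats::ave(
          seq_along(afas_rows), ann2$gene_id[afas_rows], FUN = seq_along)
        counts[s] <- screen(x, ann2, params)
      }
    })
  }

  null_mean <- mean(counts)
  null_sd <- sqrt(mean((counts - null_mean)^2))
  structure(list(
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    n_shuffles = n_shuffles,
    seed = as.integer(seed),
    empirical_p = (1 + sum(counts >= observed)) / (n_shuffles + 1),
    null = null,
    counts = counts
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation null (%s, %d shuffles, seed %d):\n", x$null,
              x$n_shuffles, x$seed))
  cat(sprintf("  observed %g vs expected %.2f +/- %.2f SD (empirical p = %.4g)\n",
              x$observed, x$null_mean, x$null_sd, x$empirical_p))
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' `statistic = sum((O - E)^2 / E)` against `k - 1` degrees of freedom.
#'
#' @param observed,expected numeric vectors of counts per category, same
#'   length `k >= 2`; all expected counts must be positive.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' chisq_goodness_of_fit(c(60, 40), c(50, 50))  # statistic 4, p ~ 0.0455
#' @export
chisq_goodness_of_fit <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    abort_input("observed and expected must have the same length")
  }
  if (length(observed) < 2L) abort_input("need at least 2 categories")
  if (any(expected <= 0)) abort_input("zero or negative expected cell")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# U statistic of sample a against sample b from pooled ranks (ties share
# mean ranks, so U can be half-integer).
mwu_statistic <- function(ranks_a, m) {
  sum(ranks_a) - m * (m + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. For small samples the exact p-value is
#' computed by enumerating all assignments of the pooled ranks to the two
#' groups (tie-safe, since tied values share mean ranks in every
#' enumeration); for larger samples the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact force exact enumeration (TRUE), force the normal
#'   approximation (FALSE), or decide automatically (NULL, exact while both
#'   samples have at most 20 values and the enumeration stays small).
#' @return list with `statistic` (U of `a` vs `b`), `p.value`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact two-sided p = 0.1
#' @export
rank_sum_test <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) abort_input("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- mwu_statistic(rk[seq_len(m)], m)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(list(statistic = U, p.value = 1, method = "degenerate"))
  }
  if (is.null(exact)) {
    exact <- m <= 20L && n <= 20L && choose(N, m) <= 50000
  }
  if (exact) {
    dev <- abs(U - m * n / 2)
    combos <- utils::combn(N, m)
    us <- apply(combos, 2L, function(ix) mwu_statistic(rk[ix], m))
    p <- mean(abs(us - m * n / 2) >= dev - 1e-9)
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  mu <- m * n / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("degenerate rank variance; p = 1")
    return(list(statistic = U, p.value = 1, method = "normal"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}
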