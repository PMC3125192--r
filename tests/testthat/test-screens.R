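# screens: ratios, fold-change, balance reversal, dominance, concerted change,
# priming correlation, direction concordance

test_that("cancer_normal_ratio applies the intensity floor", {
  ds <- make_dataset(n_genes = 1, afas_per_gene = 1, n_patients = 3,
                     fill = function(i, j) 100)
  v <- ds$x$values
  canc <- ds$x$samples$sample_id[ds$x$samples$tissue == "cancer" &
                                   ds$x$samples$priming == "random"]
  p <- screen_params()
  v["G01-01", canc] <- 200
  x <- expression_matrix(v, ds$x$samples)
  expect_equal(cancer_normal_ratio("G01-01", x, p), 2)
  v["G01-01", canc] <- 0
  x <- expression_matrix(v, ds$x$samples)
  expect_equal(cancer_normal_ratio("G01-01", x, p), 0.01)  # floor 1 / median 100
  expect_equal(cancer_normal_ratio("G01-S", x, p), 1)
  expect_error(cancer_normal_ratio("nope", x, p), "not in matrix")
})

test_that("fold-change screen is strict at the boundary and disjoint", {
  ds <- make_dataset(n_genes = 3, afas_per_gene = 1, n_patients = 6,
                     fill = function(i, j) 100)
  v <- ds$x$values
  canc <- ds$x$samples$sample_id[ds$x$samples$tissue == "cancer" &
                                   ds$x$samples$priming == "random"]
  v["G01-01", canc] <- 201    # ratio 2.01 -> up
  v["G02-01", canc] <- 200    # ratio 2.00 -> neither (strict)
  v["G03-01", canc] <- 49     # ratio 0.49 -> down
  x <- expression_matrix(v, ds$x$samples)
  fc <- fold_change_screen(x, ds$ann, screen_params())
  expect_equal(fc$up$probe_id, "G01-01")
  expect_equal(fc$down$probe_id, "G03-01")
  expect_length(intersect(fc$up$probe_id, fc$down$probe_id), 0)
})

test_that("fold-change lists are invariant under global rescaling and match the oracle", {
  p <- screen_params()
  for (seed in 1:6) {
    ds <- make_dataset(n_genes = 8, afas_per_gene = 3, n_patients = 6,
                       seed = seed)
    fc <- fold_change_screen(ds$x, ds$ann, p)
    orc <- o_fold_change(ds$x, ds$ann, p)
    expect_identical(fc$up$probe_id, orc$up)
    expect_identical(fc$down$probe_id, orc$down)
    x2 <- expression_matrix(ds$x$values * 7.3, ds$x$samples)
    fc2 <- fold_change_screen(x2, ds$ann, p)
    expect_identical(fc2$up$probe_id, fc$up$probe_id)
    expect_identical(fc2$down$probe_id, fc$down$probe_id)
  }
})

test_that("balance reversal: textbook pair, margin boundary, direction symmetry", {
  p <- screen_params()
  ds <- make_dataset(n_genes = 2, afas_per_gene = 1, n_patients = 6,
                     fill = function(i, j) 100)
  for (pt in 1:6) ds <- set_pair(ds, "G01", 1, pt, sc = 200, sn = 100,
                                 ac = 100, an = 200)
  pp <- pair_profiles(ds$x, ds$ann, p, "random")
  br <- balance_reversal_screen(pp, p)
  expect_equal(br$afas_probe_id, "G01-01")
  expect_equal(br$direction, "sense_up_afas_down")
  expect_equal(br$support, 6L)
  expect_false(any(br$conflict))

  # a patient at 9% sense change fails condition (3) for that patient
  ds2 <- set_pair(ds, "G01", 1, 1, sc = 109, sn = 100, ac = 50, an = 200)
  pp2 <- pair_profiles(ds2$x, ds2$ann, p, "random")
  br2 <- balance_reversal_screen(pp2, p)
  expect_equal(br2$support, 5L)

  # swapping sense and antisense values flips the direction
  ds3 <- make_dataset(n_genes = 2, afas_per_gene = 1, n_patients = 6,
                      fill = function(i, j) 100)
  for (pt in 1:6) ds3 <- set_pair(ds3, "G01", 1, pt, sc = 100, sn = 200,
                                  ac = 200, an = 100)
  br3 <- balance_reversal_screen(pair_profiles(ds3$x, ds3$ann, p, "random"), p)
  expect_equal(br3$direction, "sense_down_afas_up")
})

test_that("balance, cdna, dominance and concerted screens match brute-force enumeration", {
  p <- screen_params()
  for (seed in 1:8) {
    ds <- make_dataset(n_genes = 8, afas_per_gene = 3, n_patients = 6,
                       seed = 20 + seed)
    for (mode in c("random", "dt", "mixed")) {
      pp <- pair_profiles(ds$x, ds$ann, p, mode)
      br <- balance_reversal_screen(pp, p)
      orc <- o_balance(ds$x, ds$ann, p, mode)
      expect_identical(
        sort(paste(br$afas_probe_id, br$direction, br$support)),
        sort(paste(orc$afas_probe_id, orc$direction, orc$support)),
        info = paste(seed, mode))

      cd <- cdna_pair_screen(pp, p)
      ocd <- o_cdna(ds$x, ds$ann, p, mode)
      expect_identical(sort(paste(cd$afas_probe_id, cd$direction)),
                       sort(paste(ocd$afas_probe_id, ocd$direction)),
                       info = paste(seed, mode))

      dom <- afas_dominant_pairs(pp, p)
      expect_identical(sort(dom$afas_probe_id),
                       sort(o_dominant(ds$x, ds$ann, p, mode)),
                       info = paste(seed, mode))

      cc <- concerted_change_count(pp, p)
      occ <- o_concerted(ds$x, ds$ann, p, mode)
      expect_equal(cc$observed, occ$observed, info = paste(seed, mode))
      expect_equal(cc$expected, occ$expected, info = paste(seed, mode))
    }
  }
})

test_that("cdna preset reports change-only pairs the dominance screen rejects", {
  p <- screen_params()
  ds <- make_dataset(n_genes = 2, afas_per_gene = 1, n_patients = 6,
                     fill = function(i, j) 100)
  # sense up 20%, afas down 20%, but sense never dominant in cancer
  for (pt in 1:6) ds <- set_pair(ds, "G01", 1, pt, sc = 120, sn = 100,
                                 ac = 500, an = 600)
  pp <- pair_profiles(ds$x, ds$ann, p, "random")
  expect_equal(nrow(balance_reversal_screen(pp, p)), 0L)
  cd <- cdna_pair_screen(pp, p)
  expect_equal(cd$afas_probe_id, "G01-01")

  # boundary: exactly +10% / -10% in 3 patients is reported (inclusive)
  ds2 <- make_dataset(n_genes = 1, afas_per_gene = 1, n_patients = 6,
                      fill = function(i, j) 100)
  for (pt in 1:3) ds2 <- set_pair(ds2, "G01", 1, pt, sc = 110, sn = 100,
                                  ac = 100, an = 110)
  cd2 <- cdna_pair_screen(pair_profiles(ds2$x, ds2$ann, p, "random"), p)
  expect_equal(cd2$afas_probe_id, "G01-01")
  expect_equal(cd2$support, 3L)
})

test_that("dominance boundary is inclusive and requires both tissues", {
  p <- screen_params()
  ds <- make_dataset(n_genes = 2, afas_per_gene = 1, n_patients = 6,
                     fill = function(i, j) 100)
  v <- ds$x$values
  rd <- ds$x$samples$sample_id[ds$x$samples$priming == "random"]
  v["G01-01", rd] <- 300                       # exactly 3x in both tissues
  canc_rd <- ds$x$samples$sample_id[ds$x$samples$priming == "random" &
                                      ds$x$samples$tissue == "cancer"]
  v["G02-01", canc_rd] <- 300                  # dominant in cancer only
  x <- expression_matrix(v, ds$x$samples)
  dom <- afas_dominant_pairs(pair_profiles(x, ds$ann, p, "random"), p)
  expect_equal(dom$afas_probe_id, "G01-01")
})

test_that("concerted-change expectation follows the closed form", {
  # marginals (0.6, 0.7), N = 10 -> expected 10 * (0.42 + 0.12) = 5.4
  ds <- make_dataset(n_genes = 10, afas_per_gene = 1, n_patients = 6,
                     fill = function(i, j) 100)
  sense_up <- 1:6                              # p_up_sense = 0.6
  afas_up <- c(1:4, 7:9)                       # p_up_afas = 0.7
  for (g in 1:10) {
    gid <- sprintf("G%02d", g)
    for (pt in 1:6) {
      ds <- set_pair(ds, gid, 1, pt,
                     sc = if (g %in% sense_up) 150 else 50, sn = 100,
                     ac = if (g %in% afas_up) 150 else 50, an = 100)
    }
  }
  cc <- concerted_change_count(pair_profiles(ds$x, ds$ann, screen_params(),
                                             "random"), screen_params())
  expect_equal(cc$expected, 5.4)
  expect_equal(cc$observed, sum((1:10 %in% sense_up) == (1:10 %in% afas_up)))
  expect_equal(cc$n_pairs, 10L)
})

test_that("priming correlation: exact cases and formula agreement", {
  ds <- make_dataset(n_genes = 3, afas_per_gene = 1, n_patients = 6, seed = 31)
  v <- ds$x$values
  s <- ds$x$samples
  # make probe G01-01 identical across primings, G02-01 anti-correlated
  for (pt in 1:6) for (tis in c("normal", "cancer")) {
    a <- sprintf("P%d_%s_oligo_dT", pt, tis); b <- sprintf("P%d_%s_random", pt, tis)
    v["G01-01", a] <- v["G01-01", b]
    v["G02-01", b] <- 100 + 10 * pt + 5 * (tis == "cancer")
    v["G02-01", a] <- 1000 - v["G02-01", b]
  }
  x <- expression_matrix(v, s)
  pc <- priming_correlation(x, ds$ann, "afas")
  r <- setNames(pc$correlations$r, pc$correlations$probe_id)
  expect_equal(unname(r["G01-01"]), 1)
  expect_equal(unname(r["G02-01"]), -1)
  # third probe matches the closed-form Pearson to 1e-12
  key <- expand.grid(tissue = c("normal", "cancer"), patient = 1:6)
  va <- mapply(function(p_, t_) v["G03-01", sprintf("P%d_%s_oligo_dT", p_, t_)],
               key$patient, key$tissue)
  vb <- mapply(function(p_, t_) v["G03-01", sprintf("P%d_%s_random", p_, t_)],
               key$patient, key$tissue)
  expect_equal(unname(r["G03-01"]), o_pearson(va, vb), tolerance = 1e-12)

  # zero-variance probes are skipped, not propagated
  v["G01-01", s$priming == "oligo_dT"] <- 5
  pc2 <- priming_correlation(expression_matrix(v, s), ds$ann, "afas")
  expect_equal(pc2$n_skipped, 1L)
  expect_false("G01-01" %in% pc2$correlations$probe_id)
})

test_that("direction concordance counts agreement per reference direction", {
  ref <- data.frame(gene_id = c("A", "B", "C"), direction = c("up", "down", "up"),
                    stringsAsFactors = FALSE)
  obs <- data.frame(gene_id = c("A", "B"), direction = c("up", "up"),
                    stringsAsFactors = FALSE)
  dc <- direction_concordance(ref, obs)
  expect_equal(dc$n_agree_up, 1)
  expect_equal(dc$n_total_up, 1)
  expect_equal(dc$n_agree_down, 0)
  expect_equal(dc$n_total_down, 1)
  expect_equal(dc$unmatched, "C")

  # permuted observed labels agree with an exhaustive recount
  set.seed(4)
  genes <- sprintf("g%02d", 1:20)
  ref2 <- data.frame(gene_id = genes,
                     direction = sample(c("up", "down"), 20, replace = TRUE),
                     stringsAsFactors = FALSE)
  obs2 <- data.frame(gene_id = sample(genes),
                     direction = sample(c("up", "down"), 20, replace = TRUE),
                     stringsAsFactors = FALSE)
  dc2 <- direction_concordance(ref2, obs2)
  brute <- merge(ref2, obs2, by = "gene_id", suffixes = c("_r", "_o"))
  expect_equal(dc2$n_agree_up,
               sum(brute$direction_r == "up" & brute$direction_o == "up"))
  expect_equal(dc2$n_agree_down,
               sum(brute$direction_r == "down" & brute$direction_o == "down"))
})

test_that("margin monotonicity: higher margins give nested result sets", {
  p <- screen_params()
  for (seed in 1:4) {
    ds <- make_dataset(n_genes = 10, afas_per_gene = 3, n_patients = 6,
                       seed = 40 + seed)
    pp <- pair_profiles(ds$x, ds$ann, p, "random")
    keys <- lapply(c(0.10, 0.20, 0.30), function(m) {
      r <- balance_reversal_screen(pp, p, margin = m)
      paste(r$afas_probe_id, r$direction)
    })
    expect_true(all(keys[[2]] %in% keys[[1]]))
    expect_true(all(keys[[3]] %in% keys[[2]]))
  }
})

test_that("pairs with missing values are dropped with a message", {
  ds <- make_dataset(n_genes = 3, afas_per_gene = 2, n_patients = 6, seed = 50)
  v <- ds$x$values
  v["G01-01", "P3_cancer_random"] <- NA
  x <- expression_matrix(v, ds$x$samples)
  expect_message(pp <- pair_profiles(x, ds$ann, screen_params(), "random"),
                 "dropped 1 pair")
  expect_equal(nrow(pp$pairs), 5L)
  expect_false("G01-01" %in% pp$pairs$afas_probe_id)
})
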