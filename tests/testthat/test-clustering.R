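# clustering: ratio matrix, agglomeration, alignment, exports

test_that("ratio matrix is log2(sense/afas) with the floor engaged at zero", {
  p <- screen_params()
  ds <- make_dataset(n_genes = 3, afas_per_gene = 1, n_patients = 2,
                     fill = function(i, j) 100)
  for (pt in 1:2) {
    ds <- set_pair(ds, "G01", 1, pt, sc = 100, sn = 100, ac = 100, an = 100)
    ds <- set_pair(ds, "G02", 1, pt, sc = 300, sn = 300, ac = 100, an = 100)
    ds <- set_pair(ds, "G03", 1, pt, sc = 64, sn = 64, ac = 0, an = 0)
  }
  pp <- pair_profiles(ds$x, ds$ann,
                      screen_params(n_patients = 2, min_support = 2), "random")
  rm_ <- build_ratio_matrix(pp, p)
  expect_equal(colnames(rm_), c("normal_P1", "normal_P2", "cancer_P1", "cancer_P2"))
  expect_equal(unname(rm_["G01-01", ]), rep(0, 4))
  expect_equal(unname(rm_["G02-01", ]), rep(log2(3), 4))
  expect_equal(unname(rm_["G03-01", ]), rep(log2(64 / 1), 4))  # floor at 1
  expect_true(all(is.finite(rm_)))
})

test_that("average-linkage agglomeration reproduces hand-computed merges", {
  # pairwise euclidean distances d(1,2)=1, d(1,3)=4, d(2,3)=5:
  # merge (1,2) at height 1, then join 3 at (4+5)/2 = 4.5
  x <- rbind(r1 = c(0, 0), r2 = c(1, 0), r3 = c(-4, 0))
  hc <- hierarchical_cluster(x, distance = "euclidean", linkage = "average")
  expect_equal(hc$height, c(1, 4.5))
  expect_equal(hc$merge[1, ], c(-2L, -1L))
  expect_equal(sort(hc$merge[2, ]), c(-3L, 1L))

  # identical rows merge first at height 0
  y <- rbind(a = c(1, 2, 3), b = c(4, 1, 0), c = c(1, 2, 3))
  hcy <- hierarchical_cluster(y, distance = "euclidean")
  expect_equal(hcy$height[1], 0)
  expect_equal(sort(hcy$merge[1, ]), c(-3L, -1L))

  # leaf order is a permutation of all rows
  set.seed(2)
  z <- matrix(rnorm(40), nrow = 8,
              dimnames = list(paste0("p", 1:8), NULL))
  hcz <- hierarchical_cluster(z, distance = "correlation", linkage = "average")
  expect_setequal(hcz$order, 1:8)

  expect_error(hierarchical_cluster(z[1, , drop = FALSE]), "at least 2")
})

test_that("agglomeration agrees with stats::hclust for all linkages (no ties)", {
  set.seed(5)
  for (linkage in c("average", "complete", "single")) {
    x <- matrix(rnorm(15 * 6), nrow = 15)
    rownames(x) <- paste0("r", 1:15)
    hc <- hierarchical_cluster(x, distance = "euclidean", linkage = linkage)
    ref <- stats::hclust(dist(x), method = linkage)
    expect_equal(hc$height, ref$height, tolerance = 1e-12, info = linkage)
    # same partition at every merge height (labels of cutree clusters)
    mine <- as_hclust(hc)
    for (k in c(2, 5, 10)) {
      a <- cutree(mine, k); b <- cutree(ref, k)
      expect_equal(length(unique(paste(a, b))), k, info = paste(linkage, k))
    }
  }
})

test_that("constant rows under correlation distance are handled with a warning", {
  x <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 4, 6, 8))
  expect_warning(hc <- hierarchical_cluster(x, distance = "correlation"),
                 "constant row")
  expect_equal(hc$height[1], 0)  # b and c perfectly correlated
  expect_setequal(hc$order, 1:3)
})

test_that("align_to_order reorders rows losslessly", {
  set.seed(6)
  x <- matrix(rnorm(24), nrow = 6, dimnames = list(paste0("r", 1:6), NULL))
  ord <- c("r3", "r1", "r6", "r2", "r5", "r4")
  y <- align_to_order(x, ord)
  expect_equal(rownames(y), ord)
  expect_equal(align_to_order(y, rownames(x)), x)       # round trip
  expect_equal(align_to_order(x, rownames(x)), x)        # identity
  expect_equal(rownames(align_to_order(x, 6:1)), rev(rownames(x)))
  expect_error(align_to_order(x, c("r1", "nope")), "missing")
})

test_that("Newick export re-parses to the same merge heights", {
  skip_if_not_installed("ape")
  set.seed(9)
  x <- matrix(rnorm(10 * 5), nrow = 10, dimnames = list(paste0("p", 1:10), NULL))
  hc <- hierarchical_cluster(x, distance = "euclidean", linkage = "complete")
  tree <- ape::read.tree(text = to_newick(hc))
  expect_setequal(tree$tip.label, paste0("p", 1:10))
  depth <- ape::node.depth.edgelength(tree)          # root -> node distance
  node_heights <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  internal <- sort(node_heights[-seq_len(ape::Ntip(tree))])
  expect_equal(internal, sort(hc$height), tolerance = 1e-9)
})

test_that("heatmap export clips at threefold and writes tsv/newick/png", {
  p <- screen_params()
  ds <- make_dataset(n_genes = 4, afas_per_gene = 2, n_patients = 3, seed = 13)
  pp <- pair_profiles(ds$x, ds$ann, screen_params(n_patients = 3), "random")
  rm_ <- build_ratio_matrix(pp, p)
  rm_[1, 1] <- log2(9)         # beyond the threefold clip
  rm_[2, 1] <- log2(1 / 9)
  td <- withr::local_tempdir()
  hc <- hierarchical_cluster(rm_)
  files <- heatmap_export(rm_, hc, td)
  expect_true(all(file.exists(files)))
  tab <- utils::read.delim(files["tsv"], check.names = FALSE)
  got <- as.matrix(tab[, -1]); rownames(got) <- tab$pair_id
  expect_equal(max(got), log2(3), tolerance = 1e-5)
  expect_gte(min(got), -log2(3) - 1e-9)
  expect_equal(unname(got[rownames(rm_)[1], 1]), log2(3), tolerance = 1e-5)
  expect_equal(unname(got[rownames(rm_)[2], 1]), -log2(3), tolerance = 1e-5)
  # display copy only: source matrix untouched
  expect_equal(rm_[1, 1], log2(9))
  # rows follow the clustering leaf order
  expect_equal(tab$pair_id, hc$labels[hc$order])
})
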