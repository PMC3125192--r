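# Hierarchical clustering of sense/antisense log2 expression ratios and the
# saturating (threefold) heat-map / dendrogram exports.

#' Build the sense/antisense log-ratio matrix
#'
#' One row per sense-antisense pair, one column per (patient, tissue) sample
#' under the profile's priming mode; values are
#' `log2(max(sense, floor) / max(afas, floor))`, finite everywhere thanks to
#' the intensity floor. Columns are ordered all normals then all cancers,
#' patients ascending — the layout used for the ratio heat maps.
#'
#' @param pp a [pair_profiles()] object.
#' @param params a `screen_params` (uses `intensity_floor`).
#' @return numeric matrix of class `ratio_matrix` with rownames =
#'   `afas_probe_id` and attribute `mode`.
#' @export
build_ratio_matrix <- function(pp, params = screen_params()) {
  stopifnot(inherits(pp, "pair_profiles"))
  fl <- params$intensity_floor
  ratio <- function(S, A) log2(pmax(S, fl) / pmax(A, fl))
  m <- cbind(ratio(pp$sense_normal, pp$afas_normal),
             ratio(pp$sense_cancer, pp$afas_cancer))
  colnames(m) <- c(paste0("normal_P", pp$patients), paste0("cancer_P", pp$patients))
  rownames(m) <- pp$pairs$afas_probe_id
  structure(m, mode_priming = pp$mode, class = c("ratio_matrix", "matrix", "array"))
}

# Pairwise distance matrix. Correlation distance is 1 - Pearson across the
# row profiles; rows with zero variance have undefined correlation and get
# the maximum distance 1 (with a warning), so clustering stays total.
ratio_distance <- function(x, distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  if (distance == "euclidean") {
    return(as.matrix(stats::dist(x, method = "euclidean")))
  }
  sds <- apply(x, 1L, stats::sd)
  D <- 1 - suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    warning(sprintf("%d constant row(s) under correlation distance; distance set to 1",
                    sum(sds == 0)))
    bad <- which(sds == 0)
    D[bad, ] <- 1
    D[, bad] <- 1
  }
  diag(D) <- 0
  D
}

#' Deterministic agglomerative hierarchical clustering
#'
#' Bottom-up agglomeration with explicit, reproducible tie-breaking: at every
#' step the pair of clusters at minimal distance is merged, ties broken by
#' the smaller (then smaller second) original row index. Cluster distances
#' are updated by the chosen linkage (average, complete or single, via the
#' Lance-Williams recurrences). The merge table follows the `stats::hclust`
#' convention (negative entries are leaves, positive entries earlier merges).
#'
#' @param x a matrix (e.g. from [build_ratio_matrix()]) with at least 2 rows.
#' @param distance "correlation" (1 - Pearson, the default, clustering ratio
#'   patterns) or "euclidean".
#' @param linkage "average" (default), "complete" or "single".
#' @return object of class `afas_hclust`: list with `merge` ((n-1) x 2
#'   integer matrix), `height`, `order` (leaf order as row indices), `labels`,
#'   `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(x, distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) abort_input("hierarchical_cluster(): need at least 2 rows")
  labels <- rownames(x) %||% as.character(seq_len(n))
  D <- ratio_distance(x, distance)
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)          # hclust codes: -leaf or +merge step
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      dj <- D[i, js]
      k <- which.min(dj)          # first minimum -> smallest j on ties
      if (dj[k] < best_d - 1e-12) {  # strict -> earlier i wins ties
        best_d <- dj[k]
        best <- c(i, js[k])
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best_d
    # Lance-Williams update into slot i
    others <- setdiff(which(active), c(i, j))
    if (length(others)) {
      dnew <- switch(linkage,
        average = (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j]),
        complete = pmax(D[i, others], D[j, others]),
        single = pmin(D[i, others], D[j, others])
      )
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- step
  }
  # leaf order: depth-first walk of the merge tree
  walk <- function(k) {
    if (k < 0L) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = walk(n - 1L), labels = labels,
                 distance = distance, linkage = linkage),
            class = "afas_hclust")
}

#' @export
print.afas_hclust <- function(x, ...) {
  cat(sprintf("afas_hclust: %d leaves, %s distance, %s linkage\n",
              length(x$labels), x$distance, x$linkage))
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' @param x an `afas_hclust`.
#' @return an object of class `hclust` usable with `plot()`, `cutree()`, etc.
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "afas_hclust"))
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 dist.method = x$distance,
                 call = match.call()),
            class = "hclust")
}

#' Reorder a ratio matrix to a clustering leaf order
#'
#' Reorders the rows of `other` to the leaf order of a clustering computed on
#' a different matrix sharing the same row ids — used to align the oligo-dT
#' ratio heat map to the random-priming clustering. Values are untouched.
#'
#' @param other a matrix whose rownames cover the leaf labels.
#' @param order_ids leaf order: an `afas_hclust`, or a character vector of
#'   row ids, or an integer permutation.
#' @return `other` with rows reordered.
#' @export
align_to_order <- function(other, order_ids) {
  if (inherits(order_ids, "afas_hclust")) {
    order_ids <- order_ids$labels[order_ids$order]
  }
  if (is.numeric(order_ids)) order_ids <- rownames(other)[order_ids]
  missing_ids <- setdiff(order_ids, rownames(other))
  if (length(missing_ids)) {
    abort_input("row id(s) missing from matrix: %s",
                paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  other[order_ids, , drop = FALSE]
}

#' Newick serialization of a clustering
#'
#' Writes the merge tree as a Newick string with branch lengths equal to the
#' difference between the parent's and the child's merge height (leaves sit
#' at height 0), so every internal node's height equals its merge height and
#' the tree re-parses to the same heights.
#'
#' @param hc an `afas_hclust`.
#' @return a single Newick string, terminated with ";".
#' @export
to_newick <- function(hc) {
  stopifnot(inherits(hc, "afas_hclust"))
  node <- function(k, parent_h) {
    if (k < 0L) {
      lab <- gsub("[():,; \t]", "_", hc$labels[-k])
      return(sprintf("%s:%.9g", lab, parent_h))
    }
    h <- hc$height[k]
    sprintf("(%s,%s):%.9g", node(hc$merge[k, 1L], h), node(hc$merge[k, 2L], h),
            parent_h - h)
  }
  k <- length(hc$height)
  h <- hc$height[k]
  sprintf("(%s,%s);", node(hc$merge[k, 1L], h), node(hc$merge[k, 2L], h))
}

#' Export a clustered ratio heat map
#'
#' Writes (1) the row-reordered log2 ratio matrix clipped at plus/minus
#' log2(3) — the saturating threefold display convention: full green at
#' threefold-or-more sense excess, full red at threefold-or-more antisense
#' excess, black at balance — as a TSV; (2) the dendrogram as Newick; and
#' (3) a PNG heat map. Clipping affects the display copies only; screens
#' never consume clipped values.
#'
#' @param ratio a `ratio_matrix` (or any numeric matrix of log2 ratios).
#' @param hc optional `afas_hclust` used for row order and the Newick export;
#'   when `NULL` rows are clustered here with the defaults.
#' @param out_dir output directory.
#' @param basename file stem for the three outputs.
#' @return invisibly, a named character vector of the files written.
#' @export
heatmap_export <- function(ratio, hc = NULL, out_dir, basename = "ratio_heatmap") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(hc)) hc <- hierarchical_cluster(ratio)
  ordered <- align_to_order(as.matrix(ratio), hc)
  clip <- log2(3)
  clipped <- pmin(pmax(ordered, -clip), clip)

  tsv <- file.path(out_dir, paste0(basename, ".tsv"))
  tab <- data.frame(pair_id = rownames(clipped), clipped,
                    check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- write_results(stats::setNames(list(tab), basename), out_dir)
  tsv <- manifest$file[1L]

  nwk <- file.path(out_dir, paste0(basename, ".nwk"))
  writeLines(to_newick(hc), nwk, sep = "\n")

  png_path <- file.path(out_dir, paste0(basename, ".png"))
  pal <- grDevices::colorRampPalette(c("red", "black", "green"))(64)
  grDevices::png(png_path, width = 800, height = 200 + 12 * nrow(clipped))
  op <- graphics::par(mar = c(6, 8, 2, 1))
  graphics::image(x = seq_len(ncol(clipped)), y = seq_len(nrow(clipped)),
                  z = t(clipped[rev(seq_len(nrow(clipped))), , drop = FALSE]),
                  zlim = c(-clip, clip), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(clipped)), labels = colnames(clipped),
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(clipped)),
                 labels = rev(rownames(clipped)), las = 2, cex.axis = 0.6)
  graphics::par(op)
  grDevices::dev.off()

  invisible(c(tsv = tsv, newick = nwk, png = png_path))
}
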