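# probe_design: gene models, tiling, truncated flags

test_that("gene_model splices plus- and minus-strand genes correctly", {
  g <- gene_model("A", "chr1", "+", cbind(0, 8), genome_seq = "ACGTTTGC")
  expect_equal(g$spliced_sequence, "ACGTTTGC")

  # two-exon minus-strand gene: spliced = revcomp of concatenated exon text
  genome <- "AACCGGTTACGTACGT"
  ex <- cbind(c(1, 9), c(5, 14))
  gm <- gene_model("B", "chr1", "-", ex, genome_seq = genome)
  exon_text <- paste0(substr(genome, 2, 5), substr(genome, 10, 14))
  expect_equal(gm$spliced_sequence, o_revcomp(exon_text))

  expect_error(gene_model("C", "chr1", "+", cbind(0, 10), genome_seq = "ACGTACGT"),
               "beyond sequence")
  expect_error(gene_model("D", "chr1", "+", cbind(c(0, 3), c(5, 8)),
                          genome_seq = "ACGTACGTAC"), "overlapping")
  expect_error(gene_model("E", "chr1", "*", cbind(0, 4), genome_seq = "ACGT"),
               "strand")
})

test_that("load_gene_models reads GFF3 + FASTA, converting coordinates", {
  td <- withr::local_tempdir()
  genome <- paste(rep("ACGTTGCA", 20), collapse = "")  # 160 nt
  fa <- file.path(td, "g.fa")
  writeLines(c(">chr1 test sequence", genome), fa)
  gff <- file.path(td, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\texon\t11\t40\t.\t+\t.\tID=e1;Parent=tx1;gene_id=gplus",
    "chr1\ttest\texon\t61\t90\t.\t+\t.\tID=e2;Parent=tx1;gene_id=gplus",
    "chr1\ttest\texon\t21\t50\t.\t-\t.\tID=e3;Parent=tx2;gene_id=gminus"
  ), gff)
  models <- load_gene_models(gff, fa)
  expect_setequal(names(models), c("gplus", "gminus"))
  gp <- models$gplus
  expect_equal(gp$exons, cbind(start = c(10L, 60L), end = c(40L, 90L)))
  expect_equal(gp$spliced_sequence,
               paste0(substr(genome, 11, 40), substr(genome, 61, 90)))
  gm <- models$gminus
  expect_equal(gm$spliced_sequence, o_revcomp(substr(genome, 21, 50)))

  # strand mixing within a gene is rejected
  gff2 <- file.path(td, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\texon\t1\t10\t.\t+\t.\tgene_id=gx",
    "chr1\tt\texon\t21\t30\t.\t-\t.\tgene_id=gx"
  ), gff2)
  expect_error(load_gene_models(gff2, fa), "strand mixing")
})

test_that("tiling places probes every tile_step while a full probe fits", {
  p <- screen_params()  # step 500, length 60
  mk <- function(L) {
    gene_model("T", "chr1", "+", cbind(0, L),
               genome_seq = paste(rep("ACGT", ceiling(L / 4)), collapse = ""))
  }
  expect_equal(tile_afas_probes(mk(1500), p)$window_start, c(0L, 500L, 1000L))
  expect_equal(tile_afas_probes(mk(400), p)$window_start, 0L)
  short <- tile_afas_probes(mk(50), p)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "excluded"), "T")

  tt <- tile_afas_probes(mk(1500), p)
  expect_equal(tt$probe_id, c("T-01", "T-02", "T-03"))
  expect_true(all(nchar(tt$sequence) == 60L))
  # monotone non-decreasing probe count in L
  counts <- sapply(c(60, 400, 560, 1060, 1500, 2000), function(L)
    nrow(tile_afas_probes(mk(L), p)))
  expect_true(all(diff(counts) >= 0))
})

test_that("probe sequences are the reverse complement of the sense window", {
  p <- screen_params(tile_step = 20, probe_length = 12)
  g <- rand_gene(101)
  tab <- tile_afas_probes(g, p)
  for (i in seq_len(nrow(tab))) {
    win <- substr(g$spliced_sequence, tab$window_start[i] + 1,
                  tab$window_start[i] + 12)
    expect_identical(tab$sequence[i], o_revcomp(win))
  }
  # sense orientation flag flips the emitted strand only
  tab2 <- tile_afas_probes(g, p, sense_orientation = TRUE)
  expect_identical(tab2$sequence, sapply(tab$sequence, o_revcomp,
                                         USE.NAMES = FALSE))
})

test_that("truncated flag marks exactly the junction-spanning windows", {
  p <- screen_params(tile_step = 100, probe_length = 60)
  # single-exon gene: never truncated
  g1 <- gene_model("S", "chr1", "+", cbind(0, 300),
                   genome_seq = paste(rep("ACGT", 75), collapse = ""))
  expect_false(any(tile_afas_probes(g1, p)$truncated))

  # two exons of 300 + 300: window [270, 330) crosses the junction
  genome <- paste(rep("AAGT", 200), collapse = "")
  g2 <- gene_model("J", "chr1", "+", cbind(c(0, 350), c(300, 650)),
                   genome_seq = genome)
  expect_true(flag_truncated(list(window_start = 270, length = 60), g2))
  expect_false(flag_truncated(list(window_start = 0, length = 60), g2))
  blocks <- afasScreen:::transcript_blocks(g2, 270, 60)
  expect_equal(unname(blocks),
               cbind(c(270, 350), c(300, 380)), tolerance = 0)
  expect_error(afasScreen:::transcript_blocks(g2, 590, 60), "outside")
})

test_that("tiling agrees with the exon-walk oracle on random gene structures", {
  p <- screen_params(tile_step = 25, probe_length = 10)
  for (seed in 1:40) {
    g <- rand_gene(seed)
    tab <- tile_afas_probes(g, p)
    orc <- o_tile(g, 25, 10)
    if (is.null(orc)) {
      expect_equal(nrow(tab), 0L, info = paste("seed", seed))
      next
    }
    expect_equal(tab$window_start, orc$window_start, info = paste("seed", seed))
    expect_equal(tab$truncated, orc$truncated, info = paste("seed", seed))
    expect_identical(tab$sequence, sapply(orc$sense_window, o_revcomp,
                                          USE.NAMES = FALSE),
                     info = paste("seed", seed))
  }
})
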