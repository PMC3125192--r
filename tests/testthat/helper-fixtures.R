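# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# A small paired-design dataset with explicit values: n_genes genes, each with
# one sense probe and afas_per_gene antisense probes, n_patients patients,
# all four (tissue, priming) samples per patient. Values are filled by
# `fill(probe_index, sample_index)` or drawn log-normally.
make_dataset <- function(n_genes = 4, afas_per_gene = 2, n_patients = 6,
                         seed = 1, fill = NULL) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  ann <- data.frame(
    probe_id = c(paste0(genes, "-S"),
                 sprintf("%s-%02d", rep(genes, each = afas_per_gene),
                         rep(seq_len(afas_per_gene), n_genes))),
    gene_id = c(genes, rep(genes, each = afas_per_gene)),
    probe_class = c(rep("sense", n_genes), rep("afas", n_genes * afas_per_gene)),
    afas_index = c(rep(NA_integer_, n_genes),
                   rep(seq_len(afas_per_gene), n_genes)),
    truncated = FALSE,
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(priming = c("oligo_dT", "random"),
                      tissue = c("normal", "cancer"),
                      patient = seq_len(n_patients), stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("P%d_%s_%s", grid$patient, grid$tissue, grid$priming),
    patient_id = grid$patient, tissue = grid$tissue, priming = grid$priming,
    stringsAsFactors = FALSE
  )
  nP <- nrow(ann); nS <- nrow(meta)
  vals <- if (is.null(fill)) {
    withr_seed(seed, matrix(rlnorm(nP * nS, log(200), 1),
                            nrow = nP, ncol = nS))
  } else {
    matrix(mapply(fill, rep(seq_len(nP), nS), rep(seq_len(nS), each = nP)),
           nrow = nP)
  }
  dimnames(vals) <- list(ann$probe_id, meta$sample_id)
  list(x = afasScreen::expression_matrix(vals, meta),
       ann = afasScreen::probe_annotation(ann))
}

# set.seed without touching the caller's stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Overwrite the four values of one (gene, afas) pair for one patient, chosen
# priming mode "random". sc/sn = sense cancer/normal, ac/an = afas.
set_pair <- function(ds, gene, afas_idx, patient, sc, sn, ac, an,
                     priming = "random") {
  v <- ds$x$values
  sid <- paste0(gene, "-S")
  aid <- sprintf("%s-%02d", gene, afas_idx)
  v[sid, sprintf("P%d_cancer_%s", patient, priming)] <- sc
  v[sid, sprintf("P%d_normal_%s", patient, priming)] <- sn
  v[aid, sprintf("P%d_cancer_%s", patient, priming)] <- ac
  v[aid, sprintf("P%d_normal_%s", patient, priming)] <- an
  ds$x <- afasScreen::expression_matrix(v, ds$x$samples)
  ds
}

# Random single- or multi-exon gene structure on a random sequence.
rand_gene <- function(seed) {
  withr_seed(seed, {
    n_ex <- sample(1:5, 1)
    widths <- sample(5:120, n_ex, replace = TRUE)
    gaps <- sample(3:50, n_ex, replace = TRUE)
    starts <- cumsum(c(sample(0:20, 1), head(widths, -1) + gaps[-1]))
    ends <- starts + widths
    glen <- max(ends) + sample(0:30, 1)
    genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                    collapse = "")
    strand <- sample(c("+", "-"), 1)
    afasScreen::gene_model(sprintf("RG%05d", seed), "chr1", strand,
                           cbind(starts, ends), genome_seq = genome)
  })
}
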