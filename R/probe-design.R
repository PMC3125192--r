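#' Construct a gene model
#'
#' A gene model holds the exon structure of one gene plus its spliced sense
#' mRNA sequence (5' to 3'). Coordinates are 0-based half-open genomic
#' intervals, ascending in genomic order regardless of strand; for minus-
#' strand genes the spliced sequence is the reverse complement of the
#' concatenated genomic exon text.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome / source sequence name.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame of 0-based half-open
#'   `(start, end)` genomic intervals, non-overlapping.
#' @param spliced_sequence sense mRNA sequence; if `NULL`, derived from
#'   `genome_seq`.
#' @param genome_seq the chromosome sequence (character), used when
#'   `spliced_sequence` is not supplied.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       spliced_sequence = NULL, genome_seq = NULL) {
  if (!strand %in% c("+", "-")) abort_input("gene '%s': strand must be '+' or '-'", gene_id)
  ex <- as.matrix(exons)
  if (ncol(ex) != 2L) abort_input("gene '%s': exons must have two columns (start, end)", gene_id)
  storage.mode(ex) <- "integer"
  colnames(ex) <- c("start", "end")
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  if (any(ex[, 2L] <= ex[, 1L])) abort_input("gene '%s': empty or inverted exon", gene_id)
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
    abort_input("gene '%s': overlapping exons", gene_id)
  }
  if (is.null(spliced_sequence)) {
    if (is.null(genome_seq)) abort_input("gene '%s': need spliced_sequence or genome_seq", gene_id)
    genome_seq <- toupper(as.character(genome_seq))
    if (any(ex[, 2L] > nchar(genome_seq))) {
      abort_input("gene '%s': exon end %d beyond sequence length %d",
                  gene_id, max(ex[, 2L]), nchar(genome_seq))
    }
    parts <- substring(genome_seq, ex[, 1L] + 1L, ex[, 2L])
    spliced_sequence <- paste(parts, collapse = "")
    if (strand == "-") spliced_sequence <- revcomp(spliced_sequence)
  }
  spliced_sequence <- toupper(spliced_sequence)
  if (grepl("[^ACGTN]", spliced_sequence)) {
    abort_input("gene '%s': spliced sequence contains characters outside A,C,G,T,N", gene_id)
  }
  if (nchar(spliced_sequence) != sum(ex[, 2L] - ex[, 1L])) {
    abort_input("gene '%s': spliced sequence length %d != total exon length %d",
                gene_id, nchar(spliced_sequence), sum(ex[, 2L] - ex[, 1L]))
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = ex, spliced_sequence = spliced_sequence),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s), %d nt spliced\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nchar(x$spliced_sequence)))
  invisible(x)
}

revcomp <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  as.character(Biostrings::reverseComplement(x))
}

#' Load gene models from GFF3 and FASTA
#'
#' Exon features are grouped by gene identifier (the first available of the
#' `gene_id`, `Parent` or `ID` GFF3 attributes). Sequences are resolved from
#' the FASTA either per chromosome (record named like the GFF3 `seqid`) or
#' per gene (record named like the gene identifier, coordinates then relative
#' to that record). GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention; minus-strand genes get a
#' reverse-complemented spliced sequence.
#'
#' @param gff_path path to a GFF3 file with exon features.
#' @param fasta_path path to the genome or per-gene FASTA.
#' @return named list of `gene_model` objects.
#' @export
load_gene_models <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) abort_input("GFF3 file not found: %s", gff_path)
  if (!file.exists(fasta_path)) abort_input("FASTA file not found: %s", fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[tolower(as.character(df$type)) == "exon", , drop = FALSE]
  if (!nrow(df)) abort_input("no exon features in %s", gff_path)
  pick <- function(col) {
    if (!col %in% names(df)) return(rep(NA_character_, nrow(df)))
    v <- df[[col]]
    if (is.list(v)) v <- vapply(v, function(e) if (length(e)) as.character(e[[1L]]) else NA_character_, character(1))
    as.character(v)
  }
  gid <- pick("gene_id")
  alt <- pick("Parent")
  gid[is.na(gid)] <- alt[is.na(gid)]
  alt <- pick("ID")
  gid[is.na(gid)] <- alt[is.na(gid)]
  if (anyNA(gid)) abort_input("exon feature(s) without gene_id/Parent/ID attribute in %s", gff_path)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  models <- list()
  for (g in unique(gid)) {
    rows <- df[gid == g, , drop = FALSE]
    chrom <- unique(as.character(rows$seqnames))
    if (length(chrom) != 1L) abort_input("gene '%s': exons on multiple sequences", g)
    strand <- unique(as.character(rows$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      abort_input("gene '%s': strand mixing or missing strand", g)
    }
    src <- if (chrom %in% names(seqs)) chrom else if (g %in% names(seqs)) g else
      abort_input("gene '%s': neither sequence '%s' nor '%s' found in FASTA", g, chrom, g)
    models[[g]] <- gene_model(
      gene_id = g, chrom = chrom, strand = strand,
      exons = cbind(start = rows$start - 1L, end = rows$end),
      genome_seq = as.character(seqs[[src]])
    )
  }
  models
}

# Map a transcript-coordinate window [tstart, tstart + len) onto genomic
# blocks. Exons are walked in transcript order (descending genomic order for
# minus-strand genes); each returned block is a 0-based half-open genomic
# interval, listed in transcript order.
transcript_blocks <- function(gene, tstart, len) {
  L <- nchar(gene$spliced_sequence)
  if (tstart < 0L || len < 1L || tstart + len > L) {
    abort_input("gene '%s': window [%d, %d) outside transcript of length %d",
                gene$gene_id, tstart, tstart + len, L)
  }
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  widths <- ex[, 2L] - ex[, 1L]
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  blocks <- NULL
  for (i in seq_len(nrow(ex))) {
    a <- max(tstart, offsets[i])                # transcript coords within exon i
    b <- min(tstart + len, offsets[i] + widths[i])
    if (a >= b) next
    o1 <- a - offsets[i]
    o2 <- b - offsets[i]
    if (gene$strand == "+") {
      blk <- c(ex[i, 1L] + o1, ex[i, 1L] + o2)
    } else {
      blk <- c(ex[i, 2L] - o2, ex[i, 2L] - o1)
    }
    blocks <- rbind(blocks, blk)
  }
  dimnames(blocks) <- list(NULL, c("start", "end"))
  blocks
}

#' Tile antisense (AFAS) probes along a gene model
#'
#' Places one fixed-length probe at the start of every `tile_step` window of
#' the spliced transcript, as long as at least `probe_length` bases remain.
#' The emitted probe sequence is the reverse complement of the sense mRNA
#' window (the antisense-strand 60-mer, 5' to 3'); probes whose window
#' crosses an exon-exon junction are flagged `truncated`. Genes shorter than
#' one probe yield an empty table (the gene is excluded from design).
#'
#' @param gene a `gene_model`.
#' @param params a `screen_params` (uses `tile_step` and `probe_length`).
#' @param placement "start" (default) places the probe at the window start;
#'   "center" centers it within the window.
#' @param sense_orientation if TRUE, emit the sense-strand window sequence
#'   instead of its reverse complement. Display convention only; no
#'   downstream statistic depends on it.
#' @return data.frame with columns `probe_id`, `gene_id`, `window_start`,
#'   `length`, `sequence`, `truncated`, `n_blocks`, `has_ambiguity` and a
#'   list-column `genomic_blocks`. Zero rows when the gene is too short.
#' @export
tile_afas_probes <- function(gene, params = screen_params(),
                             placement = c("start", "center"),
                             sense_orientation = FALSE) {
  placement <- match.arg(placement)
  stopifnot(inherits(gene, "gene_model"))
  L <- nchar(gene$spliced_sequence)
  step <- params$tile_step
  plen <- params$probe_length
  empty <- data.frame(probe_id = character(0), gene_id = character(0),
                      window_start = integer(0), length = integer(0),
                      sequence = character(0), truncated = logical(0),
                      n_blocks = integer(0), has_ambiguity = logical(0),
                      stringsAsFactors = FALSE)
  empty$genomic_blocks <- list()
  if (L < plen) {
    attr(empty, "excluded") <- gene$gene_id
    return(empty)
  }
  wins <- seq.int(0L, L - plen, by = step)
  starts <- if (placement == "start") {
    wins
  } else {
    wlen <- pmin(step, L - wins)
    wins + pmax(0L, (wlen - plen) %/% 2L)
  }
  n <- length(starts)
  sense_win <- substring(gene$spliced_sequence, starts + 1L, starts + plen)
  seqs <- if (sense_orientation) sense_win else revcomp(sense_win)
  blocks <- lapply(starts, function(s) transcript_blocks(gene, s, plen))
  nb <- vapply(blocks, nrow, integer(1))
  out <- data.frame(
    probe_id = sprintf("%s-%02d", gene$gene_id, seq_len(n)),
    gene_id = gene$gene_id,
    window_start = as.integer(starts),
    length = as.integer(plen),
    sequence = seqs,
    truncated = nb > 1L,
    n_blocks = nb,
    has_ambiguity = grepl("N", sense_win, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  out$genomic_blocks <- blocks
  out
}

#' Recompute the truncated flag for one probe window
#'
#' TRUE iff the probe's transcript window maps to more than one genomic block
#' of the gene, i.e. crosses at least one exon-exon junction of the sense
#' transcript.
#'
#' @param probe a one-row probe table (from [tile_afas_probes()]) or a list
#'   with `window_start` and `length`.
#' @param gene the `gene_model` the probe was designed on.
#' @return logical scalar.
#' @export
flag_truncated <- function(probe, gene) {
  ws <- probe$window_start
  len <- probe$length %||% nchar(probe$sequence)
  nrow(transcript_blocks(gene, as.integer(ws), as.integer(len))) > 1L
}

#' Design antisense probes for a set of gene models
#'
#' Convenience wrapper over [tile_afas_probes()]: tiles every gene, collects
#' one probe table, and reports genes excluded because they are shorter than
#' one probe.
#'
#' @param genes list of `gene_model` objects (e.g. from [load_gene_models()]).
#' @param params a `screen_params`.
#' @inheritParams tile_afas_probes
#' @return list with `probes` (combined probe table) and `excluded`
#'   (data.frame `gene_id`, `reason`).
#' @export
design_probes <- function(genes, params = screen_params(),
                          placement = "start", sense_orientation = FALSE) {
  tabs <- lapply(genes, tile_afas_probes, params = params,
                 placement = placement, sense_orientation = sense_orientation)
  excluded <- vapply(tabs, function(t) !is.null(attr(t, "excluded")), logical(1))
  probes <- do.call(rbind, c(tabs[!excluded], list(make.row.names = FALSE)))
  if (is.null(probes)) probes <- tabs[[1L]]
  list(
    probes = probes,
    excluded = data.frame(
      gene_id = vapply(genes[excluded], `[[`, character(1), "gene_id"),
      reason = if (any(excluded)) "transcript shorter than probe_length" else character(0),
      stringsAsFactors = FALSE
    )
  )
}
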