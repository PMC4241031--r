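# Toy genome: random reference sequence plus simple multi-exon gene models.
# Gene CDS sequences are drawn from the 61 non-stop codons so every encoded
# protein is stop-free; each gene's sequence is generated under its own
# derived seed, so it is identical whether or not the full chromosome
# sequence is materialized.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0)),
  c("T", "C", "A", "G"),
  function(a, b) paste0(substr(a, 1, 1), b, substr(a, 2, 2))
))
SENSE_CODONS <- setdiff(sort(ALL_CODONS), STOP_CODONS)

revcomp <- function(s) {
  vapply(s, function(x) chartr("ACGTacgt", "TGCAtgca", intToUtf8(rev(utf8ToInt(x)))),
         "", USE.NAMES = FALSE)
}

random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

gene_cds_seq <- function(cfg_seed, gene_id, n_codons) {
  # per-gene derived seed so the sequence is reproducible on demand; the
  # caller's RNG stream is left untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(cfg_seed, paste0("cds:", gene_id)))
  paste(SENSE_CODONS[sample.int(length(SENSE_CODONS), n_codons, replace = TRUE)],
        collapse = "")
}

#' Build a toy genome: gene models and (optionally) reference sequence
#'
#' Places non-overlapping multi-exon gene models covering
#' `coding_fraction` of every chromosome, and optionally materializes a
#' random reference sequence with the gene CDS sequences embedded
#' (reverse-complemented for minus-strand genes). Sequence-free genomes are
#' cheap at any scale and sufficient for ancestry segmentation studies;
#' homopolymer filtering and consequence annotation need `sequence = TRUE`.
#'
#' @param cfg a [sim_config()].
#' @param sequence logical; materialize chromosome sequences and per-gene
#'   CDS sequences?
#' @return A list of class `enumap_genome` with elements `chroms`
#'   (data.frame chrom, length), `genes`, `exons` (1-based inclusive
#'   coordinates), `cds_seq` (named character or NULL), `reference` (named
#'   character or NULL) and `seed`.
#' @export
#' @examples
#' g <- make_genome(desk_config(chrom_length_bp = 2e6, n_chromosomes = 1))
#' head(g$genes)
make_genome <- function(cfg, sequence = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "genome"))
  L <- cfg$chrom_length_bp
  chroms <- data.frame(chrom = chrom_names(cfg), length = L)

  genes_l <- list(); exons_l <- list()
  for (chrom in chroms$chrom) {
    target_cds <- cfg$coding_fraction * L
    mean_cds <- 3 * 300
    n_genes <- max(1L, round(target_cds / mean_cds))
    n_codons <- sample(100:500, n_genes, replace = TRUE)
    n_exons <- sample(1:3, n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("%s_g%04d", chrom, seq_len(n_genes))

    # intron lengths per junction; spans must fit inside per-gene slots
    total_introns <- pmax(n_exons - 1L, 0L)
    intron_len <- lapply(total_introns, function(k) if (k) sample(60:500, k) else integer())
    span <- 3 * n_codons + vapply(intron_len, sum, 0)
    slot <- floor(L / n_genes)
    jitter_max <- pmax(slot - span - 2, 0)
    start <- (seq_len(n_genes) - 1L) * slot + 1L +
      floor(runif(n_genes) * (jitter_max + 1))

    # split codons across exons (codon-aligned junctions keep placement simple)
    n_ex_total <- sum(n_exons)
    e_gene <- character(n_ex_total); e_start <- numeric(n_ex_total)
    e_end <- numeric(n_ex_total); e_rank <- integer(n_ex_total)
    at <- 0L
    for (i in seq_len(n_genes)) {
      k <- n_exons[i]
      if (k > 1L) {
        cuts <- sort(sample(seq_len(n_codons[i] - 1L), k - 1L))
        codons_per <- diff(c(0L, cuts, n_codons[i]))
      } else codons_per <- n_codons[i]
      elen <- 3L * codons_per
      estart <- start[i] + c(0, cumsum(elen[-k] + intron_len[[i]]))
      idx <- at + seq_len(k)
      e_gene[idx] <- gene_id[i]
      e_start[idx] <- estart
      e_end[idx] <- estart + elen - 1
      e_rank[idx] <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
      at <- at + k
    }
    exons_l[[length(exons_l) + 1L]] <- data.frame(
      gene_id = e_gene, chrom = chrom, start = e_start, end = e_end, rank = e_rank
    )
    genes_l[[length(genes_l) + 1L]] <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = start, end = start + span - 1, n_codons = n_codons
    )
  }
  genes <- do.call(rbind, genes_l)
  exons <- do.call(rbind, exons_l)
  rownames(genes) <- rownames(exons) <- NULL

  genome <- structure(
    list(chroms = chroms, genes = genes, exons = exons,
         cds_seq = NULL, reference = NULL, seed = cfg$seed),
    class = "enumap_genome"
  )
  if (sequence) {
    genome$cds_seq <- setNames(
      vapply(seq_len(nrow(genes)),
             function(i) gene_cds_seq(cfg$seed, genes$gene_id[i], genes$n_codons[i]), ""),
      genes$gene_id
    )
    genome$reference <- build_reference(genome)
  }
  genome
}

# CDS chunks per exon in transcript order, as genomic-strand sequence
exon_genomic_seqs <- function(genome, gid) {
  g <- genome$genes[genome$genes$gene_id == gid, ]
  ex <- genome$exons[genome$exons$gene_id == gid, ]
  ex <- ex[order(ex$rank), ]
  cds <- genome$cds_seq[[gid]] %||% gene_cds_seq(genome$seed, gid, g$n_codons)
  elen <- ex$end - ex$start + 1L
  stop_at <- cumsum(elen)
  chunk <- substring(cds, stop_at - elen + 1L, stop_at)
  if (g$strand == "-") chunk <- revcomp(chunk)
  ex$seq <- chunk
  ex[order(ex$start), ]
}

build_reference <- function(genome) {
  ref <- character(0)
  for (i in seq_len(nrow(genome$chroms))) {
    chrom <- genome$chroms$chrom[i]
    L <- genome$chroms$length[i]
    set.seed(derive_seed(genome$seed, paste0("ref:", chrom)))
    bg <- random_dna(L)
    ex <- do.call(rbind, lapply(
      genome$genes$gene_id[genome$genes$chrom == chrom],
      function(gid) exon_genomic_seqs(genome, gid)
    ))
    if (!is.null(ex) && nrow(ex)) {
      ex <- ex[order(ex$start), ]
      pieces <- character(2L * nrow(ex) + 1L)
      prev <- 0L
      for (j in seq_len(nrow(ex))) {
        pieces[2L * j - 1L] <- substring(bg, prev + 1L, ex$start[j] - 1L)
        pieces[2L * j] <- ex$seq[j]
        prev <- ex$end[j]
      }
      pieces[2L * nrow(ex) + 1L] <- substring(bg, prev + 1L, L)
      bg <- paste(pieces, collapse = "")
    }
    ref[[chrom]] <- bg
  }
  ref
}

ref_base <- function(reference, chrom, pos) {
  substring(reference[chrom], pos, pos)
}

#' Write the toy genome as FASTA and GFF3
#'
#' @param genome an `enumap_genome` built with `sequence = TRUE` (FASTA) or
#'   without (GFF3 and genome table only).
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written (`fasta`, `gff3`, `genome_tsv`).
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gff3 = file.path(dir, "genes.gff3"),
                genome_tsv = file.path(dir, "genome.tsv"))
  write.table(genome$chroms, paths$genome_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(gff3_lines(genome), paths$gff3)
  if (!is.null(genome$reference)) {
    paths$fasta <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$reference), paths$fasta
    )
  }
  invisible(paths)
}

gff3_lines <- function(genome) {
  g <- genome$genes; ex <- genome$exons
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genome$chroms)))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              genome$chroms$chrom[i],
                              as.integer(genome$chroms$length[i])))
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    e <- ex[ex$gene_id == gid, ]
    e <- e[order(e$rank), ]
    elen <- e$end - e$start + 1L
    phase <- c(0L, cumsum(elen)[-length(elen)]) %% 3L
    phase <- (3L - phase) %% 3L
    out <- c(out,
      sprintf("%s\tenumap\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom[i],
              as.integer(g$start[i]), as.integer(g$end[i]), g$strand[i], gid),
      sprintf("%s\tenumap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", g$chrom[i],
              as.integer(g$start[i]), as.integer(g$end[i]), g$strand[i], gid, gid),
      sprintf("%s\tenumap\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s.t1;gene_id=%s",
              g$chrom[i], as.integer(e$start), as.integer(e$end), g$strand[i],
              phase, gid, gid, gid)
    )
  }
  c(lines, out)
}
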