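# Observation layer of the simulator: turn the truth bundle into the files
# a real experiment would hand the pipeline (VCF of the sequenced proband,
# marker genotypes, phenotypes, known-variant blacklist).

rpois_trunc2 <- function(n, lambda) {
  # Poisson truncated to >= 2: a called variant implies at least two reads
  qpois(runif(n, ppois(1, lambda), 1), lambda)
}

# observed proband variants with truth linkage, before any file I/O
observe_proband <- function(truth) {
  cfg <- truth$config
  proband <- truth$mice[[1L]]
  mut <- truth$mutations
  set.seed(derive_seed(cfg$seed, "emit"))

  carried <- integer(nrow(mut))
  for (chrom in unique(mut$chrom)) {
    i <- which(mut$chrom == chrom)
    h <- proband$diplotype[[chrom]]
    want <- ifelse(mut$origin[i] == "STRAIN", "C", "F")
    carried[i] <- (imos_at(h[[1L]], mut$pos[i]) == want) +
      (imos_at(h[[2L]], mut$pos[i]) == want)
  }
  v <- mut[carried > 0L, , drop = FALSE]
  genotype <- ifelse(carried[carried > 0L] == 2L, "hom_alt", "het")

  n <- nrow(v)
  keep <- runif(n) >= cfg$dropout_rate
  miscall <- genotype == "het" & runif(n) < cfg$het_miscall_rate
  genotype[miscall] <- "hom_alt"
  v <- v[keep, , drop = FALSE]; genotype <- genotype[keep]

  n <- nrow(v)
  depth <- rpois_trunc2(n, cfg$mean_depth)
  alt_depth <- ifelse(genotype == "hom_alt", depth,
                      pmin(pmax(rbinom(n, depth, 0.5), 1L), depth - 1L))
  alt_fwd <- rbinom(n, alt_depth, 0.5)
  v$genotype <- genotype
  v$depth <- depth; v$alt_depth <- alt_depth
  v$alt_fwd <- alt_fwd; v$alt_rev <- alt_depth - alt_fwd
  v$qual <- round(runif(n, 40, 99))

  fp <- place_catalog(cfg, cfg$fp_rate, truth$genome$reference)
  if (nrow(fp)) {
    m <- nrow(fp)
    fp$origin <- "FALSE_POSITIVE"; fp$is_causal <- FALSE
    fp$genotype <- "het"
    fp$depth <- rpois_trunc2(m, cfg$mean_depth)
    fp$alt_depth <- pmin(pmax(rbinom(m, fp$depth, 0.3), 1L), fp$depth)
    fp$alt_fwd <- rbinom(m, fp$alt_depth, 0.85)  # artifacts are strand-skewed
    fp$alt_rev <- fp$alt_depth - fp$alt_fwd
    fp$qual <- round(runif(m, 20, 60))
    v <- rbind(v, fp[, names(v)])
  }
  v <- v[order(match(v$chrom, chrom_names(cfg)), v$pos), ]
  rownames(v) <- NULL
  v
}

#' Emit the proband's observed variant calls as a VCF
#'
#' Applies the configured genotyping noise (dropout, het-to-hom miscalls,
#' truncated-Poisson depths, binomial strand counts, false-positive calls)
#' to the truth bundle and writes a VCF v4.2 with `INFO DP;SB=fwd,rev` and
#' `FORMAT GT:AD:DP` for the single proband sample.
#'
#' @param truth an `enumap_truth` from [simulate_pedigree()].
#' @param path output VCF path, or NULL to skip writing.
#' @return Invisibly, the observed variant data.frame (chrom, pos, ref,
#'   alt, genotype, depth, alt_depth, alt_fwd, alt_rev, qual) with truth
#'   columns `origin` and `is_causal`.
#' @export
emit_observed_vcf <- function(truth, path = NULL) {
  v <- observe_proband(truth)
  if (!is.null(path)) {
    cfg <- truth$config
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=enumap-simulator",
      paste0("##enumap_seed=", cfg$seed),
      sprintf("##contig=<ID=%s,length=%d>", chrom_names(cfg),
              as.integer(cfg$chrom_length_bp)),
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
      "##INFO=<ID=SB,Number=.,Type=Integer,Description=\"Per-strand alt read counts: fwd,rev\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "proband"), collapse = "\t")
    )
    rows <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%d\tPASS\tDP=%d;SB=%d,%d\tGT:AD:DP\t%s:%d,%d:%d",
      v$chrom, v$pos, v$ref, v$alt, v$qual, v$depth, v$alt_fwd, v$alt_rev,
      ifelse(v$genotype == "hom_alt", "1/1", "0/1"),
      v$depth - v$alt_depth, v$alt_depth, v$depth
    )
    writeLines(c(hdr, rows), path)
  }
  invisible(v)
}

#' Emit the marker genotype and phenotype tables
#'
#' Markers are placed at evenly spaced positions on every chromosome (plus,
#' by default, one marker exactly at the causal position, mimicking a fine
#' mapping panel). Genotypes are a direct readout of each mouse's ancestry:
#' B is the founder/B6 allele, C the CBA allele, so a mouse that is CBA/CBA
#' at a marker types CC, mixed ancestry types BC, founder/founder types BB.
#'
#' @param truth an `enumap_truth`.
#' @param n_markers_per_chrom evenly spaced markers per chromosome
#'   (defaults to the simulation config).
#' @param positions optional data.frame (chrom, pos) of explicit marker
#'   positions overriding the even spacing.
#' @param include_causal add a marker at the causal position?
#' @param dir if non-NULL, write `markers.tsv` (mouse_id, marker_id, chrom,
#'   pos, genotype) and `phenotypes.tsv` (mouse_id, affected) there.
#' @return Invisibly, `list(markers, phenotypes)` data.frames.
#' @export
emit_marker_table <- function(truth, n_markers_per_chrom = NULL,
                              positions = NULL, include_causal = TRUE,
                              dir = NULL) {
  cfg <- truth$config
  m <- n_markers_per_chrom %||% cfg$n_markers_per_chrom
  if (is.null(positions)) {
    if (m < 1L && !include_causal) stop("zero markers requested")
    L <- cfg$chrom_length_bp
    positions <- data.frame(
      chrom = rep(chrom_names(cfg), each = m),
      pos = as.integer(rep(round(seq_len(m) * L / (m + 1)),
                           times = cfg$n_chromosomes))
    )
  }
  if (include_causal &&
      !any(positions$chrom == truth$causal$chrom & positions$pos == truth$causal$pos))
    positions <- rbind(positions, data.frame(chrom = truth$causal$chrom,
                                             pos = truth$causal$pos))
  if (nrow(positions) == 0L) stop("zero markers requested")
  positions <- positions[order(match(positions$chrom, chrom_names(cfg)),
                               positions$pos), , drop = FALSE]
  positions$marker_id <- sprintf("%s_%09d", positions$chrom, positions$pos)

  rows <- lapply(truth$mice, function(mouse) {
    g <- character(nrow(positions))
    for (chrom in unique(positions$chrom)) {
      i <- which(positions$chrom == chrom)
      h <- mouse$diplotype[[chrom]]
      n_c <- (imos_at(h[[1L]], positions$pos[i]) == "C") +
        (imos_at(h[[2L]], positions$pos[i]) == "C")
      g[i] <- c("BB", "BC", "CC")[n_c + 1L]
    }
    data.frame(mouse_id = mouse$mouse_id, marker_id = positions$marker_id,
               chrom = positions$chrom, pos = positions$pos, genotype = g)
  })
  markers <- do.call(rbind, rows); rownames(markers) <- NULL
  phenotypes <- data.frame(
    mouse_id = vapply(truth$mice, `[[`, "", "mouse_id"),
    affected = vapply(truth$mice, `[[`, TRUE, "affected")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(markers, file.path(dir, "markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(markers = markers, phenotypes = phenotypes))
}

# known-variant blacklist: the previously catalogued fraction of strain
# divergence (what dbSNP-style subtraction removes in a real analysis)
emit_blacklist <- function(truth, path = NULL) {
  cfg <- truth$config
  set.seed(derive_seed(cfg$seed, "blacklist"))
  strain <- truth$mutations[truth$mutations$origin == "STRAIN", ]
  take <- runif(nrow(strain)) < cfg$known_fraction
  bl <- strain[take, c("chrom", "pos", "ref", "alt")]
  rownames(bl) <- NULL
  if (!is.null(path))
    write.table(bl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bl)
}

#' Write every simulation artifact to a directory
#'
#' Writes the observed VCF, truth table, proband ancestry BED, marker and
#' phenotype TSVs, known-variant blacklist, genome layout TSV, toy gene
#' models (GFF3) and, when the genome carries sequence, the reference FASTA.
#'
#' @param truth an `enumap_truth`.
#' @param dir output directory.
#' @return Invisibly, a named list of paths.
#' @export
write_simulation <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_genome_files(truth$genome, dir)
  paths$vcf <- file.path(dir, "observed.vcf")
  emit_observed_vcf(truth, paths$vcf)
  paths$truth <- file.path(dir, "truth_mutations.tsv")
  write.table(truth$mutations, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$segments_bed <- file.path(dir, "truth_segments.bed")
  write_bed(truth$segments, paths$segments_bed, name = truth$segments$state)
  emit_marker_table(truth, dir = dir)
  paths$markers <- file.path(dir, "markers.tsv")
  paths$phenotypes <- file.path(dir, "phenotypes.tsv")
  paths$blacklist <- file.path(dir, "blacklist.tsv")
  emit_blacklist(truth, paths$blacklist)
  invisible(paths)
}

write_bed <- function(df, path, name = ".") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), name)
  writeLines(lines, path)
}

read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else ".")
}
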