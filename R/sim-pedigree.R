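# Ancestry mosaics describe which inbred strain (C = CBA outcross partner,
# F = mutagenized B6 founder) contributed each chromosome segment.
#
# External representation: data.frame(start, end, anc), 0-based half-open,
# tiling [0, L). Internal representation ("imos") used on hot paths:
# list(b = numeric bounds of length k+1 spanning 0..L, anc = character k).

imos <- function(bounds, anc) list(b = bounds, anc = anc)
imos_pure <- function(len, anc) imos(c(0, len), anc)

imos_to_df <- function(m) {
  k <- length(m$anc)
  df <- data.frame(start = m$b[-(k + 1L)], end = m$b[-1L], anc = m$anc)
  merge_runs(df, "anc")
}

df_to_imos <- function(df) imos(c(df$start, df$end[nrow(df)]), as.character(df$anc))

# ancestry at 1-based positions (vectorized)
imos_at <- function(m, pos) m$anc[findInterval(pos - 0.5, m$b)]

imos_simplify <- function(m) {
  if (length(m$anc) <= 1L) return(m)
  keep <- c(TRUE, m$anc[-1L] != m$anc[-length(m$anc)])
  imos(c(m$b[c(keep, FALSE)], m$b[length(m$b)]), m$anc[keep])
}

irecombine <- function(m1, m2, len, cm_per_mb) {
  n_xo <- rpois(1L, len / 1e6 * cm_per_mb / 100)
  first <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (first == 1L) m1 else m2)
  xo <- sort(unique(ceiling(runif(n_xo, 0, len - 1))))
  xo <- xo[xo > 0]
  b <- sort(unique(c(0, xo, m1$b, m2$b, len)))
  b <- b[b >= 0 & b <= len]
  mid <- (b[-length(b)] + b[-1L]) / 2
  n_switch <- findInterval(mid, xo)  # crossovers to the left of each piece
  use_m1 <- (n_switch %% 2L == 0L) == (first == 1L)
  anc <- ifelse(use_m1, m1$anc[findInterval(mid, m1$b)],
                m2$anc[findInterval(mid, m2$b)])
  imos_simplify(imos(b, anc))
}

#' Recombine two parental haplotype mosaics into a gamete
#'
#' Crossover count per chromosome is Poisson with mean `chrom_length` (Mb)
#' x `cm_per_mb` / 100 (Haldane map, no interference); crossover positions
#' are uniform along the chromosome. The gamete starts from a uniformly
#' chosen parent and switches parent at every crossover.
#'
#' @param hap_a,hap_b parental mosaics: data.frame with columns `start`,
#'   `end` (0-based half-open bp) and `anc`, tiling `[0, chrom_length)`.
#' @param chrom_length chromosome length, bp.
#' @param cm_per_mb genetic map density (centimorgan per megabase).
#' @return A gamete mosaic in the same data.frame form.
#' @export
#' @examples
#' set.seed(1)
#' f <- data.frame(start = 0, end = 5e7, anc = "F")
#' c <- data.frame(start = 0, end = 5e7, anc = "C")
#' recombine(f, c, 5e7, cm_per_mb = 0.5)
recombine <- function(hap_a, hap_b, chrom_length, cm_per_mb) {
  assert_tiles(hap_a, chrom_length)
  assert_tiles(hap_b, chrom_length)
  imos_to_df(irecombine(df_to_imos(hap_a), df_to_imos(hap_b),
                        chrom_length, cm_per_mb))
}

# one haplotype of a bred mouse: an F1 gamete passed through n_meioses - 1
# further meioses, each against a fresh F1 gamete; abstracts the pedigree
# to its informative meioses while keeping marginal ancestry 50/50
bred_haplotype <- function(len, cm_per_mb, n_meioses) {
  f1_gamete <- function() irecombine(imos_pure(len, "F"), imos_pure(len, "C"),
                                     len, cm_per_mb)
  h <- f1_gamete()
  if (n_meioses > 1L)
    for (i in seq_len(n_meioses - 1L)) h <- irecombine(h, f1_gamete(), len, cm_per_mb)
  h
}

# combine two haplotype mosaics into diplotype-state segments (CC/CF/FF)
diplotype_segments <- function(hap1, hap2, chrom) {
  b <- sort(unique(c(hap1$b, hap2$b)))
  start <- b[-length(b)]; end <- b[-1L]
  n_f <- (imos_at(hap1, start + 1L) == "F") + (imos_at(hap2, start + 1L) == "F")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   state = DIPLOTYPE_STATES[n_f + 1L])
  merge_runs(df, "state")
}

diplotype_state_at <- function(mouse, chrom, pos) {
  h <- mouse$diplotype[[chrom]]
  n_f <- (imos_at(h[[1L]], pos) == "F") + (imos_at(h[[2L]], pos) == "F")
  DIPLOTYPE_STATES[n_f + 1L]
}

place_catalog <- function(cfg, rate, reference) {
  # genome-wide Poisson placement; ref base read from the reference when present
  bases <- c("A", "C", "G", "T")
  alt_tab <- t(vapply(bases, function(b) setdiff(bases, b), character(3L)))
  pos_l <- list(); ref_l <- list(); alt_l <- list(); n_per <- integer()
  for (chrom in chrom_names(cfg)) {
    n <- rpois(1L, rate * cfg$chrom_length_bp)
    n_per[[chrom]] <- n
    if (n == 0L) next
    pos <- sort(sample.int(as.integer(cfg$chrom_length_bp), n))
    ref <- if (!is.null(reference)) ref_base(reference, chrom, pos)
           else bases[sample.int(4L, n, replace = TRUE)]
    alt <- alt_tab[cbind(match(ref, bases), sample.int(3L, n, replace = TRUE))]
    pos_l[[chrom]] <- pos; ref_l[[chrom]] <- ref; alt_l[[chrom]] <- alt
  }
  data.frame(chrom = rep(chrom_names(cfg), n_per),
             pos = as.integer(unlist(pos_l, use.names = FALSE) %||% integer()),
             ref = as.character(unlist(ref_l, use.names = FALSE) %||% character()),
             alt = as.character(unlist(alt_l, use.names = FALSE) %||% character()))
}

# choose a gene, codon and substitution that changes the encoded amino acid
plant_causal <- function(cfg, genome) {
  code <- Biostrings::GENETIC_CODE
  for (attempt in seq_len(200L)) {
    gi <- sample.int(nrow(genome$genes), 1L)
    g <- genome$genes[gi, ]
    cds <- genome$cds_seq[[g$gene_id]] %||%
      gene_cds_seq(genome$seed, g$gene_id, g$n_codons)
    codon_i <- sample.int(g$n_codons, 1L)
    codon <- substring(cds, 3L * codon_i - 2L, 3L * codon_i)
    within <- sample.int(3L, 1L)
    old_base <- substring(codon, within, within)
    for (new_base in sample(setdiff(c("A", "C", "G", "T"), old_base))) {
      mut <- codon
      substr(mut, within, within) <- new_base
      if (code[[mut]] != code[[codon]] && code[[mut]] != "*") {
        cds_pos <- 3L * (codon_i - 1L) + within
        gpos <- cds_to_genomic(genome, g$gene_id, cds_pos)
        ref <- if (g$strand == "+") old_base else revcomp(old_base)
        alt <- if (g$strand == "+") new_base else revcomp(new_base)
        return(data.frame(
          chrom = g$chrom, pos = gpos, ref = ref, alt = alt,
          gene_id = g$gene_id, codon_index = codon_i,
          aa_change = paste0(code[[codon]], codon_i, code[[mut]])
        ))
      }
    }
  }
  stop("could not place a missense causal mutation in the toy genome")
}

cds_to_genomic <- function(genome, gid, cds_pos) {
  g <- genome$genes[genome$genes$gene_id == gid, ]
  ex <- genome$exons[genome$exons$gene_id == gid, ]
  ex <- ex[order(ex$rank), ]
  elen <- ex$end - ex$start + 1L
  cum <- cumsum(elen)
  j <- which(cds_pos <= cum)[1L]
  off <- cds_pos - c(0L, cum)[j] - 1L
  if (g$strand == "+") ex$start[j] + off else ex$end[j] - off
}

#' Simulate a synthetic ENU outcross pedigree
#'
#' Generates the full truth bundle for one mapping experiment: per-mouse
#' ancestry mosaics, a strain-divergence SNP catalog carried by every
#' CBA-derived haplotype, an ENU point-mutation catalog carried by the
#' mutagenized founder haplotype, and one planted recessive causal missense
#' mutation inside a gene model. The first mouse is the sequenced proband
#' and is guaranteed homozygous founder (FF) at the causal locus; a mouse
#' is affected iff it is FF there (fully penetrant recessive model).
#'
#' Strain SNPs therefore appear homozygous in CC segments and heterozygous
#' in CF segments of a mouse genome, while ENU mutations appear homozygous
#' in FF segments and heterozygous in CF segments: the density contrast the
#' ancestry HMM exploits.
#'
#' @param cfg a [sim_config()].
#' @param genome an `enumap_genome` from [make_genome()]; built on the fly
#'   when NULL.
#' @return A list of class `enumap_truth`: `config`, `genome`, `causal`
#'   (site, gene and amino-acid change), `mutations` (chrom, pos, ref, alt,
#'   origin, is_causal), `mice` (each with mouse_id, affected, diplotype)
#'   and `segments` (proband diplotype-state tiling, 0-based half-open).
#' @export
#' @examples
#' truth <- simulate_pedigree(desk_config(n_mice = 8, chrom_length_bp = 2e6,
#'                                        n_chromosomes = 2))
#' truth$causal$aa_change
#' head(truth$segments)
simulate_pedigree <- function(cfg, genome = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  errs <- validate_sim_config(cfg)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  if (is.null(genome)) genome <- make_genome(cfg)
  set.seed(derive_seed(cfg$seed, "pedigree"))

  causal <- plant_causal(cfg, genome)
  strain <- place_catalog(cfg, cfg$strain_snp_rate, genome$reference)
  enu <- place_catalog(cfg, cfg$enu_rate, genome$reference)
  # drop any random ENU hit colliding with the causal site, then plant it
  enu <- enu[!(enu$chrom == causal$chrom & enu$pos == causal$pos), ]
  enu <- rbind(enu, data.frame(chrom = causal$chrom, pos = causal$pos,
                               ref = causal$ref, alt = causal$alt))
  if (nrow(strain)) strain$origin <- "STRAIN"
  else strain$origin <- character()
  enu$origin <- "ENU"
  mutations <- rbind(strain, enu)
  mutations$is_causal <- mutations$origin == "ENU" &
    mutations$chrom == causal$chrom & mutations$pos == causal$pos
  mutations <- mutations[order(match(mutations$chrom, chrom_names(cfg)),
                               mutations$pos), ]
  rownames(mutations) <- NULL

  L <- cfg$chrom_length_bp
  new_mouse <- function(id, force_affected = FALSE) {
    for (attempt in seq_len(10000L)) {
      dip <- lapply(setNames(nm = chrom_names(cfg)), function(chrom)
        list(bred_haplotype(L, cfg$cm_per_mb, cfg$n_meioses),
             bred_haplotype(L, cfg$cm_per_mb, cfg$n_meioses)))
      m <- list(mouse_id = id, diplotype = dip)
      m$affected <- diplotype_state_at(m, causal$chrom, causal$pos) == "FF"
      if (!force_affected || m$affected) return(m)
    }
    stop("failed to breed an affected proband")
  }
  mice <- vector("list", cfg$n_mice)
  mice[[1L]] <- new_mouse("proband", force_affected = TRUE)
  if (cfg$n_mice > 1L)
    for (i in 2:cfg$n_mice) mice[[i]] <- new_mouse(sprintf("mouse_%02d", i))

  proband <- mice[[1L]]
  segments <- do.call(rbind, lapply(chrom_names(cfg), function(chrom)
    diplotype_segments(proband$diplotype[[chrom]][[1L]],
                       proband$diplotype[[chrom]][[2L]], chrom)))
  rownames(segments) <- NULL

  structure(list(config = cfg, genome = genome, causal = causal,
                 mutations = mutations, mice = mice, segments = segments),
            class = "enumap_truth")
}
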