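#' Simulation configuration for a synthetic ENU outcross
#'
#' Bundles every parameter of the synthetic pedigree generator. Defaults
#' describe a mouse-sized study: a 20 x 50 Mb autosomal genome, a
#' strain-divergence SNP density of 5e-4/bp in CBA-derived segments, an ENU
#' point-mutation density of 1e-6/bp on the mutagenized founder haplotype,
#' a genetic map of 0.5 cM/Mb, four informative meioses shaping each
#' inherited haplotype, and genotyping noise matched to ~6x whole-genome
#' coverage of a single affected animal.
#'
#' @param n_chromosomes number of (autosomal) chromosomes.
#' @param chrom_length_bp length of every chromosome, bp (>= 1e6).
#' @param enu_rate expected ENU mutations per bp on the mutagenized founder
#'   haplotype.
#' @param strain_snp_rate expected CBA-vs-reference SNPs per bp carried by
#'   every CBA-derived haplotype.
#' @param cm_per_mb genetic map density, centimorgan per megabase.
#' @param n_meioses informative meioses shaping each haplotype of a bred
#'   mouse; controls mosaic block length.
#' @param coding_fraction fraction of each chromosome covered by toy gene
#'   models (CDS).
#' @param het_miscall_rate probability that a true heterozygous variant is
#'   emitted as homozygous-alt (allele dropout at low coverage).
#' @param dropout_rate probability that a true variant is not emitted at all.
#' @param fp_rate false variant calls per bp.
#' @param mean_depth mean sequencing depth at emitted sites.
#' @param known_fraction fraction of strain SNPs present in the
#'   known-variant blacklist the simulator writes (previously catalogued
#'   strain divergence).
#' @param n_mice pedigree mice genotyped at the marker panel.
#' @param n_markers_per_chrom evenly spaced markers per chromosome.
#' @param seed RNG seed for the whole simulation.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 5e6)
#' cfg$strain_snp_rate
sim_config <- function(n_chromosomes = 20L,
                       chrom_length_bp = 50e6,
                       enu_rate = 1e-6,
                       strain_snp_rate = 5e-4,
                       cm_per_mb = 0.5,
                       n_meioses = 4L,
                       coding_fraction = 0.02,
                       het_miscall_rate = 0.1,
                       dropout_rate = 0.03,
                       fp_rate = 2e-8,
                       mean_depth = 5.8,
                       known_fraction = 0.5,
                       n_mice = 27L,
                       n_markers_per_chrom = 3L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    enu_rate = enu_rate, strain_snp_rate = strain_snp_rate,
    cm_per_mb = cm_per_mb, n_meioses = as.integer(n_meioses),
    coding_fraction = coding_fraction,
    het_miscall_rate = het_miscall_rate, dropout_rate = dropout_rate,
    fp_rate = fp_rate, mean_depth = mean_depth,
    known_fraction = known_fraction,
    n_mice = as.integer(n_mice),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  errs <- validate_sim_config(cfg)
  if (length(errs)) stop("invalid sim_config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config` candidate list.
#' @return `validate_sim_config()` returns a character vector of violations
#'   (empty when valid).
#' @export
validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs[[length(errs) + 1L]] <<- msg
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$n_chromosomes) && cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  chk(num1(cfg$chrom_length_bp) && cfg$chrom_length_bp >= 1e6,
      "chrom_length_bp must be >= 1 Mb")
  for (f in c("enu_rate", "strain_snp_rate", "fp_rate"))
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, paste(f, "must be >= 0"))
  for (f in c("het_miscall_rate", "dropout_rate", "known_fraction", "coding_fraction"))
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste(f, "must be a probability in [0, 1]"))
  chk(num1(cfg$cm_per_mb) && cfg$cm_per_mb >= 0, "cm_per_mb must be >= 0")
  chk(num1(cfg$n_meioses) && cfg$n_meioses >= 1, "n_meioses must be >= 1")
  chk(num1(cfg$mean_depth) && cfg$mean_depth > 0, "mean_depth must be > 0")
  chk(num1(cfg$n_mice) && cfg$n_mice >= 1, "n_mice must be >= 1")
  chk(num1(cfg$n_markers_per_chrom) && cfg$n_markers_per_chrom >= 0,
      "n_markers_per_chrom must be >= 0")
  chk(num1(cfg$seed), "seed must be a single number")
  chk(num1(cfg$coding_fraction) && cfg$coding_fraction * cfg$chrom_length_bp >= 300 ||
        !num1(cfg$coding_fraction),
      "coding_fraction too small: genome cannot host a coding causal site")
  chk(!num1(cfg$enu_rate) || cfg$enu_rate > 0,
      "enu_rate must be > 0: a causal ENU mutation cannot be placed")
  errs
}

#' Desk-scale simulation configuration
#'
#' A reduced genome (4 x 25 Mb) with all densities at their defaults, small
#' enough that the end-to-end pipeline, including reference sequence and
#' file round trips, runs in seconds. Used throughout the examples.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 4L, chrom_length_bp = 25e6)
  do.call(sim_config, utils::modifyList(defaults, args))
}

chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))
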