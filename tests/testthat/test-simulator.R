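test_that("recombination degenerate cases behave", {
  set.seed(1)
  L <- 5e7
  f <- data.frame(start = 0, end = L, anc = "F")
  c_ <- data.frame(start = 0, end = L, anc = "C")
  # no recombination: gamete equals one parent wholesale
  g <- recombine(f, c_, L, cm_per_mb = 0)
  expect_true(identical(g$anc, "F") || identical(g$anc, "C"))
  expect_equal(g$start, 0); expect_equal(g$end, L)
  # identical parents: gamete identical regardless of crossovers
  for (i in 1:20) expect_equal(recombine(f, f, L, cm_per_mb = 2), f)
})

test_that("crossover counts are Poisson with the map-length mean", {
  set.seed(7)
  L <- 5e7
  f <- data.frame(start = 0, end = L, anc = "F")
  c_ <- data.frame(start = 0, end = L, anc = "C")
  n_junc <- vapply(1:10000, function(i) {
    nrow(recombine(f, c_, L, cm_per_mb = 0.5)) - 1L
  }, 0L)
  # mean 0.25 crossovers (50 Mb x 0.5 cM/Mb / 100); 4 sigma Monte Carlo band
  expect_equal(mean(n_junc), 0.25, tolerance = 4 * sqrt(0.25 / 10000) / 0.25)
  expect_true(all(vapply(1:50, function(i) {
    g <- recombine(f, c_, L, cm_per_mb = 2)
    g$start[1] == 0 && g$end[nrow(g)] == L &&
      all(g$end > g$start) &&
      (nrow(g) == 1 || all(g$start[-1] == g$end[-nrow(g)]))
  }, TRUE)))
})

test_that("a zero ENU rate is rejected (no causal mutation can be placed)", {
  expect_error(tiny_cfg(enu_rate = 0), "enu_rate")
  expect_length(validate_sim_config(unclass(tiny_cfg())), 0)
})

test_that("the truth bundle is deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 99L)
  a <- simulate_pedigree(cfg)
  b <- simulate_pedigree(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$segments, b$segments)
  expect_identical(a$causal, b$causal)
  va <- emit_observed_vcf(a); vb <- emit_observed_vcf(b)
  expect_identical(va, vb)
  ma <- emit_marker_table(a); mb <- emit_marker_table(b)
  expect_identical(ma, mb)
  # and byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  emit_observed_vcf(a, f1); emit_observed_vcf(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("segments tile each chromosome and the phenotype law holds", {
  for (seed in c(3L, 11L)) {
    cfg <- tiny_cfg(seed = seed, n_mice = 12L)
    truth <- simulate_pedigree(cfg)
    agg <- tapply(truth$segments$end - truth$segments$start,
                  truth$segments$chrom, sum)
    expect_true(all(agg == cfg$chrom_length_bp))
    expect_true(all(truth$segments$end > truth$segments$start))
    # exactly one causal mutation, of ENU origin
    expect_identical(sum(truth$mutations$is_causal), 1L)
    expect_identical(truth$mutations$origin[truth$mutations$is_causal], "ENU")
    # affected <=> FF at the causal locus, proband forced affected
    expect_true(truth$mice[[1]]$affected)
    for (m in truth$mice) {
      st <- enumap:::diplotype_state_at(m, truth$causal$chrom, truth$causal$pos)
      expect_identical(m$affected, st == "FF")
    }
  }
})

test_that("noiseless emission reproduces the carried truth exactly, with origin-consistent zygosity", {
  cfg <- tiny_cfg(seed = 5L, strain_snp_rate = 2e-4, enu_rate = 5e-6,
                  het_miscall_rate = 0, dropout_rate = 0, fp_rate = 0)
  truth <- simulate_pedigree(cfg)
  v <- emit_observed_vcf(truth)
  expect_true(all(v$alt_fwd + v$alt_rev == v$alt_depth))
  expect_true(all(v$alt_depth <= v$depth))
  # zygosity must agree with the proband's ancestry state at each site
  state <- character(nrow(v))
  for (chrom in unique(v$chrom)) {
    i <- v$chrom == chrom
    s <- truth$segments[truth$segments$chrom == chrom, ]
    state[i] <- s$state[findInterval(v$pos[i] - 1, s$start)]
  }
  expect_true(all(state[v$origin == "STRAIN" & v$genotype == "hom_alt"] == "CC"))
  expect_true(all(state[v$origin == "STRAIN" & v$genotype == "het"] == "CF"))
  expect_true(all(state[v$origin == "ENU" & v$genotype == "hom_alt"] == "FF"))
  expect_true(all(state[v$origin == "ENU" & v$genotype == "het"] == "CF"))
  # every carried truth variant is emitted (no noise): re-emission is stable
  expect_identical(v, emit_observed_vcf(truth))
  # dropout 1, no false positives: nothing is emitted
  cfg2 <- tiny_cfg(seed = 5L, dropout_rate = 1, fp_rate = 0)
  expect_identical(nrow(emit_observed_vcf(simulate_pedigree(cfg2))), 0L)
})

test_that("ENU mutation counts match the Poisson expectation (Monte Carlo)", {
  cfg <- sim_config(n_mice = 1L, strain_snp_rate = 1e-7, seed = 1L)
  genome <- make_genome(cfg)
  n_rep <- 200L
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg$seed <- 1000L + i
    sum(simulate_pedigree(cfg, genome)$mutations$origin == "ENU")
  }, 0L)
  mu <- cfg$n_chromosomes * cfg$chrom_length_bp * cfg$enu_rate  # 1000
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_rep) + 1)  # +1: planted causal
})

test_that("het miscalls occur at the configured rate", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 10e6, n_mice = 1L,
                    strain_snp_rate = 5e-3, het_miscall_rate = 0.3,
                    dropout_rate = 0, fp_rate = 0, seed = 8L)
  truth <- simulate_pedigree(cfg)
  v <- emit_observed_vcf(truth)
  # true hets are the strain variants inside CF segments
  state <- character(nrow(v))
  for (chrom in unique(v$chrom)) {
    i <- v$chrom == chrom
    s <- truth$segments[truth$segments$chrom == chrom, ]
    state[i] <- s$state[findInterval(v$pos[i] - 1, s$start)]
  }
  cf_strain <- v[state == "CF" & v$origin == "STRAIN", ]
  skip_if(nrow(cf_strain) < 5000)  # needs a CF block in the mosaic draw
  frac <- mean(cf_strain$genotype == "hom_alt")
  n <- nrow(cf_strain)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("marker genotypes read out ancestry and follow intercross probabilities", {
  # complete linkage: affected mice are BB at a marker on the causal position
  cfg <- tiny_cfg(seed = 21L, n_mice = 20L)
  truth <- simulate_pedigree(cfg)
  mk <- emit_marker_table(truth)
  ph <- mk$phenotypes
  causal_id <- sprintf("%s_%09d", truth$causal$chrom, truth$causal$pos)
  at_causal <- mk$markers[mk$markers$marker_id == causal_id, ]
  aff <- ph$mouse_id[ph$affected]
  expect_true(all(at_causal$genotype[at_causal$mouse_id %in% aff] == "BB"))
  expect_false(any(at_causal$genotype[!at_causal$mouse_id %in% aff] == "BB"))

  # 10 cM away in a single-meiosis cross: P(BC or CC | affected) = 1-(1-theta)^2,
  # theta = Haldane(10 cM) = 0.0906
  cfg2 <- sim_config(n_chromosomes = 1L, chrom_length_bp = 5e7, n_mice = 1200L,
                     n_meioses = 1L, strain_snp_rate = 1e-6, seed = 31L)
  truth2 <- simulate_pedigree(cfg2)
  d <- 20e6  # 10 cM at 0.5 cM/Mb
  mpos <- if (truth2$causal$pos + d <= 5e7) truth2$causal$pos + d
          else truth2$causal$pos - d
  mk2 <- emit_marker_table(truth2, positions = data.frame(chrom = "chr1", pos = mpos),
                           include_causal = FALSE)
  ph2 <- mk2$phenotypes
  aff2 <- ph2$mouse_id[ph2$affected & ph2$mouse_id != "proband"]
  g <- mk2$markers$genotype[mk2$markers$mouse_id %in% aff2]
  theta <- (1 - exp(-2 * 0.10)) / 2
  expect_equal(theta, 0.0906, tolerance = 1e-3)
  p_rec <- 1 - (1 - theta)^2
  expect_lt(abs(mean(g != "BB") - p_rec),
            4 * sqrt(p_rec * (1 - p_rec) / length(g)))

  expect_error(emit_marker_table(truth, n_markers_per_chrom = 0L,
                                 include_causal = FALSE), "zero markers")
})
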