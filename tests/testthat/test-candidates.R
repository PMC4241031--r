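test_that("the codon-185 TGC case is labelled C185Y, and position 3 gives a stop", {
  toy <- toy_gene()
  # codon 185 spans genomic 101 + 184*3 .. +2; G is its second base
  gpos <- 101 + 184 * 3
  v <- data.frame(chrom = "chr9", pos = gpos + 1, ref = "G", alt = "A")
  r <- classify_consequence(v, toy$models, toy$reference)
  expect_identical(r$consequence, "missense")
  expect_identical(r$protein_change, "C185Y")
  expect_identical(r$gene_id, "g1")
  # third position TGC -> TGA: nonsense, stop written as *
  v3 <- data.frame(chrom = "chr9", pos = gpos + 2, ref = "C", alt = "A")
  r3 <- classify_consequence(v3, toy$models, toy$reference)
  expect_identical(r3$consequence, "nonsense")
  expect_identical(r3$protein_change, "C185*")
  # synonymous third-position change TGC -> TGT keeps the label convention
  v4 <- data.frame(chrom = "chr9", pos = gpos + 2, ref = "C", alt = "T")
  r4 <- classify_consequence(v4, toy$models, toy$reference)
  expect_identical(r4$consequence, "synonymous")
  expect_identical(r4$protein_change, "C185C")
})

test_that("a minus-strand gene mirrors the plus-strand consequence calls", {
  plus <- toy_gene(strand = "+")
  minus <- toy_gene(strand = "-")
  cds_len <- 200 * 3
  for (cds_pos in c(10, 301, 553, 554)) {
    base_plus <- substring(plus$reference[["chr9"]],
                           genomic_pos_of_cds(plus, cds_pos, "+"),
                           genomic_pos_of_cds(plus, cds_pos, "+"))
    alts <- setdiff(c("A", "C", "G", "T"), base_plus)
    for (alt in alts) {
      vp <- data.frame(chrom = "chr9", pos = genomic_pos_of_cds(plus, cds_pos, "+"),
                       ref = base_plus, alt = alt)
      gm <- genomic_pos_of_cds(minus, cds_pos, "-", cds_len = cds_len)
      vm <- data.frame(chrom = "chr9", pos = gm,
                       ref = enumap:::revcomp(base_plus),
                       alt = enumap:::revcomp(alt))
      rp <- classify_consequence(vp, plus$models, plus$reference)
      rm <- classify_consequence(vm, minus$models, minus$reference)
      expect_identical(rp$consequence, rm$consequence)
      expect_identical(rp$protein_change, rm$protein_change)
    }
  }
})

test_that("a REF mismatch or an indel is rejected with coordinates", {
  toy <- toy_gene()
  gpos <- 101 + 184 * 3
  base <- substring(toy$reference[["chr9"]], gpos, gpos)
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  expect_error(classify_consequence(
    data.frame(chrom = "chr9", pos = gpos, ref = wrong, alt = base),
    toy$models, toy$reference), "mismatch")
  expect_error(classify_consequence(
    data.frame(chrom = "chr9", pos = gpos, ref = "AT", alt = "A"),
    toy$models, toy$reference), "single-nucleotide")
})

test_that("splice classification covers the 2 intronic bases at CDS junctions", {
  # two-exon plus-strand gene: exon1 101-161 (61 bp), intron 162-260,
  # exon2 261-400 (140 bp); total CDS 201 bp
  set.seed(99)
  L <- 500
  bg <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  reference <- c(chr1 = bg)
  models <- gene_models(data.frame(
    gene_id = c("g1", "g1"), chrom = "chr1", start = c(101, 261),
    end = c(161, 400), strand = "+"))
  cls <- function(pos) {
    ref <- substring(bg, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classify_consequence(data.frame(chrom = "chr1", pos = pos, ref = ref,
                                    alt = alt), models, reference)$consequence
  }
  expect_identical(cls(162), "splice")  # donor +1
  expect_identical(cls(163), "splice")  # donor +2
  expect_identical(cls(164), "noncoding")
  expect_identical(cls(260), "splice")  # acceptor -1
  expect_identical(cls(259), "splice")  # acceptor -2
  expect_identical(cls(258), "noncoding")
  expect_identical(cls(50), "noncoding")  # upstream
  expect_true(cls(161) %in% c("missense", "nonsense", "synonymous"))
})

test_that("random SNVs agree with a full-CDS retranslation oracle", {
  cfg <- tiny_cfg(seed = 71L, n_chromosomes = 1L, chrom_length_bp = 1e6,
                  coding_fraction = 0.05)
  genome <- make_genome(cfg, sequence = TRUE)
  models <- enumap:::genome_gene_models(genome)
  reference <- genome$reference
  set.seed(72)
  n_checked <- 0
  for (i in 1:150) {
    gid <- sample(models$genes$gene_id, 1)
    gp <- cds_positions(models, gid)
    pos <- sample(gp, 1)
    ref <- substring(reference[[1]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- data.frame(chrom = models$genes$chrom[1], pos = pos, ref = ref, alt = alt)
    got <- classify_consequence(v, models, reference)
    want <- oracle_consequence(v, models, reference)
    expect_identical(got$consequence, want$consequence)
    expect_identical(got$protein_change, want$protein_change)
    n_checked <- n_checked + 1
  }
  expect_identical(n_checked, 150)
})

test_that("candidate nomination applies zygosity, consequence and region rules", {
  toy <- toy_gene()  # gene on chr9 at 101..700
  gpos <- 101 + 184 * 3  # codon 185
  base_at <- function(p) substring(toy$reference[["chr9"]], p, p)
  mk <- function(pos, ref, alt, genotype)
    data.frame(chrom = "chr9", pos = pos, ref = ref, alt = alt,
               genotype = genotype, depth = 10L, alt_depth = 10L,
               alt_fwd = 5L, alt_rev = 5L, qual = 60)
  # deliberately: 2 het missense, 1 hom synonymous, 1 hom missense in-region,
  # 1 hom nonsense out-of-region, 1 hom noncoding in-region
  v <- rbind(
    mk(gpos + 1, "G", "A", "het"),
    mk(101 + 3, base_at(101 + 3), setdiff(c("A","C","G","T"), base_at(101 + 3))[1], "het"),
    mk(gpos + 2, "C", "T", "hom_alt"),          # synonymous (TGC->TGT)
    mk(gpos + 1, "G", "A", "hom_alt"),          # missense in-region
    mk(101, base_at(101), setdiff(c("A","C","G","T"), base_at(101))[1], "hom_alt"),
    mk(720, base_at(720), setdiff(c("A","C","G","T"), base_at(720))[1], "hom_alt")
  )
  # region covers 400..730 (captures the codon-185 sites and the noncoding tail,
  # excludes the gene start)
  region <- data.frame(chrom = "chr9", start = 400, end = 730)
  cand <- nominate_candidates(v, toy$models, toy$reference, ff_segments = region)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$protein_change, "C185Y")
  expect_identical(cand$genotype, "hom_alt")
  # relaxing zygosity gives a superset
  cand_any <- nominate_candidates(v, toy$models, toy$reference,
                                  ff_segments = region, zygosity = "any")
  expect_gte(nrow(cand_any), nrow(cand))
  expect_true(all(paste(cand$pos, cand$alt) %in% paste(cand_any$pos, cand_any$alt)))
  # intersection when both region sources given
  link <- data.frame(chrom = "chr9", start = 0, end = 300)
  cand_both <- suppressWarnings(
    nominate_candidates(v, toy$models, toy$reference, ff_segments = region,
                        linkage_region = link))
  expect_identical(nrow(cand_both), 0L)
  # every candidate lies inside the region set, order-invariantly
  cand_rev <- nominate_candidates(v[rev(seq_len(nrow(v))), ], toy$models,
                                  toy$reference, ff_segments = region)
  expect_identical(cand_rev, cand)
  expect_true(all(cand$pos > 400 & cand$pos <= 730))
  expect_error(nominate_candidates(v, toy$models, toy$reference), "region")
})

test_that("the funnel report is consistent and non-increasing", {
  rep <- data.frame(stage = c("blacklist", "depth"), input = c(100L, 60L),
                    removed = c(40L, 10L), surviving = c(60L, 50L))
  class(rep) <- c("filter_report", "data.frame")
  cand <- data.frame()
  r <- rank_report(rep, n_in_region = 7L, candidates = cand)
  expect_identical(r$funnel$count, c(100L, 60L, 50L, 7L, 0L))
  expect_true(all(diff(r$funnel$count) <= 0))
  d <- tempfile(); dir.create(d)
  r2 <- rank_report(rep, 7L, cand, dir = d)
  expect_true(file.exists(file.path(d, "funnel.tsv")))
  back <- read.table(file.path(d, "funnel.tsv"), header = TRUE, sep = "\t")
  expect_identical(back$count, r$funnel$count)
})
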