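write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_header_min <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
  "##INFO=<ID=SB,Number=.,Type=Integer,Description=\"s\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1"), collapse = "\t")
)

test_that("a header-only VCF parses to an empty call table", {
  f <- write_tmp_vcf(vcf_header_min)
  v <- parse_vcf(f)
  expect_identical(nrow(v), 0L)
  expect_identical(attr(v, "n_records"), 0L)
})

test_that("multi-allelic records split into per-alt calls", {
  f <- write_tmp_vcf(c(vcf_header_min,
    "chr1\t200\t.\tC\tT,G\t60\tPASS\tDP=12;SB=2,3,1,1\tGT:AD:DP\t1/2:5,4,3:12"))
  v <- parse_vcf(f)
  expect_identical(nrow(v), 2L)
  expect_identical(v$pos, c(200L, 200L))
  expect_identical(v$alt, c("T", "G"))
  expect_identical(v$genotype, c("het", "het"))
  expect_identical(v$alt_depth, c(4L, 3L))
  expect_identical(v$alt_fwd, c(2L, 1L))
  expect_identical(v$alt_rev, c(3L, 1L))
})

test_that("records without SB are strand-unknown and exempt from the strand stage", {
  f <- write_tmp_vcf(c(vcf_header_min,
    "chr1\t100\t.\tA\tG\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:4,6:10"))
  v <- parse_vcf(f)
  expect_true(is.na(v$alt_fwd))
  r <- site_filters(v, config = filter_config(homopolymer_min_run = Inf,
                                              max_strand_skew = 0))
  expect_identical(nrow(r$variants), 1L)
})

test_that("write/parse round-trips random call tables", {
  set.seed(404)
  x <- random_calls(1000)
  rownames(x) <- NULL
  f <- tempfile(fileext = ".vcf")
  write_vcf(x, f)
  y <- parse_vcf(f)
  attributes(y)[c("vcf_header", "n_records")] <- NULL
  expect_equal(as.data.frame(y), as.data.frame(x), ignore_attr = TRUE)
})

test_that("malformed records are reported with their line number", {
  f <- write_tmp_vcf(c(vcf_header_min,
    "chr1\t100\t.\tA\tG\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:4,6:10",
    "chr1\tnotanumber\t.\tA\tG\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:4,6:10"))
  expect_error(suppressWarnings(parse_vcf(f)), "line 9")
})

test_that("an unsorted VCF warns but still parses", {
  f <- write_tmp_vcf(c(vcf_header_min,
    "chr1\t500\t.\tA\tG\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:4,6:10",
    "chr1\t100\t.\tT\tC\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:4,6:10"))
  expect_warning(v <- parse_vcf(f), "sorted")
  expect_identical(nrow(v), 2L)
})

test_that("blacklist subtraction is an exact set difference", {
  set.seed(5)
  v <- random_calls(5)
  # empty blacklist: identity
  r <- subtract_known(v, data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()))
  expect_identical(r$removed, 0L)
  expect_equal(r$variants, v, ignore_attr = TRUE)
  # 2 of 5 blacklisted
  bl <- v[c(2, 4), c("chrom", "pos", "ref", "alt")]
  r <- subtract_known(v, bl)
  expect_identical(r$removed, 2L)
  expect_identical(nrow(r$variants), 3L)

  # brute-force oracle on a larger random instance
  v <- random_calls(2000)
  bl <- rbind(v[sample.int(2000, 300), c("chrom", "pos", "ref", "alt")],
              data.frame(chrom = "chrZ", pos = 1:50, ref = "A", alt = "T"))
  r <- subtract_known(v, bl)
  naive_hit <- vapply(seq_len(nrow(v)), function(i)
    any(bl$chrom == v$chrom[i] & bl$pos == v$pos[i] &
          bl$ref == v$ref[i] & bl$alt == v$alt[i]), TRUE)
  expect_identical(r$removed, sum(naive_hit))
  expect_equal(r$variants, v[!naive_hit, ], ignore_attr = TRUE)

  # position-only mode removes same-position different-allele calls too
  v2 <- v[1:10, ]
  bl2 <- data.frame(chrom = v2$chrom[1], pos = v2$pos[1], ref = "N", alt = "N")
  expect_identical(subtract_known(v2, bl2, keys = "position")$removed,
                   sum(v2$chrom == v2$chrom[1] & v2$pos == v2$pos[1]))
})

disabled_config <- function(...) {
  filter_config(min_depth = 0, max_depth = Inf, min_allele_balance = 0,
                max_strand_skew = 1, homopolymer_min_run = Inf,
                cluster_max_variants = Inf, ...)
}

test_that("fully disabled site filters are the identity", {
  set.seed(6)
  v <- random_calls(500)
  r <- site_filters(v, reference = NULL, repeat_mask = NULL,
                    config = disabled_config())
  expect_equal(as.data.frame(r$variants), as.data.frame(v), ignore_attr = TRUE)
  expect_true(all(r$report$removed == 0))
})

test_that("a homopolymer run inside the flank removes a call", {
  ref <- c(chrX = paste0(strrep("ACGT", 12), "AAAAAA", strrep("GTCA", 12)))
  v <- data.frame(chrom = "chrX", pos = 50L, ref = "A", alt = "G",
                  genotype = "hom_alt", depth = 10L, alt_depth = 10L,
                  alt_fwd = 5L, alt_rev = 5L, qual = 60)
  cfg <- disabled_config()
  cfg$homopolymer_min_run <- 6
  r <- site_filters(v, reference = ref, config = cfg)
  expect_identical(nrow(r$variants), 0L)
  expect_identical(r$report$removed[r$report$stage == "homopolymer"], 1L)
  # run of 5 does not trigger at min_run 6
  ref5 <- c(chrX = paste0(strrep("ACGT", 12), "AAAAA", strrep("GTCA", 12)))
  expect_identical(nrow(site_filters(v, ref5, config = cfg)$variants), 1L)
  # a variant off the reference errors with its coordinates
  v$pos <- 10000L
  expect_error(site_filters(v, ref, config = cfg), "chrX:10000")
})

test_that("stage-by-stage removals match independent per-rule oracles", {
  set.seed(77)
  n <- 5000
  v <- random_calls(n, len = 5e4)  # dense enough to exercise the cluster rule
  ref <- random_reference(len = 5e4)
  mask <- data.frame(chrom = "chrA",
                     start = c(1000L, 30000L), end = c(2000L, 31000L))
  cfg <- filter_config(min_depth = 4, max_depth = 35, min_allele_balance = 0.25,
                       max_strand_skew = 0.8, homopolymer_min_run = 5,
                       homopolymer_flank = 5, cluster_window = 100,
                       cluster_max_variants = 2)
  res <- site_filters(v, ref, mask, cfg)
  rep <- res$report

  oracle <- filter_stage_oracle(v, ref, mask, cfg)
  expect_identical(rep$removed, as.integer(oracle$removed))
  expect_equal(as.data.frame(res$variants), as.data.frame(oracle$survivors),
               ignore_attr = TRUE)
  # conservation
  expect_identical(rep$input[1], nrow(v))
  expect_identical(nrow(v), nrow(res$variants) + sum(rep$removed))
  expect_identical(rep$input[-1], rep$surviving[-nrow(rep)])
})

test_that("the cascade is idempotent and monotone in its thresholds", {
  set.seed(88)
  v <- random_calls(2000, len = 1e5)
  ref <- random_reference(len = 1e5)
  cfg <- filter_config()
  r1 <- site_filters(v, ref, config = cfg)
  r2 <- site_filters(r1$variants, ref, config = cfg)
  expect_equal(as.data.frame(r2$variants), as.data.frame(r1$variants),
               ignore_attr = TRUE)
  expect_true(all(r2$report$removed == 0))

  base <- nrow(site_filters(v, ref, config = cfg)$variants)
  for (tweak in list(list(min_depth = 5), list(max_depth = 20),
                     list(min_allele_balance = 0.35),
                     list(max_strand_skew = 0.5),
                     list(homopolymer_min_run = 4),
                     list(cluster_max_variants = 1))) {
    tighter <- do.call(filter_config, tweak)
    expect_lte(nrow(site_filters(v, ref, config = tighter)$variants), base)
  }
})
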