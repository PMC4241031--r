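# Shared fixtures: all built in code at test time.

# small, fast simulation configs
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 2L, chrom_length_bp = 3e6, n_mice = 6L,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# random marker observation: counts from the intercross model at a random
# theta (or the null when theta = 0.5)
random_obs <- function(n_aff = 10L, n_un = 17L, theta = runif(1, 0, 0.5)) {
  pa <- c((1 - theta)^2, 2 * theta * (1 - theta), theta^2)
  pu <- c(1 - (1 - theta)^2, 2 - 2 * theta * (1 - theta), 1 - theta^2) / 3
  a <- as.vector(stats::rmultinom(1, n_aff, pa))
  u <- as.vector(stats::rmultinom(1, n_un, pu))
  c(nBB = a[1], nBC = a[2], nCC = a[3], uBB = u[1], uBC = u[2], uCC = u[3])
}

# independent LOD evaluation used as an oracle (vectorized over theta)
oracle_lod_curve <- function(obs, thetas) {
  pa <- cbind((1 - thetas)^2, 2 * thetas * (1 - thetas), thetas^2)
  pu <- cbind(1 - (1 - thetas)^2, 2 - 2 * thetas * (1 - thetas), 1 - thetas^2) / 3
  ratio <- cbind(log10(pa) - rep(log10(c(0.25, 0.5, 0.25)), each = length(thetas)),
                 log10(pu) - rep(log10(c(0.25, 0.5, 0.25)), each = length(thetas)))
  cnt <- as.numeric(obs[c("nBB", "nBC", "nCC", "uBB", "uBC", "uCC")])
  out <- numeric(length(thetas))
  for (j in 1:6) if (cnt[j] != 0) out <- out + cnt[j] * ratio[, j]
  out
}

# exhaustive-enumeration oracle for the 3-state HMM on few windows
enumerate_hmm <- function(windows, params) {
  n <- nrow(windows)
  states <- params$states
  e <- sapply(states, function(s)
    dpois(windows$n_hom, params$lambda_hom[[s]], log = TRUE) +
      dpois(windows$n_het, params$lambda_het[[s]], log = TRUE))
  e <- matrix(e, nrow = n)
  tr <- matrix(log(params$rho / 2), 3, 3); diag(tr) <- log(1 - params$rho)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(p) {
    lp <- log(params$pi[p[1]]) + e[1, p[1]]
    if (n > 1) for (t in 2:n) lp <- lp + tr[p[t - 1], p[t]] + e[t, p[t]]
    lp
  })
  m <- max(lp)
  list(best = m, best_path = states[paths[which.max(lp), ]],
       total = m + log(sum(exp(lp - m))))
}

random_hmm_params <- function() {
  lh <- sort(runif(3, 0.1, 40), decreasing = TRUE)   # CC > CF > FF hom rates
  lt <- c(runif(1, 0, 2), runif(1, 20, 60), runif(1, 0, 2))
  suppressWarnings(hmm_params(
    lambda_hom = c(CC = lh[1], CF = lh[2], FF = lh[3]),
    lambda_het = c(CC = lt[1], CF = lt[2], FF = lt[3]),
    rho = runif(1, 0.01, 0.3)
  ))
}

random_windows <- function(n, chrom = "chr1", width = 1e4) {
  data.frame(chrom = chrom, win = seq_len(n) - 1L,
             start = (seq_len(n) - 1L) * width, end = seq_len(n) * width,
             n_hom = rpois(n, sample(c(0.5, 5, 30), n, replace = TRUE)),
             n_het = rpois(n, sample(c(0.5, 5, 30), n, replace = TRUE)))
}

# random variant call table for filter tests
random_calls <- function(n, chroms = c("chrA", "chrB"), len = 2e5) {
  depth <- sample(1:40, n, replace = TRUE)
  alt_depth <- pmax(1L, rbinom(n, depth, 0.5))
  alt_fwd <- rbinom(n, alt_depth, 0.5)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  df <- data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(len, n, replace = TRUE),
    ref = ref, alt = alt,
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    depth = depth, alt_depth = pmin(alt_depth, depth),
    alt_fwd = alt_fwd, alt_rev = pmin(alt_depth, depth) - pmin(alt_fwd, pmin(alt_depth, depth)),
    qual = round(runif(n, 10, 99))
  )
  df$alt_depth <- pmin(df$alt_depth, df$depth)
  df$alt_fwd <- pmin(df$alt_fwd, df$alt_depth)
  df$alt_rev <- df$alt_depth - df$alt_fwd
  df[order(df$chrom, df$pos), ]
}

random_reference <- function(chroms = c("chrA", "chrB"), len = 2e5) {
  setNames(vapply(chroms, function(x)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), ""),
    chroms)
}

# a hand-built single-exon gene of n codons starting at genomic position
# `cds_start`, with codon `at` set to `codon`; returns reference + models
toy_gene <- function(n_codons = 200, at = 185, codon = "TGC", cds_start = 101,
                     strand = "+", chrom = "chr9") {
  set.seed(1234)
  codons <- sample(enumap:::SENSE_CODONS, n_codons, replace = TRUE)
  codons[at] <- codon
  cds <- paste(codons, collapse = "")
  gseq <- if (strand == "+") cds else enumap:::revcomp(cds)
  L <- cds_start - 1 + nchar(cds) + 100
  bg <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  ref <- paste0(substring(bg, 1, cds_start - 1), gseq,
                substring(bg, cds_start + nchar(cds), L))
  reference <- setNames(ref, chrom)
  models <- gene_models(data.frame(
    gene_id = "g1", chrom = chrom, start = cds_start,
    end = cds_start + nchar(cds) - 1, strand = strand))
  list(reference = reference, models = models, codons = codons)
}

genomic_pos_of_cds <- function(toy, cds_pos, strand = "+", cds_start = 101,
                               cds_len = NULL) {
  if (strand == "+") cds_start + cds_pos - 1
  else cds_start + cds_len - cds_pos
}

# genomic positions of a gene's CDS in transcript order (independent of the
# package's coordinate arithmetic)
cds_positions <- function(models, gid) {
  g <- models$genes[models$genes$gene_id == gid, ]
  ex <- models$exons[models$exons$gene_id == gid, ]
  ex <- ex[order(ex$rank), ]
  unlist(lapply(seq_len(nrow(ex)), function(j) {
    p <- ex$start[j]:ex$end[j]
    if (g$strand == "-") rev(p) else p
  }))
}

# full-CDS retranslation oracle for a single SNV
oracle_consequence <- function(variant, models, reference, code = Biostrings::GENETIC_CODE) {
  hitg <- models$exons[models$exons$chrom == variant$chrom &
                         models$exons$start <= variant$pos &
                         models$exons$end >= variant$pos, "gene_id"]
  if (!length(hitg)) return(NULL)
  gid <- hitg[1]
  g <- models$genes[models$genes$gene_id == gid, ]
  gpos <- cds_positions(models, gid)
  base_at <- function(p) substring(reference[[variant$chrom]], p, p)
  cds <- paste(vapply(gpos, base_at, ""), collapse = "")
  if (g$strand == "-") cds <- chartr("ACGT", "TGCA", cds)
  i <- match(variant$pos, gpos)
  sub <- if (g$strand == "-") chartr("ACGT", "TGCA", variant$alt) else variant$alt
  mut <- cds; substr(mut, i, i) <- sub
  aa_ref <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]]
  aa_mut <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(mut), no.init.codon = TRUE)), "")[[1]]
  d <- which(aa_ref != aa_mut)
  if (!length(d)) {
    ci <- (i - 1) %/% 3 + 1
    return(list(consequence = "synonymous",
                protein_change = paste0(aa_ref[ci], ci, aa_ref[ci])))
  }
  ci <- d[1]
  cons <- if (aa_mut[ci] == "*") "nonsense" else "missense"
  list(consequence = cons, protein_change = paste0(aa_ref[ci], ci, aa_mut[ci]))
}

# independent per-rule predicate oracle for the site-filter cascade:
# each stage re-expressed directly from its definition
filter_stage_oracle <- function(v, ref, mask, cfg) {
  chrom_len <- vapply(ref, nchar, 0L)
  s <- v
  drop1 <- s$depth < cfg$min_depth | s$depth > cfg$max_depth
  s1 <- s[!drop1, ]
  drop2 <- s1$genotype == "het" & s1$alt_depth / s1$depth < cfg$min_allele_balance
  s2 <- s1[!drop2, ]
  drop3 <- !is.na(s2$alt_fwd) & s2$alt_depth >= 4 &
    abs(s2$alt_fwd - s2$alt_rev) / s2$alt_depth > cfg$max_strand_skew
  s3 <- s2[!drop3, ]
  drop4 <- vapply(seq_len(nrow(s3)), function(i) {
    if (!is.finite(cfg$homopolymer_min_run)) return(FALSE)
    lo <- max(1, s3$pos[i] - cfg$homopolymer_flank)
    hi <- min(chrom_len[[s3$chrom[i]]], s3$pos[i] + cfg$homopolymer_flank)
    r <- rle(strsplit(substring(ref[[s3$chrom[i]]], lo, hi), "")[[1]])
    any(r$lengths >= cfg$homopolymer_min_run)
  }, TRUE)
  s4 <- s3[!drop4, ]
  drop5 <- if (is.null(mask)) rep(FALSE, nrow(s4)) else
    vapply(seq_len(nrow(s4)), function(i)
      any(mask$chrom == s4$chrom[i] & s4$pos[i] > mask$start &
            s4$pos[i] <= mask$end), TRUE)
  s5 <- s4[!drop5, ]
  drop6 <- vapply(seq_len(nrow(s5)), function(i) {
    if (!is.finite(cfg$cluster_max_variants)) return(FALSE)
    same <- s5$pos[s5$chrom == s5$chrom[i]]
    # any window of cluster_window bp containing this variant with more than
    # cluster_max_variants variants; every such window can be slid so its
    # left edge sits on a variant at or before this one
    anchors <- same[same <= s5$pos[i] & same > s5$pos[i] - cfg$cluster_window]
    any(vapply(anchors, function(w0)
      s5$pos[i] <= w0 + cfg$cluster_window - 1 &&
        sum(same >= w0 & same <= w0 + cfg$cluster_window - 1) >
          cfg$cluster_max_variants, TRUE))
  }, TRUE)
  s6 <- s5[!drop6, ]
  list(removed = c(sum(drop1), sum(drop2), sum(drop3), sum(drop4), sum(drop5),
                   sum(drop6)),
       survivors = s6)
}

# base-level agreement between two diplotype segmentations
seg_accuracy <- function(truthseg, decoded) {
  tot <- 0; hit <- 0
  for (chrom in unique(truthseg$chrom)) {
    a <- truthseg[truthseg$chrom == chrom, ]
    b <- decoded[decoded$chrom == chrom, ]
    bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
    st <- bounds[-length(bounds)]; en <- bounds[-1]
    sa <- a$state[findInterval(st, a$start)]
    sb <- b$state[findInterval(st, b$start)]
    tot <- tot + sum(en - st)
    hit <- hit + sum((en - st)[sa == sb])
  }
  hit / tot
}

# one in-memory pipeline replicate on a shared genome; returns what the
# end-to-end checks need
run_replicate <- function(cfg, genome, seed) {
  cfg$seed <- seed
  truth <- simulate_pedigree(cfg, genome)
  obs <- emit_observed_vcf(truth)
  bl <- enumap:::emit_blacklist(truth)
  fc <- filter_cascade(obs, blacklists = bl,
                       reference = genome$reference,
                       config = if (is.null(genome$reference))
                         filter_config(homopolymer_min_run = Inf)
                       else filter_config())
  seg <- segment_genome(fc$variants, genome$chroms)
  mk <- emit_marker_table(truth)
  scan <- scan_markers(mk$markers, mk$phenotypes)
  cand <- if (!is.null(genome$reference))
    nominate_candidates(fc$variants, enumap:::genome_gene_models(genome),
                        genome$reference, ff_segments = seg$segments)
  else NULL
  w <- seg$windows
  ci <- which(w$chrom == truth$causal$chrom & w$start < truth$causal$pos &
                w$end >= truth$causal$pos)
  causal_lod <- scan$lod_max[scan$chrom == truth$causal$chrom &
                               scan$pos == truth$causal$pos]
  list(truth = truth, filtered = fc$variants, report = fc$report, seg = seg,
       scan = scan, cand = cand,
       ff_at_causal = seg$path[ci] == "FF",
       accuracy = seg_accuracy(truth$segments, seg$segments),
       causal_is_top = isTRUE(abs(causal_lod - max(scan$lod_max)) < 1e-9),
       causal_recovered = !is.null(cand) && nrow(cand) > 0 &&
         any(cand$chrom == truth$causal$chrom & cand$pos == truth$causal$pos))
}
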