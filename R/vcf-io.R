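# VCF ingestion. Parsing is delegated to vcfR; records are flattened to the
# per-alt data.frame of calls the rest of the pipeline consumes:
# chrom, pos, ref, alt, genotype (het/hom_alt), depth, alt_depth,
# alt_fwd, alt_rev (NA when the source lacks strand counts), qual.

#' Parse a VCF into a per-alt variant call table
#'
#' Reads a VCF v4.2 (as written by [emit_observed_vcf()] or any caller
#' emitting GT/AD/DP genotypes; the INFO field `SB=fwd,rev` is optional and
#' treated as strand-unknown when absent). Multi-allelic records are split
#' into one call per alternate allele.
#'
#' @param path VCF file.
#' @return data.frame of calls in file order with attributes `vcf_header`
#'   (the meta and header lines) and `n_records` (pre-split record count).
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  n_meta <- sum(startsWith(lines, "##"))
  header <- lines[seq_len(n_meta + 1L)]
  if (length(lines) < n_meta + 1L || !startsWith(lines[n_meta + 1L], "#CHROM"))
    stop("malformed VCF header: no #CHROM line (line ", n_meta + 1L, ")")
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(),
                      depth = integer(), alt_depth = integer(),
                      alt_fwd = integer(), alt_rev = integer(), qual = numeric())
  if (length(lines) == n_meta + 1L) {
    attr(empty, "vcf_header") <- header; attr(empty, "n_records") <- 0L
    return(empty)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad))
    stop("malformed VCF record at line ", n_meta + 1L + bad[1L],
         ": missing or non-numeric POS/REF/ALT")

  gt <- tryCatch(vcfR::extract.gt(v, "GT"), error = function(e) NULL)
  ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
  dp_fmt <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  info_sb <- vcfR::extract.info(v, "SB")

  if (!any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    # vectorized fast path: every record biallelic
    gt1 <- if (!is.null(gt)) gt[, 1L] else rep(NA_character_, n)
    ad1 <- if (!is.null(ad)) ad[, 1L] else rep(NA_character_, n)
    alt_depth <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad1)))
    depth <- if (!is.null(dp_fmt)) as.integer(dp_fmt[, 1L]) else rep(NA_integer_, n)
    depth <- ifelse(is.na(depth), as.integer(info_dp), depth)
    fwd <- suppressWarnings(as.integer(sub(",.*$", "", info_sb)))
    rev <- suppressWarnings(as.integer(sub("^[^,]*,", "", info_sb)))
    calls <- data.frame(
      chrom = fix[, "CHROM"], pos = pos, ref = fix[, "REF"], alt = fix[, "ALT"],
      genotype = ifelse(!is.na(gt1) & gt1 %in% c("1/1", "1|1"), "hom_alt", "het"),
      depth = depth, alt_depth = alt_depth, alt_fwd = fwd, alt_rev = rev,
      qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
    )
    for (chrom in unique(calls$chrom)) {
      p <- calls$pos[calls$chrom == chrom]
      if (is.unsorted(p)) { warning("VCF not position-sorted on ", chrom); break }
    }
    attr(calls, "vcf_header") <- header
    attr(calls, "n_records") <- n
    return(calls)
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    k <- length(alts)
    gti <- if (!is.null(gt)) gt[i, 1L] else NA_character_
    alleles <- if (!is.na(gti)) suppressWarnings(as.integer(strsplit(gti, "[/|]")[[1L]]))
               else integer()
    adi <- if (!is.null(ad) && !is.na(ad[i, 1L]))
      suppressWarnings(as.integer(strsplit(ad[i, 1L], ",", fixed = TRUE)[[1L]]))
    else NA_integer_
    depth_i <- if (!is.null(dp_fmt) && !is.na(dp_fmt[i, 1L])) dp_fmt[i, 1L]
               else if (!is.na(info_dp[i])) info_dp[i]
               else if (!anyNA(adi)) sum(adi) else NA_integer_
    sbi <- if (!is.na(info_sb[i]))
      suppressWarnings(as.integer(strsplit(info_sb[i], ",", fixed = TRUE)[[1L]]))
    else NA_integer_
    cnt <- if (length(alleles)) tabulate(alleles + 1L, nbins = k + 1L)[-1L]
           else rep(1L, k)
    genotype <- ifelse(cnt >= 2L, "hom_alt", "het")
    alt_depth <- if (!anyNA(adi) && length(adi) >= k + 1L) adi[1L + seq_len(k)]
                 else rep(NA_integer_, k)
    if (length(sbi) >= 2L * k && !anyNA(sbi)) {
      fwd <- sbi[2L * seq_len(k) - 1L]; rev <- sbi[2L * seq_len(k)]
    } else fwd <- rev <- rep(NA_integer_, k)
    out[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = pos[i],
      ref = unname(fix[i, "REF"]), alt = alts,
      genotype = genotype, depth = as.integer(depth_i), alt_depth = alt_depth,
      alt_fwd = fwd, alt_rev = rev,
      qual = suppressWarnings(as.numeric(unname(fix[i, "QUAL"])))
    )
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  for (chrom in unique(calls$chrom)) {
    p <- calls$pos[calls$chrom == chrom]
    if (is.unsorted(p)) {
      warning("VCF not position-sorted on ", chrom)
      break
    }
  }
  attr(calls, "vcf_header") <- header
  attr(calls, "n_records") <- n
  calls
}

#' Write a variant call table as VCF
#'
#' The inverse of [parse_vcf()] for the fields this pipeline carries;
#' `parse_vcf(write_vcf(x))` reproduces `x`.
#'
#' @param calls variant call data.frame.
#' @param path output path.
#' @param contigs optional data.frame (chrom, length) for contig header
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=enumap",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, as.integer(contigs$length)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=SB,Number=.,Type=Integer,Description=\"Per-strand alt read counts: fwd,rev\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sample"), collapse = "\t")
  )
  sb <- ifelse(is.na(calls$alt_fwd) | is.na(calls$alt_rev), "",
               sprintf(";SB=%d,%d", calls$alt_fwd, calls$alt_rev))
  rows <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d%s\tGT:AD:DP\t%s:%d,%d:%d",
    calls$chrom, calls$pos, calls$ref, calls$alt,
    ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE)),
    calls$depth, sb,
    ifelse(calls$genotype == "hom_alt", "1/1", "0/1"),
    calls$depth - calls$alt_depth, calls$alt_depth, calls$depth
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# blacklists: plain VCF or >= 4 column TSV with header chrom,pos,ref,alt
read_blacklist <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- parse_vcf(path)
    v[, c("chrom", "pos", "ref", "alt")]
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "integer", "character", "character"))
    names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
    df
  }
}

read_genome_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("chrom", "length") %in% names(df)))
  df
}
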