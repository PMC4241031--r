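# The variant-filter cascade: blacklist subtraction followed by six
# site-quality stages applied in a fixed order (depth, allele balance,
# strand skew, homopolymer context, repeat mask, local variant cluster),
# with per-stage accounting so the funnel is auditable.

#' Filter cascade configuration
#'
#' Thresholds for the site-quality stages. Any stage can be disabled:
#' `min_depth = 0` with `max_depth = Inf`, `min_allele_balance = 0`,
#' `max_strand_skew = 1`, `homopolymer_min_run = Inf`,
#' `cluster_max_variants = Inf`.
#'
#' @param min_depth,max_depth read-depth bounds (calls outside are removed).
#' @param min_allele_balance lower bound on alt_depth/depth for
#'   heterozygous calls.
#' @param max_strand_skew upper bound on |alt_fwd - alt_rev|/alt_depth;
#'   applied only to calls with alt_depth >= 4 and known strand counts.
#' @param homopolymer_min_run single-base run length in the reference that
#'   disqualifies a call when found within `homopolymer_flank` bp.
#' @param homopolymer_flank bases of reference context examined either side
#'   of the call.
#' @param cluster_window,cluster_max_variants every variant inside any
#'   window of `cluster_window` bp holding more than `cluster_max_variants`
#'   variants is removed (dense local variation is treated as unreliable).
#' @param blacklist_keys `"site"` to match known variants on
#'   (chrom, pos, ref, alt), `"position"` to match on (chrom, pos).
#' @return A validated list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 2, max_depth = 30,
                          min_allele_balance = 0.2,
                          max_strand_skew = 0.9,
                          homopolymer_min_run = 6, homopolymer_flank = 5,
                          cluster_window = 100, cluster_max_variants = 3,
                          blacklist_keys = c("site", "position")) {
  cfg <- list(min_depth = min_depth, max_depth = max_depth,
              min_allele_balance = min_allele_balance,
              max_strand_skew = max_strand_skew,
              homopolymer_min_run = homopolymer_min_run,
              homopolymer_flank = homopolymer_flank,
              cluster_window = cluster_window,
              cluster_max_variants = cluster_max_variants,
              blacklist_keys = match.arg(blacklist_keys))
  stopifnot(cfg$min_allele_balance >= 0, cfg$min_allele_balance <= 0.5,
            cfg$homopolymer_min_run >= 3, cfg$cluster_window > 0,
            cfg$min_depth >= 0, cfg$max_depth >= cfg$min_depth,
            cfg$max_strand_skew >= 0, cfg$max_strand_skew <= 1,
            cfg$homopolymer_flank >= 0, cfg$cluster_max_variants >= 0)
  class(cfg) <- "filter_config"
  cfg
}

variant_key <- function(df, mode) {
  if (mode == "site") paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  else paste(df$chrom, df$pos, sep = ":")
}

#' Subtract known variants (blacklists)
#'
#' Removes every call whose key appears in the union of the supplied
#' blacklists, mirroring subtraction of previously catalogued variation
#' (other mutagenesis pedigrees, dbSNP-style strain divergence).
#'
#' @param variants variant call data.frame (see [parse_vcf()]).
#' @param blacklists a data.frame, file path, or list of either (TSV with
#'   chrom/pos/ref/alt columns, or plain VCF).
#' @param keys `"site"` or `"position"` matching mode.
#' @return `list(variants, removed)`: surviving calls in input order and
#'   the removed count.
#' @export
subtract_known <- function(variants, blacklists, keys = "site") {
  if (is.data.frame(blacklists) || is.character(blacklists))
    blacklists <- list(blacklists)
  sets <- lapply(blacklists, function(b) {
    if (is.character(b)) b <- read_blacklist(b)
    variant_key(b, keys)
  })
  bad <- unique(unlist(sets))
  hit <- variant_key(variants, keys) %in% bad
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, removed = sum(hit))
}

as_reference_chars <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(out))
    reference <- out
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (is.null(attr(reference, "chrom_len")))
    attr(reference, "chrom_len") <- vapply(reference, nchar, 0L)
  reference
}

# chromosome lengths without rescanning multi-Mb strings per lookup
ref_lengths <- function(reference) {
  attr(reference, "chrom_len") %||% vapply(reference, nchar, 0L)
}

homopolymer_flag <- function(variants, reference, min_run, flank) {
  clen <- ref_lengths(reference)[variants$chrom]
  miss <- !(variants$chrom %in% names(reference)) |
    is.na(clen) | variants$pos > clen | variants$pos < 1
  if (any(miss)) {
    i <- which(miss)[1L]
    stop("variant position absent from reference: ", variants$chrom[i], ":",
         variants$pos[i])
  }
  lo <- pmax(variants$pos - flank, 1)
  hi <- pmin(variants$pos + flank, clen)
  ctx <- substring(reference[variants$chrom], lo, hi)
  grepl(sprintf("([ACGTNacgtn])\\1{%d,}", as.integer(min_run) - 1L), ctx)
}

repeat_flag <- function(variants, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, nrow(variants)))
  m <- GenomicRanges::GRanges(mask$chrom,
                              IRanges::IRanges(mask$start + 1L, mask$end))
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  IRanges::overlapsAny(v, m)
}

cluster_flag <- function(variants, window, max_variants) {
  flag <- rep(FALSE, nrow(variants))
  if (!is.finite(max_variants)) return(flag)
  for (chrom in unique(variants$chrom)) {
    idx <- which(variants$chrom == chrom)
    pos <- variants$pos[idx]
    o <- order(pos)
    p <- pos[o]
    # window anchored at each variant: variants within [p_a, p_a + window - 1]
    r <- findInterval(p + window - 1 + 0.5, p)
    dense <- which(r - seq_along(p) + 1L > max_variants)
    if (length(dense)) {
      mark <- logical(length(p))
      for (a in dense) mark[a:r[a]] <- TRUE
      flag[idx[o]] <- mark
    }
  }
  flag
}

#' Apply the site-quality filter stages
#'
#' Stages run in a fixed order — depth, allele balance, strand skew,
#' homopolymer context, repeat mask, local variant cluster — each seeing
#' only the survivors of the previous stage. The returned report satisfies
#' input = survivors + sum(removed).
#'
#' @param variants variant call data.frame.
#' @param reference reference sequence: FASTA path, `DNAStringSet`, or
#'   named character vector. May be NULL only when the homopolymer stage is
#'   disabled.
#' @param repeat_mask BED path or data.frame (chrom, start, end; 0-based
#'   half-open), or NULL for no mask.
#' @param config a [filter_config()].
#' @return `list(variants, report)` where report is a `filter_report`
#'   data.frame (stage, input, removed, surviving).
#' @export
site_filters <- function(variants, reference = NULL, repeat_mask = NULL,
                         config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (is.character(repeat_mask)) repeat_mask <- read_bed(repeat_mask)
  reference <- as_reference_chars(reference)

  stages <- list(
    depth = function(v) v$depth < config$min_depth | v$depth > config$max_depth,
    allele_balance = function(v)
      v$genotype == "het" & v$alt_depth / v$depth < config$min_allele_balance,
    strand_skew = function(v)
      !is.na(v$alt_fwd) & !is.na(v$alt_rev) & v$alt_depth >= 4 &
        abs(v$alt_fwd - v$alt_rev) / v$alt_depth > config$max_strand_skew,
    homopolymer = function(v) {
      if (!is.finite(config$homopolymer_min_run)) return(rep(FALSE, nrow(v)))
      if (is.null(reference))
        stop("homopolymer stage needs a reference (or disable it)")
      homopolymer_flag(v, reference, config$homopolymer_min_run,
                       config$homopolymer_flank)
    },
    repeat_mask = function(v) repeat_flag(v, repeat_mask),
    cluster = function(v)
      cluster_flag(v, config$cluster_window, config$cluster_max_variants)
  )

  report <- data.frame(stage = character(), input = integer(),
                       removed = integer(), surviving = integer())
  v <- variants
  for (s in names(stages)) {
    n_in <- nrow(v)
    drop <- stages[[s]](v)
    drop[is.na(drop)] <- FALSE
    v <- v[!drop, , drop = FALSE]
    report <- rbind(report, data.frame(stage = s, input = n_in,
                                       removed = sum(drop), surviving = nrow(v)))
  }
  rownames(v) <- NULL
  stopifnot(nrow(variants) == nrow(v) + sum(report$removed))
  class(report) <- c("filter_report", "data.frame")
  list(variants = v, report = report)
}

#' Run the complete filter cascade with accounting
#'
#' Blacklist subtraction followed by [site_filters()], reported as one
#' funnel.
#'
#' @inheritParams site_filters
#' @param blacklists as in [subtract_known()]; NULL for none.
#' @return `list(variants, report)`.
#' @export
filter_cascade <- function(variants, blacklists = NULL, reference = NULL,
                           repeat_mask = NULL, config = filter_config()) {
  n0 <- nrow(variants)
  removed_bl <- 0L
  if (!is.null(blacklists)) {
    s <- subtract_known(variants, blacklists, config$blacklist_keys)
    variants <- s$variants; removed_bl <- s$removed
  }
  sf <- site_filters(variants, reference, repeat_mask, config)
  report <- rbind(
    data.frame(stage = "blacklist", input = n0, removed = removed_bl,
               surviving = n0 - removed_bl),
    as.data.frame(sf$report)
  )
  class(report) <- c("filter_report", "data.frame")
  stopifnot(n0 == nrow(sf$variants) + sum(report$removed))
  list(variants = sf$variants, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("variant filter funnel:\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total: %d in, %d removed, %d surviving\n",
              x$input[1L], sum(x$removed), x$surviving[nrow(x)]))
  invisible(x)
}

write_filter_report <- function(report, dir, stem = "filter_report") {
  write.table(as.data.frame(report), file.path(dir, paste0(stem, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.data.frame(report),
                       file.path(dir, paste0(stem, ".json")),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(NULL)
}
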