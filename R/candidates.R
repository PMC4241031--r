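# Consequence annotation against toy gene models and nomination of
# homozygous protein-sense-affecting candidates inside the mapped region
# set (founder-homozygous segments and/or a linkage interval).

#' Read gene models from a GFF3 subset
#'
#' Accepts the GFF3 written by [write_genome_files()] or any file whose CDS
#' features carry a `gene_id` attribute (fallback: the transcript `Parent`
#' with a trailing `.t1` stripped).
#'
#' @param path GFF3 file.
#' @return `gene_models`: list with `genes` (gene_id, chrom, strand) and
#'   `exons` (gene_id, chrom, start, end, rank; 1-based inclusive, rank in
#'   transcript order).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", path)
  gid <- if (!is.null(cds$gene_id) && !anyNA(cds$gene_id)) as.character(cds$gene_id)
         else sub("\\.t[0-9]+$", "", vapply(cds$Parent, `[[`, "", 1L))
  ex <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds))
  )
  gene_models(ex)
}

#' Build gene models from a CDS exon table
#'
#' @param exons data.frame with gene_id, chrom, start, end (1-based
#'   inclusive) and strand per exon.
#' @return A `gene_models` list (see [read_gene_models()]).
#' @export
gene_models <- function(exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(exons)))
  exons <- exons[order(exons$gene_id, exons$start), ]
  rank <- unlist(lapply(split(exons, exons$gene_id), function(e) {
    k <- nrow(e)
    if (e$strand[1L] == "+") seq_len(k) else rev(seq_len(k))
  }), use.names = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), ]
  exons$rank <- rank
  genes <- exons[!duplicated(exons$gene_id), c("gene_id", "chrom", "strand")]
  len <- tapply(exons$end - exons$start + 1L, exons$gene_id, sum)
  if (any(len %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(names(len)[len %% 3L != 0L], collapse = ", "))
  structure(list(genes = genes, exons = exons[, c("gene_id", "chrom", "start",
                                                  "end", "rank")]),
            class = "gene_models")
}

# models from the simulator's genome object (avoids a GFF3 round trip)
genome_gene_models <- function(genome) {
  ex <- genome$exons
  ex$strand <- genome$genes$strand[match(ex$gene_id, genome$genes$gene_id)]
  gene_models(ex)
}

SPLICE_PAD <- 2L  # intronic bases flanking each CDS junction counted as splice

#' Classify the coding consequence of a single-nucleotide variant
#'
#' Inside a CDS the affected codon is translated before and after the
#' substitution (reverse-complemented for minus-strand genes):
#' `missense`, `nonsense` (new stop) or `synonymous`, labelled
#' refAA + codon index (1-based from the CDS start across spliced exons) +
#' altAA, stop written `*` (e.g. `C185Y`, `R92*`). Within 2 bp of a CDS
#' exon junction on the intron side the call is `splice`; everything else
#' is `noncoding`.
#'
#' @param variant one-row data.frame (chrom, pos, ref, alt); SNVs only.
#' @param models a `gene_models` object.
#' @param reference FASTA path, `DNAStringSet` or named character vector.
#' @return list: `consequence`, `protein_change` (NA unless coding),
#'   `gene_id` (NA if intergenic).
#' @export
classify_consequence <- function(variant, models, reference) {
  reference <- as_reference_chars(reference)
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L)
    stop("only single-nucleotide variants are supported (",
         variant$chrom, ":", variant$pos, " ", variant$ref, ">", variant$alt, ")")
  if (!variant$chrom %in% names(reference) ||
      variant$pos > ref_lengths(reference)[[variant$chrom]])
    stop("variant position absent from reference: ",
         variant$chrom, ":", variant$pos)
  refb <- ref_base(reference, variant$chrom, variant$pos)
  if (refb != variant$ref)
    stop("REF allele mismatch at ", variant$chrom, ":", variant$pos,
         " (VCF ", variant$ref, ", reference ", refb, ")")

  ex <- models$exons[models$exons$chrom == variant$chrom, ]
  hit <- ex[ex$start <= variant$pos & variant$pos <= ex$end, ]
  if (nrow(hit)) {
    gid <- hit$gene_id[1L]
    g <- models$genes[models$genes$gene_id == gid, ]
    ge <- models$exons[models$exons$gene_id == gid, ]
    ge <- ge[order(ge$rank), ]
    elen <- ge$end - ge$start + 1L
    before <- c(0L, cumsum(elen))[match(hit$rank[1L], ge$rank)]
    off <- if (g$strand == "+") variant$pos - hit$start[1L]
           else hit$end[1L] - variant$pos
    cds_pos <- before + off + 1L
    codon_i <- (cds_pos - 1L) %/% 3L + 1L
    frame <- (cds_pos - 1L) %% 3L + 1L
    codon_pos <- (codon_i - 1L) * 3L + 1:3
    gpos <- vapply(codon_pos, function(p) cds_to_genomic_models(g, ge, p), 0)
    bases <- ref_base(reference, variant$chrom, gpos)
    if (g$strand == "-") bases <- revcomp(bases)
    codon <- paste(bases, collapse = "")
    sub_base <- if (g$strand == "+") variant$alt else revcomp(variant$alt)
    mut <- codon
    substr(mut, frame, frame) <- sub_base
    code <- Biostrings::GENETIC_CODE
    aa_ref <- code[[codon]]; aa_alt <- code[[mut]]
    consequence <- if (aa_alt == "*" && aa_ref != "*") "nonsense"
                   else if (aa_alt == aa_ref) "synonymous" else "missense"
    return(list(consequence = consequence,
                protein_change = paste0(aa_ref, codon_i, aa_alt),
                gene_id = gid))
  }

  # intronic splice window: within SPLICE_PAD bases of a CDS junction,
  # internal junctions only
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, ]
    ge <- ge[order(ge$start), ]
    if (nrow(ge) < 2L) next
    donors <- ge$end[-nrow(ge)]      # intron starts at donor + 1
    acceptors <- ge$start[-1L]       # intron ends at acceptor - 1
    in_splice <- any(variant$pos >= donors + 1L & variant$pos <= donors + SPLICE_PAD) ||
      any(variant$pos <= acceptors - 1L & variant$pos >= acceptors - SPLICE_PAD)
    if (in_splice)
      return(list(consequence = "splice", protein_change = NA_character_,
                  gene_id = gid))
  }
  list(consequence = "noncoding", protein_change = NA_character_,
       gene_id = NA_character_)
}

cds_to_genomic_models <- function(g, ge_ranked, cds_pos) {
  elen <- ge_ranked$end - ge_ranked$start + 1L
  cum <- cumsum(elen)
  j <- which(cds_pos <= cum)[1L]
  off <- cds_pos - c(0L, cum)[j] - 1L
  if (g$strand == "+") ge_ranked$start[j] + off else ge_ranked$end[j] - off
}

in_regions <- function(variants, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, nrow(variants)))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  IRanges::overlapsAny(v, r)
}

#' Nominate candidate causal mutations
#'
#' A variant is a candidate when it is (a) homozygous (unless `zygosity`
#' admits heterozygotes), (b) protein-sense-affecting (missense, nonsense
#' or splice), and (c) inside the region set: the founder-homozygous
#' segments, the linkage region, or their intersection when both are given
#' (a recessive causal mutation must be homozygous founder-derived and lie
#' under the linkage peak).
#'
#' @param variants filtered variant call data.frame.
#' @param models `gene_models`.
#' @param reference FASTA path, `DNAStringSet` or named character vector.
#' @param ff_segments data.frame/BED path of founder-homozygous segments
#'   (chrom, start, end, 0-based half-open; rows with other state labels in
#'   a `name`/`state` column are ignored), or NULL.
#' @param linkage_region data.frame/BED path (chrom, start, end), or NULL.
#' @param zygosity `"hom_alt"` (default) or `"any"`.
#' @return data.frame of candidates sorted by chrom, pos: chrom, pos, ref,
#'   alt, genotype, gene_id, consequence, protein_change, in_FF_segment,
#'   in_linkage_region.
#' @export
nominate_candidates <- function(variants, models, reference,
                                ff_segments = NULL, linkage_region = NULL,
                                zygosity = c("hom_alt", "any")) {
  zygosity <- match.arg(zygosity)
  reference <- as_reference_chars(reference)
  if (is.character(ff_segments)) ff_segments <- read_bed(ff_segments)
  if (is.character(linkage_region)) linkage_region <- read_bed(linkage_region)
  if (is.null(ff_segments) && is.null(linkage_region))
    stop("provide founder-homozygous segments and/or a linkage region")
  state_col <- intersect(c("state", "name"), names(ff_segments))[1L]
  if (!is.null(ff_segments) && !is.na(state_col))
    ff_segments <- ff_segments[ff_segments[[state_col]] %in% c("FF", "."), ]

  in_ff <- in_regions(variants, ff_segments)
  in_link <- in_regions(variants, linkage_region)
  in_set <- if (!is.null(ff_segments) && !is.null(linkage_region)) in_ff & in_link
            else if (!is.null(ff_segments)) in_ff else in_link
  if (!any(in_set)) {
    warning("region set contains no variants; no candidates")
  }
  keep <- in_set & (zygosity == "any" | variants$genotype == "hom_alt")
  v <- variants[keep, , drop = FALSE]
  v$in_FF_segment <- in_ff[keep]
  v$in_linkage_region <- in_link[keep]
  if (nrow(v)) {
    cons <- lapply(seq_len(nrow(v)), function(i)
      classify_consequence(v[i, ], models, reference))
    v$gene_id <- vapply(cons, `[[`, "", "gene_id")
    v$consequence <- vapply(cons, `[[`, "", "consequence")
    v$protein_change <- vapply(cons, function(x) x$protein_change %||% NA_character_,
                               NA_character_)
    v <- v[v$consequence %in% c("missense", "nonsense", "splice"), , drop = FALSE]
  } else {
    v$gene_id <- character(); v$consequence <- character()
    v$protein_change <- character()
  }
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Assemble the variant funnel report
#'
#' Machine-readable summary of the counts at every stage from raw calls to
#' final candidates, mirroring how a mapping-by-sequencing analysis is
#' reported.
#'
#' @param filter_report a `filter_report` from [filter_cascade()].
#' @param n_in_region variants inside the region set.
#' @param candidates candidate data.frame from [nominate_candidates()].
#' @param segmentation optional `segmentation` for per-state totals.
#' @param scan optional `linkage_scan` for the top marker.
#' @param dir if non-NULL, write `report.json` and `funnel.tsv` there.
#' @return list with `funnel` data.frame and summary fields.
#' @export
rank_report <- function(filter_report, n_in_region, candidates,
                        segmentation = NULL, scan = NULL, dir = NULL) {
  funnel <- data.frame(
    stage = c("total_called", "post_blacklist", "post_site_filters",
              "in_region", "protein_sense_hom"),
    count = c(filter_report$input[1L],
              if (any(filter_report$stage == "blacklist"))
                filter_report$surviving[filter_report$stage == "blacklist"][1L]
              else filter_report$input[1L],
              filter_report$surviving[nrow(filter_report)],
              n_in_region, nrow(candidates))
  )
  out <- list(funnel = funnel, candidates = candidates)
  if (!is.null(segmentation)) {
    out$bp_per_state <- segmentation$bp_per_state
    out$ff_mb <- unname(segmentation$bp_per_state[["FF"]] / 1e6)
  }
  if (!is.null(scan)) {
    top <- as.data.frame(scan)[which.max(scan$lod_max), ]
    out$top_marker <- list(marker_id = top$marker_id, chrom = top$chrom,
                           pos = top$pos, lod_max = top$lod_max,
                           theta_hat = top$theta_hat)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(funnel, file.path(dir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    json <- out
    json$candidates <- candidates
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  out
}
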