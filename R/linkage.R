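# Two-point LOD linkage for a fully penetrant recessive trait in a
# coupling-phase intercross. B denotes the founder/B6 allele (in coupling
# with the causal mutation), C the CBA allele. Affected mice are m/m, so
# P(BB) = (1-theta)^2, P(BC) = 2 theta (1-theta), P(CC) = theta^2;
# unaffected mice are the complementary mixture of +/+ and m/+ classes,
# P(geno | unaffected) = (P(geno) - P(geno | affected)/4) / (3/4).

GENO_CLASSES <- c("BB", "BC", "CC")

geno_probs <- function(theta) {
  aff <- cbind(BB = (1 - theta)^2, BC = 2 * theta * (1 - theta), CC = theta^2)
  una <- cbind(BB = (1 - (1 - theta)^2) / 3,
               BC = (2 - 2 * theta * (1 - theta)) / 3,
               CC = (1 - theta^2) / 3)
  list(affected = aff, unaffected = una)
}

as_marker_obs <- function(x) {
  need <- c("nBB", "nBC", "nCC", "uBB", "uBC", "uCC")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("marker observation lacks counts: ",
                         paste(miss, collapse = ", "))
  counts <- as.numeric(x[need])
  if (any(counts < 0)) stop("negative genotype counts")
  if (sum(counts) == 0) stop("marker observation contains no mice")
  setNames(counts, need)
}

#' Two-point LOD score at a fixed recombination fraction
#'
#' `LOD(theta) = sum over genotype-by-phenotype classes of
#' count * log10(P(geno | pheno, theta) / P(geno | pheno, 0.5))`. Classes
#' with a zero count contribute 0 even where the class probability is 0, so
#' `LOD(0)` is finite for fully consistent markers and `-Inf` as soon as a
#' recombinant genotype is observed.
#'
#' @param obs named counts `nBB, nBC, nCC` (affected) and `uBB, uBC, uCC`
#'   (unaffected); a one-row data.frame or named vector/list.
#' @param theta recombination fraction in `[0, 0.5]`.
#' @return LOD score (log10 units); exactly 0 at `theta = 0.5`.
#' @export
#' @examples
#' lod_at_theta(c(nBB = 10, nBC = 0, nCC = 0, uBB = 0, uBC = 0, uCC = 0), 0)
lod_at_theta <- function(obs, theta) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  counts <- as_marker_obs(obs)
  p <- geno_probs(theta)
  p0 <- geno_probs(0.5)
  probs <- c(p$affected[1, ], p$unaffected[1, ])
  null <- c(p0$affected[1, ], p0$unaffected[1, ])
  terms <- ifelse(counts == 0, 0, counts * (log10(probs) - log10(null)))
  sum(terms)
}

#' Maximal LOD over a recombination-fraction grid
#'
#' Evaluates the LOD curve on a grid over `[0, 0.5)` (plus the
#' `theta = 0.5` anchor, where the LOD is 0 by construction) and returns
#' the maximum; grid ties break toward smaller theta.
#'
#' @inheritParams lod_at_theta
#' @param step grid step.
#' @return list (class `linkage_result`): `theta_hat`, `lod_max`,
#'   `lod_curve` (data.frame theta, lod).
#' @export
max_lod <- function(obs, step = 0.001) {
  grid <- unique(c(seq(0, 0.5, by = step), 0.5))
  lod <- vapply(grid, function(t) lod_at_theta(obs, t), 0)
  i <- which.max(lod)
  structure(list(theta_hat = grid[i], lod_max = lod[i],
                 lod_curve = data.frame(theta = grid, lod = lod)),
            class = "linkage_result")
}

marker_counts <- function(markers, phenotypes) {
  orphan <- setdiff(unique(markers$mouse_id), phenotypes$mouse_id)
  if (length(orphan))
    stop("marker rows reference mice without phenotypes: ",
         paste(orphan, collapse = ", "))
  aff <- phenotypes$affected[match(markers$mouse_id, phenotypes$mouse_id)]
  key <- interaction(markers$marker_id, factor(markers$genotype, GENO_CLASSES),
                     factor(ifelse(aff, "n", "u"), c("n", "u")), drop = FALSE)
  tab <- table(key)
  ids <- unique(markers$marker_id)
  out <- data.frame(marker_id = ids)
  for (ph in c("n", "u")) for (g in GENO_CLASSES)
    out[[paste0(ph, g)]] <- as.integer(tab[paste(ids, g, ph, sep = ".")])
  pos <- markers[!duplicated(markers$marker_id), c("marker_id", "chrom", "pos")]
  out <- merge(pos, out, by = "marker_id", sort = FALSE)
  out[order(out$chrom, out$pos), ]
}

#' Scan a marker panel for linkage to the phenotype
#'
#' Computes genotype-by-phenotype counts per marker, maximizes the LOD over
#' the theta grid, and flags fully consistent markers. With the default
#' consistency rule a marker is fully consistent when every affected mouse
#' is BB and no unaffected mouse is BB; `consistency = "affected_only"`
#' drops the unaffected clause.
#'
#' On the grid, classes with probability 0 are clamped to a large negative
#' log-likelihood rather than `-Inf`, so markers with recombinants simply
#' never attain their maximum at theta = 0.
#'
#' @param markers long-format marker table (mouse_id, marker_id, chrom,
#'   pos, genotype in BB/BC/CC) or path to such a TSV.
#' @param phenotypes data.frame (mouse_id, affected) or path to a TSV.
#' @param step theta grid step.
#' @param use_unaffected include unaffected mice in the likelihood?
#' @param consistency `"both"` (default) or `"affected_only"`.
#' @return data.frame (class `linkage_scan`): marker_id, chrom, pos,
#'   genotype-by-phenotype counts, theta_hat, lod_max, fully_consistent.
#' @export
scan_markers <- function(markers, phenotypes, step = 0.001,
                         use_unaffected = TRUE,
                         consistency = c("both", "affected_only")) {
  consistency <- match.arg(consistency)
  if (is.character(markers)) markers <- read.table(markers, header = TRUE, sep = "\t")
  if (is.character(phenotypes))
    phenotypes <- read.table(phenotypes, header = TRUE, sep = "\t")
  obs <- marker_counts(markers, phenotypes)
  cnt <- as.matrix(obs[, c("nBB", "nBC", "nCC", "uBB", "uBC", "uCC")])
  if (!use_unaffected) cnt[, c("uBB", "uBC", "uCC")] <- 0L

  grid <- unique(c(seq(0, 0.5, by = step), 0.5))
  p <- geno_probs(grid); p0 <- geno_probs(0.5)
  logratio <- cbind(log10(p$affected) - rep(log10(p0$affected[1, ]), each = length(grid)),
                    log10(p$unaffected) - rep(log10(p0$unaffected[1, ]), each = length(grid)))
  logratio[!is.finite(logratio)] <- -1e12  # theta = 0 zero-probability classes
  lod <- cnt %*% t(logratio)               # markers x grid
  i <- apply(lod, 1L, which.max)           # ties break toward smaller theta
  obs$theta_hat <- grid[i]
  obs$lod_max <- lod[cbind(seq_len(nrow(obs)), i)]
  obs$fully_consistent <- obs$nBC == 0 & obs$nCC == 0 &
    (if (consistency == "both" && use_unaffected) obs$uBB == 0 else TRUE)
  class(obs) <- c("linkage_scan", "data.frame")
  obs
}

#' Linkage region bracketed by non-consistent markers
#'
#' The mapped interval runs from the nearest non-consistent marker to the
#' left of the leftmost fully consistent marker to the nearest one on the
#' right of the rightmost, with open ends clipped to the chromosome bounds.
#'
#' @param scan a [scan_markers()] result restricted to (or filtered for)
#'   one chromosome.
#' @param chrom chromosome to use (required if `scan` spans several).
#' @param chrom_length chromosome length, bp, for clipping open ends;
#'   defaults to the largest marker position.
#' @return data.frame (chrom, start, end), 0-based half-open bp; zero rows
#'   when no marker is fully consistent.
#' @export
consistent_region <- function(scan, chrom = NULL, chrom_length = NULL) {
  if (is.null(chrom)) {
    stopifnot(length(unique(scan$chrom)) == 1L)
    chrom <- scan$chrom[1L]
  }
  s <- scan[scan$chrom == chrom, ]
  s <- s[order(s$pos), ]
  if (!any(s$fully_consistent))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  chrom_length <- chrom_length %||% max(s$pos)
  lo <- min(s$pos[s$fully_consistent])
  hi <- max(s$pos[s$fully_consistent])
  left <- s$pos[!s$fully_consistent & s$pos < lo]
  right <- s$pos[!s$fully_consistent & s$pos > hi]
  data.frame(chrom = chrom,
             start = if (length(left)) max(left) else 0,
             end = if (length(right)) min(right) else chrom_length)
}

write_linkage <- function(scan, dir) {
  write.table(
    as.data.frame(scan)[, c("marker_id", "chrom", "pos", "theta_hat",
                            "lod_max", "fully_consistent")],
    file.path(dir, "linkage.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}
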