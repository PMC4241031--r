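# Three-state diplotype-ancestry HMM. States CC (CBA/CBA), CF
# (CBA/founder), FF (founder/founder) emit per-window homozygous and
# heterozygous variant counts as independent Poissons. CBA-derived
# segments are dense in strain SNPs (homozygous in CC, heterozygous in
# CF); founder-derived segments carry only sparse ENU mutations, so FF
# windows show a much lower homozygous density than CC windows — the
# contrast the decoder exploits. Transitions are uniform: stay with
# probability 1 - rho per window boundary, switch rho/2 to each other
# state. All arithmetic is in log space.

#' HMM parameters for ancestry segmentation
#'
#' @param lambda_hom,lambda_het named numeric vectors of per-window Poisson
#'   means for homozygous and heterozygous variant counts, one entry per
#'   state CC, CF, FF.
#' @param rho switch probability per window boundary.
#' @param pi initial state distribution (CC, CF, FF).
#' @return A list of class `hmm_params`.
#' @export
#' @examples
#' hmm_params(lambda_hom = c(CC = 125, CF = 12, FF = 0.3),
#'            lambda_het = c(CC = 0.5, CF = 110, FF = 0.3), rho = 0.01)
hmm_params <- function(lambda_hom, lambda_het, rho,
                       pi = c(CC = 0.25, CF = 0.5, FF = 0.25)) {
  lambda_hom <- lambda_hom[DIPLOTYPE_STATES]
  lambda_het <- lambda_het[DIPLOTYPE_STATES]
  pi <- pi[DIPLOTYPE_STATES]
  stopifnot(!anyNA(lambda_hom), !anyNA(lambda_het), all(lambda_hom >= 0),
            all(lambda_het >= 0), rho >= 0, rho <= 1,
            abs(sum(pi) - 1) < 1e-9, all(pi >= 0))
  if (!(lambda_hom[["CC"]] > lambda_hom[["FF"]] &&
        lambda_het[["CF"]] > lambda_het[["CC"]] &&
        lambda_het[["CF"]] > lambda_het[["FF"]]))
    warning("emission rates violate the expected density ordering ",
            "(hom: CC > FF; het: CF highest)")
  structure(list(states = DIPLOTYPE_STATES, lambda_hom = lambda_hom,
                 lambda_het = lambda_het, rho = rho, pi = pi),
            class = "hmm_params")
}

# default switch probability from the genetic map: 2 haplotypes x
# n_meioses x cm_per_mb recombination per window
default_rho <- function(cm_per_mb, n_meioses, window_bp) {
  min(1, 2 * n_meioses * (cm_per_mb / 100) * (window_bp / 1e6))
}

log_trans <- function(rho) {
  m <- matrix(log(rho / 2), 3L, 3L)
  diag(m) <- log(1 - rho)
  if (rho == 0) { m[!diag(3) == 1] <- -Inf; diag(m) <- 0 }
  dimnames(m) <- list(DIPLOTYPE_STATES, DIPLOTYPE_STATES)
  m
}

#' Bin variant calls into windows of hom/het counts
#'
#' @param variants variant call data.frame (needs chrom, pos, genotype).
#' @param genome_layout data.frame (chrom, length) or path to such a TSV.
#' @param window window width, bp (>= 1 kb); the final window of each
#'   chromosome may be shorter.
#' @return data.frame (chrom, win, start, end, n_hom, n_het), windows
#'   tiling every chromosome in order (0-based half-open).
#' @export
bin_variants <- function(variants, genome_layout, window = 250000) {
  stopifnot(window >= 1000)
  if (is.character(genome_layout)) genome_layout <- read_genome_tsv(genome_layout)
  out <- vector("list", nrow(genome_layout))
  for (i in seq_len(nrow(genome_layout))) {
    chrom <- genome_layout$chrom[i]
    len <- genome_layout$length[i]
    v <- variants[variants$chrom == chrom, ]
    if (nrow(v) && any(v$pos > len | v$pos < 1))
      stop("variant beyond chromosome end on ", chrom)
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    w <- findInterval(v$pos - 1L, starts)
    n_hom <- tabulate(w[v$genotype == "hom_alt"], nbins = length(starts))
    n_het <- tabulate(w[v$genotype != "hom_alt"], nbins = length(starts))
    out[[i]] <- data.frame(chrom = chrom, win = seq_along(starts) - 1L,
                           start = starts, end = ends,
                           n_hom = n_hom, n_het = n_het)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Emission log-likelihood of one window's counts under one state
#'
#' `log P = logPois(n_hom; lambda_hom[s]) + logPois(n_het; lambda_het[s])`.
#' A zero rate with a positive count yields `-Inf` (representable, not an
#' error).
#'
#' @param counts list/row with `n_hom`, `n_het`.
#' @param state one of CC, CF, FF.
#' @param params an [hmm_params()].
#' @return log probability.
#' @export
emission_loglik <- function(counts, state, params) {
  stopifnot(state %in% params$states)
  dpois(counts$n_hom, params$lambda_hom[[state]], log = TRUE) +
    dpois(counts$n_het, params$lambda_het[[state]], log = TRUE)
}

# emissions matrix: states x windows
emission_matrix <- function(windows, params) {
  m <- vapply(params$states, function(s)
    dpois(windows$n_hom, params$lambda_hom[[s]], log = TRUE) +
      dpois(windows$n_het, params$lambda_het[[s]], log = TRUE),
    numeric(nrow(windows)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, params$states))
  t(m)
}

#' Viterbi decoding of one chromosome's windows
#'
#' Returns the maximum-probability state path; ties at each backtrace step
#' break toward the earlier state in the order CC < CF < FF.
#'
#' @param windows window counts for a single chromosome, in order.
#' @param params an [hmm_params()].
#' @return character vector of states, one per window (empty for an empty
#'   chromosome).
#' @export
viterbi <- function(windows, params) {
  n <- nrow(windows)
  if (n == 0L) return(character())
  e <- emission_matrix(windows, params)
  tr <- log_trans(params$rho)
  delta <- log(params$pi) + e[, 1L]
  back <- matrix(1L, 3L, n)
  if (n > 1L) for (t in 2:n) {
    cand <- delta + tr  # cand[i, j]: from state i into state j
    best <- apply(cand, 2L, which.max)
    back[, t] <- best
    delta <- cand[cbind(best, 1:3)] + e[, t]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in n:2) path[t - 1L] <- back[path[t], t]
  params$states[path]
}

#' Forward log-likelihood of one chromosome's windows
#'
#' Standard forward recursion in log space; always at least the log
#' probability of the Viterbi path.
#'
#' @inheritParams viterbi
#' @return total log-likelihood (a scalar).
#' @export
forward_loglik <- function(windows, params) {
  n <- nrow(windows)
  if (n == 0L) return(0)
  e <- emission_matrix(windows, params)
  tr <- log_trans(params$rho)
  a <- log(params$pi) + e[, 1L]
  if (n > 1L) for (t in 2:n) {
    a <- apply(a + tr, 2L, logsumexp) + e[, t]
  }
  logsumexp(a)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# forward-backward posteriors: windows x states
posterior_matrix <- function(windows, params) {
  n <- nrow(windows)
  e <- emission_matrix(windows, params)
  tr <- log_trans(params$rho)
  a <- matrix(-Inf, 3L, n); b <- matrix(0, 3L, n)
  a[, 1L] <- log(params$pi) + e[, 1L]
  if (n > 1L) {
    for (t in 2:n) a[, t] <- apply(a[, t - 1L] + tr, 2L, logsumexp) + e[, t]
    for (t in (n - 1L):1L)
      b[, t] <- apply(t(tr) + e[, t + 1L] + b[, t + 1L], 2L, logsumexp)
  }
  g <- a + b
  g <- exp(t(g) - apply(g, 2L, logsumexp))
  colnames(g) <- params$states
  g
}

#' Merge a decoded state path into ancestry segments
#'
#' @param path state vector, one entry per window.
#' @param windows the matching window table (single chromosome or
#'   multi-chromosome with matching row order).
#' @return data.frame (chrom, start, end, state): maximal runs of identical
#'   states, 0-based half-open.
#' @export
segments_from_path <- function(path, windows) {
  if (length(path) != nrow(windows))
    stop("path length (", length(path), ") does not match window count (",
         nrow(windows), ")")
  if (length(path) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character()))
  df <- data.frame(chrom = windows$chrom, start = windows$start,
                   end = windows$end, state = path)
  out <- do.call(rbind, lapply(split(df, df$chrom), merge_runs, label = "state"))
  out <- out[order(match(out$chrom, unique(windows$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Estimate emission rates from the windowed counts
#'
#' Fits a three-component mixture of independent Poisson pairs to the
#' genome-wide (n_hom, n_het) histogram by EM (deterministic quantile
#' initialization, at most `max_iter` iterations, stopping when the
#' log-likelihood improves by less than `tol`), then labels the components:
#' the highest homozygous rate is CC, the highest heterozygous rate among
#' the rest is CF, the remainder FF.
#'
#' @param windows window count table from [bin_variants()].
#' @param rho switch probability to store in the returned parameters.
#' @param max_iter,tol EM controls.
#' @return An [hmm_params()].
#' @export
fit_hmm_params <- function(windows, rho, max_iter = 500L, tol = 1e-6) {
  x <- windows$n_hom; y <- windows$n_het
  n <- length(x)
  stopifnot(n >= 3L)
  # The estimator leans on the model structure rather than blind
  # clustering, because any of the three states can be absent from a small
  # genome (a fully founder-derived chromosome set has no CC or CF
  # windows) and an unconstrained mixture then relabels states.
  #
  # Strain-SNP density per window sets the scale s: CC windows carry it as
  # homozygous counts, CF windows as heterozygous counts. Windows are
  # hard-assigned to the nearest structural template in log1p space —
  # CC ~ (s, 0), CF ~ (0.1 s, s) (allele dropout turns a fraction of CF
  # hets into homs), FF ~ (0, 0) — giving method-of-moments rates per
  # state, with the template itself standing in for a state that has no
  # windows. EM then refines the fit only while it preserves the
  # template correspondence.
  s <- max(quantile(x, 0.98, names = FALSE), quantile(y, 0.98, names = FALSE))
  lx <- log1p(x); ly <- log1p(y)
  if (s < 5) {
    # no strain-dense cluster anywhere: the genome is founder-derived
    assign0 <- rep(3L, n)
    s <- max(5, s)
  } else {
    centers <- rbind(CC = c(log1p(s), 0),
                     CF = c(log1p(0.1 * s), log1p(s)),
                     FF = c(0, 0))
    d <- sapply(1:3, function(j) (lx - centers[j, 1])^2 + (ly - centers[j, 2])^2)
    assign0 <- max.col(-matrix(d, ncol = 3), ties.method = "first")
  }
  template_lh <- c(s, 0.1 * s, 1e-4)
  template_lt <- c(1e-4, s, 1e-4)
  lh <- lt <- mix <- numeric(3)
  for (j in 1:3) {
    sel <- assign0 == j
    lh[j] <- if (sum(sel) >= 3) mean(x[sel]) else template_lh[j]
    lt[j] <- if (sum(sel) >= 3) mean(y[sel]) else template_lt[j]
    mix[j] <- mean(sel)
  }
  lh <- pmax(lh, 1e-4); lt <- pmax(lt, 1e-4)
  mix <- pmax(mix, 1e-3); mix <- mix / sum(mix)
  moments <- list(lh = lh, lt = lt, mix = mix)

  if (all(mix >= 0.02)) {
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      lg <- vapply(1:3, function(j)
        dpois(x, lh[j], log = TRUE) + dpois(y, lt[j], log = TRUE) + log(mix[j]),
        numeric(n))
      m <- apply(lg, 1L, max)
      w <- exp(lg - m)
      rs <- rowSums(w)
      ll <- sum(m + log(rs))
      w <- w / rs
      ws <- colSums(w)
      lh <- pmax(colSums(w * x) / ws, 1e-4)
      lt <- pmax(colSums(w * y) / ws, 1e-4)
      mix <- ws / n
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    # accept the refinement only if each component is still nearest its own
    # structural template; otherwise keep the supervised moments
    centers <- rbind(c(log1p(s), 0), c(log1p(0.1 * s), log1p(s)), c(0, 0))
    nearest <- vapply(1:3, function(j)
      which.min((log1p(lh[j]) - centers[, 1])^2 +
                  (log1p(lt[j]) - centers[, 2])^2), 0L)
    if (!identical(nearest, 1:3)) {
      lh <- moments$lh; lt <- moments$lt; mix <- moments$mix
    }
  }
  hmm_params(
    lambda_hom = setNames(lh, DIPLOTYPE_STATES),
    lambda_het = setNames(lt, DIPLOTYPE_STATES),
    rho = rho,
    pi = setNames(pmax(mix, 1e-6) / sum(pmax(mix, 1e-6)), DIPLOTYPE_STATES)
  )
}

#' Segment a genome into diplotype-ancestry states
#'
#' Bins the filtered variants, obtains emission parameters (supplied or
#' estimated with [fit_hmm_params()]), decodes each chromosome
#' independently by Viterbi, and reports segments, per-state totals and
#' per-window posteriors.
#'
#' @param variants filtered variant call data.frame.
#' @param genome_layout data.frame (chrom, length) or TSV path.
#' @param window window width, bp.
#' @param params an [hmm_params()], or NULL to estimate from the data.
#' @param rho switch probability used when estimating (default 0.01 per
#'   250 kb window, scaled to `window`).
#' @return list of class `segmentation` with `segments`, `bp_per_state`
#'   (named total bp), `posterior` (window table with per-state posterior
#'   columns), `path`, `windows`, `params`.
#' @export
segment_genome <- function(variants, genome_layout, window = 250000,
                           params = NULL, rho = NULL) {
  if (is.character(genome_layout)) genome_layout <- read_genome_tsv(genome_layout)
  windows <- bin_variants(variants, genome_layout, window)
  rho <- rho %||% default_rho(cm_per_mb = 0.5, n_meioses = 4, window_bp = window)
  if (is.null(params)) params <- fit_hmm_params(windows, rho = rho)
  chroms <- genome_layout$chrom
  path <- character(nrow(windows))
  post <- matrix(NA_real_, nrow(windows), 3L,
                 dimnames = list(NULL, DIPLOTYPE_STATES))
  for (chrom in chroms) {
    i <- which(windows$chrom == chrom)
    if (!length(i)) next
    path[i] <- viterbi(windows[i, ], params)
    post[i, ] <- posterior_matrix(windows[i, ], params)
  }
  segments <- segments_from_path(path, windows)
  bp <- vapply(DIPLOTYPE_STATES, function(s)
    sum(segments$end[segments$state == s] - segments$start[segments$state == s]), 0)
  posterior <- cbind(windows, as.data.frame(post))
  structure(list(segments = segments, bp_per_state = bp, posterior = posterior,
                 path = path, windows = windows, params = params),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  mb <- x$bp_per_state / 1e6
  cat("ancestry segmentation:", nrow(x$segments), "segments\n")
  cat(sprintf("  %s: %.1f Mb\n", names(mb), mb), sep = "")
  cat(sprintf("founder-homozygous (FF) total: %.1f Mb\n", mb[["FF"]]))
  invisible(x)
}

write_segmentation <- function(seg, dir) {
  write.table(seg$windows, file.path(dir, "window_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(seg$posterior, file.path(dir, "posteriors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(seg$segments, file.path(dir, "segments.bed"),
            name = seg$segments$state)
  jsonlite::write_json(
    list(bp_per_state = as.list(seg$bp_per_state),
         ff_mb = unname(seg$bp_per_state[["FF"]] / 1e6)),
    file.path(dir, "segmentation_summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(NULL)
}
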