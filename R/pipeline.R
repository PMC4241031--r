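# End-to-end orchestration: simulate -> filter -> linkage -> segment ->
# candidates, driven by one YAML/JSON config and one global seed. Each
# stage reads its inputs from the artifact directory files written by the
# previous stage, so any stage can be rerun in isolation and `run` is
# byte-identical to chaining the stage commands.

#' Validate a pipeline run configuration
#'
#' Accepts a YAML/JSON path or a list with optional sections `simulate`
#' (fields of [sim_config()]), `filter` (fields of [filter_config()]),
#' `hmm` (`window`, `rho`, optional `lambda_hom`/`lambda_het`/`pi`),
#' `linkage` (`step`, `use_unaffected`, `consistency`) and a global `seed`.
#' Unknown fields and invalid values are all reported together, not
#' first-failure.
#'
#' @param config path or list.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errs <- character()
  note <- function(msg) errs[[length(errs) + 1L]] <<- msg

  known <- c("seed", "simulate", "filter", "hmm", "linkage")
  for (f in setdiff(names(config), known)) note(paste0("unknown section: ", f))
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) note("seed must be a single number")

  sim <- NULL
  sim_args <- config$simulate %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  for (f in bad) note(paste0("simulate: unknown field ", f))
  sim_try <- tryCatch(
    do.call(sim_config, sim_args[setdiff(names(sim_args), bad)]),
    error = function(e) {
      note(paste0("simulate: ", conditionMessage(e))); NULL
    })
  sim <- sim_try

  filt_args <- config$filter %||% list()
  bad <- setdiff(names(filt_args), names(formals(filter_config)))
  for (f in bad) note(paste0("filter: unknown field ", f))
  filt <- tryCatch(
    do.call(filter_config, filt_args[setdiff(names(filt_args), bad)]),
    error = function(e) { note(paste0("filter: ", conditionMessage(e))); NULL })

  hmm <- config$hmm %||% list()
  hmm$window <- hmm$window %||% 250000
  if (!is.numeric(hmm$window) || hmm$window < 1000)
    note("hmm: window must be >= 1000 bp")
  if (!is.null(hmm$rho) && (hmm$rho < 0 || hmm$rho > 1))
    note("hmm: rho must lie in [0, 1]")

  linkage <- config$linkage %||% list()
  linkage$step <- linkage$step %||% 0.001
  linkage$use_unaffected <- linkage$use_unaffected %||% TRUE
  linkage$consistency <- linkage$consistency %||% "both"
  if (!is.numeric(linkage$step) || linkage$step <= 0 || linkage$step > 0.5)
    note("linkage: step must lie in (0, 0.5]")
  if (!linkage$consistency %in% c("both", "affected_only"))
    note("linkage: consistency must be 'both' or 'affected_only'")

  if (length(errs))
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "))
  structure(list(seed = as.integer(seed), simulate = sim, filter = filt,
                 hmm = hmm, linkage = linkage),
            class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config a `run_config` (or plain list).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  x <- list(
    seed = config$seed,
    simulate = unclass(config$simulate)[names(formals(sim_config))],
    filter = unclass(config$filter)[setdiff(names(formals(filter_config)), "")],
    hmm = config$hmm, linkage = config$linkage
  )
  x$simulate$seed <- NULL  # the global seed governs; stage seeds are derived
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the whole mapping-by-sequencing pipeline
#'
#' Executes simulate, filter, linkage, segment and candidates in order
#' (or a prefix via `stages`), writing every stage's artifacts under
#' `out_dir`. Stage seeds are derived from the global seed with
#' [derive_seed()], so the same config and seed give byte-identical
#' artifacts, and each stage rerun in isolation reproduces its part.
#'
#' @param config a `run_config`, or anything [validate_config()] accepts.
#' @param out_dir artifact directory (created).
#' @param stages prefix of `c("simulate", "filter", "linkage", "segment",
#'   "candidates")` to run.
#' @param genome optional pre-built `enumap_genome` (with sequence) shared
#'   across runs; built from the simulate config when NULL.
#' @return Invisibly, a list with the in-memory results of each stage run
#'   (`truth`, `filtered`, `report`, `scan`, `region`, `segmentation`,
#'   `candidates`, `funnel`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "filter", "linkage",
                                    "segment", "candidates"),
                         genome = NULL) {
  config <- validate_config(if (inherits(config, "run_config")) unclass(config)
                            else config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  res <- list(paths = list(dir = out_dir))
  logf("enumap run: seed=%d stages=%s", config$seed, paste(stages, collapse = ","))

  if ("simulate" %in% stages) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    if (is.null(genome)) genome <- make_genome(sim_cfg, sequence = TRUE)
    truth <- simulate_pedigree(sim_cfg, genome)
    res$truth <- truth
    res$paths <- c(res$paths, write_simulation(truth, out_dir))
    logf("simulate: %d mutations (%d ENU), causal %s:%d %s>%s (%s in %s)",
         nrow(truth$mutations), sum(truth$mutations$origin == "ENU"),
         truth$causal$chrom, truth$causal$pos, truth$causal$ref,
         truth$causal$alt, truth$causal$aa_change, truth$causal$gene_id)
  }

  if ("filter" %in% stages) {
    calls <- parse_vcf(file.path(out_dir, "observed.vcf"))
    fc <- filter_cascade(calls,
                         blacklists = file.path(out_dir, "blacklist.tsv"),
                         reference = file.path(out_dir, "reference.fa"),
                         repeat_mask = NULL, config = config$filter)
    res$filtered <- fc$variants
    res$report <- fc$report
    write_vcf(fc$variants, file.path(out_dir, "filtered.vcf"),
              contigs = read_genome_tsv(file.path(out_dir, "genome.tsv")))
    write_filter_report(fc$report, out_dir)
    logf("filter: %d -> %d calls", fc$report$input[1L],
         fc$report$surviving[nrow(fc$report)])
  }

  if ("linkage" %in% stages) {
    scan <- scan_markers(file.path(out_dir, "markers.tsv"),
                         file.path(out_dir, "phenotypes.tsv"),
                         step = config$linkage$step,
                         use_unaffected = config$linkage$use_unaffected,
                         consistency = config$linkage$consistency)
    res$scan <- scan
    write_linkage(scan, out_dir)
    layout <- read_genome_tsv(file.path(out_dir, "genome.tsv"))
    top <- scan[which.max(scan$lod_max), ]
    region <- consistent_region(
      scan, chrom = top$chrom,
      chrom_length = layout$length[layout$chrom == top$chrom]
    )
    res$region <- region
    write_bed(region, file.path(out_dir, "linkage_region.bed"))
    logf("linkage: top marker %s (LOD %.2f); region %s", top$marker_id,
         top$lod_max,
         if (nrow(region)) sprintf("%s:%.0f-%.0f", region$chrom, region$start,
                                   region$end) else "none")
  }

  if ("segment" %in% stages) {
    filtered <- parse_vcf(file.path(out_dir, "filtered.vcf"))
    sim_cfg <- config$simulate
    rho <- config$hmm$rho %||%
      default_rho(sim_cfg$cm_per_mb, sim_cfg$n_meioses, config$hmm$window)
    params <- NULL
    if (!is.null(config$hmm$lambda_hom))
      params <- hmm_params(unlist(config$hmm$lambda_hom),
                           unlist(config$hmm$lambda_het), rho,
                           pi = unlist(config$hmm$pi %||%
                                         c(CC = 0.25, CF = 0.5, FF = 0.25)))
    seg <- segment_genome(filtered, file.path(out_dir, "genome.tsv"),
                          window = config$hmm$window, params = params, rho = rho)
    res$segmentation <- seg
    write_segmentation(seg, out_dir)
    logf("segment: FF total %.1f Mb in %d segments",
         seg$bp_per_state[["FF"]] / 1e6, nrow(seg$segments))
  }

  if ("candidates" %in% stages) {
    filtered <- parse_vcf(file.path(out_dir, "filtered.vcf"))
    models <- read_gene_models(file.path(out_dir, "genes.gff3"))
    region <- read_bed(file.path(out_dir, "linkage_region.bed"))
    segs <- read_bed(file.path(out_dir, "segments.bed"))
    cand <- withCallingHandlers(
      nominate_candidates(
        filtered, models, file.path(out_dir, "reference.fa"),
        ff_segments = segs,
        linkage_region = if (nrow(region)) region else NULL
      ),
      warning = function(w) {
        logf("candidates: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res$candidates <- cand
    write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ff <- segs[segs$name == "FF", ]
    region_set <- if (nrow(region)) {
      # clip FF segments to the (single-interval) linkage region
      r <- ff[ff$chrom == region$chrom[1L], ]
      r$start <- pmax(r$start, region$start[1L])
      r$end <- pmin(r$end, region$end[1L])
      r[r$end > r$start, ]
    } else ff
    n_in_region <- sum(in_regions(filtered, region_set))
    res$funnel <- rank_report(res$report %||%
                                read_filter_report(file.path(out_dir, "filter_report.tsv")),
                              n_in_region, cand,
                              segmentation = res$segmentation,
                              scan = res$scan, dir = out_dir)
    logf("candidates: %d in-region variants, %d candidates",
         n_in_region, nrow(cand))
  }
  invisible(res)
}

read_filter_report <- function(path) {
  rep <- read.table(path, header = TRUE, sep = "\t")
  class(rep) <- c("filter_report", "data.frame")
  rep
}
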