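MOSAIC_ANCESTRIES <- c("C", "F")
DIPLOTYPE_STATES <- c("CC", "CF", "FF")

#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws its random numbers under a seed derived
#' deterministically from the global seed and the stage name, so a stage can
#' be rerun in isolation and still reproduce the output of a full run.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  # all intermediates stay below 2^53, so double arithmetic is exact
  as.integer((abs(seed) %% 2147483647 * 69069 + h) %% 2147483646)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge adjacent intervals sharing a label
#'
#' @param df data.frame with columns start, end and a label column, sorted,
#'   contiguous (each start equals the previous end).
#' @param label name of the label column.
#' @return data.frame with maximal runs merged.
#' @keywords internal
merge_runs <- function(df, label = "state") {
  if (nrow(df) <= 1L) return(df)
  r <- rle(as.character(df[[label]]))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  out <- df[idx_start, , drop = FALSE]
  out$end <- df$end[idx_end]
  rownames(out) <- NULL
  out
}

# value of a piecewise-constant mosaic (start,end half-open, 0-based) at
# 1-based positions; vectorized over pos
mosaic_at <- function(mosaic, pos) {
  i <- findInterval(pos - 1L, mosaic$start)
  mosaic[[ncol(mosaic)]][i]
}

assert_tiles <- function(mosaic, len) {
  stopifnot(
    nrow(mosaic) >= 1L,
    mosaic$start[1] == 0,
    mosaic$end[nrow(mosaic)] == len,
    all(mosaic$end > mosaic$start),
    nrow(mosaic) == 1L ||
      all(mosaic$start[-1] == mosaic$end[-nrow(mosaic)])
  )
  invisible(mosaic)
}
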