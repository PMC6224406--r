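## Internal helpers shared across modules.

#' Derive a deterministic sub-seed for a named stage
#'
#' A single global integer seed drives every source of randomness in the
#' package; each stage (SNV placement, CNV placement, permutation nulls, ...)
#' draws from its own substream whose seed is a deterministic hash of the
#' global seed and the stage name.  Keeps independent stages reproducible
#' even when one of them changes how much randomness it consumes.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ## multiplicative hashing folded into the 31-bit signed-integer range
  as.integer((abs(seed) * 48271 + h * 69621 + 17) %% (2^31 - 1))
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(substream_seed(seed, stage), code)
}

## -- interval arithmetic ----------------------------------------------------
## All internal coordinates are 0-based half-open [start, end); conversion to
## the 1-based inclusive convention happens only at MAF/TSS I/O boundaries.

as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)  # IRanges is 1-based closed
}

iranges_to_tbl <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Total width of the union of a set of intervals
#' @noRd
interval_union_width <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(as_iranges(start, end))))
}

#' Width of the overlap between one interval and a set of intervals
#' @noRd
interval_overlap_width <- function(start, end, set_start, set_end) {
  if (length(set_start) == 0L) return(0L)
  q <- as_iranges(start, end)
  s <- IRanges::reduce(as_iranges(set_start, set_end))
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(q), s)))
}

#' Set-difference of one interval against a set, returned as a tibble
#' @noRd
interval_setdiff <- function(start, end, sub_start, sub_end) {
  q <- as_iranges(start, end)
  if (length(sub_start) == 0L) return(iranges_to_tbl(q))
  iranges_to_tbl(IRanges::setdiff(q, as_iranges(sub_start, sub_end)))
}

## does position (0-based) fall in any of the intervals?
pos_in_intervals <- function(pos, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), as_iranges(start, end))
}

## geometric mean, guarding zeros
geom_mean <- function(x) exp(mean(log(x)))

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
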