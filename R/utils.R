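# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed, restoring global RNG state after.
# All exported simulators route randomness through this; no global state leaks.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open intervals -> GRanges (1-based inclusive internally)
gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
}

# GRanges -> data.frame of 0-based half-open intervals
df0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# total bp in the union of 0-based half-open intervals
union_bp <- function(chrom, start, end) {
  if (length(chrom) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
    gr0(chrom, start, end)))))
}

# overlap in bp between one interval and a set (both 0-based half-open)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
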