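#' Match detected CNV calls against a truth set
#'
#' Bipartite greedy matching: candidate (truth, call) pairs share a
#' chromosome (and event type when \code{type_strict}) and overlap
#' reciprocally at \code{>= reciprocal} of both interval lengths.
#' Candidates are sorted by decreasing overlap fraction (the smaller of
#' the two reciprocal fractions; ties broken by truth then call input
#' order) and greedily accepted so that every truth record and every call
#' is matched at most once. TP = matched pairs, FN = unmatched truth,
#' FP = unmatched calls.
#'
#' @param truth,calls data.frames with columns chrom, start, end, svtype
#'   (0-based half-open), on the same coordinate system.
#' @param reciprocal reciprocal-overlap threshold in (0, 1] (default 0.5,
#'   standard SV benchmarking practice).
#' @param type_strict require matching svtype (default TRUE).
#' @return object of class \code{match_report}: list with tp, fp, fn,
#'   tpr, fdr, by_type (per-svtype breakdown), reciprocal, and the
#'   matched \code{pairs} (truth/call row indices with overlap fraction).
#' @export
match_calls <- function(truth, calls, reciprocal = 0.5,
                        type_strict = TRUE) {
  if (reciprocal <= 0 || reciprocal > 1) stop("reciprocal must be in (0,1]")
  assert_columns(truth, c("chrom", "start", "end", "svtype"), "truth")
  assert_columns(calls, c("chrom", "start", "end", "svtype"), "calls")

  cand <- NULL
  if (nrow(truth) > 0L && nrow(calls) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      gr0(truth$chrom, truth$start, truth$end),
      gr0(calls$chrom, calls$start, calls$end))
    ti <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
    if (type_strict) {
      ok <- truth$svtype[ti] == calls$svtype[ci]
      ti <- ti[ok]; ci <- ci[ok]
    }
    if (length(ti) > 0L) {
      ov <- interval_overlap(truth$start[ti], truth$end[ti],
                             calls$start[ci], calls$end[ci])
      f_t <- ov / (truth$end[ti] - truth$start[ti])
      f_c <- ov / (calls$end[ci] - calls$start[ci])
      frac <- pmin(f_t, f_c)
      ok <- frac >= reciprocal
      cand <- data.frame(truth_idx = ti[ok], call_idx = ci[ok],
                         overlap_frac = frac[ok])
    }
  }

  matched_t <- logical(nrow(truth))
  matched_c <- logical(nrow(calls))
  pairs <- data.frame(truth_idx = integer(), call_idx = integer(),
                      overlap_frac = numeric())
  if (!is.null(cand) && nrow(cand) > 0L) {
    o <- order(-cand$overlap_frac, cand$truth_idx, cand$call_idx)
    cand <- cand[o, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      t <- cand$truth_idx[i]; c <- cand$call_idx[i]
      if (!matched_t[t] && !matched_c[c]) {
        matched_t[t] <- TRUE; matched_c[c] <- TRUE
        pairs <- rbind(pairs, cand[i, , drop = FALSE])
      }
    }
  }
  rownames(pairs) <- NULL
  tp <- nrow(pairs); fn <- sum(!matched_t); fp <- sum(!matched_c)
  by_type <- do.call(rbind, lapply(c("DEL", "DUP"), function(tt) {
    t_idx <- which(truth$svtype == tt)
    c_idx <- which(calls$svtype == tt)
    tp_t <- sum(matched_t[t_idx])
    data.frame(svtype = tt, tp = tp_t, fn = length(t_idx) - tp_t,
               fp = sum(!matched_c[c_idx]),
               tpr = if (length(t_idx)) tp_t / length(t_idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    tpr = if (nrow(truth)) tp / nrow(truth) else NA_real_,
    fdr = if (nrow(calls)) fp / nrow(calls) else NA_real_,
    by_type = by_type, reciprocal = reciprocal, pairs = pairs
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "match_report (reciprocal >= %.2f): TP %d, FP %d, FN %d; TPR %.3f, FDR %.3f\n",
    x$reciprocal, x$tp, x$fp, x$fn, x$tpr, x$fdr))
  print(x$by_type)
  invisible(x)
}

#' Evaluate a call file against a truth file across thresholds
#'
#' Reads both TSVs with \code{\link{read_cnv_calls}} and runs
#' \code{\link{match_calls}} at each reciprocal-overlap threshold.
#'
#' @param truth_tsv,calls_tsv CNV call tables (see
#'   \code{\link{write_cnv_calls}}).
#' @param thresholds numeric vector of reciprocal-overlap thresholds.
#' @param type_strict require matching svtype.
#' @return data.frame with one row per threshold: reciprocal, tp, fp, fn,
#'   tpr, fdr.
#' @export
evaluate_against_truth_files <- function(truth_tsv, calls_tsv,
                                         thresholds = c(0.5, 0.9),
                                         type_strict = TRUE) {
  truth <- read_cnv_calls(truth_tsv)
  calls <- read_cnv_calls(calls_tsv)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    r <- match_calls(truth, calls, reciprocal = th,
                     type_strict = type_strict)
    data.frame(reciprocal = th, tp = r$tp, fp = r$fp, fn = r$fn,
               tpr = r$tpr, fdr = r$fdr)
  }))
  rownames(out) <- NULL
  out
}
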