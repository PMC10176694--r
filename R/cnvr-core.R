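# A cnvr_set is a data.frame (id, chrom, start, end, event_type,
# n_carriers, maf) with two attributes:
#   carriers — list of named character vectors, accession -> loss/gain/both
#   members  — list of integer vectors indexing the input call table
new_cnvr_set <- function(df, carriers, members = NULL) {
  if (!"maf" %in% names(df)) df$maf <- rep(NA_real_, nrow(df))
  attr(df, "carriers") <- carriers
  attr(df, "members") <- members
  class(df) <- c("cnvr_set", "data.frame")
  df
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat("cnvr_set with", nrow(x), "CNVR(s):",
      sum(x$event_type == "loss"), "loss,",
      sum(x$event_type == "gain"), "gain,",
      sum(x$event_type == "both"), "both\n")
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' @export
`[.cnvr_set` <- function(x, i, ...) {
  carriers <- attr(x, "carriers")
  members <- attr(x, "members")
  out <- as.data.frame(x)[i, , drop = FALSE]
  ri <- seq_len(nrow(as.data.frame(x)))[i]
  new_cnvr_set(out, carriers[ri],
               if (!is.null(members)) members[ri] else NULL)
}

#' Filter CNV calls by minimum length
#'
#' CNVs are defined as deletions/duplications of at least \code{min_len}
#' bp; shorter calls are dropped. The boundary is inclusive
#' (length >= \code{min_len} retained). Per-type retained/removed counts
#' are attached as the \code{"report"} attribute.
#'
#' @param calls data.frame with columns accession, chrom, start, end,
#'   svtype (0-based half-open).
#' @param min_len minimum call length in bp (default 50).
#' @return the retained calls, with a \code{report} attribute.
#' @export
filter_calls <- function(calls, min_len = 50L) {
  assert_columns(calls, c("accession", "chrom", "start", "end", "svtype"),
                 "calls")
  len <- calls$end - calls$start
  keep <- len >= min_len
  report <- list(
    removed = sum(!keep),
    retained = sum(keep),
    retained_by_type = table(factor(calls$svtype[keep],
                                    levels = c("DEL", "DUP")))
  )
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Merge per-accession CNV calls into CNV regions (CNVRs)
#'
#' Deterministic greedy clustering under stringent reciprocal overlap.
#' Calls are sorted by (chrom, start, end, accession) and scanned once: a
#' call joins the currently open cluster iff its overlap with the cluster's
#' running extent is at least \code{reciprocal} of the call length AND at
#' least \code{reciprocal} of the extent length; on joining, the extent is
#' extended to the union of the two intervals. Otherwise a new cluster
#' opens. Clusters carried by fewer than \code{min_carriers} distinct
#' accessions are dropped.
#'
#' An accession appearing several times in one cluster counts once; its
#' event is recorded as loss if any of its member calls is a DEL, gain if
#' any is a DUP, and \code{both} if it carries one of each. The CNVR
#' \code{event_type} is \code{loss} if every carrier event is loss,
#' \code{gain} if every carrier event is gain, and \code{both} otherwise.
#'
#' @param calls filtered CNV call data.frame (see
#'   \code{\link{filter_calls}}).
#' @param reciprocal required reciprocal-overlap fraction in (0, 1]
#'   (default 0.90).
#' @param min_carriers minimum number of distinct carrier accessions
#'   (default 10).
#' @return a \code{cnvr_set}; the \code{"members"} attribute records, per
#'   CNVR, the row indices of \code{calls} that built it.
#' @export
merge_to_cnvrs <- function(calls, reciprocal = 0.90, min_carriers = 10L) {
  assert_columns(calls, c("accession", "chrom", "start", "end", "svtype"),
                 "calls")
  if (reciprocal <= 0 || reciprocal > 1) {
    stop("reciprocal must be in (0, 1]")
  }
  n <- nrow(calls)
  empty <- new_cnvr_set(
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), event_type = character(),
               n_carriers = integer(), stringsAsFactors = FALSE),
    carriers = list(), members = list())
  if (n == 0L) return(empty)

  o <- order(calls$chrom, calls$start, calls$end, calls$accession)
  s <- calls$start[o]; e <- calls$end[o]; ch <- calls$chrom[o]

  cluster_of <- integer(n)
  cur <- 0L
  cs <- ce <- NA_integer_; cch <- NA_character_
  ext_s <- integer(); ext_e <- integer(); ext_ch <- character()
  for (i in seq_len(n)) {
    join <- FALSE
    if (cur > 0L && identical(ch[i], cch)) {
      ov <- interval_overlap(s[i], e[i], cs, ce)
      if (ov >= reciprocal * (e[i] - s[i]) &&
          ov >= reciprocal * (ce - cs)) join <- TRUE
    }
    if (join) {
      cs <- min(cs, s[i]); ce <- max(ce, e[i])
    } else {
      cur <- cur + 1L
      cs <- s[i]; ce <- e[i]; cch <- ch[i]
    }
    cluster_of[i] <- cur
    ext_s[cur] <- cs; ext_e[cur] <- ce; ext_ch[cur] <- cch
  }

  rows <- vector("list", cur)
  carriers_list <- vector("list", cur)
  members_list <- vector("list", cur)
  keep <- logical(cur)
  for (k in seq_len(cur)) {
    idx <- which(cluster_of == k)     # positions in sorted order
    orig <- o[idx]
    acc <- calls$accession[orig]
    typ <- calls$svtype[orig]
    has_del <- tapply(typ == "DEL", acc, any)
    has_dup <- tapply(typ == "DUP", acc, any)
    ev <- ifelse(has_del & has_dup, "both",
                 ifelse(has_del, "loss", "gain"))
    ev <- setNames(as.character(ev), names(has_del))
    ev <- ev[order(names(ev))]
    n_carr <- length(ev)
    keep[k] <- n_carr >= min_carriers
    event_type <- if (all(ev == "loss")) "loss"
      else if (all(ev == "gain")) "gain" else "both"
    rows[[k]] <- data.frame(
      chrom = ext_ch[k], start = ext_s[k], end = ext_e[k],
      event_type = event_type, n_carriers = n_carr,
      stringsAsFactors = FALSE)
    carriers_list[[k]] <- ev
    members_list[[k]] <- orig
  }
  if (!any(keep)) return(empty)
  df <- do.call(rbind, rows[keep])
  df <- cbind(id = sprintf("cnvr%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new_cnvr_set(df, carriers_list[keep], members_list[keep])
}

#' Compute CNVR minor allele frequency under the loss/gain recoding
#'
#' A loss carrier contributes 1 alt allele (genotype 0/1), a gain carrier 2
#' (genotype 1/1; an accession carrying both events counts as gain). The
#' alt-allele frequency is taken over \code{2 * length(all_samples)}
#' alleles and folded to the minor side.
#'
#' @param cnvrs a \code{cnvr_set}.
#' @param all_samples ordered ids of the full panel (carriers must be a
#'   subset).
#' @return the \code{cnvr_set} with its \code{maf} column filled.
#' @export
compute_cnvr_maf <- function(cnvrs, all_samples) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  carriers <- attr(cnvrs, "carriers")
  total <- 2 * length(all_samples)
  maf <- vapply(carriers, function(ev) {
    if (!all(names(ev) %in% all_samples)) {
      stop("carrier accession not in all_samples")
    }
    alt <- sum(ev == "loss") + 2 * sum(ev %in% c("gain", "both"))
    f <- alt / total
    min(f, 1 - f)
  }, 1.0)
  cnvrs$maf <- maf
  cnvrs
}

#' Filter CNVRs by minor allele frequency
#'
#' Retains CNVRs with \code{maf >= floor} (boundary inclusive), matching
#' the MAF criterion applied to the SNP set. Counts are attached as the
#' \code{"report"} attribute.
#'
#' @param cnvrs a \code{cnvr_set} with maf computed.
#' @param floor MAF floor (default 0.05).
#' @export
filter_cnvrs_by_maf <- function(cnvrs, floor = 0.05) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  if (anyNA(cnvrs$maf)) stop("compute_cnvr_maf first")
  keep <- cnvrs$maf >= floor
  out <- cnvrs[keep, ]
  attr(out, "report") <- list(removed = sum(!keep), retained = sum(keep))
  out
}

#' Summarise a CNVR set
#'
#' Counts per event type, total non-overlapping bp covered (union across
#' possibly overlapping CNVRs), genome fraction when a genome size is
#' given, and length statistics.
#'
#' @param cnvrs a \code{cnvr_set}.
#' @param genome_bp optional total genome size in bp.
#' @return list with \code{n}, \code{by_type}, \code{total_bp},
#'   \code{genome_fraction}, \code{length_min}, \code{length_mean},
#'   \code{length_max}.
#' @export
summarize_cnvrs <- function(cnvrs, genome_bp = NULL) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  len <- cnvrs$end - cnvrs$start
  total <- union_bp(cnvrs$chrom, cnvrs$start, cnvrs$end)
  list(
    n = nrow(cnvrs),
    by_type = table(factor(cnvrs$event_type,
                           levels = c("loss", "gain", "both"))),
    total_bp = total,
    genome_fraction = if (is.null(genome_bp)) NA_real_ else
      total / genome_bp,
    length_min = if (length(len)) min(len) else NA_integer_,
    length_mean = if (length(len)) mean(len) else NA_real_,
    length_max = if (length(len)) max(len) else NA_integer_
  )
}

#' Recode a CNVR set as a genotype matrix
#'
#' Applies the VCF recoding as dosages: loss carrier 1, gain (or both)
#' carrier 2, non-carrier 0. The result feeds LD classification and PCA
#' exactly like a SNP matrix; marker position is the CNVR start.
#'
#' @param cnvrs a \code{cnvr_set}.
#' @param samples full ordered sample panel.
#' @return A \code{\link{genotype_matrix}} with one marker per CNVR.
#' @export
cnvr_genotypes <- function(cnvrs, samples) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  carriers <- attr(cnvrs, "carriers")
  dosage <- matrix(0L, nrow = nrow(cnvrs), ncol = length(samples),
                   dimnames = list(cnvrs$id, samples))
  for (i in seq_len(nrow(cnvrs))) {
    ev <- carriers[[i]]
    dosage[i, names(ev)[ev == "loss"]] <- 1L
    dosage[i, names(ev)[ev %in% c("gain", "both")]] <- 2L
  }
  markers <- data.frame(id = cnvrs$id, chrom = cnvrs$chrom,
                        pos = cnvrs$start, ref = "N", alt = "<CNV>",
                        stringsAsFactors = FALSE)
  genotype_matrix(markers, samples, dosage, strict_pos = FALSE)
}
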