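#' Principal component analysis of a genotype matrix
#'
#' Centred-dosage PCA of samples. Monomorphic markers are dropped with a
#' message; missing dosages are mean-imputed per marker (equivalent to
#' centring then zero-filling). Optionally each marker is scaled by its
#' binomial allele-frequency standard deviation
#' \eqn{\sqrt{p(1-p)}} (smartpca-style normalisation). Component signs are
#' fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param g a \code{\link{genotype_matrix}} (SNPs or recoded CNVRs).
#' @param k number of components to keep; truncated to the matrix rank
#'   with a warning when too large.
#' @param scale_freq logical; apply allele-frequency scaling
#'   (default FALSE).
#' @return object of class \code{pca_result}: list with \code{scores}
#'   (sample x k), \code{explained_pct} (per component, over all
#'   components), \code{sdev}, \code{samples}, \code{k},
#'   \code{n_dropped_monomorphic}.
#' @export
genotype_pca <- function(g, k = 10L, scale_freq = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"), k >= 1)
  if (length(g$samples) < 2L) stop("need at least 2 samples")
  X <- g$dosage                       # markers x samples
  mono <- apply(X, 1L, function(r) {
    v <- r[!is.na(r)]
    length(v) < 2L || var(v) == 0
  })
  if (any(mono)) {
    message("dropped ", sum(mono), " monomorphic marker(s)")
    X <- X[!mono, , drop = FALSE]
  }
  if (nrow(X) == 0L) stop("no polymorphic markers left")
  mu <- rowMeans(X, na.rm = TRUE)
  X <- X - mu
  X[is.na(X)] <- 0
  if (scale_freq) {
    p <- mu / 2
    X <- X / sqrt(p * (1 - p))
  }
  sv <- svd(t(X))                     # samples x markers
  pos <- sv$d > max(sv$d) * 1e-12
  rank <- sum(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds matrix rank ", rank, "; truncated")
    k <- rank
  }
  eig <- sv$d^2
  explained <- 100 * eig / sum(eig)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores, explained_pct = explained[seq_len(k)],
                 explained_all = explained, sdev = sv$d / sqrt(ncol(X)),
                 samples = g$samples, k = k,
                 n_dropped_monomorphic = sum(mono),
                 loadings = loadings),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$samples), "samples,", x$k, "components\n")
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of the first two principal components
#'
#' @param x a \code{pca_result}.
#' @param populations optional named character vector
#'   (accession -> population) used to colour points.
#' @param ... passed to \code{plot}.
#' @export
plot.pca_result <- function(x, populations = NULL, ...) {
  s <- x$scores
  col <- "grey30"
  if (!is.null(populations)) {
    pops <- factor(populations[x$samples])
    col <- c("steelblue", "darkorange", "forestgreen",
             "firebrick")[as.integer(pops)]
  }
  plot(s[, 1L], s[, 2L], col = col, pch = 19,
       xlab = sprintf("PC1 (%.2f%%)", x$explained_pct[1L]),
       ylab = sprintf("PC2 (%.2f%%)", x$explained_pct[2L]), ...)
  if (!is.null(populations)) {
    legend("topright", legend = levels(pops), col = c(
      "steelblue", "darkorange", "forestgreen", "firebrick"
    )[seq_along(levels(pops))], pch = 19, bty = "n")
  }
  invisible(NULL)
}

#' Write PCA scores as a TSV
#' @param x a \code{pca_result}.
#' @param path output TSV.
#' @export
write_pca_scores <- function(x, path) {
  df <- data.frame(sample = x$samples, x$scores, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
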