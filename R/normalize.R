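#' Reads-per-million-mapped (rpmm) normalization
#'
#' Scales each sample's counts to reads per million mapped to the
#' denominator class: `value = raw * 1e6 / sum(raw over denominator
#' features in that sample)`. By default every feature is normalized
#' against its own RNA class's per-sample total (for miRNAs: the sample's
#' miRNA total), so within each class the per-sample sums equal 1e6.
#' Setting `denominator_class = "all"` uses the global per-sample total
#' instead.
#'
#' isomiR matrices should be normalized with the archetype class's
#' denominator: pass the archetype counts' per-sample class totals via
#' `denominator_totals`.
#'
#' @param counts features x samples raw count matrix.
#' @param rna_class named character vector of feature classes; may be
#'   omitted when `denominator_class = "all"` or `denominator_totals` is
#'   given.
#' @param denominator_class `"class"` (default, per-class totals) or
#'   `"all"` (per-sample grand total).
#' @param denominator_totals optional numeric vector of per-sample
#'   denominator totals overriding both conventions (used for isomiRs).
#' @return numeric matrix of rpmm values with a `denominator` attribute
#'   recording the convention used.
#' @export
rpmm <- function(counts, rna_class = NULL, denominator_class = c("class", "all"),
                 denominator_totals = NULL) {
  denominator_class <- match.arg(denominator_class)
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  if (!is.null(denominator_totals)) {
    den <- denominator_totals[colnames(counts)]
    if (any(is.na(den) | den <= 0))
      stop("rpmm: zero or missing denominator for sample(s): ",
           paste(colnames(counts)[is.na(den) | den <= 0], collapse = ", "))
    out <- sweep(counts, 2, den, "/") * 1e6
    attr(out, "denominator") <- "explicit_totals"
    return(out)
  }
  if (denominator_class == "all") {
    den <- colSums(counts)
    if (any(den == 0))
      stop("rpmm: zero denominator for sample(s): ",
           paste(colnames(counts)[den == 0], collapse = ", "))
    out <- sweep(counts, 2, den, "/") * 1e6
    attr(out, "denominator") <- "all"
    return(out)
  }
  if (is.null(rna_class)) stop("rpmm: rna_class required for per-class denominators")
  cls <- rna_class[rownames(counts)]
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    den <- colSums(counts[idx, , drop = FALSE])
    if (any(den == 0))
      stop("rpmm: zero ", cl, " denominator for sample(s): ",
           paste(colnames(counts)[den == 0], collapse = ", "))
    out[idx, ] <- sweep(counts[idx, , drop = FALSE], 2, den, "/") * 1e6
  }
  attr(out, "denominator") <- "class"
  out
}

#' Standardize a matrix along rows or columns (z-scores)
#'
#' Uses the population standard deviation (divisor n). Zero-variance rows
#' or columns are emitted as all-zero and flagged in the `degenerate`
#' attribute rather than producing NaN.
#'
#' @param x numeric matrix.
#' @param margin 1 to standardize each row, 2 for each column.
#' @return matrix of the same shape, mean 0 / sd 1 along `margin`, with a
#'   logical `degenerate` attribute marking flattened slices.
#' @export
zscore <- function(x, margin = 1) {
  stopifnot(margin %in% c(1, 2))
  if (margin == 2) {
    tout <- zscore(t(x), margin = 1)
    out <- t(tout)
    attr(out, "degenerate") <- attr(tout, "degenerate")
    return(out)
  }
  mu <- rowMeans(x)
  sd <- sqrt(rowMeans((x - mu)^2))
  deg <- sd == 0
  sd[deg] <- 1
  out <- (x - mu) / sd
  out[deg, ] <- 0
  attr(out, "degenerate") <- stats::setNames(deg, rownames(x))
  out
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
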