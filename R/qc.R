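#' Filter samples by aligned-read depth (and optionally whole regions)
#'
#' A sample is kept only if strictly more than `min_aligned_reads` reads
#' were aligned (metadata column `aligned_reads`; a sample at exactly the
#' threshold is dropped). When `min_region_samples` is given, any region
#' left with that many surviving samples or fewer is discarded entirely —
#' the extra rule used for intervention-style cohorts.
#'
#' @param counts features x samples count matrix.
#' @param meta metadata with `sample_id`, `region`, `aligned_reads`.
#' @param min_aligned_reads read threshold (default 2e6; the microglia
#'   preset uses 1.8e6, the human preset 1e4).
#' @param min_region_samples region-discard threshold (default `NULL`:
#'   rule off; the intervention preset uses 3).
#' @return list with `counts`, `meta` (both filtered) and `qc` (a
#'   `qc_report` list: kept/dropped ids with reasons and thresholds).
#' @export
filter_samples <- function(counts, meta, min_aligned_reads = 2e6,
                           min_region_samples = NULL) {
  stopifnot(min_aligned_reads >= 0)
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("filter_samples: samples in counts missing from metadata")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  keep <- meta$aligned_reads > min_aligned_reads
  reason <- ifelse(keep, NA_character_, "low_aligned_reads")
  if (!is.null(min_region_samples)) {
    surv <- table(meta$region[keep])
    bad_regions <- names(surv)[surv <= min_region_samples]
    bad_regions <- union(bad_regions, setdiff(meta$region, names(surv)))
    drop_region <- keep & meta$region %in% bad_regions
    reason[drop_region] <- "region_too_small"
    keep <- keep & !drop_region
  }
  if (!any(keep)) stop("filter_samples: all samples dropped")
  qc <- list(kind = "sample_filter",
             thresholds = list(min_aligned_reads = min_aligned_reads,
                               min_region_samples = min_region_samples),
             n_input = nrow(meta), n_kept = sum(keep),
             kept = meta$sample_id[keep],
             dropped = data.frame(sample_id = meta$sample_id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
  class(qc) <- "qc_report"
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE], qc = qc)
}

#' Filter features by minimum count prevalence within a group
#'
#' A feature is retained iff in at least one group the fraction of samples
#' with a raw count greater than or equal to `min_count` reaches
#' `min_fraction` (both thresholds inclusive; fractions are compared
#' exactly, so 1 of 10 samples passes 10%). Groups default to brain
#' regions.
#'
#' @param counts features x samples count matrix.
#' @param groups factor/character vector of group labels per sample (same
#'   order as `colnames(counts)`).
#' @param min_count inclusive raw-count threshold (default 5; human preset
#'   uses 2).
#' @param min_fraction inclusive prevalence threshold (default 0.10).
#' @return list with `counts` (filtered) and `qc` (a `qc_report`).
#' @export
filter_features <- function(counts, groups, min_count = 5, min_fraction = 0.10) {
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("filter_features: 'groups' must have one label per sample")
  if (any(is.na(groups)) || any(table(groups) == 0))
    stop("filter_features: empty group")
  keep <- rep(FALSE, nrow(counts))
  for (g in unique(groups)) {
    idx <- groups == g
    frac <- rowSums(counts[, idx, drop = FALSE] >= min_count) / sum(idx)
    keep <- keep | frac >= min_fraction
  }
  qc <- list(kind = "feature_filter",
             thresholds = list(min_count = min_count, min_fraction = min_fraction),
             n_input = nrow(counts), n_kept = sum(keep),
             kept = rownames(counts)[keep],
             dropped = data.frame(feature_id = rownames(counts)[!keep],
                                  reason = rep("below_prevalence", sum(!keep)),
                                  stringsAsFactors = FALSE))
  class(qc) <- "qc_report"
  list(counts = counts[keep, , drop = FALSE], qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s): kept %d of %d (%.1f%%)\n", x$kind, x$n_kept,
              x$n_input, 100 * x$n_kept / max(x$n_input, 1L)))
  thr <- x$thresholds[!vapply(x$thresholds, is.null, TRUE)]
  cat("  thresholds:", paste(names(thr), unlist(thr), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Features expressed in a brain region
#'
#' A feature is expressed in a region if at least 10% of that region's
#' samples have a raw count of at least `min_count` (both inclusive).
#'
#' @param counts features x samples raw count matrix.
#' @param meta metadata with `sample_id` and `region`.
#' @param region a region label present in `meta$region`.
#' @param min_count,min_fraction inclusive thresholds (defaults 5, 0.10).
#' @return character vector of expressed feature ids.
#' @export
expressed_in_region <- function(counts, meta, region, min_count = 5,
                                min_fraction = 0.10) {
  if (!region %in% meta$region)
    stop("expressed_in_region: unknown region: ", region)
  idx <- meta$sample_id[meta$region == region]
  sub <- counts[, colnames(counts) %in% idx, drop = FALSE]
  frac <- rowSums(sub >= min_count) / ncol(sub)
  rownames(counts)[frac >= min_fraction]
}

#' RNA-class composition per region with cubic age trends
#'
#' For every region, computes each RNA class's share of the total raw
#' counts over expressed features (shares sum to 1 per region), the same
#' shares resolved per age stage, and a least-squares third-degree
#' polynomial of share versus age per (region, class).
#'
#' @param counts raw count matrix.
#' @param meta sample metadata.
#' @param rna_class named character vector of feature classes.
#' @param min_count,min_fraction expression thresholds passed to
#'   [expressed_in_region()].
#' @return list with `composition` (region, rna_class, share),
#'   `by_age` (region, rna_class, age_months, share) and `trend`
#'   (region, rna_class, b0..b3 cubic coefficients, increasing powers).
#' @export
class_composition <- function(counts, meta, rna_class, min_count = 5,
                              min_fraction = 0.10) {
  comp <- list(); by_age <- list(); trend <- list()
  for (r in unique(meta$region)) {
    expressed <- expressed_in_region(counts, meta, r, min_count, min_fraction)
    samp <- meta$sample_id[meta$region == r]
    sub <- counts[expressed, colnames(counts) %in% samp, drop = FALSE]
    if (sum(sub) == 0) stop("class_composition: region with zero expressed counts: ", r)
    cls <- rna_class[rownames(sub)]
    totals <- tapply(rowSums(sub), cls, sum)
    comp[[r]] <- data.frame(region = r, rna_class = names(totals),
                            share = as.numeric(totals) / sum(totals),
                            stringsAsFactors = FALSE)
    meta_r <- meta[meta$region == r, ]
    for (a in sort(unique(meta_r$age_months))) {
      s2 <- sub[, colnames(sub) %in% meta_r$sample_id[meta_r$age_months == a],
                drop = FALSE]
      t2 <- tapply(rowSums(s2), cls, sum)
      t2[is.na(t2)] <- 0
      by_age[[paste(r, a)]] <- data.frame(region = r, rna_class = names(t2),
                                          age_months = a,
                                          share = as.numeric(t2) / max(sum(t2), 1),
                                          stringsAsFactors = FALSE)
    }
  }
  by_age <- do.call(rbind, by_age)
  for (r in unique(by_age$region)) {
    for (cl in unique(by_age$rna_class[by_age$region == r])) {
      d <- by_age[by_age$region == r & by_age$rna_class == cl, ]
      co <- if (length(unique(d$age_months)) >= 4)
        stats::lm(share ~ poly(age_months, 3, raw = TRUE), data = d)$coefficients
      else rep(NA_real_, 4)
      trend[[paste(r, cl)]] <- data.frame(region = r, rna_class = cl,
                                          b0 = co[1], b1 = co[2], b2 = co[3],
                                          b3 = co[4], stringsAsFactors = FALSE)
    }
  }
  list(composition = do.call(rbind, c(comp, list(make.row.names = FALSE))),
       by_age = by_age,
       trend = do.call(rbind, c(trend, list(make.row.names = FALSE))))
}
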