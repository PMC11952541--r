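#' Group center statistic for fold-change calculation
#'
#' `geometric_mean` computes `exp(mean(log(v + pseudocount))) -
#' pseudocount` (floored at 0) so zero-containing groups stay defined;
#' `median` is the arithmetic median. The sex contrast uses the geometric
#' center, the old-vs-young age ladder uses medians, the human effect-size
#' preset uses the geometric center again.
#'
#' @param values non-negative numeric vector.
#' @param method "geometric_mean" or "median".
#' @param pseudocount added inside the log for the geometric method
#'   (default 0.5; must be > 0 when zeros are present).
#' @return a single non-negative number.
#' @export
group_center <- function(values, method = c("geometric_mean", "median"),
                         pseudocount = 0.5) {
  method <- match.arg(method)
  if (length(values) == 0) stop("group_center: empty group")
  if (any(values < 0)) stop("group_center: negative values")
  if (method == "median") return(stats::median(values))
  if (any(values == 0) && pseudocount <= 0)
    stop("group_center: pseudocount must be > 0 with zero counts")
  max(exp(mean(log(values + pseudocount))) - pseudocount, 0)
}

#' Welch's two-sample t-test p-value
#'
#' Two-sided Welch test (unequal variances, Satterthwaite degrees of
#' freedom). Degenerate zero-variance cases are resolved explicitly:
#' both groups constant and equal means gives p = 1, constant with
#' different means gives p = 0.
#'
#' @param a,b numeric vectors with at least two values each.
#' @return the two-sided p-value.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_test: both groups need >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD on `nA + nB - 2`
#' degrees of freedom. Returns NA with a warning when the pooled SD is 0.
#'
#' @param a,b numeric vectors with at least two values each.
#' @return signed effect size (sign convention A - B).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("cohens_d: both groups need >= 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) {
    if (mean(a) == mean(b)) return(0)
    warning("cohens_d: zero pooled SD with unequal means; returning NA")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Differential expression between two groups, stratified by region
#'
#' For every (feature, stratum): fold change `centerA / centerB` of the
#' group center statistic, two-sided Welch p-value, BH adjustment within
#' the stratum's retained feature family, and significance flags (padj <
#' `alpha` together with fold change >= `fc_threshold` for up, <=
#' 1/`fc_threshold` for down). Features with fold change exactly 1 are
#' removed before adjustment (flag `excluded_no_dereg`); fold changes with
#' a zero denominator center are reported as `Inf` and excluded from
#' significance calling.
#'
#' @param norm normalized expression matrix.
#' @param meta sample metadata.
#' @param group_col metadata column holding the contrast levels.
#' @param level_a,level_b the two levels compared (fold change = A / B).
#' @param stratify metadata column defining strata (default "region";
#'   `NULL` for a single stratum).
#' @param center "geometric_mean" or "median"; @param pseudocount for the
#'   geometric center.
#' @param alpha adjusted-p threshold (default 0.05); @param fc_threshold
#'   fold-change threshold (default 1.5).
#' @param effect_size also compute Cohen's d and flag |d| >= `d_threshold`
#'   (the human preset); @param d_threshold default 0.5.
#' @return data.frame of DE records (one row per feature x stratum).
#' @export
de_analysis <- function(norm, meta, group_col, level_a, level_b,
                        stratify = "region",
                        center = c("geometric_mean", "median"),
                        pseudocount = 0.5, alpha = 0.05, fc_threshold = 1.5,
                        effect_size = FALSE, d_threshold = 0.5) {
  center <- match.arg(center)
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  strata <- if (is.null(stratify)) rep("all", nrow(meta)) else meta[[stratify]]
  out <- list()
  for (s in unique(strata)) {
    ia <- strata == s & meta[[group_col]] == level_a
    ib <- strata == s & meta[[group_col]] == level_b
    if (sum(ia) < 2 || sum(ib) < 2) {
      warning("de_analysis: stratum '", s, "' skipped (level with < 2 samples)")
      next
    }
    A <- norm[, ia, drop = FALSE]; B <- norm[, ib, drop = FALSE]
    ca <- apply(A, 1, group_center, method = center, pseudocount = pseudocount)
    cb <- apply(B, 1, group_center, method = center, pseudocount = pseudocount)
    fc <- ifelse(cb == 0, ifelse(ca == 0, 1, Inf), ca / cb)
    rec <- data.frame(feature = rownames(norm), stratum = s,
                      contrast = paste(level_a, "vs", level_b),
                      center_a = ca, center_b = cb, fc = fc,
                      log2fc = log2(fc),
                      n_a = sum(ia), n_b = sum(ib),
                      excluded_no_dereg = fc == 1,
                      stringsAsFactors = FALSE)
    rec$p <- NA_real_; rec$padj <- NA_real_
    test_idx <- which(!rec$excluded_no_dereg & is.finite(rec$fc))
    rec$p[test_idx] <- vapply(test_idx, function(i)
      welch_test(A[i, ], B[i, ]), numeric(1))
    rec$padj[test_idx] <- bh_adjust(rec$p[test_idx])
    rec$significant_up <- !is.na(rec$padj) & rec$padj < alpha &
      rec$fc >= fc_threshold & is.finite(rec$fc)
    rec$significant_down <- !is.na(rec$padj) & rec$padj < alpha &
      rec$fc <= 1 / fc_threshold
    if (effect_size) {
      rec$cohens_d <- vapply(seq_len(nrow(norm)), function(i)
        suppressWarnings(cohens_d(A[i, ], B[i, ])), numeric(1))
      rec$large_effect <- !is.na(rec$cohens_d) & abs(rec$cohens_d) >= d_threshold
    }
    out[[s]] <- rec
  }
  if (!length(out)) stop("de_analysis: no stratum had enough samples")
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Age-ladder differential expression (each older age vs the youngest)
#'
#' Runs [de_analysis()] for every older age stage against the control age
#' (default: the youngest), per region, with the arithmetic-median center.
#'
#' @param norm,meta as in [de_analysis()].
#' @param control_age control age in months (default min age present).
#' @param ... passed to [de_analysis()].
#' @return combined data.frame of DE records with an `age` column.
#' @export
de_age_ladder <- function(norm, meta, control_age = NULL, ...) {
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  ages <- sort(unique(meta$age_months))
  if (is.null(control_age)) control_age <- ages[1]
  older <- ages[ages > control_age]
  out <- list()
  for (a in older) {
    keep <- meta$age_months %in% c(a, control_age)
    rec <- tryCatch(
      de_analysis(norm[, keep, drop = FALSE], meta[keep, , drop = FALSE],
                  group_col = "age_months", level_a = a, level_b = control_age,
                  center = "median", ...),
      error = function(e) NULL)
    if (is.null(rec)) next
    rec$age <- a
    out[[as.character(a)]] <- rec
  }
  if (!length(out)) stop("de_age_ladder: no comparison had enough samples")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify DE features as unique or multiple across regions
#'
#' Per direction (up / down), counts the regions in which a feature is
#' significantly deregulated in at least one comparison; a feature is
#' "unique" when that is exactly one region and "multiple" for more than
#' one. Directions are tracked separately.
#'
#' @param records DE records from [de_analysis()] / [de_age_ladder()].
#' @return data.frame with `feature`, `direction`, `regions`
#'   (comma-joined), `n_regions`, `label`.
#' @export
classify_uniqueness <- function(records) {
  out <- list()
  for (dir in c("up", "down")) {
    flag <- if (dir == "up") records$significant_up else records$significant_down
    sub <- records[flag, c("feature", "stratum")]
    if (!nrow(sub)) next
    agg <- stats::aggregate(stratum ~ feature, sub,
                            function(r) sort(unique(r)), simplify = FALSE)
    out[[dir]] <- data.frame(
      feature = agg$feature, direction = dir,
      regions = vapply(agg$stratum, paste, "", collapse = ","),
      n_regions = lengths(agg$stratum),
      label = ifelse(lengths(agg$stratum) == 1, "unique", "multiple"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(feature = character(), direction = character(),
                      regions = character(), n_regions = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Bin numeric ages into half-open intervals
#'
#' Default intervals are the human-cohort bins \[71, 81), \[81, 92),
#' \[92, 103) in years. Ages outside every interval are returned as NA
#' with a warning.
#'
#' @param ages numeric vector.
#' @param intervals list of `c(lower, upper)` pairs, each half-open
#'   `[lower, upper)`.
#' @return character vector of interval labels (e.g. `"[71,81)"`).
#' @export
bin_ages <- function(ages, intervals = list(c(71, 81), c(81, 92), c(92, 103))) {
  labels <- vapply(intervals, function(iv) sprintf("[%g,%g)", iv[1], iv[2]), "")
  out <- rep(NA_character_, length(ages))
  for (i in seq_along(intervals)) {
    iv <- intervals[[i]]
    out[ages >= iv[1] & ages < iv[2]] <- labels[i]
  }
  if (any(is.na(out)))
    warning("bin_ages: ", sum(is.na(out)), " age(s) outside all intervals excluded")
  out
}

#' Build a ranked feature list for gene-set enrichment export
#'
#' Orders features from strongest-negative to strongest-positive effect:
#' negative-effect features come first, most significant at the extreme;
#' positive-effect features follow, most significant last. Features
#' without a sign (fold change 1 / rho 0) sit mid-list and are flagged.
#' Ties break deterministically by feature id.
#'
#' @param features character vector of feature ids.
#' @param effect signed effect (log2 fold change or correlation).
#' @param p p-values used as the significance ordering.
#' @return data.frame `feature`, `effect`, `p`, `unsigned` in ranked
#'   order.
#' @export
rank_for_gsea <- function(features, effect, p) {
  stopifnot(length(features) == length(effect), length(effect) == length(p))
  if (!length(features))
    return(data.frame(feature = character(), effect = numeric(),
                      p = numeric(), unsigned = logical()))
  df <- data.frame(feature = features, effect = effect, p = p,
                   unsigned = effect == 0 | !is.finite(effect),
                   stringsAsFactors = FALSE)
  neg <- df[!df$unsigned & df$effect < 0, ]
  pos <- df[!df$unsigned & df$effect > 0, ]
  mid <- df[df$unsigned, ]
  neg <- neg[order(neg$p, neg$feature), ]
  pos <- pos[order(-pos$p, pos$feature), ]
  mid <- mid[order(mid$feature), ]
  out <- rbind(neg, mid, pos)
  rownames(out) <- NULL
  out
}
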