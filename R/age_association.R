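#' Spearman rank correlation with a documented p-value
#'
#' rho is the Pearson correlation of average ranks (ties averaged). The
#' p-value uses the t approximation `t = rho * sqrt((n - 2) / (1 -
#' rho^2))` on n - 2 degrees of freedom, two-sided; `method = "exact"`
#' enumerates all permutations of `y` (only for n <= 8) and returns the
#' exact two-sided permutation p for |rho|.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method "t" (default) or "exact".
#' @return list with `rho`, `p`, and `degenerate` (TRUE when either
#'   vector is constant; rho and p are then NA).
#' @export
spearman <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y) || n < 3) stop("spearman: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "exact") {
    if (n > 8) stop("spearman: exact permutation p only for n <= 8")
    perms <- permutations_of(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(idx) stats::cor(rank(x), ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), degenerate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Region-wise Spearman correlation of expression with age
#'
#' Per region (optionally per sex), correlates every feature's normalized
#' expression with age in months, adjusts p-values by Benjamini-Hochberg
#' within each (region, split) family, and flags significance:
#' `significant_pos` when padj < `alpha` and rho > `rho_threshold`
#' (strict), `significant_neg` for rho < -`rho_threshold`.
#'
#' Strata with fewer than 3 samples, fewer than 2 distinct ages, or (for
#' split analyses) without at least 2 distinct ages carrying >= 2 samples
#' each are skipped with a warning — the rule generalizing the exclusion
#' of sparsely sampled old-female regions.
#'
#' @param norm normalized expression matrix.
#' @param meta sample metadata with `region`, `age_months`, `sex`.
#' @param split "none" (all samples) or "sex" (separate analyses).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param rho_threshold strict correlation threshold (default 0.5).
#' @return data.frame of correlation records: feature, region, split,
#'   rho, p, padj, n, significant_pos, significant_neg.
#' @export
age_correlation <- function(norm, meta, split = c("none", "sex"),
                            alpha = 0.05, rho_threshold = 0.5) {
  split <- match.arg(split)
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  splits <- if (split == "sex") unique(meta$sex) else "all"
  out <- list()
  for (sx in splits) {
    sel0 <- if (split == "sex") meta$sex == sx else rep(TRUE, nrow(meta))
    for (r in unique(meta$region)) {
      sel <- sel0 & meta$region == r
      age <- meta$age_months[sel]
      if (sum(sel) < 3 || length(unique(age)) < 2 ||
          sum(table(age) >= 2) < 2) {
        warning("age_correlation: stratum (", r, ", ", sx, ") skipped")
        next
      }
      sub <- norm[, sel, drop = FALSE]
      rk_age <- rank(age)
      rks <- t(apply(sub, 1, rank))
      rho <- suppressWarnings(as.numeric(stats::cor(t(rks), rk_age)))
      deg <- apply(sub, 1, function(v) stats::sd(v) == 0)
      rho[deg] <- NA
      n <- sum(sel)
      t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
      p <- pmin(p, 1)
      rec <- data.frame(feature = rownames(norm), region = r, split = sx,
                        rho = rho, p = p, n = n, stringsAsFactors = FALSE)
      ok <- !is.na(rec$p)
      rec$padj <- NA_real_
      rec$padj[ok] <- bh_adjust(rec$p[ok])
      rec$significant_pos <- !is.na(rec$padj) & rec$padj < alpha &
        rec$rho > rho_threshold
      rec$significant_neg <- !is.na(rec$padj) & rec$padj < alpha &
        rec$rho < -rho_threshold
      out[[paste(sx, r)]] <- rec
    }
  }
  if (!length(out)) stop("age_correlation: no stratum had enough samples")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify correlated features as unique or multiple across regions
#'
#' A feature is "unique" if it is significantly positively (or negatively)
#' age-correlated in exactly one region, "multiple" when the same
#' direction holds in more than one region; directions are tracked
#' separately.
#'
#' @param records correlation records from [age_correlation()] (one
#'   split at a time; filter the `split` column first if needed).
#' @return data.frame `feature`, `direction`, `regions`, `n_regions`,
#'   `label`.
#' @export
classify_correlation_uniqueness <- function(records) {
  out <- list()
  for (dir in c("pos", "neg")) {
    flag <- if (dir == "pos") records$significant_pos else records$significant_neg
    sub <- records[flag, c("feature", "region")]
    if (!nrow(sub)) next
    agg <- stats::aggregate(region ~ feature, sub,
                            function(r) sort(unique(r)), simplify = FALSE)
    out[[dir]] <- data.frame(
      feature = agg$feature, direction = dir,
      regions = vapply(agg$region, paste, "", collapse = ","),
      n_regions = lengths(agg$region),
      label = ifelse(lengths(agg$region) == 1, "unique", "multiple"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(feature = character(), direction = character(),
                      regions = character(), n_regions = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Aggregate age-related candidates from correlation and DE evidence
#'
#' A feature is a candidate if it is significantly positively or
#' negatively age-correlated in at least one region, or significantly
#' up-/downregulated in at least one old-vs-young age comparison in at
#' least one region. A feature whose direction changes across regions
#' still counts as one candidate.
#'
#' @param corr_records records from [age_correlation()] (may be NULL).
#' @param de_records records from [de_age_ladder()] (may be NULL).
#' @return list with `candidates` (character vector),
#'   `per_region` (named list of feature sets) and `table` (data.frame
#'   feature / regions / directions / sources).
#' @export
build_candidates <- function(corr_records = NULL, de_records = NULL) {
  entries <- list()
  if (!is.null(corr_records)) {
    hit <- corr_records$significant_pos | corr_records$significant_neg
    if (any(hit))
      entries$corr <- data.frame(
        feature = corr_records$feature[hit],
        region = corr_records$region[hit],
        direction = ifelse(corr_records$significant_pos[hit], "up", "down"),
        source = "correlation", stringsAsFactors = FALSE)
  }
  if (!is.null(de_records)) {
    hit <- de_records$significant_up | de_records$significant_down
    if (any(hit))
      entries$de <- data.frame(
        feature = de_records$feature[hit],
        region = de_records$stratum[hit],
        direction = ifelse(de_records$significant_up[hit], "up", "down"),
        source = "de", stringsAsFactors = FALSE)
  }
  if (!length(entries))
    return(list(candidates = character(0), per_region = list(),
                table = data.frame(feature = character(), regions = character(),
                                   directions = character(), sources = character(),
                                   stringsAsFactors = FALSE)))
  ev <- unique(do.call(rbind, c(entries, list(make.row.names = FALSE))))
  candidates <- sort(unique(ev$feature))
  per_region <- lapply(split(ev$feature, ev$region), function(x) sort(unique(x)))
  tab <- do.call(rbind, lapply(candidates, function(f) {
    sub <- ev[ev$feature == f, ]
    data.frame(feature = f,
               regions = paste(sort(unique(sub$region)), collapse = ","),
               directions = paste(sort(unique(sub$direction)), collapse = ","),
               sources = paste(sort(unique(sub$source)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(candidates = candidates, per_region = per_region, table = tab)
}

#' Intersect per-region significant sets with an external feature list
#'
#' @param per_region named list of feature sets (e.g.
#'   `build_candidates()$per_region` or per-region significant sets).
#' @param external character vector of external feature ids (e.g. a
#'   published target-predicted miRNA list).
#' @return data.frame `region`, `n_significant`, `n_overlap`, `overlap`
#'   (comma-joined ids).
#' @export
intersect_with_list <- function(per_region, external) {
  if (!length(per_region))
    return(data.frame(region = character(), n_significant = integer(),
                      n_overlap = integer(), overlap = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(per_region), function(r) {
    ov <- intersect(per_region[[r]], external)
    data.frame(region = r, n_significant = length(per_region[[r]]),
               n_overlap = length(ov),
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
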