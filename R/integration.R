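#' miRNA-mRNA target anti-correlation analysis
#'
#' For one regulator miRNA, correlates each linked target gene with the
#' miRNA per region (Spearman, t-approximation p-values), adjusts across
#' the whole (gene x region) family by Benjamini-Hochberg, and tiers the
#' hits: `anticorrelated` when rho <= `rho_threshold` (-0.3) and padj <
#' `alpha`; `strongly_anticorrelated` when rho < `strong_threshold`
#' (-0.5) and padj < `alpha` (the functionally-validated tier).
#'
#' @param mirna_norm normalized miRNA matrix (features x samples).
#' @param mrna_matrix genes x samples expression matrix; samples are
#'   matched to `mirna_norm` by column name.
#' @param links data.frame with columns `mirna`, `gene` (optional `tier`).
#' @param meta sample metadata with `region`.
#' @param mirna the regulator to analyse (default: the single miRNA in
#'   `links`).
#' @param rho_threshold,strong_threshold,alpha tier thresholds.
#' @return list with `records` (data.frame mirna / gene / region / rho /
#'   p / padj / n / anticorrelated / strongly_anticorrelated), `missing`
#'   (linked genes absent from the matrix) and `per_gene_regions` (named
#'   list: regions in which each gene is significantly anti-correlated).
#' @export
target_anticorrelation <- function(mirna_norm, mrna_matrix, links, meta,
                                   mirna = NULL, rho_threshold = -0.3,
                                   strong_threshold = -0.5, alpha = 0.05) {
  if (!nrow(links)) stop("target_anticorrelation: empty link list")
  if (is.null(mirna)) {
    mirna <- unique(links$mirna)
    if (length(mirna) > 1)
      stop("target_anticorrelation: multiple miRNAs in links; pass 'mirna'")
  }
  if (!mirna %in% rownames(mirna_norm))
    stop("target_anticorrelation: miRNA absent from matrix: ", mirna)
  genes <- unique(links$gene[links$mirna == mirna])
  missing <- setdiff(genes, rownames(mrna_matrix))
  genes <- intersect(genes, rownames(mrna_matrix))
  if (!length(genes)) stop("target_anticorrelation: no linked gene has data")
  common <- intersect(colnames(mirna_norm), colnames(mrna_matrix))
  if (!length(common)) stop("target_anticorrelation: no matched samples")
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  out <- list()
  for (r in unique(meta$region)) {
    ids <- meta$sample_id[meta$region == r]
    if (length(ids) < 3) next
    mv <- mirna_norm[mirna, ids]
    for (g in genes) {
      sp <- spearman(mrna_matrix[g, ids], mv)
      out[[paste(g, r)]] <- data.frame(mirna = mirna, gene = g, region = r,
                                       rho = sp$rho, p = sp$p,
                                       n = length(ids),
                                       stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  ok <- !is.na(rec$p)
  rec$padj <- NA_real_
  rec$padj[ok] <- bh_adjust(rec$p[ok])
  rec$anticorrelated <- !is.na(rec$padj) & rec$padj < alpha &
    rec$rho <= rho_threshold
  rec$strongly_anticorrelated <- !is.na(rec$padj) & rec$padj < alpha &
    rec$rho < strong_threshold
  sig <- rec[rec$anticorrelated, , drop = FALSE]
  per_gene <- lapply(split(sig$region, sig$gene), function(x) sort(unique(x)))
  list(records = rec, missing = missing, per_gene_regions = per_gene)
}

#' isomiR expression profiles relative to their archetype
#'
#' Computes, for one archetype miRNA and its isomiR family: per-(region,
#' age) median rpmm trajectories per isomiR and for the archetype; the
#' archetype-share trajectory `archetype / (archetype + sum(isomiRs))`;
#' the top-k isomiRs by median expression over all samples; and a region
#' clustering (complete linkage on the per-region mean standardized
#' isomiR expression, cut into `n_region_clusters`).
#'
#' @param isomir_norm rpmm-normalized isomiR matrix (same denominator as
#'   the archetype matrix).
#' @param mirna_norm rpmm-normalized miRNA matrix containing the
#'   archetype row.
#' @param archetype archetype feature id.
#' @param isomir_map data.frame with columns `isomir`, `archetype`.
#' @param meta sample metadata with `region` and `age_months`.
#' @param top_k top expressed isomiRs to report (default 25).
#' @param n_region_clusters region dendrogram cut (default 3).
#' @return list with `trajectories` (data.frame isomir / region /
#'   age_months / median_rpmm, incl. the archetype), `share` (data.frame
#'   region / age_months / archetype_share), `overall_share` (scalar),
#'   `top_isomirs`, `region_clusters` (named integer vector).
#' @export
isomir_profiles <- function(isomir_norm, mirna_norm, archetype, isomir_map,
                            meta, top_k = 25, n_region_clusters = 3) {
  if (!archetype %in% rownames(mirna_norm))
    stop("isomir_profiles: archetype absent from miRNA matrix: ", archetype)
  iso_ids <- isomir_map$isomir[isomir_map$archetype == archetype]
  iso_ids <- intersect(iso_ids, rownames(isomir_norm))
  if (!length(iso_ids)) stop("isomir_profiles: no isomiRs mapped to ", archetype)
  common <- intersect(colnames(isomir_norm), colnames(mirna_norm))
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  iso <- isomir_norm[iso_ids, common, drop = FALSE]
  arch <- mirna_norm[archetype, common]
  traj <- list(); share <- list()
  for (r in unique(meta$region)) {
    for (a in sort(unique(meta$age_months[meta$region == r]))) {
      ids <- meta$sample_id[meta$region == r & meta$age_months == a]
      med_iso <- apply(iso[, ids, drop = FALSE], 1, stats::median)
      med_arch <- stats::median(arch[ids])
      traj[[paste(r, a)]] <- data.frame(
        isomir = c(archetype, names(med_iso)),
        region = r, age_months = a,
        median_rpmm = c(med_arch, as.numeric(med_iso)),
        is_archetype = c(TRUE, rep(FALSE, length(med_iso))),
        stringsAsFactors = FALSE)
      denom <- med_arch + sum(med_iso)
      share[[paste(r, a)]] <- data.frame(
        region = r, age_months = a,
        archetype_share = if (denom > 0) med_arch / denom else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  med_all <- apply(iso, 1, stats::median)
  top <- names(sort(med_all, decreasing = TRUE))[seq_len(min(top_k, length(med_all)))]
  z <- zscore(iso, margin = 1)
  z <- z[!attr(z, "degenerate"), , drop = FALSE]
  region_clusters <- NULL
  if (nrow(z) >= 1 && length(unique(meta$region)) >= n_region_clusters) {
    reg_mean <- vapply(sort(unique(meta$region)), function(r)
      rowMeans(z[, meta$sample_id[meta$region == r], drop = FALSE]),
      numeric(nrow(z)))
    if (is.null(dim(reg_mean)))
      reg_mean <- matrix(reg_mean, nrow = 1,
                         dimnames = list(rownames(z), sort(unique(meta$region))))
    hc <- stats::hclust(stats::dist(t(reg_mean)), method = "complete")
    region_clusters <- stats::cutree(hc, k = n_region_clusters)
  }
  arch_med <- stats::median(arch)
  list(trajectories = do.call(rbind, c(traj, list(make.row.names = FALSE))),
       share = do.call(rbind, c(share, list(make.row.names = FALSE))),
       overall_share = arch_med / (arch_med + sum(med_all)),
       top_isomirs = top, region_clusters = region_clusters)
}
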