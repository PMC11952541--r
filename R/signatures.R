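#' Top variable features by coefficient of variation of group medians
#'
#' For each feature, takes the median expression per group (default:
#' brain region) and computes the coefficient of variation (sd / mean) of
#' that median vector. Returns the `k` features with the highest CV; ties
#' are broken lexicographically by feature id. Features with zero mean
#' median (CV undefined) are excluded with a warning.
#'
#' @param norm normalized expression matrix (features x samples).
#' @param meta sample metadata.
#' @param k number of features to select (default 50).
#' @param group metadata column defining the groups (default "region").
#' @return character vector of selected feature ids (attribute `cv`
#'   carries the CV values of all usable features).
#' @export
top_variable_features <- function(norm, meta, k = 50, group = "region") {
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  med <- group_medians(norm, meta[[group]])
  if (ncol(med) < 2) stop("top_variable_features: need >= 2 groups")
  mu <- rowMeans(med)
  cv <- apply(med, 1, stats::sd) / mu
  bad <- !is.finite(cv)
  if (any(bad)) {
    warning("top_variable_features: ", sum(bad),
            " feature(s) with undefined CV excluded")
    cv <- cv[!bad]
  }
  if (k > length(cv)) {
    warning("top_variable_features: k exceeds usable feature count; returning all")
    k <- length(cv)
  }
  ord <- order(-cv, names(cv))
  sel <- names(cv)[ord][seq_len(k)]
  attr(sel, "cv") <- cv
  sel
}

# features x groups matrix of per-group medians
group_medians <- function(norm, groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  out <- vapply(lv, function(g)
    apply(norm[, groups == g, drop = FALSE], 1, stats::median),
    numeric(nrow(norm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(norm), lv))
  out
}

#' Binarize region-median z-scores against the brain average
#'
#' A feature differs from the brain average in a region if the absolute
#' z-score of its region median is greater than or equal to `z_threshold`
#' (inclusive). Features entirely below the threshold in every region are
#' kept in the matrix but flagged for removal from display.
#'
#' @param region_medians features x regions matrix of medians.
#' @param z_threshold inclusive |z| threshold (default 0.5).
#' @return list with `binary` (0/1 matrix), `z` (the z-score matrix) and
#'   `display` (logical; FALSE for features entirely below threshold).
#' @export
signature_binarize <- function(region_medians, z_threshold = 0.5) {
  z <- zscore(region_medians, margin = 1)
  binary <- (abs(z) >= z_threshold) * 1L
  list(binary = binary, z = z, display = rowSums(binary) > 0)
}

#' Cluster regions on binarized signature profiles
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' binary region profiles, cut into `n_clusters` clusters. Distance is
#' Euclidean on the 0/1 columns by default (same ordering as Hamming);
#' `"hamming"` (Manhattan on 0/1) and `"jaccard"` (binary) are available.
#'
#' @param binary features x regions 0/1 matrix.
#' @param n_clusters number of clusters to cut (default 4).
#' @param distance one of "euclidean", "hamming", "jaccard".
#' @return named integer vector of cluster labels per region.
#' @export
cluster_regions <- function(binary, n_clusters = 4,
                            distance = c("euclidean", "hamming", "jaccard")) {
  distance <- match.arg(distance)
  if (ncol(binary) < n_clusters)
    stop("cluster_regions: fewer regions than clusters")
  d <- switch(distance,
              euclidean = stats::dist(t(binary)),
              hamming = stats::dist(t(binary), method = "manhattan"),
              jaccard = stats::dist(t(binary), method = "binary"))
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' Region-signature analysis (CV selection, binarization, clustering)
#'
#' Convenience wrapper running [top_variable_features()],
#' [signature_binarize()] and [cluster_regions()] on one dataset, with
#' per-feature specificity classification: a feature is brain-region
#' specific when it differs from the brain average in exactly one region.
#'
#' @param norm normalized matrix; @param meta metadata.
#' @param k top features by CV; @param z_threshold binarization threshold.
#' @param n_clusters region clusters; @param ages optional age subset
#'   (e.g. the young-adult set `c(3, 12, 15)`).
#' @return list with `features`, `region_medians`, `z`, `binary`,
#'   `display`, `region_clusters`, `specificity` (data.frame feature_id /
#'   n_regions / class in specific|multi|none).
#' @export
region_signatures <- function(norm, meta, k = 50, z_threshold = 0.5,
                              n_clusters = 4, ages = NULL) {
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  if (!is.null(ages)) {
    keep <- meta$age_months %in% ages
    norm <- norm[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  sel <- top_variable_features(norm, meta, k = k)
  med <- group_medians(norm[sel, , drop = FALSE], meta$region)
  bz <- signature_binarize(med, z_threshold)
  nreg <- rowSums(bz$binary)
  spec <- data.frame(feature_id = rownames(bz$binary), n_regions = nreg,
                     class = ifelse(nreg == 1, "specific",
                                    ifelse(nreg > 1, "multi", "none")),
                     stringsAsFactors = FALSE)
  list(features = as.character(sel), universe = rownames(norm),
       region_medians = med, z = bz$z,
       binary = bz$binary, display = bz$display,
       region_clusters = cluster_regions(bz$binary, n_clusters),
       specificity = spec)
}

#' Compare male and female region signatures
#'
#' Classifies each feature appearing in either sex's signature set:
#' `common` (selected in both sexes), within those `same_single_region`
#' (differs from the brain average in exactly one and the same region in
#' both sexes) and `same_multi_region_set` (the same set of more than one
#' region in both sexes); plus `male_only` / `female_only` exclusive sets.
#'
#' @param sig_m,sig_f results of [region_signatures()] for the two sexes
#'   (must share the feature universe they were computed from).
#' @return list of character vectors: `common`, `same_single_region`,
#'   `same_multi_region_set`, `male_only`, `female_only`.
#' @export
compare_sex_signatures <- function(sig_m, sig_f) {
  fm <- sig_m$features; ff <- sig_f$features
  if (length(intersect(sig_m$universe, sig_f$universe)) == 0)
    stop("compare_sex_signatures: signatures computed on disjoint feature universes")
  common <- intersect(fm, ff)
  regset <- function(sig, f) {
    if (!f %in% rownames(sig$binary)) return(character(0))
    colnames(sig$binary)[sig$binary[f, ] == 1]
  }
  same_single <- common[vapply(common, function(f) {
    a <- regset(sig_m, f); b <- regset(sig_f, f)
    length(a) == 1 && identical(a, b)
  }, TRUE)]
  same_multi <- common[vapply(common, function(f) {
    a <- regset(sig_m, f); b <- regset(sig_f, f)
    length(a) > 1 && setequal(a, b)
  }, TRUE)]
  list(common = common, same_single_region = same_single,
       same_multi_region_set = same_multi,
       male_only = setdiff(fm, ff), female_only = setdiff(ff, fm))
}
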