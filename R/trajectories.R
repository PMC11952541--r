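#' Build standardized per-(feature, region) age trajectories
#'
#' For every feature and region, summarizes expression per age stage
#' (median by default) over the shared age grid and z-scores the summary
#' across ages (population SD). One trajectory per (feature, region) is
#' produced, so 1,174 features over 15 regions yield 17,610 trajectories.
#' Constant trajectories are flagged degenerate and regions covering
#' fewer than 3 age stages are flagged non-clusterable.
#'
#' @param norm normalized expression matrix.
#' @param meta sample metadata with `region` and `age_months`.
#' @param summary "median" or "mean" per-age summary.
#' @return object of class `trajectory_set`: list with `z` (trajectories
#'   x ages matrix of z-scored summaries), `raw` (unstandardized),
#'   `info` (data.frame feature / region / degenerate / clusterable),
#'   `ages` (the age grid) and `summary`.
#' @export
build_trajectories <- function(norm, meta, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  fun <- if (summary == "median") stats::median else mean
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  ages <- sort(unique(meta$age_months))
  regions <- sort(unique(meta$region))
  n_traj <- nrow(norm) * length(regions)
  raw <- matrix(NA_real_, n_traj, length(ages),
                dimnames = list(NULL, as.character(ages)))
  info <- data.frame(feature = rep(rownames(norm), times = length(regions)),
                     region = rep(regions, each = nrow(norm)),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (r in regions) {
    meta_r <- meta[meta$region == r, ]
    cells <- lapply(ages, function(a) meta_r$sample_id[meta_r$age_months == a])
    sub <- norm[, meta$region == r, drop = FALSE]
    summ <- vapply(cells, function(ids) {
      if (!length(ids)) return(rep(NA_real_, nrow(norm)))
      apply(norm[, ids, drop = FALSE], 1, fun)
    }, numeric(nrow(norm)))
    if (is.null(dim(summ))) summ <- matrix(summ, nrow = 1)
    raw[row + seq_len(nrow(norm)), ] <- summ
    row <- row + nrow(norm)
  }
  rownames(raw) <- paste(info$feature, info$region, sep = "|")
  n_obs <- rowSums(!is.na(raw))
  complete <- n_obs == length(ages)
  z <- raw
  mu <- rowMeans(raw, na.rm = TRUE)
  sd <- sqrt(rowMeans((raw - mu)^2, na.rm = TRUE))
  deg <- !is.na(sd) & sd == 0
  sd[deg | is.na(sd)] <- 1
  z <- (raw - mu) / sd
  z[deg, ] <- 0
  info$degenerate <- deg
  info$clusterable <- complete & !deg & n_obs >= 3
  out <- list(z = z, raw = raw, info = info, ages = ages, summary = summary)
  class(out) <- "trajectory_set"
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d trajectories (%d features x %d regions), %d age stages\n",
              nrow(x$z), length(unique(x$info$feature)),
              length(unique(x$info$region)), length(x$ages)))
  cat(sprintf("  clusterable: %d, degenerate: %d\n",
              sum(x$info$clusterable), sum(x$info$degenerate)))
  invisible(x)
}

# squared Euclidean distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) + outer(rep(1, nrow(a)), rowSums(b^2)) -
    2 * a %*% t(b)
}

#' Fuzzy c-means clustering of trajectories
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))`, centroids the
#' `u^m`-weighted means. Centroids are initialized from `k` trajectories
#' chosen by distance-weighted (kmeans++-style) sampling under `seed`;
#' with `nstart > 1` the run with the lowest final objective is kept.
#' Iteration stops when the maximum membership change falls below `tol`;
#' the objective function value is recorded per iteration (it is
#' non-increasing). After convergence the centroids are recomputed once
#' from the final memberships, so each centroid equals the
#' membership-weighted mean exactly.
#'
#' @param x trajectories x ages matrix (z-scored, complete rows), or a
#'   `trajectory_set` (its clusterable rows are used).
#' @param k number of clusters (>= 1).
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on memberships (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param seed integer seed for the centroid initialization.
#' @param nstart number of initializations; the lowest-objective run wins
#'   (default 3).
#' @return object of class `fuzzy_cmeans`: list with `centroids` (k x
#'   ages), `membership` (rows sum to 1), `k`, `m`, `objective`
#'   (per-iteration values), `converged`, `iterations`, `seed`.
#' @export
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-6, max_iter = 200, seed = 1L,
                         nstart = 3L) {
  if (inherits(x, "trajectory_set")) x <- x$z[x$info$clusterable, , drop = FALSE]
  stopifnot(k >= 1, m > 1, k <= nrow(x))
  best <- NULL
  warn_nc <- FALSE
  for (run in seq_len(max(1L, nstart))) {
    fit <- fcm_once(x, k, m, tol, max_iter, seed + (run - 1L) * 1009L)
    if (is.null(best) || utils::tail(fit$objective, 1) <
          utils::tail(best$objective, 1)) best <- fit
    if (!fit$converged) warn_nc <- TRUE
  }
  if (warn_nc && !best$converged)
    warning("fuzzy_cmeans: not converged after ", max_iter, " iterations")
  u <- best$u
  um <- u^m
  centroids <- (t(um) %*% x) / colSums(um)
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  dimnames(u) <- list(rownames(x), rownames(centroids))
  out <- list(centroids = centroids, membership = u, k = k, m = m,
              objective = best$objective, converged = best$converged,
              iterations = best$iterations, seed = seed)
  class(out) <- "fuzzy_cmeans"
  out
}

# one seeded c-means run with kmeans++-style centroid initialization
fcm_once <- function(x, k, m, tol, max_iter, seed) {
  n <- nrow(x)
  eps <- 1e-12
  centroids <- withr_seed(seed, {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1)
    if (k > 1) for (j in 2:k) {
      d2 <- apply(cross_dist2(x, x[idx[seq_len(j - 1)], , drop = FALSE]),
                  1, min)
      d2[idx[seq_len(j - 1)]] <- 0
      idx[j] <- if (sum(d2) > 0) sample.int(n, 1, prob = d2)
      else sample.int(n, 1)
    }
    x[idx, , drop = FALSE] + matrix(stats::rnorm(k * ncol(x), sd = 1e-9), k)
  })
  update_u <- function(centroids) {
    d2 <- pmax(cross_dist2(x, centroids), eps)
    w <- d2^(-1 / (m - 1))
    w / rowSums(w)
  }
  u <- update_u(centroids)
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    u_new <- update_u(centroids)
    d2 <- pmax(cross_dist2(x, centroids), eps)
    objective <- c(objective, sum(u_new^m * d2))
    if (max(abs(u_new - u)) < tol) { u <- u_new; converged <- TRUE; break }
    u <- u_new
  }
  list(u = u, objective = objective, converged = converged, iterations = it)
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("fuzzy c-means: k=%d, m=%g, %d trajectories, %s after %d iteration(s)\n",
              x$k, x$m, nrow(x$membership),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Minimum-centroid-distance curve over a range of cluster numbers
#'
#' For each k, runs a short fuzzy c-means and records the minimum
#' pairwise distance between centroids (an mfuzz-style Dmin diagnostic).
#' The curve is meant for visual inspection; an automatic elbow
#' suggestion (largest relative drop) is provided but never applied
#' silently.
#'
#' @param x trajectory matrix or `trajectory_set`.
#' @param k_range integer vector of cluster numbers (default 2:20).
#' @param m fuzzifier; @param seed seed; @param max_iter per-k iteration
#'   cap for the short runs (default 30).
#' @return data.frame `k`, `min_centroid_dist` with attribute
#'   `suggested_k`.
#' @export
select_k <- function(x, k_range = 2:20, m = 2, seed = 1L, max_iter = 30) {
  if (inherits(x, "trajectory_set")) x <- x$z[x$info$clusterable, , drop = FALSE]
  k_range <- k_range[k_range >= 2 & k_range < nrow(x)]
  dmin <- vapply(k_range, function(k) {
    fit <- suppressWarnings(fuzzy_cmeans(x, k, m = m, seed = seed,
                                         max_iter = max_iter, tol = 1e-4))
    min(stats::dist(fit$centroids))
  }, numeric(1))
  out <- data.frame(k = k_range, min_centroid_dist = dmin)
  if (length(dmin) > 1) {
    drop_rel <- -diff(dmin) / pmax(dmin[-length(dmin)], 1e-12)
    attr(out, "suggested_k") <- k_range[which.max(drop_rel) + 1L]
  }
  out
}

#' Hard-assign trajectories and filter by maximum membership
#'
#' Each trajectory goes to the cluster of its highest membership;
#' trajectories whose maximum membership is strictly below
#' `min_membership` are discarded (0.15 kept, 0.14 dropped).
#'
#' @param model a [fuzzy_cmeans()] fit.
#' @param min_membership threshold (default 0.15).
#' @return data.frame `trajectory`, `cluster`, `membership`, `kept`.
#' @export
assign_and_filter <- function(model, min_membership = 0.15) {
  u <- model$membership
  best <- max.col(u, ties.method = "first")
  mm <- u[cbind(seq_len(nrow(u)), best)]
  data.frame(trajectory = rownames(u), cluster = best, membership = mm,
             kept = mm >= min_membership, stringsAsFactors = FALSE)
}

#' Cluster specificity: region share and feature incidence
#'
#' Per cluster (singletons excluded from evaluation): the share of
#' members from the most frequent region (`region_specific` when >=
#' `region_share_threshold`) and the incidence of the most frequent
#' feature (`feature_specific` when >= `feature_incidence_threshold`).
#' Trajectory names are parsed as `feature|region`.
#'
#' @param assignments output of [assign_and_filter()] (kept rows used).
#' @param region_share_threshold default 0.30 (inclusive).
#' @param feature_incidence_threshold default 4 (inclusive).
#' @return data.frame per evaluated cluster: `cluster`, `size`,
#'   `top_region`, `top_region_share`, `region_specific`, `top_feature`,
#'   `top_feature_incidence`, `feature_specific`.
#' @export
cluster_specificity <- function(assignments, region_share_threshold = 0.30,
                                feature_incidence_threshold = 4) {
  kept <- assignments[assignments$kept, , drop = FALSE]
  parts <- strsplit(kept$trajectory, "|", fixed = TRUE)
  kept$feature <- vapply(parts, `[`, "", 1L)
  kept$region <- vapply(parts, `[`, "", 2L)
  out <- list()
  for (cl in sort(unique(kept$cluster))) {
    sub <- kept[kept$cluster == cl, ]
    if (nrow(sub) <= 1) next  # singleton clusters are excluded
    rt <- sort(table(sub$region), decreasing = TRUE)
    ft <- sort(table(sub$feature), decreasing = TRUE)
    out[[as.character(cl)]] <- data.frame(
      cluster = cl, size = nrow(sub),
      top_region = names(rt)[1],
      top_region_share = as.numeric(rt[1]) / nrow(sub),
      region_specific = rt[1] / nrow(sub) >= region_share_threshold,
      top_feature = names(ft)[1],
      top_feature_incidence = as.integer(ft[1]),
      feature_specific = ft[1] >= feature_incidence_threshold,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = integer(), size = integer(),
                      top_region = character(), top_region_share = numeric(),
                      region_specific = logical(), top_feature = character(),
                      top_feature_incidence = integer(),
                      feature_specific = logical(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster center lines and the per-feature cluster trace
#'
#' Returns the centroid trajectory of every cluster holding at least one
#' kept trajectory of `feature` (or of all clusters when `feature` is
#' NULL). The centroids equal the membership-weighted means of the model.
#'
#' @param model a [fuzzy_cmeans()] fit.
#' @param assignments output of [assign_and_filter()].
#' @param feature optional feature id to trace across clusters.
#' @return list with `centers` (matrix, one row per selected cluster) and
#'   `clusters` (the cluster indices).
#' @export
center_lines <- function(model, assignments, feature = NULL) {
  kept <- assignments[assignments$kept, , drop = FALSE]
  if (!is.null(feature)) {
    f <- sub("\\|.*$", "", kept$trajectory)
    kept <- kept[f == feature, , drop = FALSE]
  }
  cls <- sort(unique(kept$cluster))
  list(centers = model$centroids[cls, , drop = FALSE], clusters = cls)
}
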