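test_that("trajectory count is features x regions and z-rows are standardized", {
  meta <- tiny_meta(regions = c("r1", "r2", "r3"), ages = c(3, 12, 15, 18),
                    n_rep = 2)
  set.seed(2)
  m <- tiny_matrix(meta, 7, fill = function(n) rgamma(n, 4))
  ts <- build_trajectories(m, meta)
  expect_equal(nrow(ts$z), 7 * 3)
  expect_equal(ncol(ts$z), 4)
  ok <- ts$info$clusterable
  expect_true(all(abs(rowMeans(ts$z[ok, ])) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(ts$z[ok, ]^2)) - 1) < 1e-12))
  # constant feature is degenerate and excluded from clustering
  m2 <- m; m2[1, ] <- 3
  ts2 <- build_trajectories(m2, meta)
  expect_true(all(ts2$info$degenerate[ts2$info$feature == "f001"]))
  expect_false(any(ts2$info$clusterable[ts2$info$feature == "f001"]))
  # a linearly increasing feature keeps a strictly increasing z-trajectory
  m3 <- m; m3[2, ] <- meta$age_months * 2 + 1
  ts3 <- build_trajectories(m3, meta)
  tr <- ts3$z[ts3$info$feature == "f002", ][1, ]
  expect_true(all(diff(tr) > 0))
})

test_that("fuzzy c-means: k=1 collapses, separated duplicates resolve, rows sum to 1", {
  x <- rbind(a1 = c(5, 5, 5, -5), a2 = c(5, 5, 5, -5),
             b1 = c(-5, -5, -5, 5), b2 = c(-5, -5, -5, 5))
  fit1 <- fuzzy_cmeans(x, k = 1, seed = 1)
  expect_true(all(fit1$membership == 1))
  expect_equal(as.numeric(fit1$centroids), colMeans(x))
  fit2 <- fuzzy_cmeans(x, k = 2, seed = 1)
  expect_true(all(apply(fit2$membership, 1, max) > 0.99))
  ord <- order(fit2$centroids[, 1])
  expect_equal(unname(fit2$centroids[ord[1], ]), c(-5, -5, -5, 5),
               tolerance = 0.05)
  expect_equal(unname(fit2$centroids[ord[2], ]), c(5, 5, 5, -5),
               tolerance = 0.05)
  expect_equal(unname(rowSums(fit2$membership)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(diff(fit2$objective) <= 1e-8))
})

test_that("centroids equal the membership-weighted means exactly after convergence", {
  tr <- sample_trajectories(per_template = 25, sigma = 0.3, seed = 3)
  fit <- fuzzy_cmeans(tr$x, k = 4, seed = 3)
  um <- fit$membership^fit$m
  recomputed <- (t(um) %*% tr$x) / colSums(um)
  expect_lt(max(abs(recomputed - fit$centroids)), 1e-9)
  # deterministic under a fixed seed
  fit2 <- fuzzy_cmeans(tr$x, k = 4, seed = 3)
  expect_identical(fit$centroids, fit2$centroids)
})

test_that("planted templates are recovered and order only relabels clusters", {
  tr <- sample_trajectories(per_template = 30, sigma = 0.3, seed = 7)
  fit <- fuzzy_cmeans(tr$x, k = 4, seed = 7)
  hard <- max.col(fit$membership)
  expect_gte(ari(hard, tr$labels), 0.8)
  set.seed(1)
  perm <- sample(nrow(tr$x))
  fitp <- fuzzy_cmeans(tr$x[perm, ], k = 4, seed = 7)
  expect_gte(ari(max.col(fitp$membership), tr$labels[perm]), 0.8)
  expect_equal(ari(max.col(fitp$membership), hard[perm]), 1, tolerance = 1e-9)
})

test_that("independent c-means implementation agrees on well-separated data", {
  tr <- sample_trajectories(per_template = 20, sigma = 0.15, seed = 11)
  fit <- fuzzy_cmeans(tr$x, k = 4, seed = 11)
  ref <- e1071::cmeans(tr$x, centers = 4, m = 2)
  expect_equal(ari(max.col(fit$membership), ref$cluster), 1, tolerance = 1e-9)
})

test_that("select_k drops sharply after the true template count", {
  tr <- sample_trajectories(per_template = 20, sigma = 0.05, seed = 13)
  curve <- select_k(tr$x, k_range = 2:6, seed = 13)
  d <- curve$min_centroid_dist
  # distance collapses once k exceeds the 4 planted templates
  expect_gt(min(d[curve$k <= 4]), 2 * max(d[curve$k > 4]))
  # identical trajectories at k=2: near-zero centroid separation
  same <- matrix(rep(c(1, 2, 3, 2), 10), nrow = 10, byrow = TRUE)
  rownames(same) <- paste0("t", 1:10)
  c2 <- suppressWarnings(select_k(same, k_range = 2, seed = 1))
  expect_lt(c2$min_centroid_dist, 0.2)
  expect_identical(select_k(tr$x, k_range = 2:4, seed = 5),
                   select_k(tr$x, k_range = 2:4, seed = 5))
})

test_that("assignment filter is strict below 15% and specificity thresholds are inclusive", {
  u <- rbind(t1 = c(0.86, 0.14), t2 = c(0.85, 0.15), t3 = c(0.5, 0.5))
  colnames(u) <- c("c1", "c2")
  model <- structure(list(membership = u / rowSums(u),
                          centroids = matrix(0, 2, 3), k = 2, m = 2),
                     class = "fuzzy_cmeans")
  model$membership <- u   # exact values for the boundary check
  asg <- assign_and_filter(model, min_membership = 0.15)
  expect_true(all(asg$kept[asg$trajectory %in% c("t1", "t2", "t3")]))
  u2 <- rbind(lo = c(0.14, 0.13, 0.73))  # max membership 0.73 -> kept
  model2 <- model; model2$membership <- rbind(hi = c(0.86, 0.14),
                                              lo = c(0.14, 0.86),
                                              edge = c(0.15, 0.85))
  asg2 <- assign_and_filter(model2)
  expect_equal(asg2$membership, c(0.86, 0.86, 0.85))
  model3 <- model
  model3$membership <- rbind(drop = c(0.14, 0.14), keep = c(0.15, 0.15))
  asg3 <- assign_and_filter(model3)
  expect_false(asg3$kept[asg3$trajectory == "drop"])
  expect_true(asg3$kept[asg3$trajectory == "keep"])

  # cluster of 10 with 3 from one region: 30% >= 30% -> region specific
  asg4 <- data.frame(
    trajectory = c(sprintf("f%02d|regA", 1:3), sprintf("f%02d|reg%02d", 4:10, 4:10),
                   sprintf("g01|reg%02d", 1:4), "h|x", "h2|x2"),
    cluster = c(rep(1, 10), rep(2, 4), 3, 3),
    membership = 0.9, kept = TRUE)
  spec <- cluster_specificity(asg4)
  c1 <- spec[spec$cluster == 1, ]
  expect_true(c1$region_specific)          # 3/10 = 30% inclusive
  expect_false(c1$feature_specific)
  c2 <- spec[spec$cluster == 2, ]
  expect_true(c2$feature_specific)         # g01 appears 4 times
  expect_equal(c2$top_feature, "g01")
  # singleton clusters are excluded from evaluation
  asg5 <- asg4; asg5$cluster[asg5$cluster == 3] <- c(3, 4)
  spec5 <- cluster_specificity(asg5)
  expect_false(any(spec5$cluster %in% c(3, 4)))
  # 2/10 = 20% fails the region threshold
  asg6 <- asg4
  asg6$trajectory[3] <- "f03|regZ"
  expect_false(cluster_specificity(asg6)[1, "region_specific"])
})

test_that("center lines trace a feature across clusters and recompute exactly", {
  tr <- sample_trajectories(per_template = 15, sigma = 0.2, seed = 17)
  rownames(tr$x)[1:3] <- c("mirX|r01", "mirX|r02", "mirX|r03")
  fit <- fuzzy_cmeans(tr$x, k = 4, seed = 17)
  asg <- assign_and_filter(fit)
  cl <- center_lines(fit, asg, feature = "mirX")
  expected <- sort(unique(asg$cluster[asg$kept &
    grepl("^mirX\\|", asg$trajectory)]))
  expect_equal(cl$clusters, expected)
  expect_equal(nrow(cl$centers), length(expected))
  none <- center_lines(fit, asg, feature = "absent")
  expect_equal(length(none$clusters), 0)
  all_cl <- center_lines(fit, asg)
  expect_equal(nrow(all_cl$centers), length(unique(asg$cluster[asg$kept])))
})
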