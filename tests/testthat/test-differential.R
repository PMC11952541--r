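test_that("group centers match closed forms", {
  expect_equal(group_center(c(2, 8), "geometric_mean", pseudocount = 0), 4)
  expect_equal(group_center(c(1, 2, 9), "median"), 2)
  expect_equal(group_center(c(0, 0, 0), "geometric_mean", pseudocount = 1), 0)
  expect_error(group_center(numeric(0)), "empty")
  expect_error(group_center(c(0, 1), "geometric_mean", pseudocount = 0),
               "pseudocount")
})

test_that("Welch p matches the textbook formula and handles degenerate groups", {
  a <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  b <- c(10.1, 8.2, 12.5, 9.9)
  expect_equal(welch_test(a, b), welch_oracle(a, b), tolerance = 1e-10)
  expect_equal(welch_test(a, a), 1)
  # equal n and equal variances: Welch df collapse to Student df
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(welch_test(x, y), t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(welch_test(c(1, 1), c(1, 1)), 1)
  expect_equal(welch_test(c(1, 1), c(2, 2)), 0)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment equals the brute-force min-tail formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("Cohen's d follows the pooled-SD formula and sign convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 vs 2; pooled SD on nA+nB-2 df = sqrt((1*2 + 1*2)/2) = sqrt(2)
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2))
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  sp <- sqrt((9 * var(a) + 11 * var(b)) / 20)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
})

test_that("DE analysis computes fold changes, reciprocal symmetry and flags", {
  meta <- tiny_meta(regions = "cortex", ages = 3, sexes = c("M", "F"),
                    n_rep = 4)
  set.seed(8)
  m <- tiny_matrix(meta, 6, fill = function(n) rgamma(n, 5, 0.1))
  m[, meta$sex == "M"] <- 2 * m[, meta$sex == "F"]   # exact 2x everywhere
  for (center in c("geometric_mean", "median")) {
    rec <- de_analysis(m, meta, "sex", "M", "F", center = center,
                       pseudocount = 0)
    expect_equal(rec$fc, rep(2, 6), tolerance = 1e-12)
    rev_rec <- de_analysis(m, meta, "sex", "F", "M", center = center,
                           pseudocount = 0)
    expect_equal(rec$fc * rev_rec$fc, rep(1, 6), tolerance = 1e-12)
    expect_equal(rec$log2fc, -rev_rec$log2fc, tolerance = 1e-12)
    expect_equal(rec$p, rev_rec$p, tolerance = 1e-12)
  }
  rec <- de_analysis(m, meta, "sex", "M", "F", effect_size = TRUE)
  rev_rec <- de_analysis(m, meta, "sex", "F", "M", effect_size = TRUE)
  expect_equal(rec$cohens_d, -rev_rec$cohens_d, tolerance = 1e-12)
  # fc == 1 features are excluded before adjustment
  m2 <- m; m2[1, ] <- 7
  rec2 <- de_analysis(m2, meta, "sex", "M", "F", center = "median")
  expect_true(rec2$excluded_no_dereg[1])
  expect_true(is.na(rec2$padj[1]))
})

test_that("null DE data stays quiet and a planted 4-fold sex effect is found", {
  detected <- logical(6); fp <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(n_features = 80, regions = c("cortex", "pons"),
                      n_per_group = 5,
                      planted_sex_effects = list(list(
                        feature = 1, regions = "cortex", log2_offset = 2)),
                      seed = 300 + s)
    meta <- generate_metadata(cfg)
    gen <- generate_counts(meta, cfg)
    norm <- rpmm(gen$counts, gen$rna_class)
    rec <- de_analysis(norm, meta, "sex", "M", "F")
    hit <- rec[rec$feature == "mir-0001", ]
    detected[s] <- hit$significant_up[hit$stratum == "cortex"] &&
      !hit$significant_up[hit$stratum == "pons"]
    null_rec <- rec[rec$feature != "mir-0001", ]
    fp[s] <- mean(null_rec$significant_up | null_rec$significant_down,
                  na.rm = TRUE)
  }
  expect_gte(mean(detected), 5 / 6)
  expect_lte(mean(fp), 0.01)
})

test_that("uniqueness labels count regions per direction", {
  rec <- data.frame(
    feature = c("a", "a", "a", "b", "c", "c"),
    stratum = c("r1", "r2", "r3", "r1", "r1", "r2"),
    significant_up = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    significant_down = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  lab <- classify_uniqueness(rec)
  expect_equal(lab$label[lab$feature == "a" & lab$direction == "up"], "multiple")
  expect_equal(lab$label[lab$feature == "b" & lab$direction == "up"], "unique")
  # c is up in r1 and down in r2: tracked separately, each unique
  expect_setequal(lab$label[lab$feature == "c"], c("unique", "unique"))
})

test_that("age binning respects half-open intervals", {
  expect_equal(bin_ages(80), "[71,81)")
  expect_equal(bin_ages(81), "[81,92)")
  expect_equal(suppressWarnings(bin_ages(103)), NA_character_)
  expect_warning(bin_ages(c(75, 103)), "outside")
  expect_equal(bin_ages(c(71, 91.9, 92)),
               c("[71,81)", "[81,92)", "[92,103)"))
})

test_that("GSEA ranking runs from strongest-negative to strongest-positive", {
  r <- rank_for_gsea(c("up1", "up2", "dn1"), c(1, 0.5, -1),
                     c(0.001, 0.5, 0.01))
  expect_equal(r$feature, c("dn1", "up2", "up1"))
  r2 <- rank_for_gsea(c("a", "b", "c"), c(2, 1, 3), c(0.5, 0.01, 0.1))
  expect_equal(r2$feature, c("a", "c", "b"))   # all positive: pure p-order, most significant last
  expect_equal(nrow(rank_for_gsea(character(0), numeric(0), numeric(0))), 0)
  r3 <- rank_for_gsea(c("x", "neg"), c(0, -2), c(0.5, 0.01))
  expect_true(r3$unsigned[r3$feature == "x"])
  expect_equal(r3$feature[1], "neg")
})
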