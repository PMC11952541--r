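test_that("metadata is the full factorial design, deterministic, with cell drops", {
  cfg <- sim_config(n_features = 10, sexes = "M", n_per_group = 2, seed = 4)
  meta <- generate_metadata(cfg)
  expect_equal(nrow(meta), 15 * 7 * 1 * 2)
  expect_identical(meta, generate_metadata(cfg))

  cfg2 <- sim_config(n_features = 10, n_per_group = 2, seed = 4,
                     drop_cells = list(list(region = "pons", sex = "F",
                                            ages = c(26, 28))))
  m2 <- generate_metadata(cfg2)
  expect_equal(sum(m2$region == "pons" & m2$sex == "F" &
                     m2$age_months %in% c(26, 28)), 0)
  expect_gt(sum(m2$region == "pons" & m2$sex == "F" & m2$age_months == 21), 0)

  expect_error(sim_config(regions = character(0)), "non-empty")
  expect_error(sim_config(n_per_group = 1), ">= 2")
  expect_error(sim_config(ages_months = c(3, 3, 12)), "increasing")
})

test_that("counts are non-negative integers with library sizes in the configured envelope", {
  cfg <- sim_config(n_features = 40, regions = c("cortex", "pons"),
                    n_per_group = 3, library_size_mean = 5e4,
                    library_size_cv = 0.2, seed = 9)
  meta <- generate_metadata(cfg)
  gen <- generate_counts(meta, cfg)
  expect_true(all(gen$counts >= 0))
  expect_true(all(gen$counts == round(gen$counts)))
  expect_identical(dim(gen$counts), c(40L, nrow(meta)))
  # totals within a generous lognormal envelope around the configured mean
  expect_true(all(colSums(gen$counts) > 5e4 / 4))
  expect_true(all(colSums(gen$counts) < 5e4 * 4))
  expect_error(generate_counts(meta, sim_config(n_features = 5,
    planted_age_effects = list(list(feature = 9, regions = "pons",
                                    shape = "linear", magnitude = 0.5)))),
    "outside")
})

test_that("null features give age correlations centered at zero; planted linear effects realize the target rho", {
  regions <- atlas_regions()[1:8]
  rhos_null <- c(); rhos_planted <- c()
  for (s in 1:5) {
    cfg <- sim_config(n_features = 40, regions = regions, n_per_group = 5,
                      planted_age_effects = list(
                        list(feature = 1, regions = regions,
                             shape = "linear", magnitude = 0.9)),
                      seed = 100 + s)
    meta <- generate_metadata(cfg)
    gen <- generate_counts(meta, cfg)
    norm <- rpmm(gen$counts, gen$rna_class)
    corr <- suppressWarnings(age_correlation(norm, meta, split = "none"))
    rhos_planted <- c(rhos_planted, corr$rho[corr$feature == "mir-0001"])
    rhos_null <- c(rhos_null, corr$rho[corr$feature %in%
                                         sprintf("mir-%04d", 20:40)])
  }
  expect_lt(abs(median(rhos_null, na.rm = TRUE)), 0.1)
  expect_gt(mean(rhos_planted > 0.5), 0.95)
  expect_gt(mean(rhos_planted), 0.75)
})

test_that("step and peak shapes shift expression only at the configured ages", {
  cfg <- sim_config(n_features = 100, regions = "cortex", n_per_group = 5,
                    nb_dispersion = 0.01, library_size_mean = 1e6,
                    planted_age_effects = list(
                      list(feature = 1, regions = "cortex", shape = "step",
                           magnitude = 3, onset_age = 15),
                      list(feature = 2, regions = "cortex", shape = "peak",
                           magnitude = 3, peak_age = 15)),
                    seed = 21)
  meta <- generate_metadata(cfg)
  gen <- generate_counts(meta, cfg)
  norm <- rpmm(gen$counts, gen$rna_class)
  by_age <- function(f) tapply(norm[f, ], meta$age_months, median)
  st <- by_age("mir-0001")
  expect_gt(min(st[c("15", "18", "21", "26", "28")]) / max(st[c("3", "12")]), 3)
  pk <- by_age("mir-0002")
  expect_gt(pk["15"] / max(pk[names(pk) != "15"]), 3)
})

test_that("isomiR families stay below their archetype in expectation", {
  cfg <- sim_config(n_features = 20, regions = c("cortex", "pons"),
                    n_per_group = 3, n_isomir_per_archetype = 4,
                    archetype_fraction = 0.7, seed = 12)
  meta <- generate_metadata(cfg)
  gen <- generate_counts(meta, cfg)
  for (a in unique(gen$isomir_map$archetype)) {
    iso <- gen$isomir_map$isomir[gen$isomir_map$archetype == a]
    expect_lt(sum(gen$isomir_counts[iso, ]), sum(gen$counts[a, ]))
  }
})

test_that("annotation clusters features within the window and round-trips through GFF3", {
  cfg <- sim_config(n_features = 12, genome_layout = list(
    n_chromosomes = 2L, cluster_size = 3L, intra_gap = 5000L,
    inter_gap = 50000L, opposite_strand_prob = 0), seed = 5)
  ann <- generate_annotation(cfg)
  # first two features share a cluster: 5,000 intervening bases
  expect_identical(ann$chrom[1], ann$chrom[2])
  expect_equal(ann$start[2] - ann$end[1] - 1, 5000)
  # last member of a cluster and the next cluster on the same chromosome are isolated
  base <- baseline_neighbors(ann, window = 10000)
  expect_equal(unname(base["mean_same_strand"]), 2 * 4 * 2 / 12) # 4 within-cluster pairs per chrom
  tmp <- tempfile(fileext = ".gff3")
  write_annotation(ann, tmp)
  back <- read_annotation(tmp)
  expect_equal(back[order(back$feature_id), names(ann)],
               ann[order(ann$feature_id), ], ignore_attr = TRUE)
})

test_that("mRNA generator realizes exact anti-correlation at coupling -1 and rejects positive couplings", {
  links <- data.frame(mirna = "mir-0001", gene = "geneA", coupling = -1)
  cfg <- sim_config(n_features = 10, regions = c("cortex", "pons"),
                    n_per_group = 4, target_links = links,
                    n_mrna_genes = 5, seed = 3)
  meta <- generate_metadata(cfg)
  gen <- generate_counts(meta, cfg)
  norm <- rpmm(gen$counts, gen$rna_class)
  mr <- generate_mrna(meta, norm, cfg)
  for (r in c("cortex", "pons")) {
    ids <- meta$sample_id[meta$region == r]
    expect_equal(cor(mr$mrna["geneA", ids], norm["mir-0001", ids],
                     method = "spearman"), -1)
  }
  expect_identical(mr$mrna, generate_mrna(meta, norm, cfg)$mrna)
  bad <- cfg; bad$target_links$coupling <- 0.5
  expect_error(generate_mrna(meta, norm, bad), "<= 0")
  expect_error(sim_config(target_links = data.frame(
    mirna = "m", gene = "g", coupling = 0.2)), "<= 0")
})
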