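# fixture: chr1 holds a, b, c, d in a row; gaps are intervening bases
# a-b: 9999, b-c: 10000, c-d: 10001; e sits alone on chr2
neighborhood_fixture <- function(strand = c("+", "+", "+", "-", "+")) {
  len <- 100
  s1 <- 1000
  s2 <- s1 + len + 9999       # a|b gap  9,999
  s3 <- s2 + len + 10000      # b|c gap 10,000
  s4 <- s3 + len + 10001      # c|d gap 10,001
  data.frame(feature_id = c("a", "b", "c", "d", "e"),
             chrom = c(rep("chr1", 4), "chr2"),
             start = c(s1, s2, s3, s4, 500),
             end = c(s1, s2, s3, s4, 500) + len - 1,
             strand = strand, rna_class = "miRNA",
             derives_from = NA_character_, stringsAsFactors = FALSE)
}

test_that("the 10 kb window is inclusive at the boundary and strand-aware", {
  ann <- neighborhood_fixture()
  sig <- list(r1 = c("a", "b", "c", "d", "e"))
  nb <- neighbor_counts(ann, sig, window = 10000)
  pf <- nb$per_feature
  get <- function(f, col) pf[pf$feature == f, col]
  expect_equal(get("a", "n_same_strand"), 1)        # b at 9,999
  expect_equal(get("b", "n_same_strand"), 2)        # a and c (10,000 inclusive)
  expect_equal(get("c", "n_same_strand"), 1)        # b only; d is 10,001 away
  expect_equal(get("d", "n_same_strand"), 0)
  expect_equal(get("d", "n_opposite_strand"), 0)    # c is out of range anyway
  expect_equal(get("e", "n_same_strand"), 0)        # lone feature -> (0, 0)
  expect_equal(get("e", "n_opposite_strand"), 0)
  expect_equal(sum(pf$n_opposite_strand), 0)
})

test_that("opposite strands are tallied separately and the relation is symmetric", {
  ann <- neighborhood_fixture(strand = c("+", "-", "+", "+", "+"))
  sig <- list(r1 = c("a", "b", "c"))
  nb <- neighbor_counts(ann, sig, window = 10000)$per_feature
  expect_equal(nb$n_opposite_strand[nb$feature == "a"], 1)   # b
  expect_equal(nb$n_same_strand[nb$feature == "a"], 0)
  expect_equal(nb$n_opposite_strand[nb$feature == "b"], 2)   # a and c
  expect_equal(nb$n_opposite_strand[nb$feature == "c"], 1)
  # only significant features count
  nb2 <- neighbor_counts(ann, list(r1 = c("a", "c")), window = 10000)$per_feature
  expect_equal(sum(nb2$n_same_strand) + sum(nb2$n_opposite_strand), 0)
  # unannotated significant features are reported, not fatal
  nb3 <- neighbor_counts(ann, list(r1 = c("a", "ghost")))
  expect_equal(nb3$unannotated, "ghost")
  # empty significant set: no tallies
  nb4 <- neighbor_counts(ann, list(r1 = character(0)))
  expect_equal(nrow(nb4$per_feature), 0)
})

test_that("tuple occurrences accumulate across regions", {
  ann <- neighborhood_fixture()
  nb <- neighbor_counts(ann, list(r1 = c("a", "b"), r2 = c("a", "b"),
                                  r3 = "e"))
  tup <- nb$tuple_counts
  expect_equal(tup$occurrences[tup$n_same_strand == 1 &
                                 tup$n_opposite_strand == 0], 4)
  expect_equal(tup$occurrences[tup$n_same_strand == 0 &
                                 tup$n_opposite_strand == 0], 1)
})

test_that("baseline neighbor means match hand computation and strand symmetry", {
  ann <- neighborhood_fixture()
  # directed same-strand pairs among {a,b,c} as above: a-b, b-a, b-c, c-b = 4
  base <- baseline_neighbors(ann, window = 10000)
  expect_equal(unname(base["mean_same_strand"]), 4 / 5)
  expect_equal(unname(base["mean_opposite_strand"]), 0)
  # three features pairwise within 10 kb on one strand: mean 2
  clust <- data.frame(feature_id = c("x", "y", "z"), chrom = "chr1",
                      start = c(1, 1001, 2001), end = c(100, 1100, 2100),
                      strand = "+", rna_class = "miRNA",
                      derives_from = NA_character_)
  expect_equal(unname(baseline_neighbors(clust)["mean_same_strand"]), 2)
  # flipping every strand swaps nothing for a uniform layout but preserves totals
  flipped <- ann
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  expect_equal(baseline_neighbors(flipped), base)
  # mixed layout: flipping exchanges the two means
  mixed <- neighborhood_fixture(strand = c("+", "-", "+", "+", "+"))
  bm <- baseline_neighbors(mixed)
  bm_f <- baseline_neighbors(transform(mixed,
    strand = ifelse(strand == "+", "-", "+")))
  expect_equal(unname(bm["mean_same_strand"]), unname(bm_f["mean_same_strand"]))
  expect_equal(unname(bm["mean_opposite_strand"]),
               unname(bm_f["mean_opposite_strand"]))
})

test_that("cumulative coordinates concatenate chromosomes in order", {
  ann <- data.frame(feature_id = c("a", "b", "c"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(100, 900, 50), end = c(200, 1000, 150),
                    strand = "+", rna_class = "miRNA",
                    derives_from = NA_character_)
  cc <- cumulative_coordinates(ann, chrom_order = c("chr1", "chr2"))
  expect_equal(cc$offset[cc$feature_id == "a"], 100)   # first chromosome
  expect_equal(cc$offset[cc$feature_id == "c"], 1000 + 50)
  expect_true(all(diff(cc$offset[cc$chrom == "chr1"]) > 0))
  # order permutation moves offsets but preserves within-chromosome order
  cc2 <- cumulative_coordinates(ann, chrom_order = c("chr2", "chr1"))
  expect_equal(cc2$offset[cc2$feature_id == "a"], 150 + 100)
  expect_true(all(diff(cc2$offset[cc2$chrom == "chr1"]) > 0))
  # explicit lengths
  cc3 <- cumulative_coordinates(ann, chrom_order = c("chr1", "chr2"),
                                chrom_lengths = c(chr1 = 5000, chr2 = 300))
  expect_equal(cc3$offset[cc3$feature_id == "c"], 5050)
  expect_error(cumulative_coordinates(ann, chrom_order = "chr1"), "missing")
})

test_that("neighbor counts are invariant to chromosome-order permutation", {
  ann <- neighborhood_fixture()
  ann_perm <- ann[c(5, 3, 1, 4, 2), ]
  sig <- list(r1 = c("a", "b", "c", "d", "e"))
  a1 <- neighbor_counts(ann, sig)$per_feature
  a2 <- neighbor_counts(ann_perm, sig)$per_feature
  a2 <- a2[match(a1$feature, a2$feature), ]
  expect_equal(a1$n_same_strand, a2$n_same_strand)
  expect_equal(a1$n_opposite_strand, a2$n_opposite_strand)
})
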