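ann_to_granges <- function(ann) {
  GenomicRanges::GRanges(seqnames = ann$chrom,
                         ranges = IRanges::IRanges(ann$start, ann$end),
                         strand = ann$strand, feature_id = ann$feature_id)
}

# symmetric neighbor pairs within `window` intervening bases, never self;
# returns data.frame(a, b, same_strand) with both orientations
neighbor_pairs <- function(ann, window) {
  gr <- ann_to_granges(ann)
  hits <- GenomicRanges::findOverlaps(gr, maxgap = window, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = FALSE)
  if (!length(hits))
    return(data.frame(a = character(), b = character(), same_strand = logical()))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  data.frame(a = ann$feature_id[i], b = ann$feature_id[j],
             same_strand = ann$strand[i] == ann$strand[j],
             stringsAsFactors = FALSE)
}

#' Strand-aware neighborhood counts of significantly age-correlated features
#'
#' For every significant feature in every region, counts the other
#' significant features of that region whose genomic interval lies within
#' `window` intervening bases (edge-to-edge gap; overlap counts as 0;
#' the boundary is inclusive, so a 10,000 bp gap is inside a 10 kb
#' window) on the same chromosome, split into same-strand and
#' opposite-strand tallies. A feature never counts itself. Occurrences of
#' each (same, opposite) tuple are accumulated across regions.
#'
#' @param ann annotation data frame (see [read_annotation()]).
#' @param significant_sets named list (per region) of significant feature
#'   ids.
#' @param window intervening-base threshold (default 10000).
#' @return list with `per_feature` (data.frame feature / region /
#'   n_same_strand / n_opposite_strand), `tuple_counts` (aggregated
#'   occurrence table) and `unannotated` (significant ids missing from
#'   the annotation).
#' @export
neighbor_counts <- function(ann, significant_sets, window = 10000) {
  stopifnot(window > 0)
  all_sig <- unique(unlist(significant_sets))
  unannotated <- setdiff(all_sig, ann$feature_id)
  pairs <- neighbor_pairs(ann, window)
  out <- list()
  for (r in names(significant_sets)) {
    sig <- intersect(significant_sets[[r]], ann$feature_id)
    if (!length(sig)) next
    sub <- pairs[pairs$a %in% sig & pairs$b %in% sig, , drop = FALSE]
    same <- table(factor(sub$a[sub$same_strand], levels = sig))
    opp <- table(factor(sub$a[!sub$same_strand], levels = sig))
    out[[r]] <- data.frame(feature = sig, region = r,
                           n_same_strand = as.integer(same[sig]),
                           n_opposite_strand = as.integer(opp[sig]),
                           stringsAsFactors = FALSE)
  }
  per_feature <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(feature = character(), region = character(),
                  n_same_strand = integer(), n_opposite_strand = integer(),
                  stringsAsFactors = FALSE)
  tuples <- if (nrow(per_feature))
    stats::aggregate(occurrences ~ n_same_strand + n_opposite_strand,
                     cbind(per_feature, occurrences = 1L), sum)
  else data.frame(n_same_strand = integer(), n_opposite_strand = integer(),
                  occurrences = integer())
  list(per_feature = per_feature, tuple_counts = tuples,
       unannotated = unannotated)
}

#' Baseline neighbor density over the whole annotation
#'
#' Mean number of same-strand and opposite-strand neighbors within
#' `window` intervening bases over all annotated features, independent of
#' any significance calls. Gives the genome-wide expectation against
#' which the significant-set neighborhood counts are read.
#'
#' @param ann annotation data frame.
#' @param window intervening-base threshold (default 10000).
#' @return named numeric vector `c(mean_same_strand, mean_opposite_strand)`.
#' @export
baseline_neighbors <- function(ann, window = 10000) {
  pairs <- neighbor_pairs(ann, window)
  n <- nrow(ann)
  c(mean_same_strand = sum(pairs$same_strand) / n,
    mean_opposite_strand = sum(!pairs$same_strand) / n)
}

#' Cumulative genome-wide coordinates
#'
#' Maps each feature's start to a single genome-wide axis: the sum of the
#' lengths of all preceding chromosomes (in the given order) plus its
#' start. Chromosome lengths default to the maximum annotated end per
#' chromosome.
#'
#' @param ann annotation data frame.
#' @param chrom_order character vector ordering the chromosomes (default:
#'   order of first appearance).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame `feature_id`, `chrom`, `offset`, sorted by offset.
#' @export
cumulative_coordinates <- function(ann, chrom_order = NULL,
                                   chrom_lengths = NULL) {
  if (is.null(chrom_order)) chrom_order <- unique(ann$chrom)
  if (!all(ann$chrom %in% chrom_order))
    stop("cumulative_coordinates: chromosome(s) missing from chrom_order")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(ann$end, ann$chrom, max)
  shift <- stats::setNames(cumsum(c(0, as.numeric(chrom_lengths[chrom_order])))[seq_along(chrom_order)],
                           chrom_order)
  out <- data.frame(feature_id = ann$feature_id, chrom = ann$chrom,
                    offset = shift[ann$chrom] + ann$start,
                    stringsAsFactors = FALSE)
  out[order(out$offset), , drop = FALSE]
}
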