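#' Assemble a pipeline configuration
#'
#' Bundles input file paths, a cohort preset and threshold overrides into
#' a validated configuration for [run_pipeline()]. Presets fill every
#' threshold; explicit overrides win.
#'
#' Presets: `atlas` (aligned-read threshold 2e6, feature count 5 in 10%
#' of one region, no region-discard rule), `intervention` (atlas plus
#' discarding regions left with <= 3 samples), `microglia` (aligned-read
#' threshold 1.8e6), `human` (aligned-read threshold 1e4, count
#' threshold 2, feature-filter groups = sexes).
#'
#' @param counts path to the counts TSV (first column feature id,
#'   optional `rna_class` column).
#' @param metadata path to the metadata TSV.
#' @param annotation optional GFF3 path.
#' @param isomirs,isomir_map optional isomiR counts TSV and
#'   isomir-to-archetype map TSV.
#' @param mrna,links optional mRNA matrix TSV and target-link TSV.
#' @param preset cohort preset (see Details).
#' @param out_dir output directory for stage outputs and the manifest.
#' @param seed integer seed for the stochastic stages (c-means init).
#' @param cmeans_k clusters for trajectory clustering (default 10).
#' @param ... threshold overrides (`min_aligned_reads`,
#'   `min_region_samples`, `min_count`, `min_fraction`, `alpha`,
#'   `fc_threshold`, `rho_threshold`, `min_membership`, `window`,
#'   `pc_variance_threshold`, `signature_k`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, annotation = NULL,
                            isomirs = NULL, isomir_map = NULL,
                            mrna = NULL, links = NULL,
                            preset = c("atlas", "intervention", "microglia", "human"),
                            out_dir, seed = 1L, cmeans_k = 10L, ...) {
  preset <- match.arg(preset)
  thresholds <- list(min_aligned_reads = 2e6, min_region_samples = NULL,
                     min_count = 5, min_fraction = 0.10, alpha = 0.05,
                     fc_threshold = 1.5, rho_threshold = 0.5,
                     min_membership = 0.15, window = 10000,
                     pc_variance_threshold = 0.6, signature_k = 50,
                     feature_groups = "region")
  preset_over <- switch(preset,
    atlas = list(),
    intervention = list(min_region_samples = 3),
    microglia = list(min_aligned_reads = 1.8e6),
    human = list(min_aligned_reads = 1e4, min_count = 2,
                 feature_groups = "sex"))
  thresholds <- utils::modifyList(thresholds, preset_over)
  over <- list(...)
  bad <- setdiff(names(over), names(thresholds))
  if (length(bad)) stop("pipeline_config: unknown threshold(s): ",
                        paste(bad, collapse = ", "))
  thresholds <- utils::modifyList(thresholds, over)
  cfg <- list(paths = list(counts = counts, metadata = metadata,
                           annotation = annotation, isomirs = isomirs,
                           isomir_map = isomir_map, mrna = mrna, links = links),
              preset = preset, thresholds = thresholds,
              out_dir = out_dir, seed = as.integer(seed),
              cmeans_k = as.integer(cmeans_k))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_write <- function(obj, path) {
  if (is.matrix(obj)) write_counts(obj, NULL, path)
  else if (is.data.frame(obj))
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            null = "null", force = TRUE)
  path
}

#' Run the full atlas pipeline from a configuration
#'
#' Executes the stages in dependency order — ingest/QC, rpmm
#' normalization, PVCA, region signatures, sex differential expression,
#' old-vs-young age ladder, age correlation and candidate aggregation,
#' trajectory clustering, genomic neighborhood analysis, and (when inputs
#' are present) isomiR profiling and target anti-correlation — writing
#' each stage's outputs under `config$out_dir` and a run manifest with
#' md5 hashes and the thresholds actually used. A stage failure aborts
#' with the stage name; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(obj, name) {
    path <- pipeline_write(obj, file.path(config$out_dir, name))
    files <<- c(files, path)
    invisible(path)
  }

  dat <- stage("ingest", {
    cc <- read_counts(config$paths$counts)
    meta <- read_metadata(config$paths$metadata)
    list(counts = cc$counts, rna_class = cc$rna_class, meta = meta)
  })
  qc <- stage("qc", {
    sf <- filter_samples(dat$counts, dat$meta,
                         min_aligned_reads = thr$min_aligned_reads,
                         min_region_samples = thr$min_region_samples)
    groups <- sf$meta[[thr$feature_groups]]
    ff <- filter_features(sf$counts, groups, min_count = thr$min_count,
                          min_fraction = thr$min_fraction)
    emit(list(sample_filter = unclass(sf$qc), feature_filter = unclass(ff$qc)),
         "qc_report.json")
    list(counts = ff$counts, meta = sf$meta,
         rna_class = dat$rna_class[rownames(ff$counts)])
  })
  norm <- stage("normalize", {
    cls <- if (is.null(qc$rna_class))
      stats::setNames(rep("miRNA", nrow(qc$counts)), rownames(qc$counts))
    else qc$rna_class
    nm <- rpmm(qc$counts, cls)
    emit(nm, "rpmm.tsv")
    nm
  })
  pv <- stage("pvca", {
    factors <- intersect(c("region", "age_months", "sex"), names(qc$meta))
    factors <- factors[vapply(factors,
      function(f) length(unique(qc$meta[[f]])) >= 2, TRUE)]
    if (length(factors) >= 1) {
      res <- pvca(norm, qc$meta, factors,
                  pc_variance_threshold = thr$pc_variance_threshold)
      emit(list(shares = as.list(res$shares), retained_pcs = res$retained_pcs),
           "pvca.json")
      res
    } else NULL
  })
  sig <- stage("signatures", {
    res <- region_signatures(norm, qc$meta, k = thr$signature_k)
    emit(res$specificity, "signature_specificity.tsv")
    emit(res$binary, "signature_binary.tsv")
    res
  })
  de_sex <- stage("de_sex", {
    if (length(unique(qc$meta$sex)) == 2) {
      sx <- sort(unique(qc$meta$sex), decreasing = TRUE)  # M vs F
      rec <- de_analysis(norm, qc$meta, "sex", sx[1], sx[2],
                         center = "geometric_mean", alpha = thr$alpha,
                         fc_threshold = thr$fc_threshold)
      emit(rec, "de_sex.tsv")
      rec
    } else NULL
  })
  de_age <- stage("de_age", {
    rec <- de_age_ladder(norm, qc$meta, alpha = thr$alpha,
                         fc_threshold = thr$fc_threshold)
    emit(rec, "de_age_ladder.tsv")
    rec
  })
  corr <- stage("age_correlation", {
    rec <- suppressWarnings(age_correlation(norm, qc$meta, split = "none",
                                            alpha = thr$alpha,
                                            rho_threshold = thr$rho_threshold))
    emit(rec, "age_correlation.tsv")
    rec
  })
  cand <- stage("candidates", {
    cs <- build_candidates(corr, de_age)
    emit(cs$per_region, "candidates_per_region.json")
    emit(cs$table, "candidates.tsv")
    cs
  })
  traj <- stage("trajectories", {
    ts <- build_trajectories(norm, qc$meta)
    model <- suppressWarnings(fuzzy_cmeans(ts, k = min(config$cmeans_k,
                                                       sum(ts$info$clusterable) - 1L),
                                           seed = config$seed))
    asg <- assign_and_filter(model, min_membership = thr$min_membership)
    spec <- cluster_specificity(asg)
    emit(asg, "trajectory_assignments.tsv")
    emit(spec, "cluster_specificity.tsv")
    emit(list(k = model$k, m = model$m, seed = model$seed,
              converged = model$converged,
              centroids = apply(model$centroids, 1, as.numeric, simplify = FALSE)),
         "cmeans_model.json")
    list(set = ts, model = model, assignments = asg, specificity = spec)
  })
  if (!is.null(config$paths$annotation)) {
    stage("genomics", {
      ann <- read_annotation(config$paths$annotation)
      sig_sets <- lapply(split(corr, corr$region), function(d)
        d$feature[d$significant_pos | d$significant_neg])
      nb <- neighbor_counts(ann, sig_sets, window = thr$window)
      emit(nb$per_feature, "neighbor_counts.tsv")
      emit(nb$tuple_counts, "neighbor_tuples.tsv")
      emit(as.list(baseline_neighbors(ann, window = thr$window)),
           "neighbor_baseline.json")
    })
  }
  if (!is.null(config$paths$mrna) && !is.null(config$paths$links)) {
    stage("targets", {
      mrna <- read_matrix(config$paths$mrna)
      links <- utils::read.table(config$paths$links, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      ta <- target_anticorrelation(norm, mrna, links, qc$meta)
      emit(ta$records, "target_anticorrelation.tsv")
      emit(ta$per_gene_regions, "target_regions.json")
    })
  }
  if (!is.null(config$paths$isomirs) && !is.null(config$paths$isomir_map)) {
    stage("isomirs", {
      iso <- read_counts(config$paths$isomirs)$counts
      map <- utils::read.table(config$paths$isomir_map, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      cls <- if (is.null(qc$rna_class))
        stats::setNames(rep("miRNA", nrow(qc$counts)), rownames(qc$counts))
      else qc$rna_class
      den <- colSums(qc$counts)  # archetype-class denominator shared by isomiRs
      iso_norm <- rpmm(iso[, colnames(qc$counts), drop = FALSE],
                       denominator_totals = den)
      for (a in intersect(unique(map$archetype), rownames(norm))) {
        prof <- isomir_profiles(iso_norm, norm, a, map, qc$meta)
        emit(prof$share, sprintf("isomir_share_%s.tsv", a))
      }
    })
  }
  manifest <- list(
    preset = config$preset, seed = config$seed,
    thresholds = thr[!vapply(thr, is.null, TRUE)],
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
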