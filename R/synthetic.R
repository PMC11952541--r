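#' The 15 brain-region labels of the atlas design
#'
#' Default region set used by [sim_config()]: corpus callosum, choroid
#' plexus, subventricular zone, anterior/posterior hippocampus,
#' hypothalamus, thalamus, caudate putamen, pons, medulla, cerebellum,
#' olfactory bulb and motor/entorhinal/visual cortex.
#'
#' @return Character vector of length 15.
#' @export
atlas_regions <- function() {
  c("corpus_callosum", "choroid_plexus", "svz",
    "hippocampus_anterior", "hippocampus_posterior",
    "hypothalamus", "thalamus", "caudate_putamen",
    "pons", "medulla", "cerebellum", "olfactory_bulb",
    "motor_cortex", "entorhinal_cortex", "visual_cortex")
}

#' Configuration for the synthetic small-RNA atlas generator
#'
#' Defines the cohort design (regions x age stages x sexes x replicates),
#' the count noise model (gamma-Poisson / negative binomial with a shared
#' per-feature dispersion), and the planted effects that give downstream
#' stages a ground truth: region-specific expression signatures, aging
#' trajectories (linear / step / peak), sex offsets, isomiR families,
#' clustered genomic coordinates and anti-correlated mRNA targets.
#'
#' Planted age effects are lists with fields `feature` (integer index or
#' feature id), `regions`, `sexes` (default all), `shape` (`"linear"`,
#' `"step"` or `"peak"`) and `magnitude`. For `linear` the magnitude is the
#' target Spearman correlation with age (the generator converts it to a
#' log2-scale signal amplitude via the feature's expected counting noise);
#' for `step` and `peak` it is a log2 offset applied from `onset_age`
#' onwards, or at `peak_age` only.
#'
#' @param n_features number of features to simulate.
#' @param regions character vector of region labels.
#' @param ages_months strictly increasing numeric age stages (months).
#' @param sexes character vector of sex labels; sex effects apply to the
#'   first level.
#' @param n_per_group samples per (region, age, sex) cell; must be >= 2.
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of per-sample sequencing depth (counts in the matrix).
#' @param nb_dispersion negative-binomial dispersion shared by features.
#' @param base_log2_mean,base_log2_sd distribution of baseline log2
#'   abundances across features.
#' @param rna_class_probs named probabilities for RNA-class labels.
#' @param planted_region_signatures list of `list(feature, regions,
#'   log2_offset)` entries.
#' @param planted_age_effects list of planted trajectories (see Details).
#' @param planted_sex_effects list of `list(feature, regions, log2_offset)`
#'   entries; the offset is applied to samples of the first sex level.
#' @param n_isomir_per_archetype isomiR variants generated per archetype.
#' @param isomir_archetypes feature ids acting as archetypes (default: the
#'   first three features when isomiRs are requested).
#' @param archetype_fraction expected share of an archetype's family
#'   expression retained by the canonical form (isomiRs split the rest).
#' @param target_links data frame with columns `mirna`, `gene`,
#'   `coupling` (in \[-1, 0\]; the target Gaussian-copula correlation).
#' @param n_mrna_genes total genes in the simulated mRNA matrix
#'   (unlinked genes are pure noise).
#' @param mrna_link_all_regions logical; couple linked genes in every
#'   region (default) or only in `link_regions`.
#' @param genome_layout list with `n_chromosomes`, `cluster_size`,
#'   `intra_gap`, `inter_gap`, `opposite_strand_prob`, `feature_length`
#'   controlling the clustered coordinate layout.
#' @param frac_low_reads fraction of samples whose simulated aligned-read
#'   metadata falls below 2 million (they fail the default QC).
#' @param aligned_reads_meanlog,aligned_reads_sdlog lognormal parameters
#'   of the aligned-read metadata for passing samples.
#' @param drop_cells optional list of `list(region, sex, ages)` design
#'   cells to omit (e.g. old-female pons).
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_features = 1174,
                       regions = atlas_regions(),
                       ages_months = c(3, 12, 15, 18, 21, 26, 28),
                       sexes = c("M", "F"),
                       n_per_group = 5,
                       library_size_mean = 1e6,
                       library_size_cv = 0.25,
                       nb_dispersion = 0.15,
                       base_log2_mean = 5,
                       base_log2_sd = 2,
                       rna_class_probs = c(miRNA = 1),
                       planted_region_signatures = list(),
                       planted_age_effects = list(),
                       planted_sex_effects = list(),
                       n_isomir_per_archetype = 0,
                       isomir_archetypes = NULL,
                       archetype_fraction = 0.7,
                       target_links = NULL,
                       n_mrna_genes = 0,
                       mrna_link_all_regions = TRUE,
                       genome_layout = list(),
                       frac_low_reads = 0.02,
                       aligned_reads_meanlog = log(8e6),
                       aligned_reads_sdlog = 0.4,
                       drop_cells = NULL,
                       seed = 1L) {
  if (length(regions) == 0L || length(ages_months) == 0L)
    stop("sim_config: 'regions' and 'ages_months' must be non-empty")
  if (any(diff(ages_months) <= 0))
    stop("sim_config: 'ages_months' must be strictly increasing")
  if (n_per_group < 2)
    stop("sim_config: 'n_per_group' must be >= 2 (two-sample tests need >= 2 per group)")
  stopifnot(n_features >= 1, library_size_mean > 0, library_size_cv > 0,
            nb_dispersion > 0, archetype_fraction > 0, archetype_fraction < 1)
  for (eff in c(planted_region_signatures, planted_sex_effects)) {
    if (!is.finite(eff$log2_offset)) stop("sim_config: planted offsets must be finite")
  }
  for (eff in planted_age_effects) {
    if (!eff$shape %in% c("linear", "step", "peak"))
      stop("sim_config: age-effect shape must be linear, step or peak")
    if (!is.finite(eff$magnitude)) stop("sim_config: planted magnitudes must be finite")
  }
  if (!is.null(target_links)) {
    if (any(target_links$coupling > 0))
      stop("sim_config: target couplings must be <= 0 (anti-correlation generator)")
  }
  layout_defaults <- list(n_chromosomes = 5L, cluster_size = 3L,
                          intra_gap = 5000L, inter_gap = 50000L,
                          opposite_strand_prob = 0.25, feature_length = 80L)
  genome_layout <- utils::modifyList(layout_defaults, genome_layout)
  if (n_isomir_per_archetype > 0 && is.null(isomir_archetypes))
    isomir_archetypes <- feature_ids(min(3L, n_features))
  cfg <- list(n_features = as.integer(n_features), regions = regions,
              ages_months = ages_months, sexes = sexes,
              n_per_group = as.integer(n_per_group),
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              nb_dispersion = nb_dispersion,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              rna_class_probs = rna_class_probs,
              planted_region_signatures = planted_region_signatures,
              planted_age_effects = planted_age_effects,
              planted_sex_effects = planted_sex_effects,
              n_isomir_per_archetype = as.integer(n_isomir_per_archetype),
              isomir_archetypes = isomir_archetypes,
              archetype_fraction = archetype_fraction,
              target_links = target_links, n_mrna_genes = as.integer(n_mrna_genes),
              mrna_link_all_regions = isTRUE(mrna_link_all_regions),
              genome_layout = genome_layout,
              frac_low_reads = frac_low_reads,
              aligned_reads_meanlog = aligned_reads_meanlog,
              aligned_reads_sdlog = aligned_reads_sdlog,
              drop_cells = drop_cells, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

feature_ids <- function(n) sprintf("mir-%04d", seq_len(n))

resolve_feature <- function(x, config) {
  if (is.numeric(x)) {
    if (any(x < 1 | x > config$n_features))
      stop("planted feature index outside 1..n_features")
    return(feature_ids(config$n_features)[x])
  }
  if (!all(x %in% feature_ids(config$n_features)))
    stop("planted feature id not among generated features: ", paste(setdiff(x, feature_ids(config$n_features)), collapse = ", "))
  x
}

#' Generate the per-sample metadata table of a synthetic cohort
#'
#' Builds the full factorial design (region x age x sex x replicate),
#' omitting any cells listed in `config$drop_cells`, and draws aligned-read
#' metadata so that about `config$frac_low_reads` of the samples fall below
#' the 2-million-read QC threshold. Samples of the same (age, sex,
#' replicate) share an individual id, mimicking one animal dissected into
#' all regions.
#'
#' @param config a [sim_config()] object.
#' @return A data frame with columns `sample_id`, `region`, `age_months`,
#'   `sex`, `individual`, `treatment`, `cohort`, `aligned_reads`.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(replicate = seq_len(config$n_per_group),
                      sex = config$sexes, age_months = config$ages_months,
                      region = config$regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(config$drop_cells)) {
    for (cell in config$drop_cells) {
      hit <- grid$region %in% cell$region & grid$sex %in% cell$sex &
        grid$age_months %in% cell$ages
      grid <- grid[!hit, , drop = FALSE]
    }
  }
  n <- nrow(grid)
  meta <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    region = grid$region,
    age_months = grid$age_months,
    sex = grid$sex,
    individual = sprintf("ind_%s_%02g_%d", grid$sex, grid$age_months, grid$replicate),
    treatment = "none", cohort = "atlas",
    stringsAsFactors = FALSE)
  meta$aligned_reads <- withr_seed(config$seed, {
    reads <- round(stats::rlnorm(n, config$aligned_reads_meanlog,
                                 config$aligned_reads_sdlog))
    low <- stats::runif(n) < config$frac_low_reads
    reads[low] <- round(stats::runif(sum(low), 2e5, 2e6))
    as.integer(pmin(reads, .Machine$integer.max))
  })
  meta
}

# evaluate expr under a temporary RNG state seeded with `seed`;
# returns the value of expr and restores the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# expected count noise sd on the log2 scale for NB(mu, dispersion phi)
log2_noise_sd <- function(mu, phi) sqrt(1 / pmax(mu, 1e-8) + phi) / log(2)

# per-feature x per-sample log2 offset matrix encoding all planted effects
planted_offsets <- function(meta, config, base_mu) {
  ids <- feature_ids(config$n_features)
  off <- matrix(0, config$n_features, nrow(meta),
                dimnames = list(ids, meta$sample_id))
  for (eff in config$planted_region_signatures) {
    f <- resolve_feature(eff$feature, config)
    off[f, meta$region %in% eff$regions] <-
      off[f, meta$region %in% eff$regions] + eff$log2_offset
  }
  for (eff in config$planted_sex_effects) {
    f <- resolve_feature(eff$feature, config)
    hit <- meta$region %in% eff$regions & meta$sex == config$sexes[1L]
    off[f, hit] <- off[f, hit] + eff$log2_offset
  }
  age_rank <- match(meta$age_months, sort(unique(config$ages_months)))
  for (eff in config$planted_age_effects) {
    f <- resolve_feature(eff$feature, config)
    sexes <- if (is.null(eff$sexes)) config$sexes else eff$sexes
    hit <- meta$region %in% eff$regions & meta$sex %in% sexes
    if (!any(hit)) next
    if (eff$shape == "linear") {
      rho <- min(abs(eff$magnitude), 0.99) * sign(eff$magnitude)
      sd_n <- log2_noise_sd(base_mu[f], config$nb_dispersion)
      amp <- sd_n * abs(rho) / sqrt(1 - rho^2)
      r <- age_rank[hit]
      z <- (r - mean(seq_along(config$ages_months))) /
        stats::sd(seq_along(config$ages_months)) /
        sqrt((length(config$ages_months) - 1) / length(config$ages_months))
      off[f, hit] <- off[f, hit] + sign(rho) * amp * z
    } else if (eff$shape == "step") {
      onset <- if (is.null(eff$onset_age)) config$ages_months[2L] else eff$onset_age
      off[f, hit & meta$age_months >= onset] <-
        off[f, hit & meta$age_months >= onset] + eff$magnitude
    } else { # peak
      peak <- if (is.null(eff$peak_age)) config$ages_months[ceiling(length(config$ages_months) / 2)] else eff$peak_age
      off[f, hit & meta$age_months == peak] <-
        off[f, hit & meta$age_months == peak] + eff$magnitude
    }
  }
  off
}

#' Generate negative-binomial counts with planted effects
#'
#' Counts are gamma-Poisson (negative binomial) around
#' `library_size * softmax(base abundance + planted log2 offsets)`, so the
#' planted region, sex and aging effects act multiplicatively on the
#' expected expression while per-sample depth varies lognormally. Linear
#' aging effects are calibrated so the expected Spearman correlation with
#' age in the planted cells matches the configured magnitude. isomiR rows
#' (if configured) share each archetype's trajectory with lower means.
#'
#' @param meta metadata from [generate_metadata()].
#' @param config the [sim_config()] object used for `meta`.
#' @return A list with elements `counts` (integer matrix, features x
#'   samples), `rna_class` (named character), `isomir_counts` (matrix or
#'   NULL), `isomir_map` (data.frame isomir/archetype or NULL) and `truth`
#'   (ground-truth list echoing the planted effects).
#' @export
generate_counts <- function(meta, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- feature_ids(config$n_features)
  withr_seed(config$seed + 1L, {
    base_log2 <- stats::rnorm(config$n_features, config$base_log2_mean,
                              config$base_log2_sd)
    names(base_log2) <- ids
    abund <- 2^base_log2
    base_mu <- config$library_size_mean * abund / sum(abund)
    off <- planted_offsets(meta, config, base_mu)
    m <- abund * 2^off              # features x samples, recycled by column
    m <- sweep(m, 2, colSums(m), "/")
    cv <- config$library_size_cv
    lib <- stats::rlnorm(nrow(meta),
                         log(config$library_size_mean) - log(1 + cv^2) / 2,
                         sqrt(log(1 + cv^2)))
    mu <- sweep(m, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), size = 1 / config$nb_dispersion,
                                    mu = mu),
                     nrow = config$n_features,
                     dimnames = list(ids, meta$sample_id))
    rna_class <- sample(names(config$rna_class_probs), config$n_features,
                        replace = TRUE, prob = config$rna_class_probs)
    names(rna_class) <- ids
    isomir_counts <- NULL; isomir_map <- NULL
    if (config$n_isomir_per_archetype > 0) {
      arch <- resolve_feature(config$isomir_archetypes, config)
      iso_ids <- character(0); iso_mu <- NULL
      map <- list()
      for (a in arch) {
        w <- stats::rgamma(config$n_isomir_per_archetype, 1)
        w <- w / sum(w) * (1 - config$archetype_fraction) / config$archetype_fraction
        this_ids <- sprintf("%s_iso%02d", a, seq_len(config$n_isomir_per_archetype))
        iso_ids <- c(iso_ids, this_ids)
        iso_mu <- rbind(iso_mu, outer(w, mu[a, ]))
        map[[a]] <- data.frame(isomir = this_ids, archetype = a,
                               stringsAsFactors = FALSE)
      }
      isomir_counts <- matrix(stats::rnbinom(length(iso_mu),
                                             size = 1 / config$nb_dispersion,
                                             mu = iso_mu),
                              nrow = length(iso_ids),
                              dimnames = list(iso_ids, meta$sample_id))
      isomir_map <- do.call(rbind, map)
      rownames(isomir_map) <- NULL
    }
    truth <- list(
      feature_ids = ids,
      planted_region_signatures = lapply(config$planted_region_signatures,
        function(e) { e$feature <- resolve_feature(e$feature, config); e }),
      planted_sex_effects = lapply(config$planted_sex_effects,
        function(e) { e$feature <- resolve_feature(e$feature, config); e }),
      planted_age_effects = lapply(config$planted_age_effects, function(e) {
        e$feature <- resolve_feature(e$feature, config)
        e$template <- switch(e$shape,
          linear = seq_along(config$ages_months),
          step = {
            onset <- if (is.null(e$onset_age)) config$ages_months[2L] else e$onset_age
            as.numeric(config$ages_months >= onset)
          },
          peak = {
            peak <- if (is.null(e$peak_age)) config$ages_months[ceiling(length(config$ages_months) / 2)] else e$peak_age
            as.numeric(config$ages_months == peak)
          })
        if (!is.null(e$magnitude) && e$magnitude < 0) e$template <- -e$template
        e
      }),
      base_mu = base_mu)
    list(counts = counts, rna_class = rna_class,
         isomir_counts = isomir_counts, isomir_map = isomir_map,
         truth = truth)
  })
}

#' Generate a clustered genomic annotation for the synthetic features
#'
#' Features (and isomiRs, which inherit their archetype's interval) are
#' laid out in clusters: members of a cluster sit `intra_gap` intervening
#' bases apart (within the default 10 kb neighborhood window), while
#' consecutive clusters are separated by `inter_gap` bases (outside it).
#' Each member's strand flips from the cluster's '+' baseline with
#' probability `opposite_strand_prob`.
#'
#' @param config a [sim_config()] object.
#' @param rna_class optional named class vector from [generate_counts()].
#' @return A data frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand`, `rna_class`, `derives_from` (1-based closed
#'   intervals).
#' @export
generate_annotation <- function(config, rna_class = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- feature_ids(config$n_features)
  gl <- config$genome_layout
  n <- config$n_features
  layout <- withr_seed(config$seed + 2L, {
    chrom <- character(n); start <- integer(n); strand <- character(n)
    cursor <- rep(1L, gl$n_chromosomes)
    cluster_of <- (seq_len(n) - 1L) %/% gl$cluster_size
    chr_of <- cluster_of %% gl$n_chromosomes + 1L
    for (i in seq_len(n)) {
      ch <- chr_of[i]
      start[i] <- cursor[ch]
      gap <- if (i < n && cluster_of[min(i + 1L, n)] == cluster_of[i])
        gl$intra_gap else gl$inter_gap
      cursor[ch] <- cursor[ch] + gl$feature_length + gap
      chrom[i] <- paste0("chr", ch)
      strand[i] <- if (stats::runif(1) < gl$opposite_strand_prob) "-" else "+"
    }
    list(chrom = chrom, start = start, strand = strand)
  })
  chrom <- layout$chrom; start <- layout$start; strand <- layout$strand
  ann <- data.frame(feature_id = ids, chrom = chrom, start = start,
                    end = start + gl$feature_length - 1L, strand = strand,
                    rna_class = if (is.null(rna_class)) "miRNA" else unname(rna_class[ids]),
                    derives_from = NA_character_, stringsAsFactors = FALSE)
  if (config$n_isomir_per_archetype > 0) {
    arch <- resolve_feature(config$isomir_archetypes, config)
    iso <- do.call(rbind, lapply(arch, function(a) {
      row <- ann[ann$feature_id == a, ]
      data.frame(feature_id = sprintf("%s_iso%02d", a, seq_len(config$n_isomir_per_archetype)),
                 chrom = row$chrom, start = row$start, end = row$end,
                 strand = row$strand, rna_class = "isomiR",
                 derives_from = a, stringsAsFactors = FALSE)
    }))
    ann <- rbind(ann, iso)
  }
  rownames(ann) <- NULL
  ann
}

#' Generate a matched mRNA matrix with anti-correlated planted targets
#'
#' Linked genes follow a Gaussian copula with the regulating miRNA: within
#' each region the gene equals `coupling * z(miRNA) + sqrt(1 - coupling^2)
#' * noise`, so the population correlation with the miRNA is the (negative)
#' coupling. Unlinked genes are pure noise.
#'
#' @param meta sample metadata (samples of the mRNA matrix; must match the
#'   columns of `mirna_norm`).
#' @param mirna_norm normalized miRNA matrix (features x samples).
#' @param config a [sim_config()] with `target_links` and `n_mrna_genes`.
#' @return list with `mrna` (genes x samples matrix) and `truth`
#'   (data.frame of (gene, region) pairs whose true correlation is <= -0.3).
#' @export
generate_mrna <- function(meta, mirna_norm, config) {
  stopifnot(inherits(config, "sim_config"))
  links <- config$target_links
  if (!is.null(links) && any(links$coupling > 0))
    stop("generate_mrna: couplings must be <= 0")
  if (!is.null(links) && !all(links$mirna %in% rownames(mirna_norm)))
    stop("generate_mrna: target_links reference miRNAs absent from the matrix")
  genes <- sprintf("gene%04d", seq_len(max(config$n_mrna_genes,
                                           if (is.null(links)) 0L else length(unique(links$gene)))))
  if (!is.null(links)) genes <- unique(c(links$gene, genes))[seq_len(max(config$n_mrna_genes, length(unique(links$gene))))]
  mat <- withr_seed(config$seed + 3L, {
    mat <- matrix(stats::rnorm(length(genes) * nrow(meta)),
                  nrow = length(genes),
                  dimnames = list(genes, meta$sample_id))
    if (!is.null(links)) {
      for (k in seq_len(nrow(links))) {
        g <- links$gene[k]; m <- links$mirna[k]; c0 <- links$coupling[k]
        for (r in unique(meta$region)) {
          idx <- meta$sample_id[meta$region == r]
          z <- mirna_norm[m, idx]
          if (stats::sd(z) == 0) next
          z <- (z - mean(z)) / stats::sd(z)
          mat[g, idx] <- c0 * z + sqrt(max(0, 1 - c0^2)) * stats::rnorm(length(idx))
        }
      }
    }
    mat
  })
  truth <- if (is.null(links)) NULL else {
    strong <- links[links$coupling <= -0.3, , drop = FALSE]
    if (nrow(strong) == 0) NULL else
      expand.grid(gene = unique(strong$gene), region = unique(meta$region),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  list(mrna = mat, truth = truth)
}

#' Simulate a full synthetic atlas dataset and write it to disk
#'
#' Runs [generate_metadata()], [generate_counts()],
#' [generate_annotation()] and (if configured) [generate_mrna()], then
#' writes counts, metadata, GFF3 annotation, isomiR counts, mRNA matrix,
#' target links and a ground-truth JSON under `dir`.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if missing); if `NULL` nothing is
#'   written and the objects are only returned.
#' @return Invisibly, a list with all generated objects and file paths.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  meta <- generate_metadata(config)
  gen <- generate_counts(meta, config)
  ann <- generate_annotation(config, gen$rna_class)
  mrna <- NULL
  if (!is.null(config$target_links) || config$n_mrna_genes > 0) {
    norm <- rpmm(gen$counts, gen$rna_class)
    mrna <- generate_mrna(meta, norm, config)
  }
  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths$counts <- file.path(dir, "counts.tsv")
    write_counts(gen$counts, gen$rna_class, paths$counts)
    paths$metadata <- file.path(dir, "metadata.tsv")
    utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$annotation <- file.path(dir, "annotation.gff3")
    write_annotation(ann, paths$annotation)
    if (!is.null(gen$isomir_counts)) {
      paths$isomirs <- file.path(dir, "isomir_counts.tsv")
      write_counts(gen$isomir_counts, NULL, paths$isomirs)
      paths$isomir_map <- file.path(dir, "isomir_map.tsv")
      utils::write.table(gen$isomir_map, paths$isomir_map, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mrna)) {
      paths$mrna <- file.path(dir, "mrna.tsv")
      write_counts(mrna$mrna, NULL, paths$mrna)
      if (!is.null(config$target_links)) {
        paths$links <- file.path(dir, "target_links.tsv")
        utils::write.table(config$target_links, paths$links, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    paths$truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gen$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(list(meta = meta, counts = gen$counts, rna_class = gen$rna_class,
                 isomir_counts = gen$isomir_counts, isomir_map = gen$isomir_map,
                 annotation = ann, mrna = mrna, truth = gen$truth,
                 paths = paths, config = config))
}
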