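#' Read a raw count matrix from TSV/CSV
#'
#' Expects a header row, a first column of feature ids, an optional
#' `rna_class` column, and one column per sample. Counts must be
#' non-negative integers; duplicate feature or sample ids are rejected.
#'
#' @param path file path (tab- or comma-separated, inferred from the
#'   extension: `.csv` means comma).
#' @return list with `counts` (integer matrix, features x samples) and
#'   `rna_class` (named character vector, or NULL when absent).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("read_counts: file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("read_counts: duplicate feature ids")
  df <- df[-1L]
  rna_class <- NULL
  if ("rna_class" %in% names(df)) {
    rna_class <- stats::setNames(as.character(df$rna_class), ids)
    df$rna_class <- NULL
  }
  if (anyDuplicated(names(df))) stop("read_counts: duplicate sample ids")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("read_counts: non-numeric count values")
  if (any(mat < 0) || any(mat != round(mat)))
    stop("read_counts: counts must be non-negative integers")
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  list(counts = mat, rna_class = rna_class)
}

#' Read a real-valued expression matrix from TSV/CSV
#'
#' Like [read_counts()] but without the integer constraint; used for
#' normalized or mRNA expression tables.
#'
#' @param path file path.
#' @return numeric matrix (features x samples).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("read_matrix: file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("read_matrix: duplicate feature ids")
  df <- df[-1L]
  df$rna_class <- NULL
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("read_matrix: non-numeric values")
  rownames(mat) <- ids
  mat
}

#' Write a count/expression matrix as TSV (first column = feature id)
#'
#' @param mat matrix with feature rownames and sample colnames.
#' @param rna_class optional named class vector written as a `rna_class`
#'   column after the feature id.
#' @param path output path.
#' @export
write_counts <- function(mat, rna_class = NULL, path) {
  df <- data.frame(feature_id = rownames(mat), stringsAsFactors = FALSE)
  if (!is.null(rna_class)) df$rna_class <- unname(rna_class[rownames(mat)])
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Requires columns `sample_id`, `region`, `age_months`, `sex`,
#' `aligned_reads`; `individual`, `treatment` and `cohort` are optional.
#'
#' @param path TSV/CSV file path.
#' @return data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("read_metadata: file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "region", "age_months", "sex", "aligned_reads")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_metadata: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("read_metadata: duplicate sample ids")
  if (any(df$age_months <= 0)) stop("read_metadata: ages must be positive")
  df
}

#' Read a feature annotation from GFF3
#'
#' Coordinates stay in GFF3's native 1-based closed convention. The `ID`
#' attribute becomes the feature id and `Derives_from` (isomiR to
#' archetype) is carried through when present; the GFF3 `type` column is
#' taken as the RNA class.
#'
#' @param path GFF3 file path.
#' @return data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `rna_class`, `derives_from`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("read_annotation: file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    feature_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    rna_class = as.character(mc$type),
    derives_from = if ("Derives_from" %in% names(mc))
      vapply(mc$Derives_from, function(x) if (length(x)) as.character(x[1]) else NA_character_, "")
    else NA_character_,
    stringsAsFactors = FALSE)
  if (any(df$end < df$start))
    stop("read_annotation: interval with end < start")
  if (anyDuplicated(df$feature_id))
    stop("read_annotation: duplicate feature ids")
  df
}

#' Write a feature annotation to GFF3
#'
#' @param ann annotation data frame (see [read_annotation()]).
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$source <- "mirage"
  S4Vectors::mcols(gr)$type <- ann$rna_class
  S4Vectors::mcols(gr)$ID <- ann$feature_id
  if (any(!is.na(ann$derives_from)))
    S4Vectors::mcols(gr)$Derives_from <- ann$derives_from
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
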