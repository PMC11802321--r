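#' @importFrom utils read.table write.table
NULL

read_tsv_noheader <- function(path, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read gene models from a BED6 file
#'
#' Columns: chrom, start, end, name (gene id), score, strand. Coordinates are
#' BED-style 0-based half-open. TSS/TES are derived from strand: for "+"
#' (and unstranded ".") genes TSS = start and TES = end; for "-" genes
#' TSS = end and TES = start.
#'
#' @param path Path to a BED6 file (no header).
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_noheader(path, "gene models")
  if (ncol(df) < 6) stop("gene models: expected >= 6 BED columns, got ", ncol(df))
  chrom <- as.character(df[[1]]); start <- df[[2]]; end <- df[[3]]
  gene_id <- as.character(df[[4]]); strand <- as.character(df[[6]])
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad))
    stop("gene models: invalid coordinates (start >= end or negative) at line ",
         paste(bad, collapse = ", "))
  badstr <- which(!strand %in% c("+", "-", "."))
  if (length(badstr))
    stop("gene models: unknown strand symbol at line ",
         paste(badstr, collapse = ", "))
  dup <- which(duplicated(gene_id))
  if (length(dup))
    stop("gene models: duplicate gene_id at line ", paste(dup, collapse = ", "),
         " (", paste(unique(gene_id[dup]), collapse = ", "), ")")
  if (any(!nzchar(chrom))) stop("gene models: empty chrom field")
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand,
             tss = ifelse(strand == "-", end, start),
             tes = ifelse(strand == "-", start, end),
             stringsAsFactors = FALSE)
}

#' Write gene models to BED6
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(genes$chrom, format_bp(genes$start), format_bp(genes$end),
                    genes$gene_id, 0L, genes$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a bedGraph signal track
#'
#' Four columns: chrom, start, end, value. The returned track is sorted by
#' (chrom, start); overlapping intervals or negative values are errors.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A `signal_track` data frame (`chrom`, `start`, `end`, `value`).
#' @export
read_signal_track <- function(path) {
  df <- read_tsv_noheader(path, "signal track")
  if (ncol(df) != 4) stop("signal track: expected 4 bedGraph columns, got ", ncol(df))
  tr <- new_signal_track(df[[1]], df[[2]], df[[3]], df[[4]])
  validate_signal_track(tr, paste0("signal track ", basename(path)))
  tr
}

#' Write a signal track as bedGraph
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_signal_track <- function(track, path) {
  out <- data.frame(track$chrom, format_bp(track$start), format_bp(track$end),
                    format(track$value, scientific = FALSE, trim = TRUE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peak set from BED
#' @param path Path to a BED file (>= 3 columns). Peaks may overlap.
#' @param name Mark name (e.g. "H3K9me3").
#' @return List with elements `name` and `intervals` (chrom/start/end).
#' @export
read_peaks <- function(path, name) {
  df <- read_tsv_noheader(path, "peaks")
  if (ncol(df) < 3) stop("peaks: expected >= 3 BED columns")
  iv <- data.frame(chrom = as.character(df[[1]]), start = df[[2]], end = df[[3]],
                   stringsAsFactors = FALSE)
  if (any(iv$start < 0 | iv$start >= iv$end)) stop("peaks: invalid interval")
  list(name = name, intervals = iv)
}

#' Write a peak set to BED3
#' @param peaks Peak set from [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  iv <- peaks$intervals
  out <- data.frame(iv$chrom, format_bp(iv$start), format_bp(iv$end))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read repeat annotations (BED6 + family, subfamily)
#'
#' Columns 1-6 are standard BED; column 7 is the repeat family and column 8
#' the subfamily.
#'
#' @param path Path to the annotation file.
#' @return Data frame with `chrom`, `start`, `end`, `family`, `subfamily`.
#' @export
read_repeats <- function(path) {
  df <- read_tsv_noheader(path, "repeats")
  if (ncol(df) < 8) stop("repeats: expected BED6+2 (family, subfamily)")
  fam <- as.character(df[[7]])
  fam[is.na(fam)] <- ""
  if (any(!nzchar(fam)))
    stop("repeats: empty family at line ",
         paste(which(!nzchar(fam)), collapse = ", "))
  out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]], end = df[[3]],
                    family = fam, subfamily = as.character(df[[8]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$start >= out$end)) stop("repeats: invalid interval")
  out
}

#' Write repeat annotations to BED6+2
#' @param repeats Repeat annotation data frame.
#' @param path Output path.
#' @export
write_repeats <- function(repeats, path) {
  out <- data.frame(repeats$chrom, format_bp(repeats$start),
                    format_bp(repeats$end),
                    paste0(repeats$family, ":", repeats$subfamily), 0L, ".",
                    repeats$family, repeats$subfamily)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count matrix and its sample sheet
#'
#' The counts file is TSV with a header; the first column is `gene_id` and
#' the remaining columns are samples. The sample sheet is TSV with columns
#' `sample_id`, `genotype`, `treatment`, `timepoint_weeks`, `replicate`.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return A `count_matrix`: list with `counts` (integer matrix, genes x
#'   samples) and `samples` (data frame, one row per column of `counts`).
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  cts <- utils::read.table(counts_path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (colnames(cts)[1] != "gene_id") stop("counts: first column must be gene_id")
  samples <- read_sample_sheet(samples_path)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  count_matrix(m, samples)
}

read_sample_sheet <- function(path) {
  samples <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                               comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "treatment", "timepoint_weeks", "replicate")
  miss <- setdiff(need, colnames(samples))
  if (length(miss)) stop("sample sheet: missing columns ", paste(miss, collapse = ", "))
  key <- with(samples, paste(genotype, treatment, timepoint_weeks, replicate))
  if (anyDuplicated(key))
    stop("sample sheet: duplicated (genotype, treatment, timepoint, replicate)")
  samples
}

#' Construct a count matrix container
#'
#' @param counts Non-negative integer matrix (genes x samples) with row and
#'   column names.
#' @param samples Sample sheet data frame; `sample_id` must match the count
#'   matrix columns one-to-one.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  if (is.null(rownames(counts))) stop("count_matrix: counts need gene_id rownames")
  if (anyDuplicated(rownames(counts))) stop("count_matrix: duplicate gene_ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("count_matrix: counts must be non-negative and complete")
  if (any(counts != round(counts))) stop("count_matrix: counts must be integers")
  if (!setequal(colnames(counts), samples$sample_id) ||
      anyDuplicated(samples$sample_id))
    stop("count_matrix: sample sheet does not match count columns")
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a count matrix and sample sheet as TSV
#' @param cm A `count_matrix`.
#' @param counts_path,samples_path Output paths.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
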