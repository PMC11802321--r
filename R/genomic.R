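#' @importFrom IRanges IRanges findOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All coordinates are 0-based half-open (BED convention) everywhere in the
# package; 1-based dialects are converted at the reader boundary.

#' Construct a signal track
#'
#' A signal track carries piecewise-constant genomic coverage (bedGraph
#' semantics): per chromosome, sorted non-overlapping half-open intervals
#' with finite non-negative values.
#'
#' @param chrom,start,end,value Parallel vectors describing the intervals
#'   (0-based half-open) and their values.
#' @return A `signal_track` data frame sorted by (chrom, start).
#' @export
signal_track <- function(chrom, start, end, value) {
  validate_signal_track(new_signal_track(chrom, start, end, value))
}

new_signal_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

validate_signal_track <- function(track, what = "signal track") {
  if (any(!is.finite(track$value)) || any(track$value < 0))
    stop(what, ": values must be finite and >= 0")
  if (any(track$start < 0) || any(track$start >= track$end))
    stop(what, ": intervals must satisfy 0 <= start < end")
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in by_chrom) {
    s <- track$start[idx]; e <- track$end[idx]
    o <- order(s)
    bad <- which(e[o][-length(o)] > s[o][-1])
    if (length(bad)) {
      i <- idx[o][bad[1]]; j <- idx[o][bad[1] + 1]
      stop(sprintf("%s: overlapping intervals %s:[%d,%d) and %s:[%d,%d)",
                   what, track$chrom[i], track$start[i], track$end[i],
                   track$chrom[j], track$start[j], track$end[j]))
    }
  }
  invisible(track)
}

#' Build strand-aware metagene regions
#'
#' Each metagene spans the gene body (TSS to TES) plus a promoter window of
#' `promoter_bp` upstream of the TSS in the strand-aware sense. The start is
#' clamped at 0; no chromosome-length clipping is performed.
#'
#' @param genes Gene-model data frame as returned by [read_gene_models()].
#' @param promoter_bp Upstream window size in bp (>= 0).
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @examples
#' gm <- data.frame(gene_id = "g", chrom = "chr1", start = 10000, end = 12000,
#'                  strand = "+", tss = 10000, tes = 12000)
#' build_metagene_region(gm, 2000)  # chr1:[8000,12000)
#' @export
build_metagene_region <- function(genes, promoter_bp = 2000) {
  stopifnot(promoter_bp >= 0)
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$start, pmax(0, genes$start - promoter_bp))
  end <- ifelse(minus, genes$end + promoter_bp, genes$end)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows
#'
#' The window covers `promoter_bp` bases immediately upstream of the TSS
#' (clamped at 0 for plus-strand genes near the chromosome origin).
#'
#' @inheritParams build_metagene_region
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_region <- function(genes, promoter_bp = 2000) {
  stopifnot(promoter_bp > 0)
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss, pmax(0, genes$tss - promoter_bp))
  end <- ifelse(minus, genes$tss + promoter_bp, genes$tss)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Integrate a signal track over regions
#'
#' Computes, for each region, the sum over track intervals of value times the
#' overlap length with the region (the area under the piecewise-constant
#' coverage). Regions with no overlapping signal get 0.
#'
#' @param track A `signal_track` (bedGraph semantics).
#' @param regions Data frame with columns `chrom`, `start`, `end`.
#' @return Numeric vector, one integral per region row; attribute
#'   `covered_bp` holds the number of region bases covered by the track.
#' @export
integrate_signal <- function(track, regions) {
  n <- nrow(regions)
  total <- numeric(n)
  covered <- numeric(n)
  if (nrow(track) > 0 && n > 0) {
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      ti <- which(track$chrom == ch)
      if (!length(ti)) next
      # IRanges is 1-based closed; shift half-open starts by +1
      q <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
      s <- IRanges::IRanges(track$start[ti] + 1L, track$end[ti])
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      w <- pmin(regions$end[ri][qh], track$end[ti][sh]) -
        pmax(regions$start[ri][qh], track$start[ti][sh])
      contrib <- w * track$value[ti][sh]
      acc <- numeric(length(ri))
      tmp <- tapply(contrib, qh, sum)
      acc[as.integer(names(tmp))] <- tmp
      total[ri] <- total[ri] + acc
      cov <- numeric(length(ri))
      tmpc <- tapply(w, qh, sum)
      cov[as.integer(names(tmpc))] <- tmpc
      covered[ri] <- covered[ri] + cov
    }
  }
  attr(total, "covered_bp") <- covered
  total
}

#' Assign repeat loci to chromatin compartments
#'
#' Every locus belongs to the "all" compartment; it additionally belongs to
#' "heterochromatin" if it overlaps any H3K9me3 peak by at least 1 bp, and to
#' "euchromatin" if it overlaps any H3K27ac peak. Memberships are not
#' mutually exclusive.
#'
#' @param repeats Repeat annotation data frame from [read_repeats()].
#' @param k9me3_peaks,k27ac_peaks Peak sets from [read_peaks()].
#' @return `repeats` with added logical columns `all`, `heterochromatin`,
#'   `euchromatin`.
#' @export
assign_compartments <- function(repeats, k9me3_peaks, k27ac_peaks) {
  repeats$all <- TRUE
  repeats$heterochromatin <- overlaps_any(repeats, k9me3_peaks$intervals)
  repeats$euchromatin <- overlaps_any(repeats, k27ac_peaks$intervals)
  repeats
}

overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    out[qi] <- IRanges::overlapsAny(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1L, subject$end[si]))
  }
  out
}
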