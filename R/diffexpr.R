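#' Remove genes with low average counts
#'
#' Retains genes whose mean count across all samples is strictly greater than
#' `min_avg` (a mean of exactly `min_avg` is removed).
#'
#' @param cm A `count_matrix`.
#' @param min_avg Average-count threshold (default 10).
#' @return The filtered `count_matrix`.
#' @export
filter_low_counts <- function(cm, min_avg = 10) {
  keep <- rowMeans(cm$counts) > min_avg
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count / geometric-mean ratios over genes with a
#' non-zero geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts Count matrix (genes x samples) or a `count_matrix`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  logc <- log(counts)
  log_geo <- rowMeans(logc)                        # -Inf when any count is 0
  usable <- is.finite(log_geo)
  if (!any(usable)) stop("size_factors: no gene has non-zero counts in every sample")
  sf <- apply(logc[usable, , drop = FALSE], 2,
              function(lc) exp(stats::median(lc - log_geo[usable])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("size_factors: sample with no usable ratios")
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test between two sample groups
#'
#' A transparent two-group contrast on size-factor-normalized counts:
#' lfc = log2((mB + c) / (mA + c)) with pseudocount c; method-of-moments
#' per-gene dispersion a = max(0, (s2_pooled - m_pooled) / m_pooled^2)
#' (floored); delta-method standard error
#' se^2 = (1/ln 2)^2 * ((1/mA + a)/nA + (1/mB + a)/nB); Wald z = lfc / se
#' with a two-sided normal p. Genes with both group means zero get
#' lfc = 0, p = 1. Unlike full DE engines, no dispersion shrinkage, outlier
#' replacement, or independent filtering is performed.
#'
#' @param cm A `count_matrix` (unnormalized counts).
#' @param group_a,group_b Character vectors of sample ids (group A is the
#'   reference/control; the fold-change is B over A). Each needs >= 2
#'   replicates.
#' @param sf Size factors named by sample id (default: computed from the full
#'   matrix).
#' @param pseudocount Pseudocount c on the normalized-mean scale.
#' @param dispersion_floor Lower floor on the moment dispersion estimate.
#' @return Data frame with `gene_id`, `lfc`, `se`, `p`.
#' @export
nb_wald_test <- function(cm, group_a, group_b, sf = size_factors(cm),
                         pseudocount = 0.5, dispersion_floor = 1e-8) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("nb_wald_test: each group needs >= 2 replicates")
  miss <- setdiff(c(group_a, group_b), colnames(cm$counts))
  if (length(miss)) stop("nb_wald_test: unknown samples ",
                         paste(miss, collapse = ", "))
  norm <- sweep(cm$counts, 2, sf[colnames(cm$counts)], "/")
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mp <- (na * ma + nb * mb) / (na + nb)
  disp <- pmax(dispersion_floor, (s2 - mp) / mp^2)
  disp[!is.finite(disp)] <- dispersion_floor
  lfc <- log2((mb + pseudocount) / (ma + pseudocount))
  se <- sqrt((1 / log(2))^2 * ((1 / ma + disp) / na + (1 / mb + disp) / nb))
  z <- ifelse(is.finite(se) & se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  both_zero <- ma == 0 & mb == 0
  lfc[both_zero] <- 0
  p[both_zero | !is.finite(se)] <- 1
  data.frame(gene_id = rownames(cm$counts), lfc = lfc, se = se, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-time-point differential expression for the full design
#'
#' Filters low-count genes, computes one set of size factors over all samples
#' together, and runs the NB Wald contrast of each TMX-treated genotype
#' against the FloxCre+vehicle control at every time point, adjusting
#' p-values (BH) across genes within each (contrast, time point).
#'
#' @param cm A `count_matrix` covering the whole design.
#' @param thresholds A [cascade_thresholds()].
#' @param control List with the control condition (default FloxCre+vehicle).
#' @return Data frame with `contrast` (the TMX genotype), `timepoint_weeks`,
#'   `gene_id`, `lfc`, `se`, `p`, `padj`. The knockout contrast is
#'   `"FloxCre"`.
#' @export
de_timecourse <- function(cm, thresholds = cascade_thresholds(),
                          control = list(genotype = "FloxCre",
                                         treatment = "vehicle")) {
  cm <- filter_low_counts(cm, thresholds$min_avg_count)
  sf <- size_factors(cm)
  sm <- cm$samples
  tps <- sort(unique(sm$timepoint_weeks))
  genos <- unique(sm$genotype[sm$treatment == "TMX"])
  out <- list()
  for (tp in tps) {
    ctrl_ids <- sm$sample_id[sm$genotype == control$genotype &
                               sm$treatment == control$treatment &
                               sm$timepoint_weeks == tp]
    for (g in genos) {
      trt_ids <- sm$sample_id[sm$genotype == g & sm$treatment == "TMX" &
                                sm$timepoint_weeks == tp]
      if (length(trt_ids) < 2 || length(ctrl_ids) < 2) next
      res <- nb_wald_test(cm, ctrl_ids, trt_ids, sf = sf)
      res$padj <- bh_adjust(res$p)
      res$contrast <- g
      res$timepoint_weeks <- tp
      out[[paste(g, tp)]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("contrast", "timepoint_weeks", "gene_id", "lfc", "se", "p", "padj")]
}

#' Call differentially expressed genes
#'
#' A gene is a DEG at a time point when padj < `padj_max`, |lfc| > `lfc_min`
#' and se < `se_max`; its direction is the sign of the fold-change.
#'
#' @param results DE table with columns `gene_id`, `timepoint_weeks`, `lfc`,
#'   `se`, `padj` (e.g. one contrast of [de_timecourse()]).
#' @param thresholds A [cascade_thresholds()].
#' @return Subset of `results` rows that pass, with an added `direction`
#'   column (`"up"`/`"down"`).
#' @export
call_degs <- function(results, thresholds = cascade_thresholds()) {
  keep <- results$padj < thresholds$padj_max &
    abs(results$lfc) > thresholds$lfc_min &
    results$se < thresholds$se_max
  keep[is.na(keep)] <- FALSE
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$lfc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Subtract non-specific (treatment-control) DEGs
#'
#' Removes from the knockout DEG set, per time point, every gene that is a
#' DEG in any of the treatment-control contrasts at the same time point.
#'
#' @param ako_degs DEG table for the knockout contrast (from [call_degs()]),
#'   with `gene_id` and `timepoint_weeks`.
#' @param control_degs List of DEG tables for the treatment-control
#'   contrasts; each must cover the same time points.
#' @return `ako_degs` with the non-specific rows removed.
#' @export
subtract_nonspecific <- function(ako_degs, control_degs) {
  tps <- unique(ako_degs$timepoint_weeks)
  for (cd in control_degs) {
    extra <- setdiff(unique(cd$timepoint_weeks), tps)
    if (length(extra))
      stop("subtract_nonspecific: time-point mismatch (",
           paste(extra, collapse = ", "), ")")
  }
  drop <- rep(FALSE, nrow(ako_degs))
  for (cd in control_degs) {
    key_cd <- paste(cd$gene_id, cd$timepoint_weeks)
    drop <- drop | paste(ako_degs$gene_id, ako_degs$timepoint_weeks) %in% key_cd
  }
  out <- ako_degs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
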