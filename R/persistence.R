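#' Fisher persistence score for one gene
#'
#' Combines a gene's per-time-point adjusted p-values with Fisher's method.
#' Missing time points (genes filtered at some weeks) reduce the number of
#' combined components rather than being imputed.
#'
#' @param padj_series Adjusted p-values across the time course (NAs dropped).
#' @param ... Passed to [fisher_combine()].
#' @return Combined probability.
#' @export
persistence_score <- function(padj_series, ...) {
  s <- padj_series[!is.na(padj_series)]
  if (!length(s)) stop("persistence_score: empty series")
  fisher_combine(s, ...)
}

#' Classify persistently dysregulated genes
#'
#' A gene is labeled up or down when (i) its knockout-series Fisher score is
#' below `fisher_ako`, (ii) its expression is altered by at least
#' `pct_change` (20% by default, i.e. max |lfc| >= log2(1.2)) at one or more
#' time points, and (iii) it is not persistently dysregulated in the
#' treatment controls (Fisher score >= `fisher_tc`). Direction is the sign of
#' the mean log2 fold-change across time points; an exact zero mean leaves
#' the gene unlabeled.
#'
#' @param ako_scores Named (by gene) knockout Fisher scores.
#' @param tc_scores Named treatment-control Fisher scores, gene-aligned with
#'   `ako_scores` (when several treatment controls exist, pass the minimum
#'   per gene so persistence in any control removes the gene).
#' @param lfc_matrix Gene x time-point matrix of knockout log2 fold-changes
#'   (rownames = gene ids).
#' @param thresholds A [cascade_thresholds()].
#' @return Data frame with `gene_id`, `fisher_p_ako`, `fisher_p_tc`,
#'   `max_abs_pct_change` (fold-change magnitude, as a fraction, on the
#'   stronger side), `label` in {up, down, none}, `direction_score` (mean
#'   lfc).
#' @export
classify_persistent <- function(ako_scores, tc_scores, lfc_matrix,
                                thresholds = cascade_thresholds()) {
  genes <- names(ako_scores)
  if (is.null(genes) || !identical(genes, names(tc_scores)) ||
      !identical(genes, rownames(lfc_matrix)))
    stop("classify_persistent: gene sets misaligned across inputs")
  max_abs_lfc <- apply(abs(lfc_matrix), 1, max, na.rm = TRUE)
  max_abs_pct <- 2^max_abs_lfc - 1
  mean_lfc <- rowMeans(lfc_matrix, na.rm = TRUE)
  lfc_cut <- log2(1 + thresholds$pct_change)
  pass <- ako_scores < thresholds$fisher_ako &
    tc_scores >= thresholds$fisher_tc &
    max_abs_lfc >= lfc_cut & mean_lfc != 0
  pass[is.na(pass)] <- FALSE
  label <- rep("none", length(genes))
  label[pass & mean_lfc > 0] <- "up"
  label[pass & mean_lfc < 0] <- "down"
  data.frame(gene_id = genes, fisher_p_ako = unname(ako_scores),
             fisher_p_tc = unname(tc_scores),
             max_abs_pct_change = unname(max_abs_pct), label = label,
             direction_score = unname(mean_lfc), stringsAsFactors = FALSE)
}

#' Persistence analysis of a DE time course
#'
#' Computes the per-gene Fisher score for the knockout contrast and for each
#' treatment-control contrast, assembles the knockout lfc matrix, and
#' classifies genes. The treatment controls are scored as a single unit —
#' one Fisher combination per gene over every (control genotype, time point)
#' adjusted p — and that score flags a gene as non-specific only when a
#' control also shows at least a `pct_change` alteration at one or more time
#' points.
#'
#' @param de_results Output of [de_timecourse()].
#' @param thresholds A [cascade_thresholds()].
#' @param ako_contrast Name of the knockout contrast (default `"FloxCre"`).
#' @return List with `records` (see [classify_persistent()]) and `lfc_matrix`.
#' @export
persistence_analysis <- function(de_results,
                                 thresholds = cascade_thresholds(),
                                 ako_contrast = "FloxCre") {
  ako <- de_results[de_results$contrast == ako_contrast, , drop = FALSE]
  if (!nrow(ako)) stop("persistence_analysis: no rows for knockout contrast")
  genes <- sort(unique(ako$gene_id))
  tps <- sort(unique(ako$timepoint_weeks))
  to_matrix <- function(df, col) {
    m <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
    m[cbind(match(df$gene_id, genes), match(df$timepoint_weeks, tps))] <- df[[col]]
    m
  }
  padj_ako <- to_matrix(ako, "padj")
  lfc_mat <- to_matrix(ako, "lfc")
  # adjusted p can underflow to exactly 0 for extreme Wald z; these are
  # computed values, so floor them at the smallest positive double
  ako_scores <- apply(padj_ako, 1, persistence_score, floor_zero = TRUE)
  # The treatment controls are scored as one unit: a single Fisher
  # combination over every (control genotype, time point) adjusted p. A gene
  # is persistently dysregulated in the controls only when that combined
  # score is small AND some control shows a >= pct_change alteration at >= 1
  # time point; otherwise its effective control score is left at 1.
  lfc_cut <- log2(1 + thresholds$pct_change)
  tc_contrasts <- setdiff(unique(de_results$contrast), ako_contrast)
  tc_padj <- do.call(cbind, lapply(tc_contrasts, function(g)
    to_matrix(de_results[de_results$contrast == g, , drop = FALSE], "padj")))
  tc_lfc <- do.call(cbind, lapply(tc_contrasts, function(g)
    to_matrix(de_results[de_results$contrast == g, , drop = FALSE], "lfc")))
  tc_mat <- rep(1, length(genes))
  if (length(tc_contrasts)) {
    sc <- apply(tc_padj, 1, function(s)
      if (all(is.na(s))) NA_real_ else persistence_score(s, floor_zero = TRUE))
    changed <- apply(abs(tc_lfc), 1, max, na.rm = TRUE) >= lfc_cut
    sc[is.na(sc) | !changed] <- 1
    tc_mat <- sc
  }
  names(tc_mat) <- genes
  records <- classify_persistent(ako_scores, tc_mat, lfc_mat, thresholds)
  list(records = records, lfc_matrix = lfc_mat)
}

#' Per-cluster fold-change trajectories
#'
#' Arithmetic mean and sample SD of the log2 fold-change per cluster per time
#' point (single-gene clusters report sd = 0). Empty clusters are omitted
#' with a warning.
#'
#' @param lfc_matrix Gene x time-point lfc matrix (rownames = gene ids).
#' @param records Persistence records from [classify_persistent()].
#' @return Data frame with `label`, `timepoint_weeks`, `mean_lfc`, `sd_lfc`,
#'   `n_genes`.
#' @export
trajectory_summary <- function(lfc_matrix, records) {
  out <- list()
  for (lab in c("up", "down")) {
    ids <- records$gene_id[records$label == lab]
    if (!length(ids)) {
      warning("trajectory_summary: empty cluster ", lab, " omitted")
      next
    }
    sub <- lfc_matrix[ids, , drop = FALSE]
    sd_col <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    })
    out[[lab]] <- data.frame(label = lab,
                             timepoint_weeks = as.numeric(colnames(lfc_matrix)),
                             mean_lfc = colMeans(sub, na.rm = TRUE),
                             sd_lfc = sd_col, n_genes = length(ids),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
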