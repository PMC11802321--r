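#' Compare a DEG set against a reference DEG set
#'
#' Reports the shared gene count, the percentage of the reference recovered,
#' the one-sided hypergeometric (Fisher exact enrichment) probability of the
#' overlap, and the Spearman correlation of the shared genes' log2
#' fold-changes. The correlation is flagged missing when fewer than 3 genes
#' are shared.
#'
#' @param query Data frame with `gene_id` and `lfc` (one time point's DEGs).
#' @param reference Data frame with `gene_id` and `lfc`.
#' @param universe_size Number of testable genes the sets were drawn from
#'   (must be at least the size of their union).
#' @param reference_name Label for the reference set.
#' @param timepoint_weeks Time point label carried into the report.
#' @return One-row data frame: `timepoint_weeks`, `reference_name`,
#'   `n_query`, `n_reference`, `n_shared`, `pct_of_reference`, `overlap_p`,
#'   `rho`.
#' @export
compare_deg_sets <- function(query, reference, universe_size,
                             reference_name = "reference",
                             timepoint_weeks = NA_real_) {
  qid <- unique(query$gene_id); rid <- unique(reference$gene_id)
  if (universe_size < length(union(qid, rid)))
    stop("compare_deg_sets: universe smaller than the union of the sets")
  shared <- intersect(qid, rid)
  k <- length(shared)
  overlap_p <- if (k == 0) 1 else
    hypergeom_overlap(length(rid), length(qid), k, universe_size)
  rho <- NA_real_
  if (k >= 3) {
    qlfc <- query$lfc[match(shared, query$gene_id)]
    rlfc <- reference$lfc[match(shared, reference$gene_id)]
    rho <- suppressWarnings(spearman_rho(qlfc, rlfc))
  }
  data.frame(timepoint_weeks = timepoint_weeks,
             reference_name = reference_name,
             n_query = length(qid), n_reference = length(rid), n_shared = k,
             pct_of_reference = 100 * k / length(rid), overlap_p = overlap_p,
             rho = rho, stringsAsFactors = FALSE)
}

#' Concordance of per-time-point DEG sets with reference sets
#'
#' One overlap report per (time point, reference), long format.
#'
#' @param degs DEG table with `gene_id`, `timepoint_weeks`, `lfc` (e.g. the
#'   knockout DEGs after treatment-control subtraction).
#' @param references Named list of reference data frames (`gene_id`, `lfc`).
#' @param universe_size Shared gene-universe size (by default, the number of
#'   genes tested in the query experiment).
#' @return Data frame of [compare_deg_sets()] rows.
#' @export
concordance_series <- function(degs, references, universe_size) {
  tps <- sort(unique(degs$timepoint_weeks))
  out <- list()
  for (ref_nm in names(references)) {
    for (tp in tps) {
      q <- degs[degs$timepoint_weeks == tp, , drop = FALSE]
      out[[paste(ref_nm, tp)]] <- compare_deg_sets(
        q, references[[ref_nm]], universe_size,
        reference_name = ref_nm, timepoint_weeks = tp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
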