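#' Length-normalized methylation features per gene region
#'
#' Integrates one context's methylation track over the gene body (TSS to TES
#' span) or the strand-aware promoter window and divides by the full region
#' length, reported as a percentage. Uncovered bases contribute zero; with
#' `denominator = "covered"` the mean is taken over covered bases instead.
#' Genes with no overlapping signal get value 0 and `covered_bp = 0`.
#'
#' @param track A `signal_track` of per-base methylation fractions for one
#'   dinucleotide context.
#' @param genes Gene models from [read_gene_models()].
#' @param region `"gene_body"` or `"promoter"`.
#' @param promoter_bp Promoter window size in bp.
#' @param context Context label carried into the output (e.g. `"mCA"`).
#' @param denominator `"region_length"` (default) or `"covered"`.
#' @return Data frame with `gene_id`, `context`, `region`, `value` (percent),
#'   `covered_bp`.
#' @export
methylation_by_region <- function(track, genes,
                                  region = c("gene_body", "promoter"),
                                  promoter_bp = 2000, context = NA_character_,
                                  denominator = c("region_length", "covered")) {
  region <- match.arg(region)
  denominator <- match.arg(denominator)
  regs <- if (region == "gene_body") {
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end, stringsAsFactors = FALSE)
  } else {
    promoter_region(genes, promoter_bp)
  }
  total <- integrate_signal(track, regs)
  covered <- attr(total, "covered_bp")
  len <- if (denominator == "region_length") regs$end - regs$start else covered
  value <- ifelse(len > 0, 100 * as.numeric(total) / len, 0)
  data.frame(gene_id = regs$gene_id, context = context, region = region,
             value = value, covered_bp = covered, stringsAsFactors = FALSE)
}

#' Compare a per-gene feature across persistence clusters
#'
#' Kruskal-Wallis test with Dunn's pairwise comparisons over the groups
#' {up, down, background}.
#'
#' @param values Named numeric vector (one value per gene) or a feature table
#'   column aligned with `labels`.
#' @param labels Cluster labels per gene (`"up"`, `"down"`, anything else is
#'   background).
#' @param adjust_method Dunn adjustment across the pairwise family.
#' @return List with `kw` (see [kruskal_wallis()]) and `dunn` (data frame).
#' @export
cluster_feature_test <- function(values, labels, adjust_method = "holm") {
  labels <- as.character(labels)
  grp <- ifelse(labels %in% c("up", "down"), labels, "background")
  groups <- split(values, grp)[c("up", "down", "background")]
  groups <- groups[!vapply(groups, is.null, logical(1))]
  list(kw = kruskal_wallis(groups),
       dunn = dunn_posthoc(groups, adjust_method = adjust_method))
}

#' Bootstrap robustness of a cluster-feature difference
#'
#' Delegates to [bootstrap_group_comparison()] with the subsample size set to
#' the rounded mean of the up and down cluster sizes, mirroring the
#' size-matched background subsampling design.
#'
#' @param values Per-gene feature values.
#' @param labels Cluster labels (`"up"`, `"down"`, rest = background).
#' @param thresholds A [cascade_thresholds()] (supplies `n_boot` and `alpha`).
#' @param seed Integer seed.
#' @param adjust_method Per-replicate Dunn adjustment (default `"none"`; see
#'   [bootstrap_group_comparison()]).
#' @return See [bootstrap_group_comparison()].
#' @export
robustness_bootstrap <- function(values, labels,
                                 thresholds = cascade_thresholds(), seed,
                                 adjust_method = "none") {
  labels <- as.character(labels)
  grp <- ifelse(labels %in% c("up", "down"), labels, "background")
  bootstrap_group_comparison(values, grp, n_boot = thresholds$n_boot,
                             alpha = thresholds$alpha, seed = seed,
                             adjust_method = adjust_method)
}
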