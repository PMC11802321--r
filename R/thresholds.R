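#' Analysis thresholds
#'
#' Container for every numeric cutoff used by the pipeline. Defaults follow
#' the study design this package implements: differentially expressed genes
#' require an adjusted p below 0.05, an absolute log2 fold-change above 0.15
#' (roughly a 10% change) and a fold-change standard error below 0.5; genes
#' enter the analysis only when their average count across all samples is
#' strictly above 10; persistence requires a Fisher combined p below 1e-5 in
#' the knockout series, a Fisher combined p of at least 0.1 in every
#' treatment-control series, and at least a 20% change at one or more time
#' points; promoters span 2 kb upstream of the transcription start site;
#' bootstrap comparisons use 1000 replicates at a 0.05 significance level.
#'
#' @param padj_max Adjusted-p ceiling for DEG calling.
#' @param lfc_min Minimum absolute log2 fold-change for DEG calling.
#' @param se_max Maximum log2 fold-change standard error for DEG calling.
#' @param min_avg_count Genes with mean count strictly above this are retained.
#' @param fisher_ako Fisher combined-p ceiling for knockout persistence.
#' @param fisher_tc Fisher combined-p floor in the treatment controls below
#'   which a gene is considered a non-specific (tamoxifen/recombinase)
#'   responder and removed.
#' @param pct_change Minimum fold-change magnitude, as a fraction, required at
#'   one or more time points (0.20 means a 20% change, i.e. |log2 FC| >=
#'   log2(1.2)).
#' @param promoter_bp Promoter window upstream of the TSS, in bp.
#' @param n_boot Number of bootstrap replicates.
#' @param alpha Significance level for bootstrap fraction-significant
#'   summaries.
#' @return An object of class `cascade_thresholds` (a validated list).
#' @export
cascade_thresholds <- function(padj_max = 0.05, lfc_min = 0.15, se_max = 0.5,
                               min_avg_count = 10, fisher_ako = 1e-5,
                               fisher_tc = 0.1, pct_change = 0.20,
                               promoter_bp = 2000, n_boot = 1000,
                               alpha = 0.05) {
  th <- list(padj_max = padj_max, lfc_min = lfc_min, se_max = se_max,
             min_avg_count = min_avg_count, fisher_ako = fisher_ako,
             fisher_tc = fisher_tc, pct_change = pct_change,
             promoter_bp = promoter_bp, n_boot = n_boot, alpha = alpha)
  errs <- validate_thresholds(th)
  if (length(errs)) stop("invalid thresholds: ", paste(errs, collapse = "; "))
  structure(th, class = "cascade_thresholds")
}

validate_thresholds <- function(th) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  for (nm in c("padj_max", "fisher_ako", "fisher_tc", "alpha")) {
    v <- th[[nm]]
    chk(is.numeric(v) && length(v) == 1 && v > 0 && v <= 1,
        sprintf("%s must be a probability in (0,1]", nm))
  }
  for (nm in c("lfc_min", "se_max", "pct_change")) {
    v <- th[[nm]]
    chk(is.numeric(v) && length(v) == 1 && v > 0, sprintf("%s must be > 0", nm))
  }
  for (nm in c("min_avg_count", "promoter_bp", "n_boot")) {
    v <- th[[nm]]
    chk(is.numeric(v) && length(v) == 1 && v > 0, sprintf("%s must be positive", nm))
  }
  errs
}

#' @export
print.cascade_thresholds <- function(x, ...) {
  cat("cascade_thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}
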