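#' Spike-in normalization of region counts
#'
#' Scales each sample's counts by ref / spike, where ref is the geometric
#' mean of the spike-in counts across the samples being normalized together
#' (the batch). Rescaling every spike-in by a common factor leaves the result
#' unchanged.
#'
#' @param counts Region x sample count matrix.
#' @param spikein Named numeric vector of spike-in counts (names = sample
#'   ids), or a data frame with `sample_id` and `spikein_count`.
#' @return Normalized matrix, same shape as `counts`.
#' @export
spikein_normalize <- function(counts, spikein) {
  if (is.data.frame(spikein))
    spikein <- stats::setNames(spikein$spikein_count, spikein$sample_id)
  sp <- spikein[colnames(counts)]
  if (any(is.na(sp))) stop("spikein_normalize: missing spike-in counts for ",
                           paste(colnames(counts)[is.na(sp)], collapse = ", "))
  if (any(sp <= 0)) stop("spikein_normalize: zero or negative spike-in count")
  ref <- exp(mean(log(sp)))
  sweep(counts, 2, ref / sp, "*")
}

norm_within_batch <- function(counts, samples, spikein, mark, tp) {
  ids <- samples$sample_id[samples$mark == mark & samples$timepoint_weeks == tp]
  if (!length(ids)) stop("no samples for mark ", mark, " at week ", tp)
  spikein_normalize(counts[, ids, drop = FALSE], spikein)
}

cond_means <- function(norm, samples) {
  ids <- colnames(norm)
  cond <- samples$condition[match(ids, samples$sample_id)]
  if (!all(c("aKO", "control") %in% cond))
    stop("both aKO and control samples are required")
  list(ako = rowMeans(norm[, cond == "aKO", drop = FALSE]),
       control = rowMeans(norm[, cond == "control", drop = FALSE]))
}

#' Occupancy log2 fold-change per gene for one mark and time point
#'
#' Spike-in-normalizes the mark's samples within the time-point batch,
#' averages replicates per condition on the normalized scale, and computes
#' lfc = log2((mean aKO + c) / (mean control + c)).
#'
#' @param counts Region x sample raw count matrix.
#' @param samples Occupancy sample sheet (`sample_id`, `mark`, `condition`,
#'   `timepoint_weeks`, `replicate`).
#' @param spikein Spike-in counts (see [spikein_normalize()]).
#' @param mark Mark name.
#' @param timepoint Time point in weeks.
#' @param pseudocount Pseudocount c on the normalized scale.
#' @return Data frame with `gene_id`, `mark`, `timepoint_weeks`, `lfc`.
#' @export
occupancy_log2fc <- function(counts, samples, spikein, mark, timepoint,
                             pseudocount = 0.5) {
  norm <- norm_within_batch(counts, samples, spikein, mark, timepoint)
  m <- cond_means(norm, samples)
  data.frame(gene_id = rownames(counts), mark = mark,
             timepoint_weeks = timepoint,
             lfc = log2((m$ako + pseudocount) / (m$control + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Occupancy log2 fold-changes for every mark and time point
#'
#' @inheritParams occupancy_log2fc
#' @return Long data frame of [occupancy_log2fc()] rows.
#' @export
occupancy_lfc_table <- function(counts, samples, spikein, pseudocount = 0.5) {
  out <- list()
  for (mk in unique(samples$mark))
    for (tp in sort(unique(samples$timepoint_weeks[samples$mark == mk])))
      out[[paste(mk, tp)]] <- occupancy_log2fc(counts, samples, spikein, mk,
                                               tp, pseudocount)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene knockout/control depletion ratios over time
#'
#' Within each time point the mark's samples are spike-in-normalized,
#' replicates averaged per condition, and the aKO mean divided by the control
#' mean (the control is thereby set to 1 at each time point). Weeks are
#' converted to days (x 7). Genes with zero control signal at a time point
#' get an NA ratio there and are flagged.
#'
#' @inheritParams occupancy_log2fc
#' @param mark Mark to profile (default `"MeCP2"`).
#' @return Data frame with `gene_id`, `timepoint_weeks`, `t_days`, `ratio`,
#'   `flagged` (zero control signal).
#' @export
depletion_ratios <- function(counts, samples, spikein, mark = "MeCP2") {
  tps <- sort(unique(samples$timepoint_weeks[samples$mark == mark]))
  out <- list()
  for (tp in tps) {
    norm <- norm_within_batch(counts, samples, spikein, mark, tp)
    m <- cond_means(norm, samples)
    zero <- m$control == 0
    out[[as.character(tp)]] <- data.frame(
      gene_id = rownames(counts), timepoint_weeks = tp, t_days = tp * 7,
      ratio = ifelse(zero, NA_real_, m$ako / m$control), flagged = zero,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene exponential decay constants and half-lives
#'
#' Fits y = exp(t * tau) to each gene's depletion-ratio series (time in
#' days) and derives the half-life ln(2)/|tau| for decaying genes. Genes with
#' fewer than 2 usable time points are skipped.
#'
#' @param ratios Output of [depletion_ratios()].
#' @param floor Value floor before the log (see [fit_exp_decay()]).
#' @return Data frame with `gene_id`, `tau` (per day), `half_life` (days, NA
#'   when tau >= 0), `n_points`.
#' @export
decay_constants <- function(ratios, floor = 1e-6) {
  usable <- ratios[!is.na(ratios$ratio), , drop = FALSE]
  by_gene <- split(usable, usable$gene_id)
  by_gene <- by_gene[lengths(lapply(by_gene, nrow)) > 0]
  rows <- lapply(by_gene, function(df) {
    if (nrow(df) < 2) return(NULL)
    tau <- fit_exp_decay(df$t_days, df$ratio, floor = floor)
    data.frame(gene_id = df$gene_id[1], tau = tau, half_life = half_life(tau),
               n_points = nrow(df), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Z-scored occupancy fold-change trajectories by cluster
#'
#' Within each time point, standardizes the per-gene log2 fold-changes across
#' all genes (Z-score; `center_only = TRUE` skips the scaling), then reports
#' the per-cluster mean Z per time point together with Kruskal-Wallis/Dunn
#' tests of the clusters against the background at each time point.
#'
#' @param lfc_df Data frame with `gene_id`, `timepoint_weeks`, `lfc` for one
#'   mark.
#' @param labels Named cluster labels per gene (`"up"`/`"down"`/other).
#' @param center_only Center without scaling.
#' @return List with `trajectory` (`label`, `timepoint_weeks`, `mean_z`,
#'   `n_genes`) and `tests` (Dunn rows per time point).
#' @export
zscore_trajectory <- function(lfc_df, labels, center_only = FALSE) {
  lab <- as.character(labels[lfc_df$gene_id])
  lab[is.na(lab) | !lab %in% c("up", "down")] <- "background"
  traj <- list(); tests <- list()
  for (tp in sort(unique(lfc_df$timepoint_weeks))) {
    sel <- lfc_df$timepoint_weeks == tp
    x <- lfc_df$lfc[sel]
    if (length(x) < 2) stop("zscore_trajectory: need >= 2 genes per time point")
    s <- stats::sd(x)
    if (s == 0) {
      warning("zscore_trajectory: zero SD at week ", tp, "; Z set to 0")
      z <- rep(0, length(x))
    } else {
      z <- (x - mean(x)) / if (center_only) 1 else s
    }
    g <- lab[sel]
    for (cl in unique(g)) {
      traj[[paste(cl, tp)]] <- data.frame(
        label = cl, timepoint_weeks = tp, mean_z = mean(z[g == cl]),
        n_genes = sum(g == cl), stringsAsFactors = FALSE)
    }
    if (length(unique(g)) >= 2) {
      dn <- dunn_posthoc(split(z, g))
      dn$timepoint_weeks <- tp
      tests[[as.character(tp)]] <- dn
    }
  }
  traj <- do.call(rbind, traj); rownames(traj) <- NULL
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  list(trajectory = traj, tests = tests)
}

#' Repeat-family occupancy analysis by chromatin compartment
#'
#' For each compartment ("all", plus the "heterochromatin"/"euchromatin"
#' subsets from [assign_compartments()]) and repeat family: per-locus reads
#' per kilobase (RPK) in each condition, the log2 ratio of the family's
#' median RPKs, a Wilcoxon rank-sum p comparing the aKO and control RPK
#' distributions, and BH adjustment across families within the compartment.
#' Following the compartment definition, only loci with non-zero counts in
#' both conditions are analysed. Families whose control median is zero are
#' flagged missing.
#'
#' @param repeat_counts Data frame with `locus_id`, `family`, `length`,
#'   `ako_count`, `control_count`.
#' @param compartments Repeat annotation with logical membership columns from
#'   [assign_compartments()], row-aligned with `repeat_counts`.
#' @return Data frame with `family`, `compartment`, `n_loci`, `median_lfc`,
#'   `p`, `padj`.
#' @export
repeat_family_analysis <- function(repeat_counts, compartments) {
  stopifnot(nrow(repeat_counts) == nrow(compartments))
  rpk_ako <- repeat_counts$ako_count / (repeat_counts$length / 1000)
  rpk_ctrl <- repeat_counts$control_count / (repeat_counts$length / 1000)
  detected <- repeat_counts$ako_count > 0 & repeat_counts$control_count > 0
  out <- list()
  for (comp in c("all", "heterochromatin", "euchromatin")) {
    member <- compartments[[comp]] & detected
    fams <- sort(unique(repeat_counts$family[member]))
    rows <- lapply(fams, function(fam) {
      i <- member & repeat_counts$family == fam
      med_c <- stats::median(rpk_ctrl[i])
      med_a <- stats::median(rpk_ako[i])
      lfc <- if (med_c == 0) NA_real_ else log2(med_a / med_c)
      p <- wilcoxon_rank_sum(rpk_ako[i], rpk_ctrl[i])$p
      data.frame(family = fam, compartment = comp, n_loci = sum(i),
                 median_lfc = lfc, p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (!is.null(res) && nrow(res)) {
      res$padj <- bh_adjust(res$p)
      out[[comp]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
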