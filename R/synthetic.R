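#' @importFrom stats rnbinom rbeta rnorm runif rgamma
NULL

#' Default synthetic-experiment configuration
#'
#' Defines the simulated study: a 6-point time course (1, 2, 3, 4, 6 and 8
#' weeks) over five genotype/treatment groups (the conditional knockout
#' FloxCre+TMX, its FloxCre+vehicle control, and WT/Flox/Cre tamoxifen
#' treatment controls) with 3 replicates each; 2000 genes on one synthetic
#' chromosome, of which 93 are planted as persistently up-regulated and 142
#' as down-regulated after the knockout, alongside tamoxifen- and
#' recombinase-responsive nuisance genes; negative-binomial counts; gene-body
#' methylation tracks per dinucleotide context with higher non-CpG
#' methylation in the persistent clusters; spike-in-scaled occupancy counts
#' with gene-specific exponential depletion of the knocked-out protein
#' (faster at persistent genes); histone-acetylation shifts (down cluster
#' negative from week 1, up cluster positive from week 4); and repeat loci
#' with chromatin-compartment structure.
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Planted persistent cluster sizes.
#' @param n_tamoxifen,n_cre Nuisance genes responding to tamoxifen (all
#'   TMX-treated genotypes) or to recombinase activation (Cre-carrying
#'   TMX-treated genotypes).
#' @param timepoints Time points in weeks.
#' @param replicates RNA replicates per condition per time point.
#' @param baseline_range Range for log-uniform baseline mean counts.
#' @param dispersion Negative-binomial dispersion (variance = mu + a mu^2).
#' @param depth_sdlog Log-SD of per-sample depth factors.
#' @param lfc_range Magnitude range of the planted asymptotic log2
#'   fold-change for persistent genes.
#' @param ramp_weeks Time constant of the monotone trajectory
#'   lfc(t) = lfc_max (1 - exp(-t / ramp_weeks)).
#' @param nuisance_lfc_range Magnitude range of nuisance effects (constant in
#'   time, random sign).
#' @param occupancy_timepoints Occupancy (CUT&RUN-like) time points in weeks.
#' @param occupancy_replicates Occupancy replicates per condition.
#' @param tau_background,tau_persistent Mean and SD (per day) of the planted
#'   occupancy decay constants for background and persistent genes.
#' @param occupancy_dispersion NB dispersion of occupancy counts.
#' @param occupancy_base_range Range for log-uniform baseline occupancy
#'   counts per metagene.
#' @param batch_sdlog Log-SD of the per-time-point occupancy batch scale
#'   (absolute signal magnitude varies by batch; comparisons stay within a
#'   time point).
#' @param lib_sdlog Log-SD of per-sample occupancy library factors (undone by
#'   spike-in normalization).
#' @param spike_base Expected spike-in count at library factor 1.
#' @param histone_shift Magnitude of the planted acetylation log2 FC shift.
#' @param meth_background Named background methylation means per context.
#' @param meth_cluster_multiplier Multiplier on non-CpG means for persistent
#'   clusters.
#' @param meth_mcg_down_multiplier Multiplier on the mCG mean for the down
#'   cluster only.
#' @param meth_concentration Beta concentration of per-gene methylation means.
#' @param gene_length_range,gap_range Gene-body and intergenic-gap length
#'   ranges (bp).
#' @param repeat_fraction Fraction of intergenic gaps carrying a repeat locus.
#' @param repeat_length_range Repeat locus length range (bp).
#' @return A `cascade_sim_config` list.
#' @export
cascade_sim_config <- function(n_genes = 2000, n_up = 93, n_down = 142,
                               n_tamoxifen = 60, n_cre = 40,
                               timepoints = c(1, 2, 3, 4, 6, 8),
                               replicates = 3,
                               baseline_range = c(20, 2000),
                               dispersion = 0.05,
                               depth_sdlog = 0.1,
                               lfc_range = c(1.0, 1.5),
                               ramp_weeks = 2,
                               nuisance_lfc_range = c(1.2, 1.8),
                               occupancy_timepoints = c(1, 2, 4, 8),
                               occupancy_replicates = 3,
                               tau_background = c(mean = -0.077, sd = 0.015),
                               tau_persistent = c(mean = -0.135, sd = 0.02),
                               occupancy_dispersion = 0.02,
                               occupancy_base_range = c(100, 1000),
                               batch_sdlog = 0.3,
                               lib_sdlog = 0.2,
                               spike_base = 10000,
                               histone_shift = 0.4,
                               meth_background = c(mCA = 0.04, mCT = 0.03,
                                                   mCC = 0.02, mCG = 0.75),
                               meth_cluster_multiplier = 1.5,
                               meth_mcg_down_multiplier = 1.1,
                               meth_concentration = 50,
                               gene_length_range = c(2000, 20000),
                               gap_range = c(1000, 5000),
                               repeat_fraction = 0.5,
                               repeat_length_range = c(300, 3000)) {
  cfg <- as.list(environment())
  class(cfg) <- "cascade_sim_config"
  errs <- validate_sim_config(cfg)
  if (length(errs)) stop("invalid simulation config: ",
                         paste(errs, collapse = "; "))
  cfg
}

validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$n_up + cfg$n_down + cfg$n_tamoxifen + cfg$n_cre <= cfg$n_genes,
      "cluster sizes exceed n_genes")
  chk(cfg$replicates >= 2, "replicates must be >= 2")
  chk(cfg$occupancy_replicates >= 1, "occupancy_replicates must be >= 1")
  chk(cfg$dispersion > 0, "dispersion must be > 0")
  chk(all(cfg$lfc_range > 0) && diff(cfg$lfc_range) >= 0, "bad lfc_range")
  chk(all(cfg$timepoints > 0), "timepoints must be positive weeks")
  chk(all(c("mCA", "mCT", "mCC", "mCG") %in% names(cfg$meth_background)),
      "meth_background must name mCA, mCT, mCC, mCG")
  chk(cfg$tau_background[["mean"]] < 0 && cfg$tau_persistent[["mean"]] < 0,
      "planted decay constants must be negative")
  errs
}

repeat_families <- function() {
  data.frame(
    family = c("L1", "B1", "ERVK", "MajorSatellite"),
    weight = c(0.4, 0.3, 0.2, 0.1),
    p_hetero = c(0.3, 0.05, 0.5, 0.9),
    p_eu = c(0.10, 0.4, 0.05, 0.02),
    ako_mult = c(1.1, 1.0, 1.3, 1.4),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic experiment
#'
#' Generates RNA counts, gene models, per-context methylation tracks,
#' spike-in-scaled occupancy counts, peak sets, repeat annotations with
#' per-locus counts, and the ground-truth table, all index-consistent and
#' deterministic given the seed.
#'
#' @param config A [cascade_sim_config()].
#' @param seed Integer seed (mandatory).
#' @return A `cascade_dataset` list with elements `rna` (a `count_matrix`),
#'   `gene_models`, `methyl_tracks` (named list of `signal_track`s),
#'   `occupancy` (list: `counts`, `samples`, `spikein`), `peaks`, `repeats`,
#'   `repeat_counts`, `truth`, `config`, `seed`.
#' @export
simulate_experiment <- function(config = cascade_sim_config(), seed) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  errs <- validate_sim_config(config)
  if (length(errs)) stop("invalid simulation config: ",
                         paste(errs, collapse = "; "))
  with_seed(seed, simulate_experiment_impl(config, seed))
}

simulate_experiment_impl <- function(cfg, seed) {
  G <- cfg$n_genes
  gene_id <- sprintf("gene%04d", seq_len(G))

  ## --- genome layout: one synthetic chromosome, non-overlapping genes ----
  glen <- as.integer(round(runif(G, cfg$gene_length_range[1],
                                 cfg$gene_length_range[2])))
  gap <- as.integer(round(runif(G, cfg$gap_range[1], cfg$gap_range[2])))
  # leave room for a 2 kb promoter before the first gene
  start <- cumsum(c(3000L, (glen + gap)[-G]))
  gene_models <- data.frame(
    gene_id = gene_id, chrom = "chrS", start = start, end = start + glen,
    strand = sample(c("+", "-"), G, replace = TRUE),
    stringsAsFactors = FALSE)
  gene_models$tss <- ifelse(gene_models$strand == "-", gene_models$end,
                            gene_models$start)
  gene_models$tes <- ifelse(gene_models$strand == "-", gene_models$start,
                            gene_models$end)

  ## --- ground-truth labels and effects -----------------------------------
  label <- rep("null", G)
  lab_pool <- c(rep("up", cfg$n_up), rep("down", cfg$n_down),
                rep("tamoxifen_responsive", cfg$n_tamoxifen),
                rep("cre_responsive", cfg$n_cre))
  label[sample.int(G, length(lab_pool))] <- sample(lab_pool)
  lfc_max <- numeric(G)
  lfc_max[label == "up"] <- runif(sum(label == "up"),
                                  cfg$lfc_range[1], cfg$lfc_range[2])
  lfc_max[label == "down"] <- -runif(sum(label == "down"),
                                     cfg$lfc_range[1], cfg$lfc_range[2])
  nuis_lfc <- numeric(G)
  is_nuis <- label %in% c("tamoxifen_responsive", "cre_responsive")
  nuis_lfc[is_nuis] <- sample(c(-1, 1), sum(is_nuis), replace = TRUE) *
    runif(sum(is_nuis), cfg$nuisance_lfc_range[1], cfg$nuisance_lfc_range[2])

  ## --- RNA counts ---------------------------------------------------------
  groups <- data.frame(
    genotype = c("FloxCre", "FloxCre", "WT", "Flox", "Cre"),
    treatment = c("TMX", "vehicle", "TMX", "TMX", "TMX"),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    expand.grid(genotype = groups$genotype[i], treatment = groups$treatment[i],
                timepoint_weeks = cfg$timepoints,
                replicate = seq_len(cfg$replicates),
                stringsAsFactors = FALSE)
  }))
  samples$sample_id <- with(samples, paste(genotype, treatment,
                                           paste0("wk", timepoint_weeks),
                                           paste0("r", replicate), sep = "_"))
  samples <- samples[, c("sample_id", "genotype", "treatment",
                         "timepoint_weeks", "replicate")]
  baseline <- exp(runif(G, log(cfg$baseline_range[1]),
                        log(cfg$baseline_range[2])))
  depth <- exp(rnorm(nrow(samples), 0, cfg$depth_sdlog))
  ramp <- function(t) 1 - exp(-t / cfg$ramp_weeks)
  counts <- matrix(0L, G, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    sm <- samples[s, ]
    lfc <- numeric(G)
    if (sm$genotype == "FloxCre" && sm$treatment == "TMX")
      lfc <- lfc + lfc_max * ramp(sm$timepoint_weeks)
    if (sm$treatment == "TMX") {
      lfc <- lfc + ifelse(label == "tamoxifen_responsive", nuis_lfc, 0)
      if (sm$genotype %in% c("FloxCre", "Cre"))
        lfc <- lfc + ifelse(label == "cre_responsive", nuis_lfc, 0)
    }
    mu <- baseline * depth[s] * 2^lfc
    counts[, s] <- as.integer(rnbinom(G, mu = mu, size = 1 / cfg$dispersion))
  }
  rna <- count_matrix(counts, samples)

  ## --- methylation tracks (per-context, segments over gene bodies) -------
  persistent <- label %in% c("up", "down")
  conc <- cfg$meth_concentration
  meth_mean <- sapply(names(cfg$meth_background), function(ctx) {
    mult <- rep(1, G)
    if (ctx == "mCG") {
      mult[label == "down"] <- cfg$meth_mcg_down_multiplier
    } else {
      mult[persistent] <- cfg$meth_cluster_multiplier
    }
    m <- pmin(cfg$meth_background[[ctx]] * mult, 0.95)
    rbeta(G, m * conc, (1 - m) * conc)
  })
  colnames(meth_mean) <- names(cfg$meth_background)
  n_seg <- 4L
  seg_bounds <- function(st, en) {
    cuts <- as.integer(round(seq(st, en, length.out = n_seg + 1)))
    list(start = cuts[-(n_seg + 1)], end = cuts[-1])
  }
  methyl_tracks <- lapply(names(cfg$meth_background), function(ctx) {
    segs <- lapply(seq_len(G), function(g) {
      b <- seg_bounds(gene_models$start[g], gene_models$end[g])
      m <- meth_mean[g, ctx]
      v <- rbeta(n_seg, m * 200, (1 - m) * 200)
      # quantize to 6 decimals so the bedGraph round trip is value-exact
      data.frame(chrom = "chrS", start = b$start, end = b$end,
                 value = as.numeric(sprintf("%.6f", v)))
    })
    all <- do.call(rbind, segs)
    new_signal_track(all$chrom, all$start, all$end, all$value)
  })
  names(methyl_tracks) <- names(cfg$meth_background)

  ## --- occupancy counts (MeCP2-like decay + histone shifts) --------------
  tau <- rnorm(G, cfg$tau_background[["mean"]], cfg$tau_background[["sd"]])
  tau[persistent] <- rnorm(sum(persistent), cfg$tau_persistent[["mean"]],
                           cfg$tau_persistent[["sd"]])
  tau <- pmin(tau, -0.005)
  marks <- c("MeCP2", "H3K27ac", "H3K9ac")
  occ_samples <- expand.grid(mark = marks, condition = c("aKO", "control"),
                             timepoint_weeks = cfg$occupancy_timepoints,
                             replicate = seq_len(cfg$occupancy_replicates),
                             stringsAsFactors = FALSE)
  occ_samples$sample_id <- with(occ_samples, paste(mark, condition,
                                                   paste0("wk", timepoint_weeks),
                                                   paste0("r", replicate),
                                                   sep = "_"))
  occ_samples <- occ_samples[, c("sample_id", "mark", "condition",
                                 "timepoint_weeks", "replicate")]
  occ_base <- exp(runif(G, log(cfg$occupancy_base_range[1]),
                        log(cfg$occupancy_base_range[2])))
  batch <- exp(rnorm(length(cfg$occupancy_timepoints), 0, cfg$batch_sdlog))
  names(batch) <- as.character(cfg$occupancy_timepoints)
  lib <- exp(rnorm(nrow(occ_samples), 0, cfg$lib_sdlog))
  ac_shift <- function(tp) {
    sh <- numeric(G)
    sh[label == "down"] <- -cfg$histone_shift            # from week 1
    if (tp >= 4) sh[label == "up"] <- cfg$histone_shift  # later accumulation
    sh
  }
  occ_counts <- matrix(0L, G, nrow(occ_samples),
                       dimnames = list(gene_id, occ_samples$sample_id))
  for (s in seq_len(nrow(occ_samples))) {
    sm <- occ_samples[s, ]
    mu <- occ_base * batch[as.character(sm$timepoint_weeks)] * lib[s]
    if (sm$condition == "aKO") {
      if (sm$mark == "MeCP2") {
        mu <- mu * exp(tau * sm$timepoint_weeks * 7)
      } else {
        mu <- mu * 2^ac_shift(sm$timepoint_weeks)
      }
    }
    occ_counts[, s] <- as.integer(rnbinom(G, mu = mu,
                                          size = 1 / cfg$occupancy_dispersion))
  }
  spikein <- data.frame(sample_id = occ_samples$sample_id,
                        spikein_count = pmax(1L, round(cfg$spike_base * lib)),
                        stringsAsFactors = FALSE)

  ## --- repeats, per-locus counts, peaks -----------------------------------
  fams <- repeat_families()
  has_rep <- runif(G) < cfg$repeat_fraction
  rep_idx <- which(has_rep & gap > cfg$repeat_length_range[1] + 200)
  fam_i <- sample(nrow(fams), length(rep_idx), replace = TRUE,
                  prob = fams$weight)
  rlen <- as.integer(pmin(round(runif(length(rep_idx),
                                      cfg$repeat_length_range[1],
                                      cfg$repeat_length_range[2])),
                          gap[rep_idx] - 100))
  rstart <- gene_models$end[rep_idx] + 50L
  repeats <- data.frame(
    chrom = "chrS", start = rstart, end = rstart + rlen,
    family = fams$family[fam_i],
    subfamily = paste0(fams$family[fam_i], "_sub",
                       1 + (seq_along(fam_i) %% 3)),
    stringsAsFactors = FALSE)
  is_het <- runif(nrow(repeats)) < fams$p_hetero[fam_i]
  is_eu <- runif(nrow(repeats)) < fams$p_eu[fam_i]
  ctrl_rpk <- rgamma(nrow(repeats), shape = 10, rate = 0.2)   # mean 50 per kb
  ako_rpk <- ctrl_rpk * fams$ako_mult[fam_i] *
    exp(rnorm(nrow(repeats), 0, 0.15))
  rep_len <- repeats$end - repeats$start
  repeat_counts <- data.frame(
    locus_id = sprintf("rep%04d", seq_len(nrow(repeats))),
    family = repeats$family, subfamily = repeats$subfamily,
    length = rep_len,
    control_count = round(ctrl_rpk * rep_len / 1000),
    ako_count = round(ako_rpk * rep_len / 1000),
    stringsAsFactors = FALSE)

  k9_iv <- repeats[is_het, c("chrom", "start", "end")]
  k9_iv$start <- pmax(0, k9_iv$start - 200); k9_iv$end <- k9_iv$end + 200
  active <- sample.int(G, round(0.3 * G))
  prom <- promoter_region(gene_models[active, , drop = FALSE], 500)
  k27_iv <- rbind(prom[, c("chrom", "start", "end")],
                  repeats[is_eu, c("chrom", "start", "end")])
  peaks <- list(
    H3K9me3 = list(name = "H3K9me3",
                   intervals = k9_iv[order(k9_iv$start), , drop = FALSE]),
    H3K27ac = list(name = "H3K27ac",
                   intervals = k27_iv[order(k27_iv$start), , drop = FALSE]))

  truth <- data.frame(gene_id = gene_id, label = label, lfc_max = lfc_max,
                      nuisance_lfc = nuis_lfc, tau = tau,
                      meth_mean, stringsAsFactors = FALSE)
  structure(list(rna = rna, gene_models = gene_models,
                 methyl_tracks = methyl_tracks,
                 occupancy = list(counts = occ_counts, samples = occ_samples,
                                  spikein = spikein),
                 peaks = peaks, repeats = repeats,
                 repeat_counts = repeat_counts, truth = truth,
                 config = cfg, seed = seed),
            class = "cascade_dataset")
}

#' @export
print.cascade_dataset <- function(x, ...) {
  cat(sprintf(paste0("cascade_dataset: %d genes, %d RNA samples, ",
                     "%d occupancy samples, %d repeat loci (seed %s)\n"),
              nrow(x$rna$counts), ncol(x$rna$counts),
              nrow(x$occupancy$samples), nrow(x$repeats),
              format(x$seed)))
  invisible(x)
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Emits every component in the formats the readers consume (TSV counts and
#' sample sheets, BED6 gene models, bedGraph methylation tracks, BED peaks,
#' BED6+2 repeats), plus the ground-truth table and a ready-to-run pipeline
#' config (`config.yaml`).
#'
#' @param dataset A `cascade_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- list(counts = p("rna_counts.tsv"), samples = p("rna_samples.tsv"),
                gene_models = p("gene_models.bed"),
                occupancy_counts = p("occupancy_counts.tsv"),
                occupancy_samples = p("occupancy_samples.tsv"),
                spikein = p("spikein_counts.tsv"),
                repeats = p("repeats.bed"),
                repeat_counts = p("repeat_counts.tsv"),
                truth = p("truth.tsv"), config = p("config.yaml"))
  write_count_matrix(dataset$rna, paths$counts, paths$samples)
  write_gene_models(dataset$gene_models, paths$gene_models)
  for (ctx in names(dataset$methyl_tracks)) {
    paths[[paste0("methyl_", ctx)]] <- p(paste0("methyl_", ctx, ".bedGraph"))
    write_signal_track(dataset$methyl_tracks[[ctx]],
                       paths[[paste0("methyl_", ctx)]])
  }
  occ <- data.frame(gene_id = rownames(dataset$occupancy$counts),
                    dataset$occupancy$counts, check.names = FALSE)
  utils::write.table(occ, paths$occupancy_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$occupancy$samples, paths$occupancy_samples,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$occupancy$spikein, paths$spikein,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (mk in names(dataset$peaks)) {
    paths[[paste0("peaks_", mk)]] <- p(paste0("peaks_", mk, ".bed"))
    write_peaks(dataset$peaks[[mk]], paths[[paste0("peaks_", mk)]])
  }
  write_repeats(dataset$repeats, paths$repeats)
  utils::write.table(dataset$repeat_counts, paths$repeat_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  num <- vapply(truth, is.numeric, logical(1))
  truth[num] <- lapply(truth[num], function(v) round(v, 10))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(
    seed = dataset$seed,
    inputs = list(
      rna_counts = "rna_counts.tsv", rna_samples = "rna_samples.tsv",
      gene_models = "gene_models.bed",
      methyl_tracks = as.list(stats::setNames(
        paste0("methyl_", names(dataset$methyl_tracks), ".bedGraph"),
        names(dataset$methyl_tracks))),
      occupancy_counts = "occupancy_counts.tsv",
      occupancy_samples = "occupancy_samples.tsv",
      spikein_counts = "spikein_counts.tsv",
      peaks_h3k9me3 = "peaks_H3K9me3.bed",
      peaks_h3k27ac = "peaks_H3K27ac.bed",
      repeats = "repeats.bed", repeat_counts = "repeat_counts.tsv"),
    stages = list(de = TRUE, persistence = TRUE, concordance = FALSE,
                  methylation = TRUE, occupancy = TRUE, repeats = TRUE),
    thresholds = unclass(cascade_thresholds()))
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with the same data components as the originating
#'   `cascade_dataset` (including the truth table when present).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  ctxs <- sub("^methyl_(.*)\\.bedGraph$", "\\1",
              list.files(dir, pattern = "^methyl_.*\\.bedGraph$"))
  methyl <- lapply(ctxs, function(ctx) read_signal_track(
    p(paste0("methyl_", ctx, ".bedGraph"))))
  names(methyl) <- ctxs
  occ_samples <- utils::read.table(p("occupancy_samples.tsv"), sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)
  occ <- utils::read.table(p("occupancy_counts.tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  occ_m <- as.matrix(occ[, -1, drop = FALSE]); rownames(occ_m) <- occ$gene_id
  truth_path <- p("truth.tsv")
  list(
    rna = read_count_matrix(p("rna_counts.tsv"), p("rna_samples.tsv")),
    gene_models = read_gene_models(p("gene_models.bed")),
    methyl_tracks = methyl,
    occupancy = list(
      counts = occ_m, samples = occ_samples,
      spikein = utils::read.table(p("spikein_counts.tsv"), sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)),
    peaks = list(
      H3K9me3 = read_peaks(p("peaks_H3K9me3.bed"), "H3K9me3"),
      H3K27ac = read_peaks(p("peaks_H3K27ac.bed"), "H3K27ac")),
    repeats = read_repeats(p("repeats.bed")),
    repeat_counts = utils::read.table(p("repeat_counts.tsv"), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE),
    truth = if (file.exists(truth_path))
      utils::read.table(truth_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
}
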