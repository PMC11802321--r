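#' Read a pipeline configuration file
#'
#' The config is YAML with keys `seed`, `inputs` (paths, relative to the
#' config file's directory), `stages` (logical toggles: `de`, `persistence`,
#' `concordance`, `methylation`, `occupancy`, `repeats`, `bootstrap`), and
#' optional `thresholds` overrides and `references` (named reference DEG
#' TSVs for the concordance stage).
#'
#' @param path Path to the YAML config.
#' @return Config list with a `base_dir` attribute.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  cfg
}

resolve_path <- function(p, base_dir) {
  if (is.null(p)) return(NULL)
  ifelse(grepl("^/", p), p, file.path(base_dir, p))
}

#' Validate a pipeline configuration
#'
#' Checks input files, threshold invariants, the seed requirement for
#' resampling stages, and cross-references (sample sheet vs count columns,
#' occupancy sample sheet vs occupancy count columns and spike-ins). All
#' violations are collected and reported together rather than stopping at the
#' first.
#'
#' @param config Config list (from [read_pipeline_config()]) or a path.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  base_dir <- attr(config, "base_dir") %||% "."
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  st <- config$stages %||% list()
  inputs <- config$inputs %||% list()
  flat <- unlist(inputs)
  for (nm in names(flat)) {
    fp <- resolve_path(flat[[nm]], base_dir)
    if (!file.exists(fp)) add(sprintf("input %s: file not found: %s", nm, fp))
  }
  th <- config$thresholds
  if (!is.null(th)) {
    full <- unclass(cascade_thresholds())
    full[names(th)] <- th
    errs <- c(errs, validate_thresholds(full))
  }
  needs_seed <- isTRUE(st$bootstrap)
  if (needs_seed && is.null(config$seed))
    add("seed is mandatory when the bootstrap stage is enabled")
  counts_p <- resolve_path(inputs$rna_counts, base_dir)
  samples_p <- resolve_path(inputs$rna_samples, base_dir)
  if (!is.null(counts_p) && !is.null(samples_p) &&
      file.exists(counts_p) && file.exists(samples_p)) {
    hdr <- strsplit(readLines(counts_p, n = 1), "\t", fixed = TRUE)[[1]]
    sm <- tryCatch(read_sample_sheet(samples_p), error = function(e) {
      add(conditionMessage(e)); NULL
    })
    if (!is.null(sm)) {
      miss <- setdiff(sm$sample_id, hdr)
      if (length(miss))
        add(paste("samples missing from count matrix:",
                  paste(miss, collapse = ", ")))
      extra <- setdiff(hdr[-1], sm$sample_id)
      if (length(extra))
        add(paste("count columns missing from sample sheet:",
                  paste(extra, collapse = ", ")))
    }
  }
  occ_p <- resolve_path(inputs$occupancy_counts, base_dir)
  occ_s <- resolve_path(inputs$occupancy_samples, base_dir)
  if (!is.null(occ_p) && !is.null(occ_s) && file.exists(occ_p) &&
      file.exists(occ_s)) {
    hdr <- strsplit(readLines(occ_p, n = 1), "\t", fixed = TRUE)[[1]]
    osm <- utils::read.table(occ_s, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    miss <- setdiff(osm$sample_id, hdr)
    if (length(miss))
      add(paste("occupancy samples missing from occupancy counts:",
                paste(miss, collapse = ", ")))
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_tsv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (differential expression,
#' persistence, concordance, methylation, occupancy/kinetics, repeats) from
#' a config file, writing one TSV per result table plus a run manifest
#' (package version, seed, thresholds actually used). The run is
#' deterministic given inputs and seed; per-stage log lines go to stderr and
#' `run.log`.
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_pipeline_config()]); [write_fixture()] emits a ready-to-run one.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  base_dir <- attr(config, "base_dir") %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages %||% list(de = TRUE, persistence = TRUE,
                                concordance = FALSE, methylation = TRUE,
                                occupancy = TRUE, repeats = TRUE,
                                bootstrap = FALSE)
  th <- unclass(cascade_thresholds())
  th[names(config$thresholds %||% list())] <- config$thresholds
  th <- do.call(cascade_thresholds, th)
  inp <- function(nm) resolve_path(config$inputs[[nm]], base_dir)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(...) {
    msg <- sprintf(...)
    message(msg)
    writeLines(msg, log_con)
  }
  outputs <- list()
  stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) {
      logline("stage %s: disabled", name)
      return(invisible(NULL))
    }
    logline("stage %s: start", name)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage %s failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), outdir), call. = FALSE)
    })
  }

  de_results <- NULL; degs <- NULL; labels <- NULL; persist <- NULL
  gene_models <- if (!is.null(inp("gene_models")))
    read_gene_models(inp("gene_models"))

  stage("de", st$de, function() {
    cm <- read_count_matrix(inp("rna_counts"), inp("rna_samples"))
    de_results <<- de_timecourse(cm, th)
    outputs$de_results <<- write_stage_tsv(de_results, outdir, "de_results.tsv")
    all_degs <- call_degs(de_results, th)
    ako <- all_degs[all_degs$contrast == "FloxCre", , drop = FALSE]
    ctrl <- split(all_degs[all_degs$contrast != "FloxCre", , drop = FALSE],
                  all_degs$contrast[all_degs$contrast != "FloxCre"])
    degs <<- subtract_nonspecific(ako, ctrl)
    outputs$degs <<- write_stage_tsv(degs, outdir, "degs.tsv")
    logline("stage de: %d genes tested, %d specific DEG calls",
            length(unique(de_results$gene_id)), nrow(degs))
  })

  stage("persistence", st$persistence && !is.null(de_results), function() {
    pa <- persistence_analysis(de_results, th)
    persist <<- pa
    labels <<- stats::setNames(pa$records$label, pa$records$gene_id)
    outputs$persistence <<- write_stage_tsv(pa$records, outdir,
                                            "persistence.tsv")
    traj <- trajectory_summary(pa$lfc_matrix, pa$records)
    if (!is.null(traj))
      outputs$trajectory <<- write_stage_tsv(traj, outdir, "trajectory.tsv")
    logline("stage persistence: %d up, %d down of %d genes",
            sum(pa$records$label == "up"), sum(pa$records$label == "down"),
            nrow(pa$records))
  })

  stage("concordance", st$concordance && !is.null(degs), function() {
    refs <- lapply(config$references, function(p)
      utils::read.table(resolve_path(p, base_dir), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
    universe <- length(unique(de_results$gene_id))
    conc <- concordance_series(degs, refs, universe)
    outputs$concordance <<- write_stage_tsv(conc, outdir, "concordance.tsv")
    logline("stage concordance: %d reports", nrow(conc))
  })

  stage("methylation", st$methylation, function() {
    ctxs <- names(config$inputs$methyl_tracks)
    feats <- list(); tests <- list(); boots <- list()
    for (ctx in ctxs) {
      track <- read_signal_track(resolve_path(
        config$inputs$methyl_tracks[[ctx]], base_dir))
      for (reg in c("gene_body", "promoter")) {
        f <- methylation_by_region(track, gene_models, reg,
                                   promoter_bp = th$promoter_bp,
                                   context = ctx)
        feats[[paste(ctx, reg)]] <- f
        if (!is.null(labels) && reg == "gene_body") {
          ct <- cluster_feature_test(f$value, labels[f$gene_id])
          dn <- ct$dunn; dn$context <- ctx; dn$region <- reg
          dn$kw_p <- ct$kw$p
          tests[[paste(ctx, reg)]] <- dn
        }
      }
    }
    outputs$methylation_features <<- write_stage_tsv(
      do.call(rbind, feats), outdir, "methylation_features.tsv")
    if (length(tests))
      outputs$methylation_tests <<- write_stage_tsv(
        do.call(rbind, tests), outdir, "methylation_tests.tsv")
    if (isTRUE(st$bootstrap) && !is.null(labels)) {
      boot_ctxs <- config$methylation_bootstrap_contexts %||% "mCA"
      for (ctx in intersect(boot_ctxs, ctxs)) {
        f <- feats[[paste(ctx, "gene_body")]]
        rb <- robustness_bootstrap(f$value, labels[f$gene_id], th,
                                   seed = config$seed)
        boots[[ctx]] <- data.frame(context = ctx,
                                   comparison = names(rb$frac_significant),
                                   frac_significant = rb$frac_significant,
                                   n_boot = rb$n_boot,
                                   stringsAsFactors = FALSE)
      }
      if (length(boots))
        outputs$methylation_bootstrap <<- write_stage_tsv(
          do.call(rbind, boots), outdir, "methylation_bootstrap.tsv")
    }
    logline("stage methylation: %d contexts", length(ctxs))
  })

  stage("occupancy", st$occupancy, function() {
    occ <- utils::read.table(inp("occupancy_counts"), sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    occ_m <- as.matrix(occ[, -1, drop = FALSE]); rownames(occ_m) <- occ[[1]]
    osm <- utils::read.table(inp("occupancy_samples"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    spikein <- utils::read.table(inp("spikein_counts"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
    lfc_tab <- occupancy_lfc_table(occ_m, osm, spikein)
    outputs$occupancy_lfc <<- write_stage_tsv(lfc_tab, outdir,
                                              "occupancy_lfc.tsv")
    if ("MeCP2" %in% osm$mark) {
      ratios <- depletion_ratios(occ_m, osm, spikein, "MeCP2")
      fits <- decay_constants(ratios)
      outputs$decay_fits <<- write_stage_tsv(fits, outdir, "decay_fits.tsv")
      if (!is.null(labels)) {
        ct <- cluster_feature_test(fits$tau, labels[fits$gene_id])
        dn <- ct$dunn; dn$kw_p <- ct$kw$p
        outputs$decay_tests <<- write_stage_tsv(dn, outdir, "decay_tests.tsv")
      }
    }
    if (!is.null(labels)) {
      zs <- list()
      for (mk in setdiff(unique(osm$mark), "MeCP2")) {
        z <- zscore_trajectory(lfc_tab[lfc_tab$mark == mk, , drop = FALSE],
                               labels)
        z$trajectory$mark <- mk
        zs[[mk]] <- z$trajectory
      }
      if (length(zs))
        outputs$zscore_trajectory <<- write_stage_tsv(
          do.call(rbind, zs), outdir, "zscore_trajectory.tsv")
    }
    logline("stage occupancy: %d marks, %d genes",
            length(unique(osm$mark)), nrow(occ_m))
  })

  stage("repeats", st$repeats, function() {
    repeats <- read_repeats(inp("repeats"))
    k9 <- read_peaks(inp("peaks_h3k9me3"), "H3K9me3")
    k27 <- read_peaks(inp("peaks_h3k27ac"), "H3K27ac")
    comp <- assign_compartments(repeats, k9, k27)
    rc <- utils::read.table(inp("repeat_counts"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    res <- repeat_family_analysis(rc, comp)
    outputs$repeat_results <<- write_stage_tsv(res, outdir,
                                               "repeat_results.tsv")
    logline("stage repeats: %d family-compartment results", nrow(res))
  })

  manifest <- list(package = "epicascade",
                   version = as.character(utils::packageVersion("epicascade")),
                   seed = config$seed, thresholds = unclass(th),
                   stages = st,
                   outputs = lapply(outputs, basename))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  logline("pipeline complete: %d output tables", length(outputs))
  invisible(outputs)
}
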