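occ_fixture <- function(ako = 50, ctrl = 100, n_genes = 3) {
  counts <- cbind(a1 = rep(ako, n_genes), c1 = rep(ctrl, n_genes))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  samples <- data.frame(sample_id = c("a1", "c1"), mark = "MeCP2",
                        condition = c("aKO", "control"), timepoint_weeks = 1,
                        replicate = 1)
  spike <- setNames(c(1000, 1000), c("a1", "c1"))
  list(counts = counts, samples = samples, spike = spike)
}

test_that("spike-in normalization rescales by the geometric-mean reference", {
  m <- cbind(s1 = c(10, 20), s2 = c(10, 20))
  expect_equal(spikein_normalize(m, c(s1 = 500, s2 = 500)), m)
  # a sample with twice the reference spike-in has its counts halved
  n <- spikein_normalize(m, c(s1 = 500, s2 = 2000))
  expect_equal(unname(n[, "s2"] / m[, "s2"]), rep(0.5, 2))
  # common scaling of all spike-ins changes nothing
  expect_equal(spikein_normalize(m, c(s1 = 500, s2 = 2000)),
               spikein_normalize(m, c(s1 = 5000, s2 = 20000)))
  expect_error(spikein_normalize(m, c(s1 = 0, s2 = 10)), "zero")
})

test_that("occupancy fold-changes use pseudocounted normalized means", {
  fx <- occ_fixture()
  lfc <- occupancy_log2fc(fx$counts, fx$samples, fx$spike, "MeCP2", 1)
  expect_equal(lfc$lfc, rep(log2(50.5 / 100.5), 3))
  expect_equal(lfc$lfc[1], -0.99283, tolerance = 1e-4)
  same <- occ_fixture(100, 100)
  expect_equal(occupancy_log2fc(same$counts, same$samples, same$spike,
                                "MeCP2", 1)$lfc, rep(0, 3))
})

test_that("depletion ratios fix the control at 1 and report days", {
  fx <- occ_fixture(100, 100)
  r <- depletion_ratios(fx$counts, fx$samples, fx$spike)
  expect_equal(r$ratio, rep(1, 3))
  expect_equal(unique(r$t_days), 7)
  # zero control signal flags the gene
  fz <- occ_fixture()
  fz$counts[2, "c1"] <- 0
  rz <- depletion_ratios(fz$counts, fz$samples, fz$spike)
  expect_true(rz$flagged[2] && is.na(rz$ratio[2]))
})

test_that("decay fitting recovers planted constants from ratio series", {
  ratios <- data.frame(gene_id = "g1", timepoint_weeks = c(1, 2, 4, 8),
                       t_days = c(7, 14, 28, 56),
                       ratio = exp(-0.1 * c(7, 14, 28, 56)), flagged = FALSE)
  fit <- decay_constants(ratios)
  expect_equal(fit$tau, -0.1, tolerance = 1e-12)
  expect_equal(fit$half_life, log(2) / 0.1, tolerance = 1e-10)
  flat <- ratios; flat$ratio <- 1
  ffit <- decay_constants(flat)
  expect_equal(ffit$tau, 0)
  expect_true(is.na(ffit$half_life))
})

test_that("Z-scored trajectories are centered and detect planted shifts", {
  set.seed(23)
  n <- 400
  lfc <- data.frame(gene_id = paste0("g", 1:n), timepoint_weeks = 1,
                    lfc = rnorm(n))
  labels <- setNames(rep("background", n), paste0("g", 1:n))
  labels[1:40] <- "up"
  lfc$lfc[1:40] <- lfc$lfc[1:40] + 1           # +1 SD of the background
  z <- zscore_trajectory(lfc, labels)
  overall <- sum(z$trajectory$mean_z * z$trajectory$n_genes) / n
  expect_equal(overall, 0, tolerance = 1e-12)  # exact centering
  up_z <- z$trajectory$mean_z[z$trajectory$label == "up"]
  expect_equal(up_z, 1, tolerance = 0.35)
  expect_true(any(z$tests$padj < 0.05))
})

test_that("planted acetylation shifts appear from the planted week on", {
  ds <- default_study()$ds
  labels <- setNames(ds$truth$label, ds$truth$gene_id)
  lfc_tab <- occupancy_lfc_table(ds$occupancy$counts, ds$occupancy$samples,
                                 ds$occupancy$spikein)
  z <- zscore_trajectory(lfc_tab[lfc_tab$mark == "H3K27ac", ], labels)
  tr <- z$trajectory
  down_w1 <- tr$mean_z[tr$label == "down" & tr$timepoint_weeks == 1]
  expect_lt(down_w1, -0.3)                     # early deacetylation
  up_w8 <- tr$mean_z[tr$label == "up" & tr$timepoint_weeks == 8]
  expect_gt(up_w8, 0.3)                        # late accumulation
  up_w1 <- tr$mean_z[tr$label == "up" & tr$timepoint_weeks == 1]
  expect_lt(abs(up_w1), 0.3)                   # no early up-cluster shift
})

test_that("repeat-family analysis reports RPK medians per compartment", {
  rc <- data.frame(locus_id = paste0("r", 1:6),
                   family = rep(c("L1", "B1"), each = 3),
                   subfamily = "s", length = c(1000, 2000, 500, 1000, 1000, 250),
                   control_count = c(10, 30, 5, 8, 12, 2),
                   ako_count = c(20, 60, 10, 8, 12, 2))
  comp <- data.frame(all = TRUE, heterochromatin = rep(c(TRUE, FALSE), each = 3),
                     euchromatin = FALSE)
  out <- repeat_family_analysis(rc, comp)
  # aKO = 2x control at every L1 locus: median lfc exactly 1
  expect_equal(out$median_lfc[out$family == "L1" & out$compartment == "all"], 1)
  # identical conditions: lfc 0, p 1
  b1 <- out[out$family == "B1" & out$compartment == "all", ]
  expect_equal(b1$median_lfc, 0)
  expect_equal(b1$p, 1)
  # B1 overlaps no peak: present only in the "all" compartment
  expect_false(any(out$family == "B1" & out$compartment != "all"))
  expect_true(all(out$padj >= out$p))
})

test_that("locus splitting leaves family medians stable", {
  rc <- data.frame(locus_id = paste0("r", 1:3), family = "L1", subfamily = "s",
                   length = c(1000, 1000, 2000),
                   control_count = c(10, 10, 20), ako_count = c(30, 30, 60))
  split_rc <- data.frame(locus_id = paste0("r", 1:4), family = "L1",
                         subfamily = "s", length = c(1000, 1000, 1000, 1000),
                         control_count = c(10, 10, 10, 10),
                         ako_count = c(30, 30, 30, 30))
  compf <- function(n) data.frame(all = rep(TRUE, n),
                                  heterochromatin = FALSE, euchromatin = FALSE)
  a <- repeat_family_analysis(rc, compf(3))
  b <- repeat_family_analysis(split_rc, compf(4))
  expect_equal(a$median_lfc[a$compartment == "all"],
               b$median_lfc[b$compartment == "all"])
})
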