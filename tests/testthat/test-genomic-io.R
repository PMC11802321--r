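write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("gene model reading derives TSS/TES from strand and validates", {
  f <- write_lines_tmp(c("chr1\t10000\t12000\tgeneA\t0\t+",
                         "chr1\t20000\t25000\tgeneB\t0\t-"), ".bed")
  gm <- read_gene_models(f)
  expect_equal(gm$tss, c(10000, 25000))
  expect_equal(gm$tes, c(12000, 20000))

  bad <- write_lines_tmp(c("chr1\t100\t200\tg1\t0\t+",
                           "chr1\t500\t400\tg2\t0\t+"), ".bed")
  expect_error(read_gene_models(bad), "line 2")
  dup <- write_lines_tmp(c("chr1\t100\t200\tg1\t0\t+",
                           "chr1\t300\t400\tg1\t0\t+"), ".bed")
  expect_error(read_gene_models(dup), "duplicate")
  odd <- write_lines_tmp("chr1\t100\t200\tg1\t0\t*", ".bed")
  expect_error(read_gene_models(odd), "strand")
})

test_that("bedGraph tracks round-trip exactly, sort, and reject overlaps", {
  tr <- signal_track(c("chr2", "chr1", "chr1"), c(50, 100, 0),
                         c(80, 150, 30), c(1.25, 0.5, 2))
  f <- tempfile(fileext = ".bedGraph")
  write_signal_track(tr, f)
  back <- read_signal_track(f)
  expect_equal(back$value, tr$value)
  expect_equal(back$start, tr$start)
  # sorted by (chrom, start) regardless of input order
  unsorted <- write_lines_tmp(c("chr1\t100\t150\t1", "chr1\t0\t30\t2"))
  got <- read_signal_track(unsorted)
  expect_equal(got$start, c(0, 100))

  over <- write_lines_tmp(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"))
  expect_error(read_signal_track(over), "overlapping")
  neg <- write_lines_tmp("chr1\t0\t10\t-1")
  expect_error(read_signal_track(neg), ">= 0")
})

test_that("metagene regions are strand-aware, clamped, and mirror-symmetric", {
  gm <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(10000, 10000, 500), end = c(12000, 12000, 900),
                   strand = c("+", "-", "+"),
                   tss = c(10000, 12000, 500), tes = c(12000, 10000, 900))
  mg <- build_metagene_region(gm, 2000)
  expect_equal(mg$start, c(8000, 10000, 0))
  expect_equal(mg$end, c(12000, 14000, 900))

  # mirrored plus/minus genes give mirrored regions; length = span + promoter
  set.seed(1)
  for (i in 1:50) {
    s <- sample(3000:50000, 1); len <- sample(500:5000, 1); pb <- sample(0:3000, 1)
    plus <- data.frame(gene_id = "p", chrom = "c", start = s, end = s + len,
                       strand = "+", tss = s, tes = s + len)
    L <- 100000
    minus <- data.frame(gene_id = "m", chrom = "c", start = L - (s + len),
                        end = L - s, strand = "-", tss = L - s,
                        tes = L - (s + len))
    rp <- build_metagene_region(plus, pb); rm_ <- build_metagene_region(minus, pb)
    expect_equal(rp$end - rp$start, len + pb)
    expect_equal(c(rm_$start, rm_$end), c(L - rp$end, L - rp$start))
  }
})

test_that("signal integration matches the per-base brute-force oracle", {
  # worked cases: a uniform box and a partial overlap
  tr <- signal_track("chr1", 0, 100, 1.0)
  expect_equal(as.numeric(integrate_signal(
    tr, data.frame(chrom = "chr1", start = 0, end = 100))), 100)
  tr2 <- signal_track("chr1", 0, 50, 2.0)
  expect_equal(as.numeric(integrate_signal(
    tr2, data.frame(chrom = "chr1", start = 25, end = 75))), 50)
  empty <- signal_track(character(), numeric(), numeric(), numeric())
  expect_equal(as.numeric(integrate_signal(
    empty, data.frame(chrom = "chr1", start = 0, end = 10))), 0)

  set.seed(7)
  for (i in 1:40) {
    tr <- random_track()
    a <- sort(sample(0:200, 2))
    if (a[1] == a[2]) next
    reg <- data.frame(chrom = "chr1", start = a[1], end = a[2])
    expect_identical(as.numeric(integrate_signal(tr, reg)),
                     integrate_brute(tr, "chr1", a[1], a[2]))
  }
})

test_that("compartment assignment matches the interval-overlap oracle", {
  reps <- data.frame(chrom = "chr1", start = c(100, 1000, 5000),
                     end = c(200, 1100, 5600),
                     family = "L1", subfamily = "L1_a")
  k9 <- list(name = "H3K9me3",
             intervals = data.frame(chrom = "chr1", start = 150, end = 400))
  k27 <- list(name = "H3K27ac",
              intervals = data.frame(chrom = "chr1", start = c(1050, 5100),
                                     end = c(1090, 5200)))
  comp <- assign_compartments(reps, k9, k27)
  expect_true(all(comp$all))
  expect_equal(comp$heterochromatin, c(TRUE, FALSE, FALSE))
  expect_equal(comp$euchromatin, c(FALSE, TRUE, TRUE))

  set.seed(11)
  for (i in 1:30) {
    reps <- data.frame(chrom = "chr1",
                       start = st <- sample(0:500, 8),
                       end = st + sample(1:50, 8, replace = TRUE),
                       family = "f", subfamily = "s")
    pk <- data.frame(chrom = "chr1", start = ps <- sample(0:500, 4),
                     end = ps + sample(1:80, 4, replace = TRUE))
    comp <- assign_compartments(reps, list(name = "a", intervals = pk),
                                list(name = "b", intervals = pk[1:2, ]))
    for (j in seq_len(nrow(reps))) {
      expect_identical(comp$heterochromatin[j],
                       overlap_brute("chr1", reps$start[j], reps$end[j], pk))
      expect_identical(comp$euchromatin[j],
                       overlap_brute("chr1", reps$start[j], reps$end[j],
                                     pk[1:2, ]))
    }
  }
})

test_that("count matrix and repeat readers enforce their invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  sm <- data.frame(sample_id = c("s1", "s2", "s3"), genotype = "WT",
                   treatment = "TMX", timepoint_weeks = 1, replicate = 1:3)
  cm <- count_matrix(m, sm)
  cf <- tempfile(); sf <- tempfile()
  write_count_matrix(cm, cf, sf)
  back <- read_count_matrix(cf, sf)
  expect_identical(back$counts, m)

  m2 <- m; m2[1, 1] <- -1
  expect_error(count_matrix(m2, sm), "non-negative")
  expect_error(count_matrix(m, sm[1:2, ]), "match")

  rf <- write_lines_tmp("chr1\t10\t100\tL1:sub\t0\t.\t\tsub")
  expect_error(read_repeats(rf), "family")
})
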