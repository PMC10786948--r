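test_that("hypergeometric assignment matches the binomial-coefficient oracle", {
  # dataset pool: guide A total 30, guide B total 70 (all counts survive the
  # per-guide UMI floor); the first cell holds 10 UMIs, all guide A
  capture <- matrix(0, nrow = 2, ncol = 3,
                    dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
  capture["A", "c1"] <- 10; capture["A", "c2"] <- 20; capture["B", "c3"] <- 70
  out <- assign_guides_hypergeom(capture)
  c1 <- dplyr::filter(out, barcode == "c1")
  oracle_p <- choose(30, 10) / choose(100, 10)
  # the single-guide cell is tested against the dataset-wide pool
  expect_equal(c1$p_adj, oracle_p, tolerance = 1e-12)
  expect_equal(c1$log2_odds, log2(11 / 1), tolerance = 1e-12)
  expect_true(c1$assigned)
  expect_equal(c1$guide, "A")

  # all-zero cell is unassigned
  capture0 <- cbind(capture, c0 = c(0, 0))
  out0 <- assign_guides_hypergeom(capture0)
  expect_false(dplyr::filter(out0, barcode == "c0")$assigned)

  # ambiguous cell: counts 20 vs 18 give LOR 0.14 < 1
  amb <- matrix(c(20, 18, 40, 40), nrow = 2,
                dimnames = list(c("A", "B"), c("c1", "c2")))
  out_amb <- assign_guides_hypergeom(amb)
  a1 <- dplyr::filter(out_amb, barcode == "c1")
  expect_equal(a1$log2_odds, log2(21 / 19), tolerance = 1e-12)
  expect_false(a1$assigned)

  expect_error(assign_guides_hypergeom(matrix(0, 0, 0)), "empty")
})

test_that("cells with tied top guide counts are never assigned", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(6:30, 1)
    capture <- matrix(c(k, k, sample(6:50, 2)), nrow = 2,
                      dimnames = list(c("A", "B"), c("tied", "other")))
    out <- assign_guides_hypergeom(capture)
    expect_false(dplyr::filter(out, barcode == "tied")$assigned)
  }
})

test_that("nucleosome signal counts the stated length bands", {
  # lengths 80, 120 (free), 160, 200 (mono), 310 (ignored)
  starts <- c(1000L, 2000L, 3000L, 4000L, 5000L)
  lens <- c(80L, 120L, 160L, 200L, 310L)
  fr <- tibble::tibble(chrom = "chr1", start = starts, end = starts + lens,
                       barcode = "bc1", count = 1L)
  tss <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 100000L, strand = "+")
  qc <- fragment_qc_metrics(fr, c(bc1 = 500), tss)
  expect_equal(qc$nucleosome_signal, 2 / 2)
  expect_equal(qc$atac_umi, 5L)

  # all fragments below 147 bp: signal 0; none below: Inf
  fr_free <- dplyr::mutate(fr, end = start + 100L)
  expect_equal(fragment_qc_metrics(fr_free, c(bc1 = 500), tss)$nucleosome_signal, 0)
  fr_mono <- dplyr::mutate(fr, end = start + 200L)
  expect_equal(fragment_qc_metrics(fr_mono, c(bc1 = 500), tss)$nucleosome_signal, Inf)
})

test_that("TSS enrichment is 1 for flat coverage and detects central signal", {
  tss <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 50000L, strand = "+")
  # one fragment covering the whole +/-1000 bp window uniformly
  flat <- tibble::tibble(chrom = "chr1", start = 49000L, end = 51001L,
                         barcode = "bc1", count = 4L)
  qc <- fragment_qc_metrics(flat, c(bc1 = 500), tss)
  expect_equal(qc$tss_enrichment, 1)

  # extra coverage at the centre doubles the ratio
  centre <- dplyr::bind_rows(
    flat,
    tibble::tibble(chrom = "chr1", start = 49950L, end = 50051L,
                   barcode = "bc1", count = 4L)
  )
  qc2 <- fragment_qc_metrics(centre, c(bc1 = 500), tss)
  expect_equal(qc2$tss_enrichment, 2)

  # minus-strand TSS: same flat identity after orientation
  tss_m <- dplyr::mutate(tss, strand = "-")
  expect_equal(fragment_qc_metrics(flat, c(bc1 = 500), tss_m)$tss_enrichment, 1)
})

test_that("QC bounds are strict and relaxing them is monotone", {
  qc <- tibble::tibble(
    barcode = paste0("c", 1:6),
    atac_umi = c(500, 5000, 5000, 5000, 5000, 100000),
    rna_umi = c(500, 500, 500, 500, 25000, 500),
    nucleosome_signal = c(1, 1, 4, 1, 1, 1),
    tss_enrichment = c(2, 2, 2, 1, 2, 2)
  )
  keep <- apply_qc_filter(qc)
  expect_equal(keep, "c2", ignore_attr = TRUE)  # boundary cells fail (exclusive bounds)
  log <- attr(keep, "filter_log")
  expect_equal(log$n_failed[log$criterion == "atac_umi"], 2L)

  # monotone: relaxing every bound keeps a superset
  keep2 <- apply_qc_filter(qc, atac_bounds = c(0, Inf), rna_bounds = c(0, Inf),
                           max_nucleosome_signal = Inf, min_tss_enrichment = 0)
  expect_true(all(keep %in% keep2))

  # undefined metrics fail
  qc_na <- dplyr::mutate(qc, nucleosome_signal = NA_real_)
  expect_length(apply_qc_filter(qc_na), 0)
})

test_that("gene activity equals the all-pairs overlap oracle", {
  # boundary fixture: + strand TSS at 5000, promoter [3000, 5000)
  tss <- tibble::tibble(gene = "gp", chrom = "chr1", tss = 5000L, strand = "+")
  fr <- tibble::tibble(
    chrom = "chr1",
    start = c(2900L, 5100L, 2000L, 4999L),
    end = c(3050L, 5200L, 2999L, 5100L),
    barcode = "bc1", count = 1L
  )
  act <- gene_activity_scores(fr, tss)
  # [2900,3050) overlaps, [5100,5200) does not, [2000,2999) does not,
  # [4999,5100) overlaps the last promoter base
  expect_equal(as.numeric(act["gp", "bc1"]), 2)

  # randomised agreement with the brute-force oracle
  set.seed(14)
  frags <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(sample(0:20000, 100, replace = TRUE)),
    barcode = sample(c("b1", "b2", "b3"), 100, replace = TRUE),
    count = 1L
  ) |>
    dplyr::mutate(end = start + as.integer(sample(50:400, 100, replace = TRUE)))
  tss10 <- tibble::tibble(
    gene = sprintf("g%02d", 1:10), chrom = "chr1",
    tss = as.integer(sample(1000:19000, 10)),
    strand = sample(c("+", "-"), 10, replace = TRUE)
  )
  act10 <- gene_activity_scores(frags, tss10)
  oracle <- oracle_gene_activity(frags, tss10)
  expect_identical(as.matrix(act10)[rownames(oracle), colnames(oracle)],
                   matrix(as.double(oracle), nrow(oracle),
                          dimnames = dimnames(oracle)))
})

test_that("module activity differences are exact log2 ratios", {
  act <- matrix(c(10, 10, 20, 20,    # gene m1: control 10, RT 20
                  5, 5, 5, 5),       # gene m2: unchanged
                nrow = 2, byrow = TRUE,
                dimnames = list(c("m1", "m2"), paste0("c", 1:4)))
  assignments <- tibble::tibble(barcode = paste0("c", 1:4), target = "TG")
  conditions <- tibble::tibble(barcode = paste0("c", 1:4),
                               condition = c("0Gy", "0Gy", "RT-frac", "RT-frac"))
  out <- differential_module_activity(act, list(up = "m1", flat = "m2"),
                                      assignments, conditions)
  expect_equal(unname(out$differences["TG", "up"]),
               log2(20.01) - log2(10.01), tolerance = 1e-12)
  expect_equal(unname(out$differences["TG", "flat"]), 0)

  # a target present in only one condition is omitted
  cond_one <- dplyr::mutate(conditions, condition = "0Gy")
  out2 <- differential_module_activity(act, list(up = "m1"),
                                       assignments, cond_one)
  expect_equal(out2$omitted, "TG")
  expect_equal(nrow(out2$differences), 0)
})

test_that("programmed promoter-activity shifts are recovered", {
  cfg <- sim_config(n_genes = 2, n_ntc = 2, cells_per_lane = 150,
                    activity_shift = 1, seed = 5)
  sim <- simulate_multiome(cfg)
  act <- gene_activity_scores(sim$fragments, sim$tss)
  assignments <- dplyr::select(sim$truth$cells, barcode, target)
  conditions <- dplyr::select(sim$truth$cells, barcode, condition)
  dma <- differential_module_activity(act, sim$truth$modules,
                                      assignments, conditions)
  expect_true(all(abs(dma$differences[, "module_A"] - 1) < 0.25))
})

test_that("an all-peaks motif has identically zero deviations", {
  set.seed(9)
  n_peaks <- 60; n_cells <- 30
  counts <- matrix(rpois(n_peaks * n_cells, 2), n_peaks,
                   dimnames = list(sprintf("p%02d", 1:n_peaks),
                                   sprintf("c%02d", 1:n_cells)))
  membership <- matrix(TRUE, n_peaks, 1, dimnames = list(rownames(counts), "ALL"))
  annot <- list(membership = membership,
                gc = setNames(runif(n_peaks, 0.3, 0.7), rownames(counts)))
  dev <- motif_deviation_zscores(counts, annot, n_background = 10, seed = 1)
  expect_true(all(dev$raw == 0))
  expect_true(all(dev$z == 0))
})

test_that("deviation z-scores calibrate on a null simulation", {
  cfg <- sim_config(n_genes = 2, n_ntc = 2, cells_per_lane = 100,
                    n_peaks = 300, seed = 11)
  sim <- simulate_multiome(cfg)
  dev <- motif_deviation_zscores(sim$peak_counts, sim$motif_annotation,
                                 n_background = 50, seed = 3)
  z <- as.vector(dev$z)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.1)
  # determinism of the background sampling
  dev2 <- motif_deviation_zscores(sim$peak_counts, sim$motif_annotation,
                                  n_background = 50, seed = 3)
  expect_identical(dev$z, dev2$z)
})

test_that("motifs without an expressed TF are excluded from differences", {
  set.seed(2)
  z <- matrix(rnorm(3 * 8), nrow = 3,
              dimnames = list(c("M1", "M2", "M3"), paste0("c", 1:8)))
  dev <- structure(list(z = z, raw = z, n_background = 10, seed = 1),
                   class = "deviation_matrix")
  rna <- matrix(c(rep(5, 8), rep(0, 8), rep(5, 8)), nrow = 3, byrow = TRUE,
                dimnames = list(c("TF1", "TF2", "TF3"), paste0("c", 1:8)))
  tf_map <- tibble::tibble(motif = c("M1", "M2", "M3"),
                           tf = c("TF1", "TF2", "TF3"))
  assignments <- tibble::tibble(barcode = paste0("c", 1:8), target = "TG")
  conditions <- tibble::tibble(barcode = paste0("c", 1:8),
                               condition = rep(c("0Gy", "RT-frac"), each = 4))
  out <- differential_motif_deviation(dev, rna, tf_map, assignments, conditions)
  expect_setequal(out$kept_motifs, c("M1", "M3"))
  expect_true("M2" %in% out$excluded_motifs)

  # equal mean z in both conditions gives difference zero
  z_eq <- matrix(rep(c(1, 2, 2, 1, 1, 2, 2, 1), each = 3), nrow = 3,
                 dimnames = dimnames(z))
  dev_eq <- structure(list(z = z_eq, raw = z_eq, n_background = 10, seed = 1),
                      class = "deviation_matrix")
  cond_alt <- tibble::tibble(barcode = paste0("c", 1:8),
                             condition = rep(c("0Gy", "RT-frac"), each = 4))
  out_eq <- differential_motif_deviation(dev_eq, rna, tf_map, assignments,
                                         cond_alt)
  expect_true(all(abs(out_eq$differences) < 1e-12))
})

test_that("logistic-regression DA agrees with the exact test in direction", {
  set.seed(8)
  n <- 100
  counts <- matrix(0, nrow = 3, ncol = 2 * n,
                   dimnames = list(c("same", "up", "bg"),
                                   sprintf("c%03d", 1:(2 * n))))
  counts["same", ] <- rpois(2 * n, 1)
  counts["up", 1:n] <- rbinom(n, 1, 0.9)
  counts["up", (n + 1):(2 * n)] <- rbinom(n, 1, 0.1)
  counts["bg", ] <- rpois(2 * n, 3)
  group_a <- colnames(counts)[1:n]
  group_b <- colnames(counts)[(n + 1):(2 * n)]
  da <- differential_accessibility_lr(counts, group_a, group_b)
  up <- dplyr::filter(da, peak == "up")
  expect_lt(up$p_value, 1e-6)
  expect_gt(up$log2_fc, 1)
  same <- dplyr::filter(da, peak == "same")
  expect_gt(same$p_value, 0.05)
  expect_lt(abs(same$log2_fc), 0.5)
  # direction agreement with Fisher's exact test on the detection table
  tab <- matrix(c(sum(counts["up", 1:n] > 0), n - sum(counts["up", 1:n] > 0),
                  sum(counts["up", (n + 1):(2 * n)] > 0),
                  n - sum(counts["up", (n + 1):(2 * n)] > 0)), 2)
  expect_lt(fisher.test(tab)$p.value, 1e-6)

  # label swap negates the fold change and preserves p
  da_swap <- differential_accessibility_lr(counts, group_b, group_a)
  expect_equal(da_swap$log2_fc, -da$log2_fc, tolerance = 1e-8)
  expect_equal(da_swap$p_value, da$p_value, tolerance = 1e-8)
})

test_that("coverage profiles are flank-normalised and order-invariant", {
  # constant coverage 4 across a wide span
  fr <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L,
                       barcode = "bc1", count = 4L)
  regions <- tibble::tibble(chrom = "chr1", center = c(5000L, 9000L))
  prof <- profile_matrix(fr, regions)
  expect_true(all(prof$normalized == 1))
  expect_true(all(prof$coverage == 4))

  # centre 8, flanks 4: normalised centre value 2
  fr2 <- dplyr::bind_rows(
    fr, tibble::tibble(chrom = "chr1", start = 4900L, end = 5101L,
                       barcode = "bc1", count = 4L)
  )
  prof2 <- profile_matrix(fr2, regions[1, ])
  expect_equal(prof2$normalized[prof2$position == 0], 2)
  expect_equal(prof2$normalized[prof2$position == -1000], 1)

  # brute-force per-base oracle on a 5-fragment toy
  set.seed(6)
  toy <- tibble::tibble(
    chrom = "chr1",
    start = c(4200L, 4800L, 5100L, 4000L, 4950L),
    end = c(4500L, 5200L, 5250L, 6100L, 5050L),
    barcode = c("b1", "b1", "b2", "b2", "b3"),
    count = c(1L, 2L, 1L, 3L, 1L)
  )
  prof_toy <- profile_matrix(toy, regions[1, ], window = 500, flank = 50)
  oracle <- oracle_profile(toy, 5000L, "chr1", 500, 50)
  expect_equal(prof_toy$coverage, oracle$coverage, tolerance = 1e-12)
  expect_equal(prof_toy$normalized, oracle$normalized, tolerance = 1e-12)

  # region order and cell order invariance
  prof_rev <- profile_matrix(fr2, regions[1, ],
                             cells = "bc1")
  expect_equal(prof_rev$normalized, prof2$normalized)
  expect_error(profile_matrix(fr, regions[0, ]), "empty region")
})
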