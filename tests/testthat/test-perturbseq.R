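test_that("single-guide retention applies both gates strictly", {
  # 4 cells: multi-guide, no guide, low features, and a clean one
  counts <- matrix(1L, nrow = 300, ncol = 4,
                   dimnames = list(sprintf("g%03d", 1:300), paste0("c", 1:4)))
  counts[250:300, 3] <- 0L  # cell 3: 249 detected features
  counts[151:300, 2] <- 0L  # cell 2: 150 features
  guides <- matrix(0L, nrow = 2, ncol = 4, dimnames = list(c("A", "B"), NULL))
  guides[, 1] <- c(5L, 2L)  # two guides detected -> removed
  guides[1, 3] <- 3L        # single guide, enough features -> kept
  guides[1, 2] <- 3L        # single guide but 150 features -> removed
  ds <- make_cell_dataset(counts, guides)
  out <- assign_single_guide(ds, min_features = 200)
  expect_equal(out$cells$barcode, "c3")
  expect_equal(out$cells$guide, "A")
  log <- attr(out, "filter_log")
  expect_equal(log$n_cells[log$reason == "low_features"], 1L)
  expect_equal(log$n_cells[log$reason == "multi_or_no_guide"], 2L)

  # boundary: exactly 200 features is not enough (rule is strictly greater)
  counts200 <- matrix(0L, nrow = 300, ncol = 1,
                      dimnames = list(sprintf("g%03d", 1:300), "c1"))
  counts200[1:200, 1] <- 1L
  g1 <- matrix(2L, 1, 1, dimnames = list("A", NULL))
  expect_error(assign_single_guide(make_cell_dataset(counts200, g1),
                                   min_features = 200), "no cells")
})

test_that("knockdown follows the pseudocount ratio within lanes", {
  # gene TG: NTC cells 99 UMIs, target cells 24 UMIs, filler keeps totals equal
  counts <- matrix(0, nrow = 3, ncol = 6,
                   dimnames = list(c("TG", "SILENT", "FILL"), paste0("c", 1:6)))
  counts["TG", ] <- c(24, 24, 24, 99, 99, 99)
  counts["FILL", ] <- 10000 - counts["TG", ]
  guides <- matrix(0, nrow = 2, ncol = 6, dimnames = list(c("sgTG", "sgNTC"), NULL))
  guides["sgTG", 1:3] <- 10; guides["sgNTC", 4:6] <- 10
  ds <- assign_single_guide(make_cell_dataset(counts, guides), min_features = 1)
  lib <- tibble::tibble(vector_id = c("sgTG", "sgNTC"),
                        target_gene = c("TG", "NTC"),
                        is_ntc = c(FALSE, TRUE))
  kd <- quantify_knockdown(ds, lib)
  row <- dplyr::filter(kd, guide == "sgTG")
  # CP10K keeps the raw values: (24 + 0.01) / (99 + 0.01)
  expect_equal(row$remaining, (24 + 0.01) / (99 + 0.01), tolerance = 1e-12)
  expect_equal(row$knockdown, 1 - row$remaining)

  # silent gene in both groups: remaining exactly 1, knockdown 0
  lib2 <- tibble::tibble(vector_id = c("sgTG", "sgNTC"),
                         target_gene = c("SILENT", "NTC"),
                         is_ntc = c(FALSE, TRUE))
  kd2 <- quantify_knockdown(ds, lib2)
  expect_equal(dplyr::filter(kd2, guide == "sgTG")$remaining, 1)
  expect_equal(dplyr::filter(kd2, guide == "sgTG")$knockdown, 0)

  # a lane without NTC cells is an error
  ds_nontc <- subset_cells <- ds
  ds_nontc$cells$guide <- "sgTG"
  expect_error(quantify_knockdown(ds_nontc, lib), "without NTC")
})

test_that("programmed knockdown is recovered from simulated data", {
  cfg <- sim_config(n_genes = 2, n_ntc = 2, cells_per_lane = 1000,
                    knockdown = 0.8, target_gene_mean = 3,
                    n_background_genes = 300, seed = 31)
  sim <- simulate_perturbseq(cfg)
  ds <- assign_single_guide(sim$dataset, min_features = 5)
  kd <- quantify_knockdown(ds, sim$library)
  kd0 <- dplyr::filter(kd, condition == "0Gy", !is.na(knockdown),
                       n_cells >= 200)
  expect_gt(nrow(kd0), 0)
  expect_true(all(abs(kd0$knockdown - 0.8) < 0.05))
})

test_that("perturbation retention applies the strict knockdown and cell rules", {
  kd <- tibble::tibble(
    guide = rep(c("gA", "gB", "gC", "gD"), each = 4),
    target_gene = "x",
    lane = rep(c("L1", "L2", "L3", "L4"), 4),
    condition = rep(c("0Gy", "0Gy", "RT-frac", "RT-hypo"), 4),
    n_cells = c(rep(20, 4),            # gA: plenty of cells
                rep(20, 4),            # gB
                c(20, 20, 9, 20),      # gC: 9 cells in RT-frac
                rep(20, 4)),           # gD
    knockdown = c(0.75, 0.75, 0.9, 0.9,   # gA: exactly 0.75 -> excluded
                  0.80, 0.50, 0.2, 0.2,   # gB: 0.80 in one 0Gy lane -> kept
                  0.95, 0.95, 0.9, 0.9,   # gC: cells rule fails
                  0.60, 0.70, 0.9, 0.9)   # gD: knockdown rule fails
  )
  expect_equal(filter_perturbations(kd), "gB")
  # boundary: exactly 10 cells passes
  kd10 <- dplyr::mutate(kd, n_cells = ifelse(guide == "gC" & n_cells == 9, 10, n_cells))
  expect_setequal(filter_perturbations(kd10), c("gB", "gC"))
})

test_that("marker selection enforces detection, fold change and truncation", {
  set.seed(5)
  n_a <- 40; n_b <- 40
  genes <- c("EXCL", "LOWPCT", sprintf("bg%02d", 1:8))
  counts <- matrix(rpois(10 * 80, 5), nrow = 10,
                   dimnames = list(genes, sprintf("c%02d", 1:80)))
  counts["EXCL", ] <- c(rep(50L, n_a), rep(0L, n_b))     # exclusive to A
  counts["LOWPCT", ] <- 0L
  counts["LOWPCT", 1:8] <- 100L                          # 20% of A cells
  labels <- rep(c("A", "B"), c(n_a, n_b))
  mk <- select_markers(counts, labels, top_k = 10)
  a_mk <- dplyr::filter(mk, cluster == "A")
  expect_equal(a_mk$gene[1], "EXCL")
  expect_false("LOWPCT" %in% a_mk$gene)

  # truncation without padding: fewer qualifying genes than top_k
  mk3 <- select_markers(counts, labels, top_k = 3)
  expect_lte(max(table(mk3$cluster)), 3)
  a_all <- dplyr::filter(select_markers(counts, labels, top_k = 100),
                         cluster == "A")
  expect_equal(nrow(dplyr::filter(select_markers(counts, labels, top_k = 10),
                                  cluster == "A")),
               min(10L, nrow(a_all)))
  expect_error(select_markers(counts, rep("A", 80)), "2 clusters")
})

test_that("module scores are zero at the reference and log2-exact", {
  # target cells have module gene at 2x the NTC level with equal totals
  counts <- matrix(0, nrow = 2, ncol = 8,
                   dimnames = list(c("MOD", "FILL"), paste0("c", 1:8)))
  counts["MOD", ] <- c(rep(200, 4), rep(100, 4))
  counts["FILL", ] <- 10000 - counts["MOD", ]
  guides <- matrix(0, nrow = 2, ncol = 8, dimnames = list(c("sgT", "sgNTC"), NULL))
  guides["sgT", 1:4] <- 10; guides["sgNTC", 5:8] <- 10
  ds <- assign_single_guide(make_cell_dataset(counts, guides), min_features = 1)
  lib <- tibble::tibble(vector_id = c("sgT", "sgNTC"),
                        target_gene = c("TG", "NTC"),
                        is_ntc = c(FALSE, TRUE))
  ms <- score_modules(ds, list(m1 = "MOD"), lib)
  expect_equal(unname(ms$scores["NTC", "m1@0Gy"]), 0)
  expect_equal(unname(ms$scores["TG", "m1@0Gy"]), 1, tolerance = 1e-4)

  long <- tidy(ms)
  expect_setequal(names(long), c("target", "module", "condition", "score"))
  expect_error(score_modules(ds, list(bad = "NOPE"), lib), "bad")
})

test_that("module shifts programmed in simulation are recovered", {
  cfg <- sim_config(n_genes = 2, n_ntc = 2, cells_per_lane = 700,
                    knockdown = 0.8, n_background_genes = 300, seed = 17)
  sim <- simulate_perturbseq(cfg)
  ds <- assign_single_guide(sim$dataset, min_features = 5)
  ms <- score_modules(ds, sim$truth$modules, sim$library)
  shift <- sim$truth$module_shifts
  for (r in seq_len(nrow(shift))) {
    col <- paste(shift$module[r], shift$condition[r], sep = "@")
    for (tg in rownames(ms$scores)) {
      expect_lt(abs(unname(ms$scores[tg, col]) - shift$shift[r]), 0.2)
    }
  }
  # unshifted module/conditions stay near zero
  expect_lt(max(abs(ms$scores[, "module_B@0Gy"])), 0.35)
})

test_that("differential expression gates on both p-value and fold change", {
  set.seed(7)
  n <- 50
  genes <- c("NULLG", "STRONG", "SMALLFC")
  counts <- matrix(0, nrow = 3, ncol = 2 * n,
                   dimnames = list(genes, sprintf("c%03d", 1:(2 * n))))
  counts["NULLG", ] <- rpois(2 * n, 5)
  counts["STRONG", 1:n] <- rpois(n, 10)        # silent in NTC
  counts["STRONG", 1:n][1:(0.1 * n)] <- 0      # ~90% detection in target
  counts["SMALLFC", ] <- c(rpois(n, 17), rpois(n, 10))  # |lfc| < 1
  guides <- matrix(0, nrow = 2, ncol = 2 * n, dimnames = list(c("sgT", "sgNTC"), NULL))
  guides["sgT", 1:n] <- 10; guides["sgNTC", (n + 1):(2 * n)] <- 10
  ds <- assign_single_guide(make_cell_dataset(counts, guides), min_features = 0)
  lib <- tibble::tibble(vector_id = c("sgT", "sgNTC"),
                        target_gene = c("TG", "NTC"),
                        is_ntc = c(FALSE, TRUE))
  de <- differential_expression(ds, "sgT", lib, "0Gy")
  expect_false(de$de[de$gene == "NULLG"])
  expect_true(de$de[de$gene == "STRONG"])
  # detection-component oracle: Fisher exact on the 2x2 detection table
  det_target <- sum(counts["STRONG", 1:n] > 0)
  oracle_p <- fisher.test(matrix(c(det_target, n - det_target, 0, n), 2))$p.value
  expect_equal(de$p_detection[de$gene == "STRONG"], oracle_p, tolerance = 1e-10)
  # fold-change gate: significant but small shift is not DE
  expect_false(de$de[de$gene == "SMALLFC"])

  # symmetry: swapping which group is "target" negates the fold change
  lib_swap <- tibble::tibble(vector_id = c("sgT", "sgNTC"),
                             target_gene = c("NTC", "TG"),
                             is_ntc = c(TRUE, FALSE))
  de_swap <- differential_expression(ds, "sgNTC", lib_swap, "0Gy")
  expect_equal(de_swap$log2_fc, -de$log2_fc, tolerance = 1e-10)
  expect_equal(de_swap$p_detection, de$p_detection, tolerance = 1e-10)

  expect_error(differential_expression(ds, "sgT", lib, "RT-frac"), "cells")
})

test_that("radiotherapy-selective flagging is strict on the excess-DEG rule", {
  de_counts <- tibble::tibble(
    target = rep(c("A", "B", "C"), each = 2),
    condition = rep(c("0Gy", "RT-frac"), 3),
    n_deg = c(20, 61, 20, 60, 30, 10)
  )
  out <- flag_rt_selective(de_counts)
  expect_true(out$flagged[out$target == "A"])    # excess 41 > 40
  expect_false(out$flagged[out$target == "B"])   # excess exactly 40
  expect_false(out$flagged[out$target == "C"])   # negative excess
  # caption variant: at-least rule includes the boundary
  out2 <- flag_rt_selective(de_counts, rule = "at-least")
  expect_true(out2$flagged[out2$target == "B"])
  expect_error(flag_rt_selective(dplyr::filter(de_counts, condition == "0Gy")),
               "missing condition")
})

test_that("cell order does not affect assignments or scores", {
  cfg <- sim_config(n_genes = 2, n_ntc = 2, cells_per_lane = 60, seed = 13)
  sim <- simulate_perturbseq(cfg)
  ds1 <- assign_single_guide(sim$dataset, min_features = 5)
  perm <- sample(ncol(sim$dataset$counts))
  ds_perm <- cell_dataset(
    counts = sim$dataset$counts[, perm],
    guides = sim$dataset$guides[, perm],
    cells = sim$dataset$cells[perm, ]
  )
  ds2 <- assign_single_guide(ds_perm, min_features = 5)
  a1 <- dplyr::arrange(ds1$cells, barcode)
  a2 <- dplyr::arrange(ds2$cells, barcode)
  expect_equal(a1$guide, a2$guide)
  kd1 <- dplyr::arrange(quantify_knockdown(ds1, sim$library), guide, lane)
  kd2 <- dplyr::arrange(quantify_knockdown(ds2, sim$library), guide, lane)
  expect_equal(kd1$knockdown, kd2$knockdown, tolerance = 1e-12)
})
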