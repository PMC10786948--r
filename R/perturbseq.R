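#' Perturb-seq analysis
#'
#' @description
#' Single-cell CRISPRi analysis with guide capture: cells are filtered to a
#' single detected guide, target knockdown is quantified on pseudobulk
#' normalised expression against non-targeting control (NTC) cells within a
#' GEM lane, retained perturbations are scored against gene-expression
#' modules, and differential expression between perturbed and NTC cells uses
#' a two-part hurdle-style test.
#'
#' @name perturbseq-analysis
NULL

#' Retain single-guide cells
#'
#' Keeps cells with strictly more than `min_features` detected genes and
#' exactly one guide with nonzero capture UMIs, and records that guide in the
#' `guide` metadata column. Removal tallies by cause are attached as the
#' `"filter_log"` attribute.
#'
#' @param dataset a [cell_dataset()] with a guide capture matrix.
#' @param min_features minimum detected genes (strict) for a cell to be kept.
#' @return the filtered `cell_dataset` with `guide` and `n_features` columns.
#' @export
assign_single_guide <- function(dataset, min_features = 200) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$guides)) abort("dataset has no guide capture matrix")
  n_features <- Matrix::colSums(dataset$counts > 0)
  n_guides_detected <- Matrix::colSums(dataset$guides > 0)
  keep_features <- n_features > min_features
  keep_single <- n_guides_detected == 1L
  keep <- keep_features & keep_single
  if (!any(keep)) abort("no cells pass single-guide retention")
  guide_idx <- apply(dataset$guides[, keep, drop = FALSE], 2L, which.max)
  out <- subset_cells(dataset, dataset$cells$barcode[keep])
  out$cells$n_features <- n_features[keep]
  out$cells$guide <- rownames(dataset$guides)[guide_idx]
  attr(out, "filter_log") <- tibble(
    reason = c("low_features", "multi_or_no_guide"),
    n_cells = c(sum(!keep_features), sum(keep_features & !keep_single))
  )
  out
}

#' Quantify target knockdown from pseudobulk expression
#'
#' Library-normalises each cell (counts per 10,000), averages each gene over
#' the cells carrying a given guide within a GEM lane (pseudobulk), and
#' computes the RNA remaining for each guide's target as
#' `(on-target pseudobulk + pseudocount) / (NTC pseudobulk + pseudocount)`
#' within the same lane. Knockdown is `1 - remaining`.
#'
#' @param dataset a `cell_dataset` with assigned `guide` metadata (see
#'   [assign_single_guide()]).
#' @param library guide library tibble (`vector_id`, `target_gene`, `is_ntc`)
#'   where `vector_id` matches the guide names.
#' @param pseudocount added to both pseudobulk terms (default 0.01).
#' @return tibble with one row per (guide, lane): `guide`, `target_gene`,
#'   `lane`, `condition`, `n_cells`, `pseudobulk`, `ntc_pseudobulk`,
#'   `remaining`, `knockdown`.
#' @export
quantify_knockdown <- function(dataset, library, pseudocount = 0.01) {
  stopifnot(inherits(dataset, "cell_dataset"))
  library <- validate_guide_library(library)
  if (!"guide" %in% names(dataset$cells)) {
    abort("cells lack guide assignments; run assign_single_guide() first")
  }
  norm <- normalize_cells(dataset$counts)
  cells <- dataset$cells
  lanes <- unique(cells$lane)

  ntc_guides <- library$vector_id[library$is_ntc]
  rows <- list()
  for (ln in lanes) {
    in_lane <- cells$lane == ln
    ntc_cells <- which(in_lane & cells$guide %in% ntc_guides)
    if (length(ntc_cells) == 0L) {
      abort(paste0("lane without NTC cells: ", ln))
    }
    ntc_pb <- Matrix::rowMeans(norm[, ntc_cells, drop = FALSE])
    for (g in unique(cells$guide[in_lane])) {
      tg <- library$target_gene[library$vector_id == g]
      if (length(tg) == 0L) next
      is_ntc_g <- library$is_ntc[library$vector_id == g]
      g_cells <- which(in_lane & cells$guide == g)
      on_pb <- if (!is_ntc_g && tg %in% rownames(norm)) {
        mean(norm[tg, g_cells])
      } else {
        NA_real_
      }
      ntc_val <- if (!is_ntc_g && tg %in% rownames(norm)) ntc_pb[[tg]] else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        guide = g, target_gene = tg, lane = ln,
        condition = cells$condition[which(in_lane)[1]],
        n_cells = length(g_cells),
        pseudobulk = on_pb, ntc_pseudobulk = ntc_val
      )
    }
  }
  list_rbind(rows) |>
    mutate(
      remaining = (.data$pseudobulk + pseudocount) / (.data$ntc_pseudobulk + pseudocount),
      knockdown = 1 - .data$remaining
    )
}

#' Retain perturbations by knockdown strength and representation
#'
#' A guide is retained when its knockdown is strictly greater than `min_kd`
#' in at least one of the untreated (0Gy) lanes and it is represented by at
#' least `min_cells` cells in every condition.
#'
#' @param kd knockdown tibble from [quantify_knockdown()].
#' @param min_kd knockdown threshold (strict; default 0.75).
#' @param min_cells minimum cells per condition (inclusive; default 10).
#' @return character vector of retained guide ids (possibly empty).
#' @export
filter_perturbations <- function(kd, min_kd = 0.75, min_cells = 10) {
  need <- c("guide", "lane", "condition", "n_cells", "knockdown")
  missing <- setdiff(need, names(kd))
  if (length(missing) > 0L) {
    abort(paste0("knockdown table missing columns: ", paste(missing, collapse = ", ")))
  }
  conditions <- unique(kd$condition)
  pass <- kd |>
    group_by(.data$guide) |>
    summarise(
      kd_ok = any(.data$knockdown > min_kd & .data$condition == "0Gy", na.rm = TRUE),
      .groups = "drop"
    )
  cells_ok <- kd |>
    group_by(.data$guide, .data$condition) |>
    summarise(n_cells = sum(.data$n_cells), .groups = "drop") |>
    group_by(.data$guide) |>
    summarise(
      cells_ok = dplyr::n() == length(conditions) & all(.data$n_cells >= min_cells),
      .groups = "drop"
    )
  res <- inner_join(pass, cells_ok, by = "guide") |>
    filter(.data$kd_ok, .data$cells_ok)
  sort(res$guide)
}

#' Select cluster marker genes
#'
#' Per cluster, candidate markers are genes detected in at least `min_pct` of
#' in-cluster cells whose log2 mean fold change versus all other cells
#' exceeds `log2(1 + min_fc)`. The `top_k` most specific markers (largest
#' fold change; ties broken by detection-rate difference, then gene id) are
#' kept.
#'
#' @param dataset a `cell_dataset` (or genes x cells matrix).
#' @param cluster_labels per-cell cluster labels aligned with the cells.
#' @param min_pct minimum in-cluster detection fraction (default 0.25).
#' @param min_fc minimum fold-change excess (default 0.25, i.e. >25% higher).
#' @param top_k markers kept per cluster (default 10).
#' @param pseudocount added to both means before the ratio.
#' @return tibble with `cluster`, `gene`, `log2_fc`, `pct_in`, `pct_out`,
#'   `rank`; use [modules_from_markers()] to turn it into a module list.
#' @export
select_markers <- function(dataset, cluster_labels, min_pct = 0.25,
                           min_fc = 0.25, top_k = 10, pseudocount = 0.01) {
  m <- if (inherits(dataset, "cell_dataset")) dataset$counts else dataset
  if (length(cluster_labels) != ncol(m)) {
    abort("cluster_labels must have one label per cell")
  }
  clusters <- sort(unique(as.character(cluster_labels)))
  if (length(clusters) < 2L) abort("select_markers needs >= 2 clusters")
  norm <- normalize_cells(m)
  lfc_min <- log2(1 + min_fc)
  out <- list()
  for (cl in clusters) {
    in_cl <- cluster_labels == cl
    if (sum(in_cl) < 2L) next
    mean_in <- Matrix::rowMeans(norm[, in_cl, drop = FALSE])
    mean_out <- Matrix::rowMeans(norm[, !in_cl, drop = FALSE])
    pct_in <- Matrix::rowMeans(m[, in_cl, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(m[, !in_cl, drop = FALSE] > 0)
    lfc <- log2(mean_in + pseudocount) - log2(mean_out + pseudocount)
    keep <- pct_in >= min_pct & lfc > lfc_min
    if (!any(keep)) next
    tab <- tibble(
      cluster = cl, gene = rownames(m)[keep],
      log2_fc = lfc[keep], pct_in = pct_in[keep], pct_out = pct_out[keep]
    ) |>
      arrange(desc(.data$log2_fc), desc(.data$pct_in - .data$pct_out), .data$gene) |>
      slice_head(n = top_k) |>
      mutate(rank = row_number())
    out[[cl]] <- tab
  }
  list_rbind(out)
}

#' Convert a marker table to a named module list
#'
#' @param markers tibble from [select_markers()] (or with `cluster`/`gene`
#'   columns from any source).
#' @return named list of gene vectors, one per cluster.
#' @export
modules_from_markers <- function(markers) {
  split(markers$gene, markers$cluster)
}

#' Score module expression per perturbation and condition
#'
#' For every (perturbation target, module, condition), computes
#' `log2((mean pseudobulk expression of the module's markers in the target's
#' cells in that condition + c) / (same for NTC cells at 0Gy + c))`, with
#' `c = 0.01`. The NTC/0Gy reference column is therefore exactly zero. Rows
#' (perturbations) and columns (module x condition) are ordered by
#' complete-linkage hierarchical clustering on 1 - Pearson correlation.
#'
#' @param dataset a `cell_dataset` with `guide` assignments.
#' @param modules named list of marker gene sets.
#' @param library guide library tibble mapping guides to targets and the NTC
#'   flag.
#' @param guides optional subset of guides to score (e.g. from
#'   [filter_perturbations()]); defaults to all assigned guides.
#' @param pseudocount ratio guard, default 0.01.
#' @return a `module_scores` object: list with `scores` (targets x
#'   module/condition matrix, including the `NTC` row), `row_order`,
#'   `col_order`, `reference` (the NTC/0Gy column name).
#' @export
score_modules <- function(dataset, modules, library, guides = NULL,
                          pseudocount = 0.01) {
  stopifnot(inherits(dataset, "cell_dataset"))
  library <- validate_guide_library(library)
  if (!"guide" %in% names(dataset$cells)) {
    abort("cells lack guide assignments; run assign_single_guide() first")
  }
  for (mn in names(modules)) {
    if (!any(modules[[mn]] %in% rownames(dataset$counts))) {
      abort(paste0("module with no genes in the matrix: ", mn))
    }
  }
  norm <- normalize_cells(dataset$counts)
  cells <- dataset$cells
  target_of <- setNames(library$target_gene, library$vector_id)
  cells$target <- if_else(
    cells$guide %in% library$vector_id[library$is_ntc],
    "NTC", unname(target_of[cells$guide])
  )
  if (!is.null(guides)) {
    keep <- cells$guide %in% guides | cells$target == "NTC"
    cells <- cells[keep, , drop = FALSE]
    norm <- norm[, cells$barcode, drop = FALSE]
  }
  if (!any(cells$target == "NTC" & cells$condition == "0Gy")) {
    abort("no NTC cells in the 0Gy condition; reference undefined")
  }
  conditions <- unique(cells$condition)
  targets <- sort(unique(cells$target))
  targets <- c(setdiff(targets, "NTC"), "NTC")

  module_means <- function(cell_idx) {
    map_dbl(modules, function(genes) {
      genes <- intersect(genes, rownames(norm))
      mean(Matrix::rowMeans(norm[genes, cell_idx, drop = FALSE]))
    })
  }
  ref <- module_means(which(cells$target == "NTC" & cells$condition == "0Gy"))

  cols <- tidyr::expand_grid(module = names(modules), condition = conditions)
  scores <- matrix(
    NA_real_, nrow = length(targets), ncol = nrow(cols),
    dimnames = list(targets, paste(cols$module, cols$condition, sep = "@"))
  )
  for (tg in targets) {
    for (cond in conditions) {
      idx <- which(cells$target == tg & cells$condition == cond)
      if (length(idx) == 0L) next
      mm <- module_means(idx)
      scores[tg, paste(names(modules), cond, sep = "@")] <-
        log2(mm + pseudocount) - log2(ref[names(modules)] + pseudocount)
    }
  }
  structure(
    list(
      scores = scores,
      row_order = pearson_hclust_order(scores),
      col_order = pearson_hclust_order(Matrix::t(scores)),
      reference = paste(names(modules), "0Gy", sep = "@"),
      modules = modules
    ),
    class = "module_scores"
  )
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("<module_scores> %d targets x %d module/condition columns\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Tidy a module score matrix into long format
#'
#' @param x a `module_scores` object from [score_modules()].
#' @param ... unused.
#' @return tibble with `target`, `module`, `condition`, `score`.
#' @exportS3Method generics::tidy
tidy.module_scores <- function(x, ...) {
  as_tibble(as.table(x$scores), .name_repair = "minimal") |>
    setNames(c("target", "key", "score")) |>
    tidyr::separate_wider_delim("key", "@", names = c("module", "condition")) |>
    as_tibble()
}

#' Hurdle-style differential expression between perturbed and NTC cells
#'
#' For each gene, combines (via Fisher's method) a detection-rate component
#' (two-sided Fisher exact test on the 2x2 detected/not x group table) with a
#' Wilcoxon rank-sum component on normalised expression in cells where the
#' gene is detected in either group. A gene is differentially expressed when
#' `p < alpha` and `|log2 fold change| > lfc_min` (both strict). A plain
#' rank-sum test over all cells is available with `method = "wilcox"`.
#'
#' @param dataset a `cell_dataset` with `guide` assignments.
#' @param target guide (or target gene) whose cells form the test group.
#' @param library guide library tibble.
#' @param condition condition to test within (both 0Gy lanes are pooled).
#' @param alpha significance level (default 0.05).
#' @param lfc_min absolute log2 fold-change gate (default 1).
#' @param method `"hurdle"` (default) or `"wilcox"`.
#' @param pseudocount fold-change guard, default 0.01.
#' @param min_cells minimum cells per side (default 3).
#' @return tibble with `gene`, `log2_fc`, `p_detection`, `p_level`,
#'   `p_value`, `de` (logical).
#' @export
differential_expression <- function(dataset, target, library, condition,
                                    alpha = 0.05, lfc_min = 1,
                                    method = c("hurdle", "wilcox"),
                                    pseudocount = 0.01, min_cells = 3) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "cell_dataset"))
  library <- validate_guide_library(library)
  cells <- dataset$cells
  ntc_guides <- library$vector_id[library$is_ntc]
  target_guides <- if (target %in% library$vector_id) {
    target
  } else {
    library$vector_id[library$target_gene == target & !library$is_ntc]
  }
  in_cond <- cells$condition == condition
  grp_a <- which(in_cond & cells$guide %in% target_guides)
  grp_b <- which(in_cond & cells$guide %in% ntc_guides)
  if (length(grp_a) < min_cells || length(grp_b) < min_cells) {
    abort(sprintf("need >= %d cells per side (have %d vs %d)",
                  min_cells, length(grp_a), length(grp_b)))
  }
  norm <- normalize_cells(dataset$counts)
  a <- norm[, grp_a, drop = FALSE]
  b <- norm[, grp_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  det_a <- Matrix::rowSums(a > 0)
  det_b <- Matrix::rowSums(b > 0)
  mean_a <- Matrix::rowMeans(a)
  mean_b <- Matrix::rowMeans(b)
  genes <- rownames(norm)

  p_det <- rep(NA_real_, length(genes))
  p_lvl <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    if (det_a[i] + det_b[i] == 0L) next
    if (method == "wilcox") {
      p_lvl[i] <- suppressWarnings(
        wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value
      )
      next
    }
    tab <- matrix(c(det_a[i], na - det_a[i], det_b[i], nb - det_b[i]), 2L)
    p_det[i] <- fisher.test(tab)$p.value
    xa <- a[i, ][a[i, ] > 0]
    xb <- b[i, ][b[i, ] > 0]
    if (length(xa) >= 2L && length(xb) >= 2L) {
      p_lvl[i] <- suppressWarnings(
        wilcox.test(xa, xb, exact = FALSE)$p.value
      )
    }
  }
  p <- if (method == "wilcox") {
    p_lvl
  } else {
    vapply(seq_along(genes), function(i) fisher_combine(c(p_det[i], p_lvl[i])),
           numeric(1))
  }
  tibble(
    gene = genes,
    log2_fc = log2(mean_a + pseudocount) - log2(mean_b + pseudocount),
    p_detection = p_det,
    p_level = p_lvl,
    p_value = p
  ) |>
    mutate(de = !is.na(.data$p_value) & .data$p_value < alpha &
             abs(.data$log2_fc) > lfc_min)
}

#' Flag radiotherapy-selective perturbations
#'
#' Flags targets with strictly more than `excess_min` excess differentially
#' expressed genes in the fractionated radiotherapy condition compared to the
#' untreated condition. The caption variant (flag at `excess >= excess_min`)
#' is available with `rule = "at-least"`.
#'
#' @param de_counts tibble with `target`, `condition`, `n_deg`.
#' @param excess_min excess DEG threshold (default 40).
#' @param rt_condition,control_condition condition labels to compare.
#' @param rule `"more-than"` (strict, default) or `"at-least"`.
#' @return tibble with `target`, `n_deg_rt`, `n_deg_control`, `excess`,
#'   `flagged`.
#' @export
flag_rt_selective <- function(de_counts, excess_min = 40,
                              rt_condition = "RT-frac",
                              control_condition = "0Gy",
                              rule = c("more-than", "at-least")) {
  rule <- match.arg(rule)
  need <- c("target", "condition", "n_deg")
  missing <- setdiff(need, names(de_counts))
  if (length(missing) > 0L) {
    abort(paste0("de_counts missing columns: ", paste(missing, collapse = ", ")))
  }
  for (cond in c(rt_condition, control_condition)) {
    if (!cond %in% de_counts$condition) {
      abort(paste0("missing condition in de_counts: ", cond))
    }
  }
  wide <- de_counts |>
    filter(.data$condition %in% c(rt_condition, control_condition)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n_deg")
  if (anyNA(wide[[rt_condition]]) || anyNA(wide[[control_condition]])) {
    abort("every target needs DEG counts in both conditions")
  }
  wide |>
    mutate(
      n_deg_rt = .data[[rt_condition]],
      n_deg_control = .data[[control_condition]],
      excess = .data$n_deg_rt - .data$n_deg_control,
      flagged = if (rule == "more-than") {
        .data$excess > excess_min
      } else {
        .data$excess >= excess_min
      }
    ) |>
    select("target", "n_deg_rt", "n_deg_control", "excess", "flagged")
}
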