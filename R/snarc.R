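#' Single-nuclei multiome perturbation analysis
#'
#' @description
#' Analysis of joint single-nuclei ATAC + RNA + CRISPRi perturbation data:
#' hypergeometric guide assignment from capture UMIs, fragment-level quality
#' control (ATAC/RNA UMI bounds, nucleosome signal, TSS enrichment), promoter
#' gene-activity scores, differential module activity between radiotherapy
#' and control conditions, background-matched motif-deviation z-scores,
#' logistic-regression differential accessibility, and flank-normalised
#' average coverage profiles.
#'
#' Fragment records use 0-based half-open coordinates (`start < end`); the
#' `count` column carries the per-fragment duplicate count and weights
#' coverage computations, while per-cell ATAC UMI totals count unique
#' fragment records.
#'
#' @name snarc-analysis
NULL

#' Hypergeometric guide assignment
#'
#' Per cell: guides with fewer than `min_guide_umi` UMIs are dropped; for
#' each surviving guide with `k` UMIs in a cell with `n` surviving UMIs, the
#' upper-tail hypergeometric probability of drawing at least `k` of that
#' guide's UMIs when drawing `n` from the dataset-wide pool (`K` = guide
#' total, `N` = all guide UMIs) is computed and Benjamini-Hochberg corrected
#' across the cell's surviving guides. The cell is assigned its majority
#' guide when the adjusted p-value is below `alpha`, the log2-odds ratio
#' between the two highest counts (`log2((top+1)/(second+1))`) exceeds
#' `min_lor`, and the total surviving UMIs exceed `min_total_umi`.
#'
#' @param capture guides x cells UMI matrix (sparse or dense) with guide
#'   rownames.
#' @param min_guide_umi per-guide UMI floor; guides below it are dropped
#'   before testing (default 6).
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param min_lor log2-odds ratio threshold, strict (default 1).
#' @param min_total_umi total surviving UMIs per cell, strict (default 6).
#' @return tibble with `barcode`, `guide` (NA when unassigned), `p_adj`,
#'   `log2_odds`, `n_umi`, `assigned`.
#' @export
assign_guides_hypergeom <- function(capture, min_guide_umi = 6, alpha = 0.05,
                                    min_lor = 1, min_total_umi = 6) {
  if (length(capture) == 0L || nrow(capture) == 0L || ncol(capture) == 0L) {
    abort("empty guide capture matrix")
  }
  m <- as.matrix(capture)
  m[m < min_guide_umi] <- 0
  totals_guide <- Matrix::rowSums(m)
  n_pool <- sum(totals_guide)
  barcodes <- colnames(capture) %||% as.character(seq_len(ncol(capture)))
  out <- vector("list", ncol(m))
  for (c_idx in seq_len(ncol(m))) {
    k <- m[, c_idx]
    surv <- which(k > 0)
    n_cell <- sum(k)
    if (length(surv) == 0L || n_pool == 0) {
      out[[c_idx]] <- tibble(barcode = barcodes[c_idx], guide = NA_character_,
                             p_adj = NA_real_, log2_odds = NA_real_,
                             n_umi = n_cell, assigned = FALSE)
      next
    }
    p <- vapply(surv, function(g) {
      phyper(k[g] - 1, totals_guide[g], n_pool - totals_guide[g], n_cell,
             lower.tail = FALSE)
    }, numeric(1))
    p_adj <- p.adjust(p, method = "BH")
    ord <- order(k[surv], decreasing = TRUE)
    top <- surv[ord[1]]
    second_count <- if (length(surv) > 1L) k[surv[ord[2]]] else 0
    lor <- unname(log2((k[top] + 1) / (second_count + 1)))
    p_top <- unname(p_adj[ord[1]])
    assigned <- p_top < alpha && lor > min_lor && n_cell > min_total_umi
    out[[c_idx]] <- tibble(
      barcode = barcodes[c_idx],
      guide = if (assigned) rownames(m)[top] else NA_character_,
      p_adj = p_top, log2_odds = lor, n_umi = n_cell,
      assigned = assigned
    )
  }
  list_rbind(out)
}

# strand-oriented per-base coverage around positions, aggregated over TSSs;
# returns a (2*window+1) coverage vector for one cell's fragments
relative_coverage <- function(starts, ends, weights, tss, strand, window) {
  cov <- numeric(2L * window + 1L)
  for (t_idx in seq_along(tss)) {
    lo <- tss[t_idx] - window
    hi <- tss[t_idx] + window
    in_win <- which(starts <= hi & ends > lo)
    for (f in in_win) {
      a <- max(starts[f], lo) - lo + 1L
      b <- min(ends[f] - 1L, hi) - lo + 1L
      if (b >= a) cov[a:b] <- cov[a:b] + weights[f]
    }
  }
  # orient so that upstream flank comes first for - strand TSSs too
  if (all(strand == "-")) rev(cov) else cov
}

#' Per-cell fragment QC metrics
#'
#' Computes, per barcode: the ATAC UMI count (number of fragment records);
#' the RNA UMI count (from `rna`); the nucleosome signal — fragments with
#' length in [147, 294] divided by fragments with length < 147 (fragments
#' longer than 294 bp are ignored by the ratio; zero nucleosome-free
#' fragments give `Inf`, which fails the filter); and the TSS enrichment —
#' mean per-base coverage in TSS +/- 50 bp divided by the mean coverage in
#' the two 100-bp outer flanks of a +/- 1000 bp window, averaged over TSSs,
#' strand-oriented. Cells without fragments get `NA` metrics and fail QC.
#'
#' @param fragments fragment tibble (`chrom`, `start`, `end`, `barcode`,
#'   `count`), 0-based half-open.
#' @param rna named per-barcode RNA UMI totals, a tibble with
#'   `barcode`/`rna_umi` columns, or a `cell_dataset`.
#' @param tss TSS tibble (`gene`, `chrom`, `tss`, `strand`).
#' @param window,center_halfwidth,flank TSS-enrichment geometry (bp).
#' @return tibble with `barcode`, `atac_umi`, `rna_umi`,
#'   `nucleosome_signal`, `tss_enrichment`.
#' @export
fragment_qc_metrics <- function(fragments, rna, tss, window = 1000,
                                center_halfwidth = 50, flank = 100) {
  validate_fragments(fragments)
  rna_umi <- if (inherits(rna, "cell_dataset")) {
    setNames(Matrix::colSums(rna$counts), colnames(rna$counts))
  } else if (is.data.frame(rna)) {
    setNames(rna$rna_umi, rna$barcode)
  } else {
    rna
  }
  barcodes <- sort(unique(c(fragments$barcode, names(rna_umi))))
  lens <- fragments$end - fragments$start
  frag_split <- split(seq_len(nrow(fragments)), fragments$barcode)

  n_pos <- 2L * window + 1L
  center_idx <- (window + 1L - center_halfwidth):(window + 1L + center_halfwidth)
  flank_idx <- c(seq_len(flank), (n_pos - flank + 1L):n_pos)

  rows <- map(barcodes, function(bc) {
    idx <- frag_split[[bc]]
    if (is.null(idx)) {
      return(tibble(barcode = bc, atac_umi = 0L, rna_umi = rna_umi[bc] %||% NA_real_,
                    nucleosome_signal = NA_real_, tss_enrichment = NA_real_))
    }
    l <- lens[idx]
    n_free <- sum(l < 147)
    n_mono <- sum(l >= 147 & l <= 294)
    ns <- if (n_free == 0L) {
      if (n_mono == 0L) NA_real_ else Inf
    } else {
      n_mono / n_free
    }
    cov <- numeric(n_pos)
    for (ch in unique(tss$chrom)) {
      on_ch <- idx[fragments$chrom[idx] == ch]
      if (length(on_ch) == 0L) next
      for (strand in c("+", "-")) {
        sel <- tss$chrom == ch & tss$strand == strand
        if (!any(sel)) next
        cov <- cov + relative_coverage(
          fragments$start[on_ch], fragments$end[on_ch],
          fragments$count[on_ch], tss$tss[sel], strand, window
        )
      }
    }
    flank_mean <- mean(cov[flank_idx])
    tss_enr <- if (flank_mean == 0) {
      if (mean(cov[center_idx]) == 0) NA_real_ else Inf
    } else {
      mean(cov[center_idx]) / flank_mean
    }
    tibble(barcode = bc, atac_umi = length(idx),
           rna_umi = unname(rna_umi[bc]) %||% NA_real_,
           nucleosome_signal = ns, tss_enrichment = tss_enr)
  })
  list_rbind(rows)
}

#' Apply multiome QC bounds
#'
#' Retains cells with ATAC UMI strictly between `atac_bounds`, RNA UMI
#' strictly between `rna_bounds`, nucleosome signal strictly below
#' `max_nucleosome_signal` and TSS enrichment strictly above
#' `min_tss_enrichment`. Cells with undefined (NA) metrics fail. Per-criterion
#' removal tallies are attached as the `"filter_log"` attribute.
#'
#' @param qc QC tibble from [fragment_qc_metrics()].
#' @param atac_bounds,rna_bounds exclusive (lower, upper) UMI bounds.
#' @param max_nucleosome_signal strict upper bound (default 4).
#' @param min_tss_enrichment strict lower bound (default 1).
#' @return character vector of retained barcodes, with a `filter_log`
#'   attribute.
#' @export
apply_qc_filter <- function(qc, atac_bounds = c(1000, 100000),
                            rna_bounds = c(50, 25000),
                            max_nucleosome_signal = 4,
                            min_tss_enrichment = 1) {
  ok_atac <- !is.na(qc$atac_umi) &
    qc$atac_umi > atac_bounds[1] & qc$atac_umi < atac_bounds[2]
  ok_rna <- !is.na(qc$rna_umi) &
    qc$rna_umi > rna_bounds[1] & qc$rna_umi < rna_bounds[2]
  ok_ns <- !is.na(qc$nucleosome_signal) &
    qc$nucleosome_signal < max_nucleosome_signal
  ok_tss <- !is.na(qc$tss_enrichment) &
    qc$tss_enrichment > min_tss_enrichment
  keep <- ok_atac & ok_rna & ok_ns & ok_tss
  out <- qc$barcode[keep]
  attr(out, "filter_log") <- tibble(
    criterion = c("atac_umi", "rna_umi", "nucleosome_signal", "tss_enrichment"),
    n_failed = c(sum(!ok_atac), sum(!ok_rna), sum(!ok_ns), sum(!ok_tss))
  )
  out
}

#' Promoter gene-activity scores from ATAC fragments
#'
#' Counts, per gene and cell, the fragments overlapping the gene's promoter:
#' the 2000 bp upstream of the TSS (`[TSS-2000, TSS)` for `+` strand genes,
#' `(TSS, TSS+2000]` for `-` strand genes; half-open intervals, overlap =
#' any shared base).
#'
#' @param fragments fragment tibble, 0-based half-open.
#' @param tss TSS tibble (`gene`, `chrom`, `tss`, `strand`); genes with an
#'   unknown strand are dropped with a warning.
#' @param upstream promoter length in bp (default 2000).
#' @return sparse genes x cells matrix of fragment counts.
#' @export
gene_activity_scores <- function(fragments, tss, upstream = 2000) {
  validate_fragments(fragments)
  bad <- !tss$strand %in% c("+", "-")
  if (any(bad)) {
    warn(paste0("dropping genes with unknown strand: ",
                paste(tss$gene[bad], collapse = ", ")))
    tss <- tss[!bad, , drop = FALSE]
  }
  barcodes <- sort(unique(fragments$barcode))
  genes <- tss$gene
  win_start <- ifelse(tss$strand == "+", tss$tss - upstream, tss$tss + 1L)
  win_end <- ifelse(tss$strand == "+", tss$tss, tss$tss + upstream + 1L)
  bc_idx <- match(fragments$barcode, barcodes)
  i <- integer(); j <- integer(); x <- integer()
  for (g in seq_along(genes)) {
    hits <- which(
      fragments$chrom == tss$chrom[g] &
        fragments$start < win_end[g] &
        fragments$end > win_start[g]
    )
    if (length(hits) == 0L) next
    tab <- table(bc_idx[hits])
    i <- c(i, rep(g, length(tab)))
    j <- c(j, as.integer(names(tab)))
    x <- c(x, as.integer(tab))
  }
  sparseMatrix(i = i, j = j, x = x,
               dims = c(length(genes), length(barcodes)),
               dimnames = list(genes, barcodes))
}

#' Differential module activity between radiotherapy and control
#'
#' Pseudobulks gene activity by perturbation target (pooling the target's
#' guides) within each condition and computes, per module,
#' `log2(pseudobulk mean of the module's genes in RT + c) - log2(same at
#' 0Gy + c)` with `c = 0.01`. Targets are ordered by complete-linkage
#' clustering on 1 - Pearson correlation.
#'
#' @param activity genes x cells activity matrix (from
#'   [gene_activity_scores()]).
#' @param modules named list of gene sets.
#' @param assignments tibble with `barcode` and `target` (target gene per
#'   cell; `"NTC"` for controls).
#' @param conditions tibble with `barcode` and `condition`.
#' @param rt_condition,control_condition condition labels.
#' @param pseudocount ratio guard, default 0.01.
#' @return list with `differences` (targets x modules matrix), `row_order`,
#'   and `omitted` (targets present in only one condition).
#' @export
differential_module_activity <- function(activity, modules, assignments,
                                         conditions,
                                         rt_condition = "RT-frac",
                                         control_condition = "0Gy",
                                         pseudocount = 0.01) {
  meta <- inner_join(assignments, conditions, by = "barcode") |>
    filter(!is.na(.data$target), .data$barcode %in% colnames(activity))
  targets <- sort(unique(meta$target))
  ok <- map_lgl(targets, function(tg) {
    conds <- meta$condition[meta$target == tg]
    all(c(rt_condition, control_condition) %in% conds)
  })
  omitted <- targets[!ok]
  targets <- targets[ok]
  diffs <- matrix(NA_real_, length(targets), length(modules),
                  dimnames = list(targets, names(modules)))
  for (tg in targets) {
    for (mn in names(modules)) {
      genes <- intersect(modules[[mn]], rownames(activity))
      if (length(genes) == 0L) abort(paste0("module with no genes in matrix: ", mn))
      pb <- function(cond) {
        bcs <- meta$barcode[meta$target == tg & meta$condition == cond]
        mean(Matrix::rowMeans(activity[genes, bcs, drop = FALSE]))
      }
      diffs[tg, mn] <- log2(pb(rt_condition) + pseudocount) -
        log2(pb(control_condition) + pseudocount)
    }
  }
  list(differences = diffs, row_order = pearson_hclust_order(diffs),
       omitted = omitted)
}

#' Background-matched motif-deviation z-scores
#'
#' chromVAR-style accessibility deviations: for motif `m` and cell `c`, the
#' expected count is `total_c * (sum of m's peak totals / grand total)` and
#' the raw deviation is `(observed - expected) / expected`. For each motif,
#' `n_background` background peak sets are drawn (with replacement) matching
#' the member peaks on GC-content and log mean-accessibility bins, and the
#' z-score is `(raw - mean(background raws)) / sd(background raws)` per
#' cell. A motif whose raw deviations are exactly zero for every cell
#' (observed equals expected by construction, e.g. a motif annotating all
#' peaks) gets z identically zero.
#'
#' @param peak_counts peaks x cells count matrix.
#' @param motif_annotation list with `membership` (peaks x motifs logical
#'   matrix) and `gc` (named per-peak GC fraction); see
#'   [simulate_multiome()] or [read_motif_map()].
#' @param n_background background sets per motif (default 50).
#' @param n_bins GC and accessibility bins for matching (default 10 each).
#' @param seed RNG seed recorded in the output.
#' @return a `deviation_matrix` object: list with `z` (motifs x cells),
#'   `raw` (motifs x cells), `n_background`, `seed`.
#' @export
motif_deviation_zscores <- function(peak_counts, motif_annotation,
                                    n_background = 50, n_bins = 10,
                                    seed = 1L) {
  membership <- motif_annotation$membership
  gc <- motif_annotation$gc[rownames(membership)]
  if (!identical(rownames(membership), rownames(peak_counts))) {
    peak_counts <- peak_counts[rownames(membership), , drop = FALSE]
  }
  if (any(Matrix::colSums(membership) == 0)) abort("motif with no member peaks")
  set.seed(seed)
  totals_cell <- Matrix::colSums(peak_counts)
  totals_peak <- Matrix::rowSums(peak_counts)
  grand <- sum(totals_peak)
  frac_peak <- totals_peak / grand

  bin_of <- function(x, n) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n + 1), names = FALSE))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  acc_bin <- bin_of(log1p(totals_peak / max(1, ncol(peak_counts))), n_bins)
  gc_bin <- bin_of(gc, n_bins)
  bin_id <- paste(gc_bin, acc_bin, sep = "_")
  bin_members <- split(seq_len(nrow(peak_counts)), bin_id)

  raw_dev <- function(peak_idx) {
    obs <- Matrix::colSums(peak_counts[peak_idx, , drop = FALSE])
    expd <- totals_cell * sum(frac_peak[peak_idx])
    as.numeric((obs - expd) / pmax(expd, .Machine$double.eps))
  }

  motifs <- colnames(membership)
  z <- matrix(NA_real_, length(motifs), ncol(peak_counts),
              dimnames = list(motifs, colnames(peak_counts)))
  raw <- z
  for (m in motifs) {
    members <- which(membership[, m])
    r <- raw_dev(members)
    raw[m, ] <- r
    if (all(r == 0)) {
      z[m, ] <- 0
      next
    }
    member_bins <- bin_id[members]
    bg <- matrix(NA_real_, n_background, ncol(peak_counts))
    for (b in seq_len(n_background)) {
      sampled <- vapply(member_bins, function(bi) {
        pool <- bin_members[[bi]]
        if (length(pool) == 0L) {
          abort(paste0("background bin exhausted for motif ", m))
        }
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      bg[b, ] <- raw_dev(sampled)
    }
    mu <- colMeans(bg)
    sdev <- apply(bg, 2L, sd)
    sdev[sdev == 0] <- NA_real_
    z[m, ] <- (r - mu) / sdev
  }
  structure(
    list(z = z, raw = raw, n_background = n_background, seed = seed),
    class = "deviation_matrix"
  )
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat(sprintf("<deviation_matrix> %d motifs x %d cells (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_background))
  invisible(x)
}

#' Tidy a motif deviation matrix
#'
#' @param x a `deviation_matrix` from [motif_deviation_zscores()].
#' @param ... unused.
#' @return tibble with `motif`, `barcode`, `raw_deviation`, `z`.
#' @exportS3Method generics::tidy
tidy.deviation_matrix <- function(x, ...) {
  long_z <- as_tibble(as.table(x$z), .name_repair = "minimal") |>
    setNames(c("motif", "barcode", "z"))
  long_raw <- as_tibble(as.table(x$raw), .name_repair = "minimal") |>
    setNames(c("motif", "barcode", "raw_deviation"))
  inner_join(long_raw, long_z, by = c("motif", "barcode"))
}

#' Differential motif deviation between radiotherapy and control
#'
#' Keeps motifs whose cognate transcription factor is expressed (detected in
#' at least `min_detect_frac` of cells in the RNA matrix), averages the
#' deviation z-score per (target, condition), and reports the signed
#' difference RT minus control per target and motif. A legacy transform
#' `sign(x) * log2(1 + |x|)` applied to the mean deviations before the
#' subtraction is available with `legacy_log2 = TRUE`.
#'
#' @param dev a `deviation_matrix`.
#' @param rna genes x cells RNA matrix or a `cell_dataset`.
#' @param tf_map tibble with `motif` and `tf` (gene name) columns.
#' @param assignments tibble with `barcode`, `target`.
#' @param conditions tibble with `barcode`, `condition`.
#' @param rt_condition,control_condition condition labels.
#' @param min_detect_frac detection fraction defining an expressed TF
#'   (default 0.05).
#' @param legacy_log2 apply the signed log transform before differencing.
#' @return list with `differences` (targets x motifs matrix), `row_order`,
#'   `kept_motifs`, `excluded_motifs`.
#' @export
differential_motif_deviation <- function(dev, rna, tf_map, assignments,
                                         conditions,
                                         rt_condition = "RT-frac",
                                         control_condition = "0Gy",
                                         min_detect_frac = 0.05,
                                         legacy_log2 = FALSE) {
  stopifnot(inherits(dev, "deviation_matrix"))
  m <- if (inherits(rna, "cell_dataset")) rna$counts else rna
  detect <- Matrix::rowMeans(m > 0)
  expressed_tf <- rownames(m)[detect >= min_detect_frac]
  kept <- tf_map |>
    filter(.data$motif %in% rownames(dev$z), .data$tf %in% expressed_tf)
  excluded <- setdiff(rownames(dev$z), kept$motif)
  if (nrow(kept) == 0L) abort("no motif has an expressed cognate TF")

  meta <- inner_join(assignments, conditions, by = "barcode") |>
    filter(!is.na(.data$target), .data$barcode %in% colnames(dev$z))
  targets <- sort(unique(meta$target))
  xf <- if (legacy_log2) function(x) sign(x) * log2(1 + abs(x)) else identity
  diffs <- matrix(NA_real_, length(targets), nrow(kept),
                  dimnames = list(targets, kept$motif))
  for (tg in targets) {
    bc_rt <- meta$barcode[meta$target == tg & meta$condition == rt_condition]
    bc_ct <- meta$barcode[meta$target == tg & meta$condition == control_condition]
    if (length(bc_rt) == 0L || length(bc_ct) == 0L) next
    mean_rt <- Matrix::rowMeans(dev$z[kept$motif, bc_rt, drop = FALSE])
    mean_ct <- Matrix::rowMeans(dev$z[kept$motif, bc_ct, drop = FALSE])
    diffs[tg, ] <- xf(mean_rt) - xf(mean_ct)
  }
  keep_rows <- !apply(diffs, 1L, function(r) all(is.na(r)))
  diffs <- diffs[keep_rows, , drop = FALSE]
  list(differences = diffs, row_order = pearson_hclust_order(diffs),
       kept_motifs = kept$motif, excluded_motifs = excluded)
}

#' Logistic-regression differential accessibility
#'
#' For each peak, compares the logistic regression of group membership on
#' binarised peak accessibility plus a `log1p(cell total)` covariate against
#' the covariate-only null with a 1-df likelihood-ratio test. The log2 fold
#' change is the ratio of detection rates with a pseudocount. Peaks
#' accessible in no cell are skipped; BH-adjusted p-values are reported.
#'
#' @param peak_counts peaks x cells count matrix.
#' @param group_a,group_b barcode vectors of the two cell groups.
#' @param pseudocount detection-rate guard (default 0.01).
#' @param min_cells minimum cells per group (default 3).
#' @return tibble with `peak`, `pct_a`, `pct_b`, `log2_fc`, `p_value`,
#'   `p_adj`.
#' @export
differential_accessibility_lr <- function(peak_counts, group_a, group_b,
                                          pseudocount = 0.01, min_cells = 3) {
  if (length(group_a) < min_cells || length(group_b) < min_cells) {
    abort(sprintf("need >= %d cells per group", min_cells))
  }
  m <- peak_counts[, c(group_a, group_b), drop = FALSE]
  label <- c(rep(1L, length(group_a)), rep(0L, length(group_b)))
  covariate <- log1p(Matrix::colSums(m))
  det <- m > 0
  rows <- list()
  for (p_idx in seq_len(nrow(m))) {
    y <- as.numeric(det[p_idx, ])
    if (sum(y) == 0) next
    pct_a <- mean(y[label == 1L])
    pct_b <- mean(y[label == 0L])
    fit_full <- suppressWarnings(
      glm(label ~ y + covariate, family = binomial())
    )
    fit_null <- suppressWarnings(
      glm(label ~ covariate, family = binomial())
    )
    lr <- fit_null$deviance - fit_full$deviance
    p <- pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      peak = rownames(m)[p_idx] %||% as.character(p_idx),
      pct_a = pct_a, pct_b = pct_b,
      log2_fc = log2(pct_a + pseudocount) - log2(pct_b + pseudocount),
      p_value = p
    )
  }
  if (length(rows) == 0L) {
    return(tibble(peak = character(), pct_a = numeric(), pct_b = numeric(),
                  log2_fc = numeric(), p_value = numeric(), p_adj = numeric()))
  }
  list_rbind(rows) |>
    mutate(p_adj = p.adjust(.data$p_value, method = "BH"))
}

#' Flank-normalised average coverage profile
#'
#' Sums per-base fragment coverage (weighted by the duplicate count) over
#' the selected cells at `center +/- window` around each region's centre,
#' averages over regions, and divides by the mean coverage of the first and
#' last `flank` base positions. Constant coverage therefore yields a profile
#' identically 1.
#'
#' @param fragments fragment tibble, 0-based half-open.
#' @param regions tibble with `chrom` and either `center` or `start`/`end`
#'   (centre = midpoint).
#' @param cells optional barcode subset (default: all barcodes present).
#' @param window half-window in bp (default 1000).
#' @param flank flank width in bp used for normalisation (default 100).
#' @return tibble with `position` (relative to centre), `coverage` (mean raw
#'   per-base coverage) and `normalized`.
#' @export
profile_matrix <- function(fragments, regions, cells = NULL, window = 1000,
                           flank = 100) {
  validate_fragments(fragments)
  if (nrow(regions) == 0L) abort("empty region set")
  if (!"center" %in% names(regions)) {
    regions$center <- (regions$start + regions$end) %/% 2L
  }
  if (!is.null(cells)) {
    fragments <- filter(fragments, .data$barcode %in% cells)
  }
  n_pos <- 2L * window + 1L
  cov <- numeric(n_pos)
  for (r_idx in seq_len(nrow(regions))) {
    lo <- regions$center[r_idx] - window
    hi <- regions$center[r_idx] + window
    hits <- which(fragments$chrom == regions$chrom[r_idx] &
                    fragments$start <= hi & fragments$end > lo)
    for (f in hits) {
      a <- max(fragments$start[f], lo) - lo + 1L
      b <- min(fragments$end[f] - 1L, hi) - lo + 1L
      if (b >= a) cov[a:b] <- cov[a:b] + fragments$count[f]
    }
  }
  cov <- cov / nrow(regions)
  flank_mean <- mean(cov[c(seq_len(flank), (n_pos - flank + 1L):n_pos)])
  tibble(
    position = seq(-window, window),
    coverage = cov,
    normalized = if (flank_mean == 0) rep(NA_real_, n_pos) else cov / flank_mean
  )
}
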