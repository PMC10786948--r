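#' Score dual-sgRNA CRISPRi screens
#'
#' @description
#' Functions for pooled CRISPRi screens read out by sgRNA counting. A screen
#' count table is a long tibble with one row per (vector, sample):
#'
#' * `vector_id` — the dual-sgRNA vector identifier
#' * `timepoint` — `"T0"` (initial population) or `"T12"` (endpoint)
#' * `arm` — `"0Gy"` (untreated) or `"RT"` (radiotherapy)
#' * `replicate` — integer replicate index
#' * `count` — nonnegative sgRNA read count (real-valued after normalisation)
#'
#' The guide library is a tibble with `vector_id`, `target_gene`, `is_ntc`
#' (non-targeting control flag) and optionally `discordant` (vector whose two
#' protospacers map to different target genes, indicating lentiviral
#' recombination).
#'
#' The growth phenotype gamma of a vector is
#' `log2(T12 count / T0 count)` minus the median NTC value of the same
#' quantity, per replicate, in the untreated arm. The radiation phenotype rho
#' is `log2(T12 RT count / T12 0Gy count)`, by default also centred on the
#' NTC median so that the normalised phenotype used for hit calling is on a
#' common scale.
#'
#' @name screen-scoring
NULL

screen_sample_key <- function(counts) {
  paste(counts$timepoint, counts$arm, counts$replicate, sep = "/")
}

validate_screen_counts <- function(counts) {
  need <- c("vector_id", "timepoint", "arm", "replicate", "count")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    abort(paste0("screen counts missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(counts$count < 0) || anyNA(counts$count)) {
    abort("screen counts must be finite and >= 0")
  }
  dup <- counts |>
    dplyr::count(.data$vector_id, .data$timepoint, .data$arm, .data$replicate) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort("duplicate (vector, timepoint, arm, replicate) rows in screen counts")
  }
  invisible(counts)
}

validate_guide_library <- function(library) {
  need <- c("vector_id", "target_gene", "is_ntc")
  missing <- setdiff(need, names(library))
  if (length(missing) > 0L) {
    abort(paste0("guide library missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(library$vector_id)) abort("vector ids must be unique")
  if (!"discordant" %in% names(library)) library$discordant <- FALSE
  library
}

#' Filter screen counts for recombined vectors and low initial coverage
#'
#' Drops vectors flagged as discordant in the library (the two protospacers of
#' the vector map to different target genes, the signature of lentiviral
#' recombination) and vectors whose mean T0 count across replicates falls
#' below `min_t0_reads`. A tally of removals by cause is attached as the
#' `"filter_log"` attribute.
#'
#' @param counts long screen count tibble (see [screen-scoring]).
#' @param library guide library tibble; must cover every vector in `counts`.
#' @param min_t0_reads minimum mean T0 read count for a vector to be kept.
#' @return the filtered count tibble, with a `filter_log` attribute.
#' @export
filter_screen_counts <- function(counts, library, min_t0_reads = 100) {
  validate_screen_counts(counts)
  library <- validate_guide_library(library)
  orphans <- setdiff(unique(counts$vector_id), library$vector_id)
  if (length(orphans) > 0L) {
    abort(paste0(
      "vectors in counts absent from library: ",
      paste(head(orphans, 10L), collapse = ", ")
    ))
  }
  discordant <- library$vector_id[library$discordant]
  t0_mean <- counts |>
    filter(.data$timepoint == "T0") |>
    group_by(.data$vector_id) |>
    summarise(t0_mean = mean(.data$count), .groups = "drop")
  low_t0 <- t0_mean$vector_id[t0_mean$t0_mean < min_t0_reads]
  no_t0 <- setdiff(unique(counts$vector_id), t0_mean$vector_id)
  drop <- union(union(discordant, low_t0), no_t0)
  out <- filter(counts, !.data$vector_id %in% drop)
  attr(out, "filter_log") <- tibble(
    reason = c("discordant_target", "low_t0", "no_t0_sample"),
    n_vectors = c(length(discordant), length(setdiff(low_t0, discordant)),
                  length(setdiff(no_t0, union(discordant, low_t0))))
  )
  out
}

#' Library-size normalise screen counts
#'
#' Scales each sample (a unique timepoint/arm/replicate combination) to a
#' common total of `scale` (counts per million by default), so that sample
#' totals are equal after normalisation.
#'
#' @param counts long screen count tibble.
#' @param scale common post-normalisation total per sample.
#' @return tibble with `count` replaced by the normalised value.
#' @export
normalize_library_size <- function(counts, scale = 1e6) {
  validate_screen_counts(counts)
  out <- counts |>
    group_by(.data$timepoint, .data$arm, .data$replicate) |>
    mutate(.total = sum(.data$count)) |>
    ungroup()
  if (any(out$.total <= 0)) {
    bad <- unique(screen_sample_key(out[out$.total <= 0, ]))
    abort(paste0("samples with zero total counts: ", paste(bad, collapse = ", ")))
  }
  out |>
    mutate(count = .data$count / .data$.total * scale) |>
    select(-".total")
}

# per-replicate log2 ratios centred on the NTC median; internal workhorse
replicate_phenotypes <- function(counts, library, pseudocount, center_rho) {
  wide <- counts |>
    mutate(slot = paste0(.data$timepoint, "_", .data$arm)) |>
    select("vector_id", "replicate", "slot", "count") |>
    tidyr::pivot_wider(names_from = "slot", values_from = "count")
  for (slot in c("T0_0Gy", "T12_0Gy", "T12_RT")) {
    if (!slot %in% names(wide)) {
      abort(paste0("missing stratum in screen counts: ", gsub("_", " ", slot)))
    }
  }
  wide <- left_join(wide, select(library, "vector_id", "is_ntc"), by = "vector_id")
  wide |>
    mutate(
      raw_gamma = log2(.data$T12_0Gy + pseudocount) - log2(.data$T0_0Gy + pseudocount),
      raw_rho = log2(.data$T12_RT + pseudocount) - log2(.data$T12_0Gy + pseudocount)
    ) |>
    group_by(.data$replicate) |>
    mutate(
      gamma = .data$raw_gamma - median(.data$raw_gamma[.data$is_ntc]),
      rho = if (center_rho) {
        .data$raw_rho - median(.data$raw_rho[.data$is_ntc])
      } else {
        .data$raw_rho
      }
    ) |>
    ungroup() |>
    select("vector_id", "replicate", "is_ntc", "gamma", "rho")
}

#' Replicate t-test significance per sgRNA vector
#'
#' Two-sided unpaired (Welch) t-test per vector comparing replicate
#' library-normalised counts between timepoints (gamma: T12 vs T0 in the
#' untreated arm) or between arms (rho: T12 RT vs T12 0Gy), on the log2 scale
#' by default. Identical replicate values on both sides give p = 1; unequal
#' means with zero variance are handled with a small variance floor.
#'
#' @param counts normalised long screen count tibble.
#' @param contrast `"gamma"` or `"rho"`.
#' @param log_scale test on `log2(count + pseudocount)` (default) or raw scale.
#' @param pseudocount added before the log transform.
#' @return tibble with `vector_id` and `p_value`.
#' @export
sgrna_significance <- function(counts, contrast = c("gamma", "rho"),
                               log_scale = TRUE, pseudocount = 1) {
  contrast <- match.arg(contrast)
  validate_screen_counts(counts)
  sides <- if (contrast == "gamma") {
    list(
      a = filter(counts, .data$timepoint == "T12", .data$arm == "0Gy"),
      b = filter(counts, .data$timepoint == "T0")
    )
  } else {
    list(
      a = filter(counts, .data$timepoint == "T12", .data$arm == "RT"),
      b = filter(counts, .data$timepoint == "T12", .data$arm == "0Gy")
    )
  }
  xf <- if (log_scale) function(v) log2(v + pseudocount) else identity
  a <- split(xf(sides$a$count), sides$a$vector_id)
  b <- split(xf(sides$b$count), sides$b$vector_id)
  ids <- intersect(names(a), names(b))
  if (any(lengths(a[ids]) < 2L) || any(lengths(b[ids]) < 2L)) {
    abort("sgrna_significance needs >= 2 replicates per side")
  }
  tibble(
    vector_id = ids,
    p_value = map_dbl(ids, function(v) welch_p(a[[v]], b[[v]]))
  )
}

#' Vector-level gamma and rho phenotypes
#'
#' Computes, per replicate and then averaged across replicates, the growth
#' phenotype gamma (`log2(T12/T0)` minus the NTC median of the same quantity,
#' untreated arm) and the radiation phenotype rho (`log2(T12 RT / T12 0Gy)`,
#' NTC-centred when `center_rho = TRUE`). Vector-level p-values come from
#' [sgrna_significance()]. The per-replicate phenotype table is attached as
#' the `"replicates"` attribute and consumed by [gene_level_scores()].
#'
#' @param counts library-normalised long screen count tibble.
#' @param library guide library tibble.
#' @param pseudocount added to normalised counts before log ratios (guards
#'   dropout vectors; negligible for vectors passing the T0 read filter).
#' @param center_rho centre rho on the NTC median (default), mirroring gamma.
#' @return vector-level phenotype tibble with columns `vector_id`,
#'   `target_gene`, `is_ntc`, `gamma`, `rho`, `p_gamma`, `p_rho`.
#' @export
compute_phenotypes <- function(counts, library, pseudocount = 1,
                               center_rho = TRUE) {
  library <- validate_guide_library(library)
  reps <- replicate_phenotypes(counts, library, pseudocount, center_rho)
  avg <- reps |>
    group_by(.data$vector_id) |>
    summarise(gamma = mean(.data$gamma), rho = mean(.data$rho), .groups = "drop")
  # recentre the replicate-averaged phenotypes so the NTC medians are
  # exactly zero at the vector level as well
  ntc_ids <- library$vector_id[library$is_ntc]
  if (any(avg$vector_id %in% ntc_ids)) {
    is_ntc_avg <- avg$vector_id %in% ntc_ids
    avg$gamma <- avg$gamma - median(avg$gamma[is_ntc_avg])
    avg$rho <- avg$rho - median(avg$rho[is_ntc_avg])
  }
  pg <- rename(sgrna_significance(counts, "gamma", pseudocount = pseudocount),
               p_gamma = "p_value")
  pr <- rename(sgrna_significance(counts, "rho", pseudocount = pseudocount),
               p_rho = "p_value")
  out <- avg |>
    left_join(select(library, "vector_id", "target_gene", "is_ntc"), by = "vector_id") |>
    left_join(pg, by = "vector_id") |>
    left_join(pr, by = "vector_id") |>
    select("vector_id", "target_gene", "is_ntc", "gamma", "rho", "p_gamma", "p_rho")
  attr(out, "replicates") <- reps
  out
}

#' Gene-level phenotypes with NTC pseudo-genes
#'
#' Aggregates vector phenotypes to genes: the gene phenotype is the mean of
#' its vectors' phenotypes, and the gene p-value is a two-sided one-sample
#' t-test of the per-replicate gene phenotypes (mean of its vectors'
#' NTC-centred log ratios in each replicate) against zero. NTC vectors are
#' partitioned into pseudo-genes of `pseudo_group_size` vectors (remainder
#' dropped) and scored identically; they drive the empiric FDR in
#' [call_hits()]. The normalised phenotypes `z_gamma`/`z_rho` divide the gene
#' phenotype by the robust SD (MAD) of the NTC pseudo-gene phenotypes.
#'
#' @param vector_table output of [compute_phenotypes()] (the `"replicates"`
#'   attribute must be present).
#' @param library guide library tibble.
#' @param pseudo_group_size vectors per NTC pseudo-gene; defaults to the
#'   number of vectors per targeted gene in the library.
#' @return gene-level tibble with `gene`, `is_pseudo`, `n_vectors`, `gamma`,
#'   `rho`, `p_gamma`, `p_rho`, `z_gamma`, `z_rho`.
#' @export
gene_level_scores <- function(vector_table, library, pseudo_group_size = NULL) {
  library <- validate_guide_library(library)
  reps <- attr(vector_table, "replicates")
  if (is.null(reps)) {
    abort("vector_table lacks the 'replicates' attribute; use compute_phenotypes()")
  }
  if (is.null(pseudo_group_size)) {
    per_gene <- library |>
      filter(!.data$is_ntc) |>
      dplyr::count(.data$target_gene)
    pseudo_group_size <- if (nrow(per_gene) > 0L) {
      as.integer(round(median(per_gene$n)))
    } else {
      1L
    }
  }
  assert_count(pseudo_group_size, "pseudo_group_size", min = 1L)

  lib <- filter(library, .data$vector_id %in% vector_table$vector_id)
  ntc_ids <- sort(lib$vector_id[lib$is_ntc])
  n_groups <- length(ntc_ids) %/% pseudo_group_size
  pseudo_map <- if (n_groups > 0L) {
    kept <- ntc_ids[seq_len(n_groups * pseudo_group_size)]
    tibble(
      vector_id = kept,
      gene = sprintf("NTC_pseudo_%04d", rep(seq_len(n_groups), each = pseudo_group_size)),
      is_pseudo = TRUE
    )
  } else {
    tibble(vector_id = character(), gene = character(), is_pseudo = logical())
  }
  target_map <- lib |>
    filter(!.data$is_ntc) |>
    mutate(gene = .data$target_gene, is_pseudo = FALSE) |>
    select("vector_id", "gene", "is_pseudo")
  gmap <- bind_rows(target_map, pseudo_map)

  rep_gene <- reps |>
    inner_join(gmap, by = "vector_id") |>
    group_by(.data$gene, .data$is_pseudo, .data$replicate) |>
    summarise(gamma = mean(.data$gamma), rho = mean(.data$rho), .groups = "drop")
  gene_tab <- rep_gene |>
    group_by(.data$gene, .data$is_pseudo) |>
    summarise(
      n_replicates = dplyr::n(),
      p_gamma = one_sample_p(.data$gamma),
      p_rho = one_sample_p(.data$rho),
      gamma = mean(.data$gamma),
      rho = mean(.data$rho),
      .groups = "drop"
    )
  n_vec <- gmap |> dplyr::count(.data$gene, name = "n_vectors")
  gene_tab <- left_join(gene_tab, n_vec, by = "gene")

  pseudo <- filter(gene_tab, .data$is_pseudo)
  if (nrow(pseudo) < 2L) {
    warn("fewer than 2 NTC pseudo-genes; normalised phenotypes set to NA")
    sg <- sr <- NA_real_
  } else {
    sg <- mad(pseudo$gamma)
    sr <- mad(pseudo$rho)
    if (sg == 0) sg <- sd(pseudo$gamma)
    if (sr == 0) sr <- sd(pseudo$rho)
  }
  gene_tab |>
    mutate(z_gamma = .data$gamma / sg, z_rho = .data$rho / sr) |>
    select("gene", "is_pseudo", "n_vectors", "n_replicates",
           "gamma", "rho", "p_gamma", "p_rho", "z_gamma", "z_rho") |>
    arrange(.data$is_pseudo, .data$gene)
}

#' Call screen hits with an NTC pseudo-gene empiric FDR
#'
#' The discriminant score of a gene is `|z| * (-log10 p)` for the chosen
#' phenotype; a gene is a hit when its discriminant reaches `threshold`
#' (boundary inclusive). The empiric false discovery rate is estimated from
#' the NTC pseudo-genes: `FDR = (pseudo-gene pass rate * number of genes) /
#' number of gene hits`. The smallest threshold achieving `target_fdr` is
#' also reported.
#'
#' @param gene_table output of [gene_level_scores()].
#' @param phenotype `"rho"` (treatment response) or `"gamma"` (growth).
#' @param threshold discriminant hit threshold (default 5).
#' @param target_fdr empiric FDR level for the adaptive threshold.
#' @return a `screen_hits` object; see [tidy.screen_hits()] and
#'   [glance.screen_hits()].
#' @export
call_hits <- function(gene_table, phenotype = c("rho", "gamma"),
                      threshold = 5, target_fdr = 0.01) {
  phenotype <- match.arg(phenotype)
  z <- gene_table[[paste0("z_", phenotype)]]
  p <- gene_table[[paste0("p_", phenotype)]]
  if (!any(gene_table$is_pseudo)) {
    abort("no NTC pseudo-genes present; empiric FDR is undefined")
  }
  tab <- gene_table |>
    mutate(
      discriminant = abs(z) * (-log10(pmax(p, 1e-300))),
      hit = .data$discriminant >= threshold & !.data$is_pseudo
    ) |>
    arrange(desc(.data$discriminant), .data$gene)

  n_genes <- sum(!tab$is_pseudo)
  empiric_fdr_at <- function(thr) {
    n_hits <- sum(tab$discriminant >= thr & !tab$is_pseudo)
    if (n_hits == 0L) return(0)
    pseudo_rate <- mean(tab$discriminant[tab$is_pseudo] >= thr)
    min(1, pseudo_rate * n_genes / n_hits)
  }
  cand <- sort(unique(tab$discriminant[!tab$is_pseudo]))
  ok <- cand[vapply(cand, function(thr) empiric_fdr_at(thr) <= target_fdr, logical(1))]
  structure(
    list(
      table = tab,
      phenotype = phenotype,
      threshold = threshold,
      target_fdr = target_fdr,
      n_genes = n_genes,
      n_hits = sum(tab$hit),
      n_pseudo_pass = sum(tab$discriminant[tab$is_pseudo] >= threshold),
      empiric_fdr = empiric_fdr_at(threshold),
      threshold_at_target_fdr = if (length(ok) > 0L) min(ok) else NA_real_
    ),
    class = "screen_hits"
  )
}

#' @export
print.screen_hits <- function(x, ...) {
  cat(sprintf(
    "<screen_hits> %s phenotype: %d/%d genes hit at discriminant >= %g (empiric FDR %.3g)\n",
    x$phenotype, x$n_hits, x$n_genes, x$threshold, x$empiric_fdr
  ))
  invisible(x)
}

#' Tidy a screen hit call
#'
#' @param x a `screen_hits` object from [call_hits()].
#' @param ... unused.
#' @return the gene-level tibble with `discriminant` and `hit` columns.
#' @exportS3Method generics::tidy
tidy.screen_hits <- function(x, ...) x$table

#' One-row summary of a screen hit call
#'
#' @param x a `screen_hits` object from [call_hits()].
#' @param ... unused.
#' @return one-row tibble with hit counts, empiric FDR and thresholds.
#' @exportS3Method generics::glance
glance.screen_hits <- function(x, ...) {
  tibble(
    phenotype = x$phenotype, threshold = x$threshold, n_genes = x$n_genes,
    n_hits = x$n_hits, n_pseudo_pass = x$n_pseudo_pass,
    empiric_fdr = x$empiric_fdr,
    threshold_at_target_fdr = x$threshold_at_target_fdr
  )
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a binomial proportion, reported in percent,
#' as used for classifier and assignment accuracy reporting. With
#' `successes = trials` the upper bound is 100% and the lower bound is
#' `(alpha/2)^(1/trials) * 100`.
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param level confidence level, default 0.95.
#' @return tibble with `estimate`, `lower`, `upper` (percent).
#' @export
#' @examples
#' clopper_pearson(15, 15) # lower bound 78.2%
clopper_pearson <- function(successes, trials, level = 0.95) {
  assert_count(trials, "trials", min = 1L)
  assert_count(successes, "successes", min = 0L)
  if (successes > trials) abort("successes must be <= trials")
  alpha <- 1 - level
  lower <- if (successes == 0L) 0 else qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1, trials - successes)
  tibble(
    estimate = 100 * successes / trials,
    lower = 100 * lower,
    upper = 100 * upper
  )
}
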