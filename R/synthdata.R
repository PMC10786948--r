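#' Simulation configuration for perturbation datasets
#'
#' Builds a validated configuration shared by [simulate_screen()],
#' [simulate_perturbseq()] and [simulate_multiome()]. Defaults mirror the
#' experimental design the analysis functions assume: triplicate screens at
#' 500x coverage per construct, lentiviral transduction at MOI 0.1 (about 95%
#' of transduced cells carrying a single integration), negative-binomial UMI
#' counts, programmed per-guide knockdown fractions and per-condition module
#' shifts, and a two-component (nucleosome-free / mono-nucleosomal) ATAC
#' fragment-length mixture.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene vectors per targeted gene (the dual-sgRNA design
#'   carries one vector of two protospacers per target).
#' @param n_ntc number of non-targeting control vectors/guides.
#' @param n_replicates screen replicates per arm.
#' @param coverage expected T0 reads (screen) per construct.
#' @param moi mean lentiviral integrations per cell (Poisson).
#' @param nb_mean expected UMI per background gene per cell.
#' @param nb_dispersion negative-binomial overdispersion phi
#'   (variance = mu + phi mu^2) for single-cell UMI counts.
#' @param screen_nb_dispersion overdispersion phi for bulk screen read
#'   counts; sequencing of sgRNA cassettes is far less dispersed than
#'   single-cell UMIs.
#' @param gamma_effects,rho_effects named numeric vectors of true per-gene
#'   log2 growth / radiation effects; genes not named have effect 0.
#' @param screen_noise_sd between-replicate log2 noise SD on screen fold
#'   changes (free simulation parameter; the count model between replicates
#'   is not constrained by the assay design).
#' @param frac_discordant fraction of targeted vectors emitted with
#'   discordant target labels (lentiviral recombination).
#' @param frac_low_t0 fraction of vectors emitted with sub-threshold T0 depth
#'   to exercise the read filter.
#' @param cells_per_lane Perturb-seq / multiome cells per GEM lane.
#' @param knockdown default fraction of target RNA removed by a targeting
#'   guide; `knockdown_map` overrides per guide.
#' @param knockdown_map optional named vector, guide id -> knockdown fraction.
#' @param target_gene_mean expected UMI per targeted gene per cell (kept
#'   higher than background so knockdown is measurable).
#' @param n_background_genes untargeted genes in the expression matrix.
#' @param module_defs named list of gene sets (defaults to two ten-gene
#'   modules drawn from the background genes).
#' @param module_shifts tibble (`module`, `condition`, `shift`) of true
#'   per-condition log2 expression shifts applied to module genes.
#' @param guide_umi_mean expected capture UMIs for a cell's true guide.
#' @param ambient_rate expected total ambient guide UMIs per cell,
#'   apportioned over guides by their population frequency.
#' @param frag_len_free_mean,frag_len_mono_mean mean fragment lengths (bp) of
#'   the nucleosome-free and mono-nucleosomal components.
#' @param frag_free_weight per-cell mixture weight on the nucleosome-free
#'   component.
#' @param n_peaks,n_motifs multiome peak and motif counts.
#' @param motif_enrichment named vector, motif id -> true log2 accessibility
#'   effect in perturbed cells under radiotherapy.
#' @param activity_shift true log2 promoter-accessibility shift applied to
#'   the first module's genes under radiotherapy.
#' @param seed default RNG seed for the generators.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 50, guides_per_gene = 1, n_ntc = 20,
                       n_replicates = 3, coverage = 500, moi = 0.1,
                       nb_mean = 0.2, nb_dispersion = 0.5,
                       screen_nb_dispersion = 0.05,
                       gamma_effects = NULL, rho_effects = NULL,
                       screen_noise_sd = 0.15,
                       frac_discordant = 0, frac_low_t0 = 0,
                       cells_per_lane = 300,
                       knockdown = 0.9, knockdown_map = NULL,
                       target_gene_mean = 2,
                       n_background_genes = 100,
                       module_defs = NULL, module_shifts = NULL,
                       guide_umi_mean = 30, ambient_rate = 0,
                       frag_len_free_mean = 75, frag_len_mono_mean = 200,
                       frag_free_weight = 0.65,
                       n_peaks = 200, n_motifs = 5,
                       motif_enrichment = NULL,
                       activity_shift = 0,
                       seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(guides_per_gene, "guides_per_gene", min = 1L)
  assert_count(n_ntc, "n_ntc")
  assert_count(n_replicates, "n_replicates", min = 1L)
  if (!is.numeric(moi) || moi <= 0) abort("moi must be > 0")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    abort("nb_dispersion must be > 0")
  }
  if (!is.numeric(screen_nb_dispersion) || screen_nb_dispersion <= 0) {
    abort("screen_nb_dispersion must be > 0")
  }
  assert_fraction(knockdown, "knockdown")
  assert_fraction(frac_discordant, "frac_discordant")
  assert_fraction(frac_low_t0, "frac_low_t0")
  assert_fraction(frag_free_weight, "frag_free_weight")
  if (!is.null(knockdown_map)) {
    if (any(knockdown_map < 0 | knockdown_map > 1)) {
      abort("knockdown fractions must be in [0, 1]")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), guides_per_gene = as.integer(guides_per_gene),
    n_ntc = as.integer(n_ntc), n_replicates = as.integer(n_replicates),
    coverage = coverage, moi = moi, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion,
    screen_nb_dispersion = screen_nb_dispersion,
    gamma_effects = gamma_effects, rho_effects = rho_effects,
    screen_noise_sd = screen_noise_sd,
    frac_discordant = frac_discordant, frac_low_t0 = frac_low_t0,
    cells_per_lane = as.integer(cells_per_lane),
    knockdown = knockdown, knockdown_map = knockdown_map,
    target_gene_mean = target_gene_mean,
    n_background_genes = as.integer(n_background_genes),
    module_defs = module_defs, module_shifts = module_shifts,
    guide_umi_mean = guide_umi_mean, ambient_rate = ambient_rate,
    frag_len_free_mean = frag_len_free_mean,
    frag_len_mono_mean = frag_len_mono_mean,
    frag_free_weight = frag_free_weight,
    n_peaks = as.integer(n_peaks), n_motifs = as.integer(n_motifs),
    motif_enrichment = motif_enrichment,
    activity_shift = activity_shift,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Fraction of transduced cells with a single lentiviral integration
#'
#' Under Poisson transduction at multiplicity of infection `moi`, the
#' fraction of transduced cells (at least one integration) that carry exactly
#' one integration is `moi * exp(-moi) / (1 - exp(-moi))`. At MOI 0.1 this is
#' about 95%, the usual justification for low-MOI pooled screens.
#'
#' @param moi mean integrations per cell; must be > 0.
#' @return fraction in (0, 1].
#' @export
#' @examples
#' expected_single_integration_fraction(0.1) # ~0.95
expected_single_integration_fraction <- function(moi) {
  if (!is.numeric(moi) || any(is.na(moi)) || any(moi <= 0)) {
    abort("moi must be > 0")
  }
  moi * exp(-moi) / (1 - exp(-moi))
}

# truncated-at-zero Poisson draws (integration counts of transduced cells)
rpois_positive <- function(n, lambda) {
  kmax <- max(10L, ceiling(lambda + 10 * sqrt(lambda)))
  probs <- stats::dpois(seq_len(kmax), lambda)
  sample.int(kmax, n, replace = TRUE, prob = probs)
}

rnb <- function(n, mu, phi) {
  rnbinom(n, size = 1 / phi, mu = mu)
}

sim_guide_library <- function(config, guides_per_gene = config$guides_per_gene,
                              prefix = "v") {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  targeted <- tidyr::expand_grid(target_gene = genes, g = seq_len(guides_per_gene)) |>
    mutate(
      vector_id = sprintf("%s_%s%d", .data$target_gene, prefix, .data$g),
      is_ntc = FALSE
    ) |>
    select("vector_id", "target_gene", "is_ntc")
  ntc <- tibble(
    vector_id = sprintf("NTC_%s%04d", prefix, seq_len(config$n_ntc)),
    target_gene = "NTC",
    is_ntc = TRUE
  )
  bind_rows(targeted, ntc)
}

#' Simulate a dual-sgRNA CRISPRi screen with ground truth
#'
#' Generates a guide library and a triplicate T0/T12 count table under the
#' screen design: T0 counts are negative binomial around `coverage`; T12
#' counts in the untreated arm scale T0 abundance by `2^gamma_true` and the
#' radiotherapy arm additionally by `2^rho_true`, with independent
#' between-replicate log2 noise. A configurable fraction of vectors is
#' emitted with discordant target labels (recombination) or sub-threshold T0
#' depth to exercise [filter_screen_counts()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `library`, `counts` (long tibble) and `truth`
#'   (`genes` and `vectors` tibbles of true effects and emitted flaws).
#' @export
simulate_screen <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes + config$n_ntc == 0L) abort("empty library")
  set.seed(derive_seed(seed, 1L))

  library <- sim_guide_library(config)
  genes <- unique(library$target_gene[!library$is_ntc])
  gamma_true <- setNames(rep(0, length(genes)), genes)
  rho_true <- gamma_true
  if (!is.null(config$gamma_effects)) {
    gamma_true[names(config$gamma_effects)] <- config$gamma_effects
  }
  if (!is.null(config$rho_effects)) {
    rho_true[names(config$rho_effects)] <- config$rho_effects
  }

  n_targeted <- sum(!library$is_ntc)
  discordant_ids <- character()
  if (config$frac_discordant > 0 && n_targeted > 0L) {
    k <- round(config$frac_discordant * n_targeted)
    discordant_ids <- sample(library$vector_id[!library$is_ntc], k)
  }
  library$discordant <- library$vector_id %in% discordant_ids

  low_ids <- character()
  if (config$frac_low_t0 > 0) {
    k <- round(config$frac_low_t0 * nrow(library))
    low_ids <- sample(library$vector_id, k)
  }

  vec <- library |>
    mutate(
      gamma_true = if_else(.data$is_ntc, 0, unname(gamma_true[.data$target_gene])),
      rho_true = if_else(.data$is_ntc, 0, unname(rho_true[.data$target_gene])),
      low_t0 = .data$vector_id %in% low_ids,
      t0_mean = if_else(.data$low_t0, config$coverage * 0.1, config$coverage)
    )

  grid <- tidyr::expand_grid(
    vec |> select("vector_id", "gamma_true", "rho_true", "t0_mean"),
    replicate = seq_len(config$n_replicates)
  )
  n <- nrow(grid)
  phi <- config$screen_nb_dispersion
  eps_g <- rnorm(n, 0, config$screen_noise_sd)
  eps_r <- rnorm(n, 0, config$screen_noise_sd)
  t0 <- rnb(n, grid$t0_mean, phi)
  t12_0 <- rnb(n, grid$t0_mean * 2^(grid$gamma_true + eps_g), phi)
  t12_rt <- rnb(n, grid$t0_mean * 2^(grid$gamma_true + grid$rho_true + eps_g + eps_r), phi)

  counts <- bind_rows(
    tibble(vector_id = grid$vector_id, timepoint = "T0", arm = "0Gy",
           replicate = grid$replicate, count = as.numeric(t0)),
    tibble(vector_id = grid$vector_id, timepoint = "T12", arm = "0Gy",
           replicate = grid$replicate, count = as.numeric(t12_0)),
    tibble(vector_id = grid$vector_id, timepoint = "T12", arm = "RT",
           replicate = grid$replicate, count = as.numeric(t12_rt))
  )

  list(
    library = library,
    counts = counts,
    truth = list(
      genes = tibble(gene = genes, gamma_true = unname(gamma_true),
                     rho_true = unname(rho_true)),
      vectors = vec |>
        select("vector_id", "target_gene", "is_ntc", "discordant",
               "low_t0", "gamma_true", "rho_true")
    )
  )
}

sim_modules <- function(config, background_genes) {
  if (!is.null(config$module_defs)) return(config$module_defs)
  n <- length(background_genes)
  size <- min(10L, n %/% 2L)
  list(
    module_A = background_genes[seq_len(size)],
    module_B = background_genes[seq_len(size) + size]
  )
}

sim_module_shifts <- function(config, modules) {
  if (!is.null(config$module_shifts)) return(config$module_shifts)
  tibble(
    module = names(modules)[1],
    condition = c("RT-frac", "RT-hypo"),
    shift = c(1, 1)
  )
}

# capture-matrix generation shared by the perturb-seq and multiome simulators
sim_guide_capture <- function(guides, cell_guides, config) {
  n_cells <- length(cell_guides)
  n_guides <- length(guides)
  per_cell <- lengths(cell_guides)
  i <- match(unlist(cell_guides), guides)
  j <- rep(seq_len(n_cells), per_cell)
  x <- rpois(length(i), config$guide_umi_mean) + 1L
  m <- sparseMatrix(i = i, j = j, x = x, dims = c(n_guides, n_cells))
  if (config$ambient_rate > 0) {
    freq <- table(factor(unlist(cell_guides), levels = guides))
    freq <- as.numeric(freq) / max(1, sum(freq))
    amb <- matrix(
      rpois(n_guides * n_cells, config$ambient_rate * freq),
      nrow = n_guides
    )
    m <- m + Matrix::Matrix(amb, sparse = TRUE)
  }
  dimnames(m) <- list(guides, NULL)
  m
}

#' Simulate a Perturb-seq experiment with ground truth
#'
#' Generates a cells x genes UMI matrix, a cells x guides capture matrix and
#' per-cell metadata under the pooled single-guide CRISPRi design: per-cell
#' integration counts are zero-truncated Poisson at `moi` (cells are sorted
#' for transduction), capture UMIs concentrate on the true guide(s) plus an
#' optional ambient background, the target gene of a cell's guide is scaled
#' by `1 - knockdown`, and module genes are scaled by per-condition log2
#' shifts. Cells carry GEM lane labels: two lanes for the untreated (0Gy)
#' condition and one for each radiotherapy condition (fractionated RT-frac,
#' hypofractionated RT-hypo).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `dataset` (a `cell_dataset`), `library` (guide tibble)
#'   and `truth` (per-cell guide identity and integration count, per-guide
#'   knockdown, module definitions and shifts).
#' @export
simulate_perturbseq <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$moi <= 0) abort("moi must be > 0")
  set.seed(derive_seed(seed, 2L))

  library <- sim_guide_library(config, guides_per_gene = 1L, prefix = "sg")
  guides <- library$vector_id
  kd <- setNames(if_else(library$is_ntc, 0, config$knockdown), guides)
  if (!is.null(config$knockdown_map)) {
    kd[names(config$knockdown_map)] <- config$knockdown_map
  }
  kd[library$vector_id[library$is_ntc]] <- 0

  lanes <- tibble(
    lane = c("L1", "L2", "L3", "L4"),
    condition = c("0Gy", "0Gy", "RT-frac", "RT-hypo")
  )
  cells <- tidyr::expand_grid(lanes, idx = seq_len(config$cells_per_lane)) |>
    mutate(barcode = sprintf("%s_BC%04d", .data$lane, .data$idx)) |>
    select("barcode", "lane", "condition")
  n_cells <- nrow(cells)

  k_int <- rpois_positive(n_cells, config$moi)
  cell_guides <- map(k_int, function(k) sample(guides, min(k, length(guides))))
  primary_guide <- map_chr(cell_guides, 1L)

  capture <- sim_guide_capture(guides, cell_guides, config)
  colnames(capture) <- cells$barcode

  background <- sprintf("BG%04d", seq_len(config$n_background_genes))
  target_genes <- unique(library$target_gene[!library$is_ntc])
  gene_ids <- c(target_genes, background)
  modules <- sim_modules(config, background)
  shifts <- sim_module_shifts(config, modules)

  base_mean <- setNames(
    c(rep(config$target_gene_mean, length(target_genes)),
      stats::rlnorm(length(background), log(config$nb_mean), 0.5)),
    gene_ids
  )
  mu <- matrix(base_mean, nrow = length(gene_ids), ncol = n_cells)
  rownames(mu) <- gene_ids
  # programmed knockdown on each cell's targets
  for (c_idx in seq_len(n_cells)) {
    for (g in cell_guides[[c_idx]]) {
      tg <- library$target_gene[library$vector_id == g]
      if (tg != "NTC") mu[tg, c_idx] <- mu[tg, c_idx] * (1 - kd[[g]])
    }
  }
  # programmed per-condition module shifts
  for (r in seq_len(nrow(shifts))) {
    mod_genes <- intersect(modules[[shifts$module[r]]], gene_ids)
    in_cond <- cells$condition == shifts$condition[r]
    if (length(mod_genes) > 0L && any(in_cond)) {
      mu[mod_genes, in_cond] <- mu[mod_genes, in_cond] * 2^shifts$shift[r]
    }
  }
  counts <- matrix(
    rnb(length(mu), as.vector(mu), config$nb_dispersion),
    nrow = nrow(mu), dimnames = list(gene_ids, cells$barcode)
  )
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  ds <- cell_dataset(counts = counts, guides = capture, cells = cells)
  list(
    dataset = ds,
    library = library,
    truth = list(
      cells = cells |>
        mutate(
          n_integrations = k_int,
          guide = if_else(.data$n_integrations == 1L, primary_guide, NA_character_),
          guides_all = map_chr(cell_guides, paste, collapse = ",")
        ),
      guides = tibble(
        guide = guides,
        target_gene = library$target_gene,
        is_ntc = library$is_ntc,
        knockdown_true = unname(kd)
      ),
      modules = modules,
      module_shifts = shifts
    )
  )
}

#' Simulate a single-nuclei multiome (ATAC + RNA + perturbation) dataset
#'
#' Generates ATAC fragment records, a peak x cell count matrix, an RNA
#' `cell_dataset` with guide capture, a motif annotation and a truth table.
#' Fragment lengths are drawn from a two-component mixture (nucleosome-free
#' vs mono-nucleosomal) with a configurable weight; per-cell fragment totals
#' span the QC bounds so the filters are exercised; promoter fragments for
#' the first module's genes are enriched by `activity_shift` log2 units under
#' radiotherapy; peaks carrying a motif in `motif_enrichment` are more
#' accessible in perturbed (non-NTC) cells under radiotherapy.
#'
#' @param config a [sim_config()]. Targets receive two guides each
#'   (`_sg1`/`_sg2`), matching the paired-guide design whose analyses pool
#'   cells by target gene.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `fragments` (tibble: chrom, start, end, barcode, count;
#'   0-based half-open), `peak_counts` (peaks x cells sparse matrix),
#'   `peaks` (tibble), `dataset` (RNA + guide `cell_dataset`),
#'   `motif_annotation` (see [motif_deviation_zscores()]), `tss` (tibble:
#'   gene, chrom, tss, strand) and `truth`.
#' @export
simulate_multiome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, 3L))

  library <- sim_guide_library(config, guides_per_gene = 2L, prefix = "sg")
  guides <- library$vector_id

  lanes <- tibble(lane = c("L1", "L2"), condition = c("0Gy", "RT-frac"))
  cells <- tidyr::expand_grid(lanes, idx = seq_len(config$cells_per_lane)) |>
    mutate(barcode = sprintf("%s_BC%04d", .data$lane, .data$idx)) |>
    select("barcode", "lane", "condition")
  n_cells <- nrow(cells)

  k_int <- rpois_positive(n_cells, config$moi)
  cell_guides <- map(k_int, function(k) sample(guides, min(k, length(guides))))
  capture <- sim_guide_capture(guides, cell_guides, config)
  colnames(capture) <- cells$barcode
  target_of <- setNames(library$target_gene, library$vector_id)
  cell_target <- map_chr(cell_guides, function(gs) {
    if (length(gs) == 1L) unname(target_of[gs[1]]) else NA_character_
  })
  perturbed <- !is.na(cell_target) & cell_target != "NTC"

  # --- genes, TSSs, promoter-level module activity --------------------------
  n_tss <- 20L
  tss <- tibble(
    gene = sprintf("GA%03d", seq_len(n_tss)),
    chrom = "chr1",
    tss = 50000L + seq_len(n_tss) * 20000L,
    strand = rep(c("+", "-"), length.out = n_tss)
  )
  modules <- config$module_defs %||% list(
    module_A = tss$gene[1:5], module_B = tss$gene[6:10]
  )

  # per-cell depth: mostly within QC bounds, a few deliberately below
  depth <- stats::rlnorm(n_cells, log(2500), 0.3)
  n_low <- max(1L, n_cells %/% 20L)
  depth[seq_len(n_low)] <- runif(n_low, 200, 600)

  promoter_rate <- setNames(rep(40, n_tss), tss$gene)
  frag_list <- vector("list", n_cells)
  for (c_idx in seq_len(n_cells)) {
    d <- depth[c_idx]
    scale_c <- d / 2500
    rates <- promoter_rate * scale_c
    if (cells$condition[c_idx] == "RT-frac" && config$activity_shift != 0) {
      rates[modules[[1]]] <- rates[modules[[1]]] * 2^config$activity_shift
    }
    n_prom <- rpois(n_tss, rates)
    # promoter fragments: uniform in [TSS-1800, TSS+200] oriented by strand
    prom <- map(seq_len(n_tss), function(g) {
      n <- n_prom[g]
      if (n == 0L) return(NULL)
      offs <- round(runif(n, -1800, 200))
      centers <- if (tss$strand[g] == "+") tss$tss[g] + offs else tss$tss[g] - offs
      centers
    })
    centers <- unlist(prom)
    n_bg <- rpois(1L, 400 * scale_c)
    centers <- c(centers, round(runif(n_bg, 1e4, 6e5)))
    n_frag <- length(centers)
    comp_free <- runif(n_frag) < config$frag_free_weight
    len <- ifelse(
      comp_free,
      pmax(30, round(rnorm(n_frag, config$frag_len_free_mean, 12))),
      pmax(150, round(rnorm(n_frag, config$frag_len_mono_mean, 25)))
    )
    start <- pmax(0, centers - len %/% 2)
    frag_list[[c_idx]] <- tibble(
      chrom = "chr1", start = as.integer(start),
      end = as.integer(start + len),
      barcode = cells$barcode[c_idx], count = 1L
    )
  }
  fragments <- list_rbind(frag_list) |> arrange(.data$chrom, .data$start)

  # --- peaks, motifs, peak x cell counts ------------------------------------
  n_peaks <- config$n_peaks
  peak_start <- 10000L + seq_len(n_peaks) * 3000L
  peaks <- tibble(
    peak = sprintf("peak_%04d", seq_len(n_peaks)),
    chrom = "chr1", start = peak_start, end = peak_start + 500L,
    gc = runif(n_peaks, 0.3, 0.7)
  )
  motifs <- sprintf("M%02d", seq_len(config$n_motifs))
  membership <- matrix(FALSE, n_peaks, config$n_motifs,
                       dimnames = list(peaks$peak, motifs))
  per_motif <- max(10L, n_peaks %/% 5L)
  for (m in seq_len(config$n_motifs)) {
    membership[sample.int(n_peaks, per_motif), m] <- TRUE
  }
  enrich <- setNames(rep(0, config$n_motifs), motifs)
  if (!is.null(config$motif_enrichment)) {
    enrich[names(config$motif_enrichment)] <- config$motif_enrichment
  }
  peak_mu <- matrix(1, n_peaks, n_cells) *
    matrix(depth / 2500, n_peaks, n_cells, byrow = TRUE)
  stratum <- perturbed & cells$condition == "RT-frac"
  for (m in motifs[enrich != 0]) {
    mem <- membership[, m]
    peak_mu[mem, stratum] <- peak_mu[mem, stratum] * 2^enrich[[m]]
  }
  peak_counts <- Matrix::Matrix(
    matrix(rnb(length(peak_mu), as.vector(peak_mu), config$nb_dispersion),
           nrow = n_peaks,
           dimnames = list(peaks$peak, cells$barcode)),
    sparse = TRUE
  )

  # --- RNA matrix: TF genes (per motif) + background ------------------------
  tf_map <- tibble(motif = motifs, tf = sprintf("TF%02d", seq_len(config$n_motifs)))
  background <- sprintf("BG%03d", seq_len(50L))
  rna_genes <- c(tf_map$tf, background)
  # nuclei RNA totals sit in the hundreds; scale with the per-cell depth
  # factor so low-depth cells exercise both UMI bounds
  rna_mean <- setNames(
    c(rep(5, nrow(tf_map)), stats::rlnorm(length(background), log(8), 0.5)),
    rna_genes
  )
  rna_mu <- outer(rna_mean, depth / 2500)
  rna_counts <- Matrix::Matrix(
    matrix(rnb(length(rna_mu), as.vector(rna_mu), config$nb_dispersion),
           nrow = length(rna_genes),
           dimnames = list(rna_genes, cells$barcode)),
    sparse = TRUE
  )
  ds <- cell_dataset(counts = rna_counts, guides = capture, cells = cells)

  motif_annotation <- list(
    membership = membership,
    gc = setNames(peaks$gc, peaks$peak),
    tf_map = tf_map
  )

  list(
    fragments = fragments,
    peak_counts = peak_counts,
    peaks = peaks,
    dataset = ds,
    motif_annotation = motif_annotation,
    tss = tss,
    truth = list(
      cells = cells |>
        mutate(n_integrations = k_int, target = cell_target,
               perturbed = perturbed, depth = depth),
      guides = tibble(guide = guides,
                      target_gene = unname(target_of[guides]),
                      is_ntc = library$is_ntc),
      motif_enrichment = tibble(motif = motifs, effect = unname(enrich)),
      modules = modules,
      activity_shift = config$activity_shift
    )
  )
}
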