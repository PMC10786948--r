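# small constructed fixtures shared across test files

# long screen count tibble from a wide spec: list(vector_id = c(T0, T12_0Gy, T12_RT))
# the same values are used for every replicate unless a function is given
make_screen_counts <- function(spec, n_replicates = 3) {
  rows <- list()
  for (v in names(spec)) {
    vals <- spec[[v]]
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vector_id = v,
        timepoint = c("T0", "T12", "T12"),
        arm = c("0Gy", "0Gy", "RT"),
        replicate = r,
        count = as.numeric(vals)
      )
    }
  }
  dplyr::bind_rows(rows)
}

make_library <- function(vector_id, target_gene, is_ntc = NULL,
                         discordant = FALSE) {
  if (is.null(is_ntc)) is_ntc <- target_gene == "NTC"
  tibble::tibble(
    vector_id = vector_id, target_gene = target_gene,
    is_ntc = is_ntc, discordant = discordant
  )
}

# dense-to-cell_dataset helper: counts and guides given as plain matrices
make_cell_dataset <- function(counts, guides = NULL, condition = "0Gy",
                              lane = "L1") {
  barcodes <- colnames(counts) %||% sprintf("BC%03d", seq_len(ncol(counts)))
  colnames(counts) <- barcodes
  if (!is.null(guides)) colnames(guides) <- barcodes
  cells <- tibble::tibble(
    barcode = barcodes,
    condition = rep_len(condition, length(barcodes)),
    lane = rep_len(lane, length(barcodes))
  )
  cell_dataset(counts = counts, guides = guides, cells = cells)
}

`%||%` <- rlang::`%||%`

# brute-force promoter-overlap oracle for gene_activity_scores
oracle_gene_activity <- function(fragments, tss, upstream = 2000) {
  barcodes <- sort(unique(fragments$barcode))
  out <- matrix(0L, nrow(tss), length(barcodes),
                dimnames = list(tss$gene, barcodes))
  for (g in seq_len(nrow(tss))) {
    if (tss$strand[g] == "+") {
      ws <- tss$tss[g] - upstream; we <- tss$tss[g]
    } else {
      ws <- tss$tss[g] + 1L; we <- tss$tss[g] + upstream + 1L
    }
    for (f in seq_len(nrow(fragments))) {
      if (fragments$chrom[f] == tss$chrom[g] &&
          fragments$start[f] < we && fragments$end[f] > ws) {
        bc <- fragments$barcode[f]
        out[g, bc] <- out[g, bc] + 1L
      }
    }
  }
  out
}

# brute-force per-base coverage oracle for profile_matrix
oracle_profile <- function(fragments, centers, chrom, window, flank) {
  n_pos <- 2L * window + 1L
  cov <- numeric(n_pos)
  for (ct in centers) {
    for (f in seq_len(nrow(fragments))) {
      if (fragments$chrom[f] != chrom) next
      for (pos in seq(ct - window, ct + window)) {
        if (pos >= fragments$start[f] && pos < fragments$end[f]) {
          cov[pos - (ct - window) + 1L] <- cov[pos - (ct - window) + 1L] +
            fragments$count[f]
        }
      }
    }
  }
  cov <- cov / length(centers)
  flank_mean <- mean(cov[c(seq_len(flank), (n_pos - flank + 1L):n_pos)])
  list(coverage = cov, normalized = cov / flank_mean)
}
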