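#' Read and write perturbation-genomics file formats
#'
#' @description
#' Readers and writers for the plain-text formats the analysis functions
#' consume: Matrix Market triplet matrices with barcode/feature sidecars
#' (10x-style layout), ATAC fragment TSVs (BED-like, 0-based half-open),
#' BED6/GTF gene annotations, JASPAR position-frequency matrices, and
#' peak x motif membership TSVs. All coordinates are 0-based half-open
#' internally; conversions happen only at parse/emit boundaries.
#'
#' @name io-formats
NULL

#' Write a sparse matrix as Matrix Market triplets with sidecars
#'
#' Writes `matrix.mtx`, `barcodes.tsv` (column names) and `features.tsv`
#' (row names) into `dir`.
#'
#' @param m matrix (sparse or dense) with row and column names.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(m, dir) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must have row (feature) and column (barcode) names")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- Matrix::Matrix(m, sparse = TRUE)
  sm <- methods::as(methods::as(methods::as(sm, "dMatrix"), "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  readr::write_lines(colnames(m), file.path(dir, "barcodes.tsv"))
  readr::write_lines(rownames(m), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a Matrix Market triplet matrix with sidecars
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return sparse matrix with features as rows and barcodes as columns.
#' @export
read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(paste0("no matrix.mtx under ", dir))
  m <- Matrix::readMM(mtx)
  # Matrix Market files may use pattern/symmetric variants; normalise to a
  # general double sparse matrix
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  features <- readr::read_lines(file.path(dir, "features.tsv"))
  if (length(features) != nrow(m) || length(barcodes) != ncol(m)) {
    abort(sprintf(
      "sidecar mismatch: matrix is %d x %d but features=%d, barcodes=%d",
      nrow(m), ncol(m), length(features), length(barcodes)
    ))
  }
  dimnames(m) <- list(features, barcodes)
  m
}

validate_fragments <- function(fragments) {
  need <- c("chrom", "start", "end", "barcode", "count")
  missing <- setdiff(need, names(fragments))
  if (length(missing) > 0L) {
    abort(paste0("fragments missing columns: ", paste(missing, collapse = ", ")))
  }
  bad <- which(fragments$start >= fragments$end)
  if (length(bad) > 0L) {
    abort(paste0("fragments with start >= end at rows: ",
                 paste(head(bad, 10L), collapse = ", ")))
  }
  invisible(fragments)
}

#' Read an ATAC fragments file
#'
#' Five-column headerless TSV: chrom, start, end, barcode, duplicate count;
#' 0-based half-open coordinates. Lines with `start >= end` are rejected
#' with their row numbers.
#'
#' @param path fragments TSV (plain or gzip).
#' @return fragment tibble.
#' @export
read_fragments <- function(path) {
  fr <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), barcode = readr::col_character(),
      count = readr::col_integer()
    ),
    comment = "#", progress = FALSE
  )
  validate_fragments(fr)
}

#' Write an ATAC fragments file
#'
#' @param fragments fragment tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  validate_fragments(fragments)
  readr::write_tsv(
    fragments[, c("chrom", "start", "end", "barcode", "count")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Query fragments overlapping a region
#'
#' @param fragments fragment tibble.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return the overlapping fragment rows.
#' @export
query_fragments <- function(fragments, chrom, start, end) {
  filter(fragments, .data$chrom == !!chrom,
         .data$start < !!end, .data$end > !!start)
}

#' Read a TSS table from BED6 or GTF
#'
#' BED input (0-based half-open): the TSS is `start` for `+` strand features
#' and `end - 1` for `-` strand. GTF input (1-based inclusive) is converted
#' to 0-based internally; rows with `type == "gene"` (or all rows if none)
#' are used and the gene name is taken from the `gene_name` or `gene_id`
#' attribute.
#'
#' @param path BED or GTF file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gtf"`.
#' @return tibble with `gene`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_tss <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (format == "bed") {
    bed <- readr::read_tsv(
      path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "ciicdc", comment = "#", progress = FALSE
    )
    if (!all(bed$strand %in% c("+", "-"))) {
      abort("unknown strand symbol in BED input")
    }
    return(tibble(
      gene = bed$name, chrom = bed$chrom,
      tss = as.integer(ifelse(bed$strand == "+", bed$start, bed$end - 1L)),
      strand = bed$strand
    ))
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    name <- df$gene_name %||% df$gene_id
    if (is.null(name)) name <- as.character(seq_len(nrow(df)))
    if (!all(as.character(df$strand) %in% c("+", "-"))) {
      abort("unknown strand symbol in GTF input")
    }
    # GTF is 1-based inclusive; GRanges keeps that; convert to 0-based
    return(tibble(
      gene = name, chrom = as.character(df$seqnames),
      tss = as.integer(ifelse(df$strand == "+", df$start - 1L, df$end - 1L)),
      strand = as.character(df$strand)
    ))
  }
  gtf <- readr::read_tsv(
    path,
    col_names = c("chrom", "source", "type", "start", "end", "score",
                  "strand", "frame", "attributes"),
    col_types = "ccciicccc", comment = "#", progress = FALSE
  )
  if (any(gtf$type == "gene")) gtf <- gtf[gtf$type == "gene", , drop = FALSE]
  if (!all(gtf$strand %in% c("+", "-"))) {
    abort("unknown strand symbol in GTF input")
  }
  name <- stringr::str_match(gtf$attributes, 'gene_name "([^"]+)"')[, 2]
  fallback <- stringr::str_match(gtf$attributes, 'gene_id "([^"]+)"')[, 2]
  name <- dplyr::coalesce(name, fallback)
  tibble(
    gene = name, chrom = gtf$chrom,
    tss = as.integer(ifelse(gtf$strand == "+", gtf$start - 1L, gtf$end - 1L)),
    strand = gtf$strand
  )
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format (`>ID NAME` header followed by four
#' `A/C/G/T [counts]` rows) into column-normalised frequency matrices.
#'
#' @param path JASPAR PFM text file.
#' @return named list of 4 x L frequency matrices (rows A, C, G, T; columns
#'   sum to 1).
#' @export
read_motifs_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) abort("no JASPAR motif headers ('>') found")
  out <- list()
  for (h_idx in seq_along(headers)) {
    h <- headers[h_idx]
    stop_at <- if (h_idx < length(headers)) headers[h_idx + 1] - 1L else length(lines)
    block <- lines[(h + 1L):stop_at]
    if (length(block) < 4L) abort("JASPAR motif block with fewer than 4 rows")
    rows <- map(block[1:4], function(l) {
      stripped <- sub("^[ACGTacgt]\\s*", "", l)
      as.numeric(regmatches(stripped, gregexpr("[0-9.eE+-]+", stripped))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort("JASPAR motif rows of unequal length")
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    sums <- colSums(pfm)
    sums[sums == 0] <- 1
    freq <- sweep(pfm, 2L, sums, "/")
    id <- sub("^>\\s*", "", lines[h])
    id <- strsplit(id, "\\s+")[[1]][1]
    out[[id]] <- freq
  }
  out
}

#' Read a peak x motif membership table
#'
#' TSV with a `peak` column and one 0/1 column per motif.
#'
#' @param path membership TSV.
#' @return logical peaks x motifs matrix with dimnames.
#' @export
read_motif_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"peak" %in% names(tab)) abort("motif map needs a 'peak' column")
  m <- as.matrix(tab[, setdiff(names(tab), "peak"), drop = FALSE]) > 0
  rownames(m) <- tab$peak
  if (any(colSums(m) == 0)) abort("motif map has an empty motif column")
  m
}

#' Write a run manifest
#'
#' Records parameters, seed and package version as JSON alongside stage
#' outputs so a run can be reproduced bit-identically.
#'
#' @param path output JSON path.
#' @param params named list of stage parameters.
#' @param seed RNG seed used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed = NULL) {
  manifest <- list(
    package = "perturbkit",
    version = as.character(utils::packageVersion("perturbkit")),
    seed = seed,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
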