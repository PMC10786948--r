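# internal helpers shared across modules

# Welch two-sample t-test on numeric vectors with deterministic degenerate
# handling: equal means with zero variance on both sides -> p = 1; unequal
# means with zero variance -> variance floor so the test is defined.
welch_p <- function(x, y, var_floor = 1e-8) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    abort("t-test needs at least 2 values per side")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  mx <- mean(x)
  my <- mean(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(1)
    vx <- var_floor
    vy <- var_floor
  }
  vx <- max(vx, var_floor)
  vy <- max(vy, var_floor)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  min(1, 2 * pt(-abs(tstat), df))
}

# one-sample t-test of x against mu with the same degenerate conventions
one_sample_p <- function(x, mu = 0, var_floor = 1e-8) {
  n <- length(x)
  if (n < 2L) abort("one-sample t-test needs at least 2 values")
  v <- stats::var(x)
  m <- mean(x)
  if (v == 0) {
    if (m == mu) return(1)
    v <- var_floor
  }
  v <- max(v, var_floor)
  tstat <- (m - mu) / sqrt(v / n)
  min(1, 2 * pt(-abs(tstat), n - 1))
}

# complete-linkage hierarchical clustering order on rows of a matrix with
# 1 - Pearson correlation distance; degenerate inputs fall back to input order
pearson_hclust_order <- function(m) {
  if (nrow(m) < 3L) return(seq_len(nrow(m)))
  sds <- apply(m, 1L, sd)
  if (any(sds == 0) || ncol(m) < 2L) return(seq_len(nrow(m)))
  d <- as.dist(1 - cor(Matrix::t(m)))
  if (anyNA(d)) return(seq_len(nrow(m)))
  hclust(d, method = "complete")$order
}

# Fisher's method for combining independent p-values (NA components dropped)
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  p <- pmin(pmax(p, 1e-300), 1)
  stat <- -2 * sum(log(p))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  invisible(as.numeric(x))
}

# substream seed derivation: deterministic child seeds below 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + stream * 1009) %% .Machine$integer.max
}
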