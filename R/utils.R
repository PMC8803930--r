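#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom stats cor median phyper pnorm pt sd setNames hclust as.dist rnorm runif rbinom
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Vectorized Welch two-sample t-test over the columns of two matrices
# (rows = samples, columns = features). Equivalent to column-wise
# stats::t.test(x, y) with var.equal = FALSE.
welch_t_cols <- function(x, y) {
  nx <- nrow(x)
  ny <- nrow(y)
  mx <- colMeans(x)
  my <- colMeans(y)
  vx <- colSums(sweep(x, 2L, mx)^2) / (nx - 1L)
  vy <- colSums(sweep(y, 2L, my)^2) / (ny - 1L)
  se2 <- vx / nx + vy / ny
  tstat <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance, zero-difference columns: t = 0/0; treat as no evidence
  degenerate <- se2 == 0
  if (any(degenerate)) {
    tstat[degenerate] <- 0
    p[degenerate] <- 1
    df[degenerate] <- nx + ny - 2L
  }
  list(statistic = tstat, df = df, p_value = p,
       mean_ref = mx, mean_alt = my)
}

# Pooled-variance (Student) two-sample t over columns
student_t_cols <- function(x, y) {
  nx <- nrow(x)
  ny <- nrow(y)
  mx <- colMeans(x)
  my <- colMeans(y)
  sp2 <- (colSums(sweep(x, 2L, mx)^2) + colSums(sweep(y, 2L, my)^2)) /
    (nx + ny - 2L)
  se2 <- sp2 * (1 / nx + 1 / ny)
  tstat <- (my - mx) / sqrt(se2)
  df <- rep(nx + ny - 2L, length(tstat))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    tstat[degenerate] <- 0
    p[degenerate] <- 1
  }
  list(statistic = tstat, df = df, p_value = p,
       mean_ref = mx, mean_alt = my)
}

# Wilcoxon rank-sum over columns; normal approximation with tie and
# continuity correction (the snRNA-seq convention for tied counts).
wilcoxon_cols <- function(x, y) {
  nx <- nrow(x)
  ny <- nrow(y)
  stat <- p <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- rank(c(x[, j], y[, j]))
    w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    nties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- (nx * ny / 12) *
      ((nx + ny + 1) - sum(nties^3 - nties) / ((nx + ny) * (nx + ny - 1)))
    z <- w - mu
    correction <- sign(z) * 0.5
    z <- if (sigma2 > 0) (z - correction) / sqrt(sigma2) else 0
    stat[j] <- w
    p[j] <- min(1, 2 * pnorm(abs(z), lower.tail = FALSE))
  }
  list(statistic = stat, df = rep(NA_real_, ncol(x)), p_value = p,
       mean_ref = colMeans(x), mean_alt = colMeans(y))
}

# spawn reproducible 31-bit sub-seeds from a master seed
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
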