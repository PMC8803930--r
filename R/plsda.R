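#' PLS-DA ordination of an auto-scaled abundance table
#'
#' Two-block partial least squares against a one-hot class response
#' (PLS-DA), fitted by the NIPALS algorithm with deterministic
#' initialization (the first response column), so results are fully
#' reproducible without a seed. Scores maximize covariance between the
#' metabolite block and the class indicator.
#'
#' @param m An abundance table at stage `auto_scaled`.
#' @param design Design tibble with `sample_id` and `group` giving the
#'   class labels (at least 2 classes, each with at least 2 samples).
#' @param n_components Number of latent components (default 2).
#' @param max_iter,tol NIPALS iteration controls.
#' @return An object of class `regen_plsda` with the score matrix,
#'   loadings and per-component explained variance; [tidy()] returns
#'   the scores as a tibble, [glance()] the variance summary and
#'   [ggplot2::autoplot()] a score scatter plot.
#' @export
plsda_ordination <- function(m, design, n_components = 2,
                             max_iter = 500L, tol = 1e-10) {
  if (abundance_stage(m) != "auto_scaled") {
    stop("plsda_ordination() expects an auto_scaled table", call. = FALSE)
  }
  v <- abund_values(m)
  design <- dplyr::filter(design, .data$sample_id %in% rownames(v))
  v <- v[design$sample_id, , drop = FALSE]
  classes <- design$group
  lev <- sort(unique(classes))
  if (length(lev) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(classes) < 2L)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  n <- nrow(v)
  if (n_components > min(n - 1L, ncol(v))) {
    stop("n_components exceeds the rank of the data", call. = FALSE)
  }
  # one-hot, column-centered response
  y <- outer(classes, lev, `==`) * 1
  y <- sweep(y, 2L, colMeans(y))
  x <- sweep(v, 2L, colMeans(v))
  ssx_total <- sum(x^2)
  ssy_total <- sum(y^2)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, ncol(v), n_components,
                     dimnames = list(colnames(v), NULL))
  weights <- matrix(0, ncol(v), n_components)
  r2x <- r2y <- numeric(n_components)
  for (h in seq_len(n_components)) {
    u <- y[, 1L]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(x, u))
      w <- w / sqrt(sum(w^2))
      t_h <- drop(x %*% w)
      q <- drop(crossprod(y, t_h))
      q <- q / sqrt(sum(q^2))
      u <- drop(y %*% q)
      if (sum((t_h - t_old)^2) < tol * sum(t_h^2)) break
      t_old <- t_h
    }
    p <- drop(crossprod(x, t_h)) / sum(t_h^2)
    b <- sum(u * t_h) / sum(t_h^2)
    scores[, h] <- t_h
    loadings[, h] <- p
    weights[, h] <- w
    r2x[h] <- sum(outer(t_h, p)^2) / ssx_total
    r2y[h] <- sum((b * outer(t_h, q))^2) / ssy_total
    x <- x - outer(t_h, p)
    y <- y - b * outer(t_h, q)
  }
  colnames(scores) <- colnames(loadings) <- colnames(weights) <-
    paste0("comp", seq_len(n_components))
  structure(list(
    scores = tibble::tibble(sample_id = design$sample_id, group = classes) |>
      dplyr::bind_cols(tibble::as_tibble(scores)),
    loadings = loadings, weights = weights,
    r2x = r2x, r2y = r2y, classes = lev, n_components = n_components
  ), class = "regen_plsda")
}

#' @export
print.regen_plsda <- function(x, ...) {
  cat("PLS-DA ordination:", nrow(x$scores), "samples,",
      nrow(x$loadings), "metabolites,", x$n_components, "components\n")
  cat("  R2X:", paste(signif(x$r2x, 3), collapse = ", "), "\n")
  cat("  R2Y:", paste(signif(x$r2y, 3), collapse = ", "), "\n")
  invisible(x)
}
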