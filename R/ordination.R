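#' Bray-Curtis dissimilarity matrix
#'
#' For non-negative profiles \eqn{x_i, x_j} the Bray-Curtis index is
#' \deqn{d_{ij} = \sum_v |x_{iv} - x_{jv}| \; / \; \sum_v (x_{iv} + x_{jv}),}
#' bounded in \[0, 1\]: 0 for identical profiles, 1 for disjoint support.
#'
#' @param table a [sample_table()] or non-negative numeric matrix,
#'   samples in rows.
#' @return A square symmetric matrix of class `distance_matrix` with the
#'   sample ids as dimnames.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' bray_curtis(m)  # 4/12
#' @export
bray_curtis <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- sum(x[i, ] + x[j, ])
      if (tot == 0)
        stop(sprintf("samples '%s' and '%s' are both all-zero; dissimilarity undefined",
                     rownames(x)[i], rownames(x)[j]))
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / tot
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

# least-squares monotone fit of y on the rank order of delta
# ("primary" tie handling: tied dissimilarities are free to fit their
# configuration distances in any order, implemented by breaking delta
# ties on ascending y before pooling adjacent violators)
monotone_fit <- function(delta, y) {
  ord <- order(delta, y)
  fit <- stats::isoreg(y[ord])$yf
  out <- numeric(length(y))
  out[ord] <- fit
  out
}

lower_tri <- function(m) m[lower.tri(m)]

config_dist <- function(x) as.matrix(stats::dist(x))

# Kruskal stress-1 of a configuration against dissimilarities delta:
# sqrt( sum((dhat - D)^2) / sum(D^2) ), dhat the monotone fit of D on
# the delta ranks. Scale-invariant in the configuration.
stress1 <- function(delta_vec, d_vec) {
  dhat <- monotone_fit(delta_vec, d_vec)
  sqrt(sum((dhat - d_vec)^2) / sum(d_vec^2))
}

#' Nonmetric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions so that the rank order
#' of configuration distances matches the rank order of the input
#' dissimilarities, minimizing Kruskal stress-1
#' \deqn{S = \sqrt{\sum_{i<j} (\hat d_{ij} - D_{ij})^2 / \sum_{i<j} D_{ij}^2}}
#' where \eqn{D} are configuration distances and \eqn{\hat d} their
#' least-squares monotone (isotonic) regression on the dissimilarity
#' ranks (primary tie handling).  Optimization is iterative majorization:
#' each iteration fits \eqn{\hat d} by pool-adjacent-violators, rescales
#' it to fixed norm, and applies the Guttman transform; the reported
#' stress is re-evaluated from the raw monotone fit and is non-increasing
#' over iterations by construction (the update is rolled back and the
#' restart stopped if it ever fails to decrease).  The first restart
#' starts from classical metric scaling of the dissimilarities; further
#' restarts are seeded random configurations, and the lowest-stress
#' restart is returned with coordinates centered and rotated to their
#' principal axes.
#'
#' @param dist a square symmetric dissimilarity matrix
#'   (e.g. [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param n_restarts number of starts (default 20; one metric start plus
#'   random starts).
#' @param max_iter iteration cap per restart (default 500).
#' @param tol convergence threshold (default 1e-7): a restart stops when
#'   the relative stress decrease falls below `tol`, or when stress
#'   itself does (an essentially perfect ordinal embedding).
#' @param seed integer seed for the random starts.
#' @return An object of class `nmds`: list with `coordinates` (samples x
#'   k), `stress` (stress-1, on the 0-1 scale), `r2_nonlinear`,
#'   `r2_linear`, `per_sample_fit` (per-sample sum of squared monotone
#'   residuals; larger = worse fitted, used for bubble sizing),
#'   `n_restarts_used`, `converged`, `stress_trace` (per-iteration stress
#'   of the best restart), and the input `dissimilarity`.
#' @seealso [shepard_fit()]
#' @export
nmds <- function(dist, k = 2L, n_restarts = 20L, max_iter = 500L,
                 tol = 1e-7, seed = 1L) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("dissimilarity matrix must be square and symmetric")
  if (k < 1L || n_restarts < 1L) stop("k and n_restarts must be >= 1")
  n <- nrow(d)
  delta_vec <- lower_tri(d)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  metric_start <- suppressWarnings(
    stats::cmdscale(d, k = k, add = FALSE))
  if (ncol(metric_start) < k)   # degenerate input: pad with zeros
    metric_start <- cbind(metric_start,
                          matrix(0, n, k - ncol(metric_start)))
  starts <- c(list(metric_start),
              replicate(n_restarts - 1L,
                        matrix(stats::rnorm(n * k), n, k),
                        simplify = FALSE))

  best <- NULL
  for (x0 in starts) {
    run <- nmds_one_start(x0, delta_vec, n, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }

  # center and rotate to principal axes; fix a sign convention so output
  # is deterministic up to the optimizer
  x <- scale(best$x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- sv$u %*% diag(sv$d, k, k)
  flip <- apply(x, 2, function(col) if (sum(col^3) < 0) -1 else 1)
  x <- sweep(x, 2, flip, `*`)
  rownames(x) <- rownames(d)
  colnames(x) <- paste0("NMDS", seq_len(k))

  res <- structure(list(coordinates = x, stress = best$stress,
                        n_restarts_used = n_restarts,
                        converged = best$converged,
                        stress_trace = best$trace,
                        dissimilarity = d),
                   class = "nmds")
  sf <- shepard_fit(d, res)
  res$r2_nonlinear <- sf$r2_nonlinear
  res$r2_linear <- sf$r2_linear
  res$per_sample_fit <- sf$per_sample_fit
  if (!res$converged)
    warning("NMDS did not reach the convergence threshold in max_iter iterations")
  res
}

nmds_one_start <- function(x, delta_vec, n, k, max_iter, tol) {
  m <- length(delta_vec)
  target_norm <- sqrt(m)           # dhat normalized to fixed sum of squares
  dmat <- config_dist(x)
  s_prev <- stress1(delta_vec, lower_tri(dmat))
  trace <- s_prev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d_vec <- lower_tri(dmat)
    dhat <- monotone_fit(delta_vec, d_vec)
    nrm <- sqrt(sum(dhat^2))
    if (nrm == 0) break
    dhat <- dhat * target_norm / nrm
    # Guttman transform with B-matrix built from dhat/D ratios
    ratio <- matrix(0, n, n)
    ratio[lower.tri(ratio)] <- ifelse(d_vec > 0, dhat / d_vec, 0)
    ratio <- ratio + t(ratio)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x_new <- (b %*% x) / n
    d_new <- config_dist(x_new)
    s_new <- stress1(delta_vec, lower_tri(d_new))
    if (s_new > s_prev) { converged <- TRUE; break }  # majorization floor
    x <- x_new
    dmat <- d_new
    trace <- c(trace, s_new)
    # near-zero stress decays geometrically, so a relative criterion
    # alone would never fire on perfectly embeddable input
    if (s_new < tol ||
        s_prev - s_new < tol * max(s_prev, .Machine$double.eps)) {
      converged <- TRUE
      s_prev <- s_new
      break
    }
    s_prev <- s_new
  }
  list(x = x, stress = s_prev, converged = converged, trace = trace)
}

#' Shepard-diagram goodness of fit
#'
#' Relates configuration distances \eqn{D} to the original
#' dissimilarities: `r2_nonlinear` is the coefficient of determination of
#' the monotone (isotonic) fit, \eqn{1 - \sum(D - \hat d)^2 / \sum(D -
#' \bar D)^2}; `r2_linear` is the squared Pearson correlation of \eqn{D}
#' with the original dissimilarities; `per_sample_fit[i]` sums the
#' squared monotone residuals over all pairs involving sample `i`
#' (larger = worse fitted).
#'
#' @param dist the dissimilarity matrix the ordination was built from.
#' @param result an [nmds()] result on the same samples.
#' @return A list with `r2_nonlinear`, `r2_linear`, `per_sample_fit`.
#' @export
shepard_fit <- function(dist, result) {
  d <- as.matrix(dist)
  x <- result$coordinates
  if (nrow(d) != nrow(x) ||
      !identical(rownames(d), rownames(x)))
    stop("sample sets of 'dist' and 'result' do not match")
  dmat <- config_dist(x)
  delta_vec <- lower_tri(d)
  d_vec <- lower_tri(dmat)
  dhat <- monotone_fit(delta_vec, d_vec)
  resid2 <- (d_vec - dhat)^2
  r2_nonlinear <- 1 - sum(resid2) / sum((d_vec - mean(d_vec))^2)
  r2_linear <- stats::cor(d_vec, delta_vec)^2
  n <- nrow(d)
  rmat <- matrix(0, n, n)
  rmat[lower.tri(rmat)] <- resid2
  rmat <- rmat + t(rmat)
  per_sample <- rowSums(rmat)
  names(per_sample) <- rownames(d)
  list(r2_nonlinear = r2_nonlinear, r2_linear = r2_linear,
       per_sample_fit = per_sample)
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("Nonmetric MDS, %d samples in %d dimension(s)\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat(sprintf("  stress-1: %.4f  (converged: %s, %d restarts)\n",
              x$stress, x$converged, x$n_restarts_used))
  cat(sprintf("  Shepard R2: non-linear %.4f, linear %.4f\n",
              x$r2_nonlinear, x$r2_linear))
  invisible(x)
}

#' @export
#' @rdname nmds
#' @param x an `nmds` object.
#' @param groups optional factor over samples used to color points.
#' @param ... further arguments to [graphics::plot()].
plot.nmds <- function(x, groups = NULL, ...) {
  co <- x$coordinates
  # bubble area proportional to per-sample misfit, as in Shepard bubble plots
  fit <- x$per_sample_fit
  cex <- 1 + 2 * sqrt(fit / max(fit, .Machine$double.eps))
  col <- if (is.null(groups)) "black" else as.integer(as.factor(groups)) + 1L
  graphics::plot(co[, 1], co[, 2], cex = cex, col = col,
                 xlab = colnames(co)[1], ylab = colnames(co)[2],
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}
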