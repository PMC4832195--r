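#' Hellinger transformation
#'
#' Row-wise square-root of relative abundances:
#' \eqn{y'_{iv} = \sqrt{y_{iv} / \sum_v y_{iv}}}.  Every transformed row
#' has unit sum of squares, which makes non-negative profile data
#' suitable for Euclidean-based ordination and redundancy analysis.
#'
#' @param table a [sample_table()] or non-negative matrix, samples in
#'   rows.
#' @return A numeric matrix of the same shape.
#' @examples
#' hellinger(rbind(a = c(1, 3)))  # sqrt(1/4), sqrt(3/4)
#' @export
hellinger <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("Hellinger transform requires non-negative values")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  out <- sqrt(sweep(x, 1, rs, `/`))
  dimnames(out) <- dimnames(x)
  out
}

#' Build an explanatory block for variance partitioning
#'
#' Expands an explanatory variable into a design-matrix block: numeric
#' vectors become one centered column; factors/characters become 0/1
#' indicator columns with the first level dropped.
#'
#' @param x numeric vector or factor/character vector over samples.
#' @param name block label.
#' @return A list of class `explanatory_block` with `name` and
#'   `design_matrix`.
#' @export
explanatory_block <- function(x, name = deparse(substitute(x))) {
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    lev <- levels(droplevels(x))
    if (length(lev) < 2L)
      stop(sprintf("block '%s' has a single level; no variance to attribute", name))
    m <- stats::model.matrix(~ x)[, -1L, drop = FALSE]
    colnames(m) <- paste0(name, lev[-1L])
  } else {
    m <- matrix(as.numeric(x) - mean(as.numeric(x)), ncol = 1L,
                dimnames = list(NULL, name))
  }
  if (qr(m)$rank < ncol(m))
    stop(sprintf("block '%s' has linearly dependent columns", name))
  structure(list(name = name, design_matrix = m),
            class = "explanatory_block")
}

block_matrix <- function(blocks) {
  do.call(cbind, lapply(blocks, function(b) b$design_matrix))
}

#' Adjusted redundancy-analysis R-squared
#'
#' Fraction of the total centered variance of a multivariate response
#' explained by the least-squares projection onto the predictor space,
#' with the Ezekiel small-sample correction
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\frac{n - 1}{n - m - 1}}
#' where `m` is the number of predictor columns.  Adjusted R-squared can
#' be negative, which is what makes negative shared fractions in
#' variance partitioning meaningful.
#'
#' @param response numeric matrix (samples x variables), typically
#'   Hellinger-transformed; it is column-centered internally.
#' @param predictors an [explanatory_block()] or list of blocks.
#' @param allow_aliased if `FALSE` (default) linearly dependent predictor
#'   columns are an error naming the aliased columns; if `TRUE` the
#'   projection uses the column space as-is and `m` is the matrix rank
#'   (needed when two blocks of a partition overlap or coincide).
#' @return Named list with `r2`, `adj_r2`, `m` (predictor rank), `n`.
#' @export
rda_adjusted_r2 <- function(response, predictors, allow_aliased = FALSE) {
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  if (inherits(predictors, "explanatory_block"))
    predictors <- list(predictors)
  x <- block_matrix(predictors)
  n <- nrow(y)
  if (nrow(x) != n) stop("predictor rows must align with response samples")
  m <- ncol(x)
  if (m >= n - 1L)
    stop("too many predictor columns for the sample size (m >= n - 1)")
  q <- qr(scale(x, center = TRUE, scale = FALSE))
  if (q$rank < m) {
    if (!allow_aliased) {
      aliased <- colnames(x)[setdiff(seq_len(m), q$pivot[seq_len(q$rank)])]
      stop("rank-deficient predictors; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
    m <- q$rank
  }
  fitted <- qr.fitted(q, y)
  ss_tot <- sum(y^2)
  r2 <- sum(fitted^2) / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  list(r2 = r2, adj_r2 = adj, m = m, n = n)
}

#' Three-way variance partitioning
#'
#' Partitions the variance of a (Hellinger-transformed) response among
#' three explanatory blocks into unique fractions `a`, `b`, `c`,
#' pairwise-shared `ab`, `ac`, `bc`, triple-shared `abc`, and `residual`,
#' via adjusted R-squared of the seven non-empty block unions and
#' inclusion-exclusion:
#' `a = R2adj(ABC) - R2adj(BC)` and so on.  Shared fractions can be
#' negative under the adjusted correction and are reported as-is.  The
#' eight fractions sum to one exactly.
#'
#' @param response numeric matrix, samples x variables.
#' @param block_a,block_b,block_c [explanatory_block()]s.
#' @param n_permutations permutations for testing the three unique
#'   fractions (0 to skip the tests).
#' @param seed seed for the permutation tests.
#' @return Object of class `vpa`: fractions (on the proportion scale),
#'   `total_explained`, `residual`, per-union adjusted R2, block names,
#'   and `pvalues` for the individually testable fractions.
#' @seealso [fraction_significance()]
#' @export
variance_partition <- function(response, block_a, block_b, block_c,
                               n_permutations = 999L, seed = 1L) {
  y <- as.matrix(response)
  blocks <- list(a = block_a, b = block_b, c = block_c)
  stopifnot(all(vapply(blocks, inherits, TRUE, "explanatory_block")))
  adj <- function(which) rda_adjusted_r2(y, blocks[which],
                                         allow_aliased = TRUE)$adj_r2
  A1 <- adj("a"); A2 <- adj("b"); A3 <- adj("c")
  A12 <- adj(c("a", "b")); A13 <- adj(c("a", "c")); A23 <- adj(c("b", "c"))
  A123 <- adj(c("a", "b", "c"))

  a <- A123 - A23
  b <- A123 - A13
  c_ <- A123 - A12
  ab <- (A123 - A3) - a - b
  ac <- (A123 - A2) - a - c_
  bc <- (A123 - A1) - b - c_
  abc <- A123 - a - b - c_ - ab - ac - bc
  residual <- 1 - A123

  pvals <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  if (n_permutations > 0L) {
    for (fr in c("a", "b", "c"))
      pvals[fr] <- fraction_significance(y, blocks, fr,
                                         n_permutations = n_permutations,
                                         seed = seed)
  }

  structure(list(
    fractions = c(a = a, b = b, c = c_, ab = ab, ac = ac, bc = bc,
                  abc = abc, residual = residual),
    total_explained = A123, residual = residual,
    adj_r2 = c(a = A1, b = A2, c = A3, ab = A12, ac = A13, bc = A23,
               abc = A123),
    block_names = vapply(blocks, `[[`, "", "name"),
    pvalues = pvals,
    n_permutations = n_permutations), class = "vpa")
}

#' Permutation test of a unique variance fraction
#'
#' Tests the unique (partial) contribution of one block given the other
#' two by partial redundancy analysis: the observed pseudo-F compares
#' the extra variance explained by the focal block over the reduced
#' (covariates-only) model with the residual variance of the full model.
#' The null distribution permutes the residuals of the reduced model
#' (i.e. `Y* = fitted_reduced + permuted residuals_reduced`), and
#' \deqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm}).}
#' Only the unique fractions `a`, `b`, `c` are individually testable;
#' shared fractions are not estimable as a single constrained model.
#'
#' @param response numeric matrix, samples x variables.
#' @param blocks named list of the three [explanatory_block()]s
#'   (`a`, `b`, `c`).
#' @param fraction_id `"a"`, `"b"` or `"c"`.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return The permutation p-value.
#' @export
fraction_significance <- function(response, blocks, fraction_id,
                                  n_permutations = 999L, seed = 1L) {
  if (!fraction_id %in% c("a", "b", "c"))
    stop("only the unique fractions 'a', 'b', 'c' are individually testable")
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  focal <- blocks[[fraction_id]]$design_matrix
  covar <- block_matrix(blocks[setdiff(c("a", "b", "c"), fraction_id)])
  n <- nrow(y)
  q_red <- qr(cbind(1, covar))
  q_full <- qr(cbind(1, covar, focal))
  m_full <- q_full$rank - 1L
  m_focal <- q_full$rank - q_red$rank
  if (m_focal < 1L) stop("focal block adds no rank over the covariates")

  pseudo_f <- function(yy) {
    ss_red <- sum(qr.resid(q_red, yy)^2)
    ss_full <- sum(qr.resid(q_full, yy)^2)
    ((ss_red - ss_full) / m_focal) / (ss_full / (n - m_full - 1L))
  }
  f_obs <- pseudo_f(y)

  fitted_red <- qr.fitted(q_red, y)
  resid_red <- y - fitted_red
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample.int(n)
    if (pseudo_f(fitted_red + resid_red[perm, , drop = FALSE]) >= f_obs)
      exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_permutations)
}

#' @export
print.vpa <- function(x, ...) {
  fr <- x$fractions * 100
  nm <- x$block_names
  cat("Variance partitioning (adjusted R2, % of total variance)\n")
  cat(sprintf("  %s: %.2f%%   %s: %.2f%%   %s: %.2f%%\n",
              nm[1], fr["a"], nm[2], fr["b"], nm[3], fr["c"]))
  cat(sprintf("  %s&%s: %.2f%%   %s&%s: %.2f%%   %s&%s: %.2f%%   all: %.2f%%\n",
              nm[1], nm[2], fr["ab"], nm[1], nm[3], fr["ac"],
              nm[2], nm[3], fr["bc"], fr["abc"]))
  cat(sprintf("  explained: %.2f%%   residual: %.2f%%\n",
              x$total_explained * 100, fr["residual"]))
  if (!all(is.na(x$pvalues)))
    cat(sprintf("  permutation p (unique fractions): %s\n",
                paste(sprintf("%s=%.3g", names(x$pvalues), x$pvalues),
                      collapse = ", ")))
  invisible(x)
}
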