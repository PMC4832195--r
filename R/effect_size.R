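#' Per-treatment summary statistics for one variable
#'
#' Pools all samples of a treatment across sites (the study design gives
#' n = 4 sites x 3 replicates = 12 per treatment) and returns the mean,
#' sample standard deviation (n - 1 denominator) and count, the inputs
#' of the log response ratio.
#'
#' @param table a [sample_table()].
#' @param metadata matching `sample_metadata`.
#' @param variable_id variable to summarize.
#' @param treatment `"CF"` or `"COF"`.
#' @return List of class `group_stats`: `treatment`, `mean`, `sd`, `n`.
#' @export
group_stats <- function(table, metadata, variable_id, treatment) {
  treatment <- match.arg(toupper(treatment), c("CF", "COF"))
  if (!variable_id %in% colnames(table))
    stop("unknown variable: ", variable_id)
  ids <- metadata$sample_id[metadata$fertilization == treatment]
  ids <- intersect(rownames(table), ids)
  if (length(ids) < 2L)
    stop("need >= 2 samples in treatment ", treatment)
  x <- table[ids, variable_id]
  m <- mean(x)
  if (m <= 0)
    stop(sprintf("non-positive mean for '%s' in %s; log ratio undefined",
                 variable_id, treatment))
  structure(list(treatment = treatment, mean = m, sd = stats::sd(x),
                 n = length(x)), class = "group_stats")
}

#' Natural-log response ratio and its sampling variance
#'
#' The response ratio of organic-plus-mineral (COF) relative to
#' mineral-only (CF) fertilization is
#' \deqn{R = \ln(\bar X_{COF} / \bar X_{CF}),}
#' with delta-method sampling variance
#' \deqn{v = \frac{SD_{COF}^2}{n_{COF}\,\bar X_{COF}^2} +
#'           \frac{SD_{CF}^2}{n_{CF}\,\bar X_{CF}^2}}
#' and meta-analytic weight \eqn{w = 1/v}.
#'
#' @param cof,cf [group_stats()] for the two treatments.
#' @return `response_ratio()`: the scalar `R`; `rr_variance()`: the
#'   scalar `v` (0 when both SDs are 0, in which case the weight is
#'   undefined and the confidence interval collapses to a point).
#' @export
response_ratio <- function(cof, cf) {
  if (cof$mean <= 0 || cf$mean <= 0)
    stop("log response ratio requires positive group means")
  log(cof$mean / cf$mean)
}

#' @rdname response_ratio
#' @export
rr_variance <- function(cof, cf) {
  if (cof$mean <= 0 || cf$mean <= 0)
    stop("sampling variance requires positive group means")
  if (cof$n < 2L || cf$n < 2L) stop("both groups need n >= 2")
  cof$sd^2 / (cof$n * cof$mean^2) + cf$sd^2 / (cf$n * cf$mean^2)
}

#' Confidence interval and significance call for a response ratio
#'
#' \eqn{CI = R \pm \lambda \sqrt{v}} with \eqn{\lambda = 1.96} for a 95%
#' interval; the effect is significant exactly when the interval
#' excludes zero.
#'
#' @param R log response ratio.
#' @param v its sampling variance (>= 0).
#' @param lambda critical multiplier (default 1.96).
#' @return List with `ci_low`, `ci_high`, `significant`.
#' @export
confidence_interval <- function(R, v, lambda = 1.96) {
  if (v < 0) stop("negative sampling variance")
  half <- lambda * sqrt(v)
  lo <- R - half
  hi <- R + half
  list(ci_low = lo, ci_high = hi, significant = (lo > 0 || hi < 0))
}

#' Response-ratio table over all ions and enzymes
#'
#' Computes the weighted log response ratio of COF versus CF for every
#' variable of the ion and enzyme tables, pooled across sites, with
#' sampling variance, weight, 95% confidence interval and significance
#' call.  Variables whose group mean is non-positive (log ratio
#' undefined) are retained in the table with `excluded_reason` set and
#' `NA` statistics.
#'
#' @param ion_table,enzyme_table [sample_table()]s (either may be `NULL`).
#' @param metadata matching `sample_metadata`.
#' @param lambda critical multiplier for the confidence interval
#'   (default 1.96, i.e. 95%).
#' @return Data frame of class `rr_table`, one row per variable in input
#'   order: `variable_id`, `category`, `R`, `v`, `w`, `ci_low`,
#'   `ci_high`, `significant`, `n_cof`, `n_cf`, `excluded_reason`.
#' @examples
#' d <- generate_dataset(synth_config(seed = 3))
#' rr <- rr_table(d$ions, d$enzymes, d$metadata)
#' head(rr[order(rr$R), c("variable_id", "R", "ci_low", "ci_high")])
#' @export
rr_table <- function(ion_table, enzyme_table, metadata, lambda = 1.96) {
  tabs <- Filter(Negate(is.null), list(ion_table, enzyme_table))
  if (length(tabs) == 0L) stop("at least one table is required")
  rows <- list()
  for (tab in tabs) {
    cats <- attr(tab, "category")
    for (j in seq_len(ncol(tab))) {
      vid <- colnames(tab)[j]
      rec <- data.frame(variable_id = vid, category = cats[j],
                        R = NA_real_, v = NA_real_, w = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        significant = NA, n_cof = NA_integer_,
                        n_cf = NA_integer_, excluded_reason = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        cof <- group_stats(tab, metadata, vid, "COF")
        cf <- group_stats(tab, metadata, vid, "CF")
        R <- response_ratio(cof, cf)
        v <- rr_variance(cof, cf)
        ci <- confidence_interval(R, v, lambda)
        rec$R <- R; rec$v <- v
        rec$w <- if (v > 0) 1 / v else NA_real_
        rec$ci_low <- ci$ci_low; rec$ci_high <- ci$ci_high
        rec$significant <- ci$significant
        rec$n_cof <- cof$n; rec$n_cf <- cf$n
        if (v == 0) rec$excluded_reason <- "zero variance; weight undefined"
        rec
      }, error = function(e) {
        rec$excluded_reason <- conditionMessage(e)
        rec
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rr_table", "data.frame")
  out
}

#' @export
print.rr_table <- function(x, digits = 4, ...) {
  cat(sprintf("Log response ratios (COF vs CF), %d variable(s), %d significant\n",
              nrow(x), sum(x$significant, na.rm = TRUE)))
  df <- as.data.frame(x)
  df$excluded_reason <- NULL
  print(format(df, digits = digits), row.names = FALSE, ...)
  excl <- x$variable_id[nzchar(x$excluded_reason)]
  if (length(excl) > 0)
    cat("excluded: ", paste(excl, collapse = ", "), "\n")
  invisible(x)
}

#' Forest-style plot of response ratios
#'
#' @param x an [rr_table()] result.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.rr_table <- function(x, ...) {
  ok <- !is.na(x$R)
  df <- x[ok, ]
  idx <- rev(seq_len(nrow(df)))
  graphics::plot(df$R, idx, xlim = range(df$ci_low, df$ci_high, 0),
                 pch = 19, col = "steelblue", yaxt = "n",
                 xlab = "ln(COF / CF)", ylab = "", ...)
  graphics::segments(df$ci_low, idx, df$ci_high, idx)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = idx, labels = df$variable_id, las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
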