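test_that("Hellinger transform matches the formula and vegan", {
  expect_equal(hellinger(rbind(a = c(1, 1, 1, 1)))[1, ],
               c(0.5, 0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_equal(hellinger(rbind(a = c(4, 0)))[1, ], c(1, 0),
               ignore_attr = TRUE)
  expect_equal(hellinger(rbind(a = c(1, 3)))[1, ],
               c(sqrt(1 / 4), sqrt(3 / 4)), ignore_attr = TRUE)
  set.seed(1)
  x <- matrix(rlnorm(6 * 4), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  h <- hellinger(x)
  expect_equal(rowSums(h^2), rep(1, 6), ignore_attr = TRUE)
  skip_if_not_installed("vegan")
  expect_equal(h, vegan::decostand(x, "hellinger"), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(hellinger(rbind(s1 = c(0, 0))), "s1")
})

test_that("adjusted R2 follows the Ezekiel formula and a normal-equations oracle", {
  # exact linear response: R2 = adjusted R2 = 1
  set.seed(2)
  x <- rnorm(24)
  y <- cbind(2 * x, -x, 0.5 * x)
  got <- rda_adjusted_r2(y, explanatory_block(x, "x"))
  expect_equal(got$r2, 1, tolerance = 1e-12)
  expect_equal(got$adj_r2, 1, tolerance = 1e-12)

  # predictor orthogonal to the response at n = 24, m = 1: adj R2 = -1/22
  y0 <- scale(matrix(rnorm(24 * 3), 24, 3), center = TRUE, scale = FALSE)
  ortho <- qr.resid(qr(cbind(1, y0)), rnorm(24))
  got0 <- rda_adjusted_r2(y0, explanatory_block(ortho, "z"))
  expect_equal(got0$r2, 0, tolerance = 1e-12)
  expect_equal(got0$adj_r2, -1 / 22, tolerance = 1e-12)

  # 50 seeded instances against explicit normal equations
  for (s in 1:50) {
    set.seed(s)
    n <- 15 + s %% 10
    y <- matrix(rnorm(n * 4), n, 4)
    xb <- list(explanatory_block(rnorm(n), "x1"),
               explanatory_block(factor(sample(letters[1:3], n,
                                               replace = TRUE)), "f"))
    mine <- rda_adjusted_r2(y, xb)
    ref <- oracle_adj_r2(y, do.call(cbind, lapply(xb, `[[`,
                                                  "design_matrix")))
    expect_equal(mine$r2, ref$r2, tolerance = 1e-9)
    expect_equal(mine$adj_r2, ref$adj_r2, tolerance = 1e-9)
  }
  z <- rnorm(10)
  dup <- structure(list(name = "dup",
                        design_matrix = cbind(z1 = z, z2 = 2 * z)),
                   class = "explanatory_block")
  expect_error(rda_adjusted_r2(matrix(rnorm(30), 10, 3), dup), "aliased")
})

test_that("three-way partition closes to 1 and behaves analytically in constructed cases", {
  # single noise-free source with mutually orthogonal blocks: expected
  # fractions follow from plugging the known raw R2 into the Ezekiel formula
  n <- 24
  set.seed(3)
  # column-centered before QR so the orthogonality survives the centering
  # inside the redundancy analysis
  basis <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), center = TRUE,
                         scale = FALSE)))
  xa <- basis[, 1]; xb <- basis[, 2]; xc <- basis[, 3]
  y <- cbind(xa, 2 * xa, -xa)
  v <- variance_partition(y, explanatory_block(xa, "A"),
                          explanatory_block(xb, "B"),
                          explanatory_block(xc, "C"),
                          n_permutations = 0)
  adj <- function(r2, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)
  expect_equal(unname(v$fractions["a"]), 1 - adj(0, 2), tolerance = 1e-9)
  expect_equal(unname(v$fractions["b"]), 0, tolerance = 1e-9)
  expect_equal(unname(v$fractions["c"]), 0, tolerance = 1e-9)
  expect_equal(unname(v$fractions["residual"]), 0, tolerance = 1e-9)
  expect_equal(sum(v$fractions), 1, tolerance = 1e-12)
  expect_equal(v$total_explained, 1, tolerance = 1e-9)

  # closure and block-order invariance on noisy data
  d <- generate_dataset(synth_config(seed = 6))
  h <- hellinger(d$ions)
  md <- d$metadata
  blocks <- list(explanatory_block(md$pH, "pH"),
                 explanatory_block(md$site, "site"),
                 explanatory_block(md$fertilization, "fert"))
  v1 <- variance_partition(h, blocks[[1]], blocks[[2]], blocks[[3]],
                           n_permutations = 0)
  expect_equal(sum(v1$fractions), 1, tolerance = 1e-12)
  v2 <- variance_partition(h, blocks[[2]], blocks[[1]], blocks[[3]],
                           n_permutations = 0)
  expect_equal(unname(v2$fractions["a"]), unname(v1$fractions["b"]),
               tolerance = 1e-12)
  expect_equal(unname(v2$fractions["ab"]), unname(v1$fractions["ab"]),
               tolerance = 1e-12)
  expect_equal(unname(v2$fractions["bc"]), unname(v1$fractions["ac"]),
               tolerance = 1e-12)
})

test_that("a duplicated block moves its variance into the shared fraction", {
  n <- 30
  set.seed(4)
  basis <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), center = TRUE,
                         scale = FALSE)))
  xa <- basis[, 1]; xc <- basis[, 2]
  y <- cbind(xa, -3 * xa)
  v <- variance_partition(y, explanatory_block(xa, "A"),
                          explanatory_block(xa, "Bdup"),
                          explanatory_block(xc, "C"),
                          n_permutations = 0)
  expect_equal(unname(v$fractions["a"]), 0, tolerance = 1e-9)
  expect_equal(unname(v$fractions["b"]), 0, tolerance = 1e-9)
  expect_gt(unname(v$fractions["ab"]), 0.9)
  expect_equal(sum(v$fractions), 1, tolerance = 1e-12)
})

test_that("permutation test rejects strong effects, respects its lower bound, and only tests unique fractions", {
  set.seed(10)
  n <- 24
  xa <- rnorm(n)
  y <- cbind(xa + rnorm(n, 0, 0.4), -xa + rnorm(n, 0, 0.4))
  blocks <- list(a = explanatory_block(xa, "A"),
                 b = explanatory_block(rnorm(n), "B"),
                 c = explanatory_block(rnorm(n), "C"))
  p <- fraction_significance(y, blocks, "a", n_permutations = 999, seed = 1)
  expect_lte(p, 0.01)
  expect_equal(fraction_significance(y, blocks, "a", n_permutations = 999,
                                     seed = 1),
               p)  # seeded determinism
  # p can never undercut the add-one bound
  expect_gte(p, 1 / 1000)
  expect_error(fraction_significance(y, blocks, "ab"), "individually testable")
})

test_that("the permutation test holds its size under the null", {
  rej <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    y <- matrix(rnorm(20 * 5), 20, 5)
    blocks <- list(a = explanatory_block(rnorm(20), "a"),
                   b = explanatory_block(rnorm(20), "b"),
                   c = explanatory_block(factor(rep(c("u", "v"), 10)), "c"))
    p <- fraction_significance(y, blocks, "a", n_permutations = 99,
                               seed = i)
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.08)
})
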