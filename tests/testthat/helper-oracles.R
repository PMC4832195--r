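# Independent brute-force evaluators used to cross-check the package's
# numerics. Deliberately written from the defining formulas, not by
# calling the code paths they verify.

# pool-adjacent-violators: least-squares nondecreasing fit to y
oracle_pava <- function(y) {
  n <- length(y)
  val <- as.numeric(y)
  wt <- rep(1, n)
  idx <- 1L
  # block-merging sweep; restart after every merge
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(val)) {
      if (val[i] > val[i + 1L]) {
        new_val <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) /
          (wt[i] + wt[i + 1L])
        new_wt <- wt[i] + wt[i + 1L]
        val <- c(val[seq_len(i - 1L)], new_val,
                 val[-seq_len(i + 1L)])
        wt <- c(wt[seq_len(i - 1L)], new_wt, wt[-seq_len(i + 1L)])
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rep(val, wt)
}

# Kruskal stress-1 of a configuration given dissimilarities (matrix),
# primary tie handling (ties in delta ordered by ascending D)
oracle_stress1 <- function(delta, coords) {
  dmat <- as.matrix(stats::dist(coords))
  dv <- dmat[lower.tri(dmat)]
  del <- as.matrix(delta)[lower.tri(as.matrix(delta))]
  ord <- order(del, dv)
  dhat <- numeric(length(dv))
  dhat[ord] <- oracle_pava(dv[ord])
  sqrt(sum((dhat - dv)^2) / sum(dv^2))
}

# adjusted R2 through explicit normal equations and residual sums of squares
oracle_adj_r2 <- function(y, x) {
  y <- scale(y, center = TRUE, scale = FALSE)
  x1 <- cbind(1, x)
  beta <- solve(crossprod(x1), crossprod(x1, y))
  resid <- y - x1 %*% beta
  r2 <- 1 - sum(resid^2) / sum(y^2)
  m <- ncol(x)
  n <- nrow(y)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1))
}

# Newman modularity of a partition from first principles
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(c(edges$from, edges$to))
  q <- 0
  for (com in unique(membership)) {
    members <- names(membership)[membership == com]
    e_c <- sum(edges$from %in% members & edges$to %in% members)
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Pearson r from explicit sums
oracle_pearson <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Bray-Curtis for one pair by direct summation
oracle_bray <- function(xi, xj) sum(abs(xi - xj)) / sum(xi + xj)

# an arbitrary simple graph with the requested node and edge counts,
# as node/edge frames for correlation_network()
make_counted_graph <- function(n_nodes, n_edges, n_positive = n_edges) {
  ids <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2))
  stopifnot(n_edges <= nrow(pairs))
  # connect a spanning cycle first so every node has degree >= 1
  cyc <- cbind(ids, ids[c(2:n_nodes, 1)])
  keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  cyc_keys <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
  rest <- pairs[!keys %in% cyc_keys, , drop = FALSE]
  chosen <- rbind(cyc, rest)[seq_len(n_edges), , drop = FALSE]
  edges <- data.frame(from = chosen[, 1], to = chosen[, 2],
                      r = rep(c(0.9, -0.9),
                              c(n_positive, n_edges - n_positive)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(variable_id = ids, category = "ion",
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
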