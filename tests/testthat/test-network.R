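toy_corr <- function(r, cats, ids = colnames(r), n_obs = 12) {
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(r)))
  dimnames(r) <- list(ids, ids)
  p <- 2 * stats::pt(abs(r * sqrt(n_obs - 2) / sqrt(pmax(1 - r^2, 0))),
                     df = n_obs - 2, lower.tail = FALSE)
  p[!is.finite(p)] <- 0
  diag(p) <- 0
  structure(list(variable_ids = ids, category = cats, r = r,
                 p = p, n_obs = n_obs, dropped = character()),
            class = "correlation_result")
}

test_that("Pearson matrices match explicit sums and cor.test", {
  x <- sample_table(cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4),
                          c = c(4, 3, 2, 1)) * 1.0,
                    sample_ids = paste0("s", 1:4))
  res <- pearson_matrix(x)
  expect_equal(res$r["a", "b"], 0.8)
  expect_equal(res$r["a", "c"], -1)
  expect_equal(diag(res$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(res$r, t(res$r))
  expect_equal(res$p, t(res$p))

  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(paste0("s", 1:12), letters[1:4]))
    res <- pearson_matrix(m)
    for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
      i <- pair[1]; j <- pair[2]
      expect_equal(res$r[i, j], oracle_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
      ct <- cor.test(m[, i], m[, j])
      expect_equal(res$p[i, j], unname(ct$p.value), tolerance = 1e-12)
    }
  }
})

test_that("zero-variance variables are dropped with a warning, small samples rejected", {
  m <- cbind(a = rnorm(6), b = rep(2, 6), c = rnorm(6))
  rownames(m) <- paste0("s", 1:6)
  expect_warning(res <- pearson_matrix(m), "zero-variance.*b")
  expect_equal(res$dropped, "b")
  expect_setequal(res$variable_ids, c("a", "c"))
  expect_error(pearson_matrix(m[1:3, ]), ">= 4 samples")
})

test_that("edge admission follows the |r| and p cutoffs and the declared mode", {
  ids <- c("enzA", "ionB", "ionC")
  r <- matrix(c(1, -0.9, 0.3, -0.9, 1, 0.95, 0.3, 0.95, 1), 3, 3,
              dimnames = list(ids, ids))
  corr <- toy_corr(r, cats = c("enzyme", "ion", "ion"))

  net_all <- build_network(corr, mode = "all")
  key <- function(net) paste(net$edges$from, net$edges$to)
  expect_setequal(key(net_all), c("enzA ionB", "ionB ionC"))
  expect_equal(net_all$edges$sign[net_all$edges$from == "enzA"], "negative")

  # enzyme-ion mode drops the ion-ion edge; ion-ion mode the reverse
  net_ei <- build_network(corr, mode = "enzyme-ion")
  expect_equal(key(net_ei), "enzA ionB")
  expect_equal(net_ei$edges$sign, "negative")
  net_ii <- build_network(corr, mode = "ion-ion")
  expect_equal(key(net_ii), "ionB ionC")

  # isolated nodes are not counted
  expect_equal(network_stats(net_ei)$n_nodes, 2)

  # below-cutoff correlations leave an empty network
  weak <- toy_corr(diag(3) + 0.2 - diag(0.2, 3), cats = rep("ion", 3),
                   ids = ids)
  empty <- build_network(weak, mode = "all")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(network_stats(empty)$n_nodes, 0)

  expect_error(build_network(corr, r_cutoff = 1.2), "r_cutoff")
  expect_error(build_network(corr, p_cutoff = 0), "p_cutoff")
})

test_that("admission is monotone in both cutoffs", {
  d <- generate_dataset(synth_config(seed = 13))
  comb <- combine_tables(d$ions, d$enzymes)
  ids <- d$metadata$sample_id[d$metadata$fertilization == "CF"]
  corr <- pearson_matrix(comb, ids)
  key <- function(net) paste(net$edges$from, net$edges$to)
  base <- build_network(corr, r_cutoff = 0.5, p_cutoff = 0.1, mode = "all")
  tighter_r <- build_network(corr, r_cutoff = 0.7, p_cutoff = 0.1,
                             mode = "all")
  tighter_p <- build_network(corr, r_cutoff = 0.5, p_cutoff = 0.01,
                             mode = "all")
  expect_true(all(key(tighter_r) %in% key(base)))
  expect_true(all(key(tighter_p) %in% key(base)))
})

test_that("at n = 12 the correlation cutoff dominates the p cutoff", {
  # the default 0.58 cutoff at n = 12 sits just above the two-sided 5% critical r
  r_crit <- sqrt(qt(0.975, 10)^2 / (qt(0.975, 10)^2 + 10))
  expect_lt(r_crit, 0.58)
  for (s in 1:10) {
    d <- generate_dataset(synth_config(seed = 300 + s))
    comb <- combine_tables(d$ions, d$enzymes)
    for (grp in c("CF", "COF")) {
      ids <- d$metadata$sample_id[d$metadata$fertilization == grp]
      corr <- pearson_matrix(comb, ids)
      strong <- abs(corr$r) > 0.58 & upper.tri(corr$r)
      expect_true(all(corr$p[strong] < 0.05))
    }
  }
})

test_that("network statistics match hand-computed graph measures", {
  g <- make_counted_graph(19, 88, n_positive = 53)
  net <- correlation_network(g$nodes, g$edges)
  s <- network_stats(net)
  expect_equal(s$n_nodes, 19)
  expect_equal(s$n_edges, 88)
  expect_equal(s$n_positive, 53)
  expect_equal(s$n_negative, 35)
  expect_equal(s$average_degree_paper, 88 / 19)
  expect_equal(s$average_degree_standard, 2 * 88 / 19)
  expect_equal(s$average_degree_standard, 2 * s$average_degree_paper)
  cum <- s$cumulative_degree_distribution
  expect_equal(unname(cum["0"]), 1)
  expect_true(all(diff(cum) <= 0))

  # path graph on 3 nodes: distances {1, 1, 2}
  path <- correlation_network(
    data.frame(variable_id = c("a", "b", "c"), category = "ion"),
    data.frame(from = c("a", "b"), to = c("b", "c"), r = 0.9))
  ps <- network_stats(path)
  expect_equal(ps$diameter, 2)
  expect_equal(ps$average_path_length, 4 / 3)

  expect_error(correlation_network(
    g$nodes, data.frame(from = "v01", to = "v01", r = 1)), "self-edges")
  expect_error(correlation_network(
    g$nodes, data.frame(from = c("v01", "v02"), to = c("v02", "v01"),
                        r = 0.9)), "duplicate")
})

test_that("community detection returns partitions whose modularity checks out", {
  # two disconnected triangles: Q = 0.5 at the component partition
  tri <- correlation_network(
    data.frame(variable_id = letters[1:6], category = "ion"),
    data.frame(from = c("a", "b", "c", "d", "e", "f"),
               to = c("b", "c", "a", "e", "f", "d"), r = 0.9))
  tri <- detect_communities(tri, seed = 1)
  expect_equal(length(unique(tri$communities)), 2)
  expect_equal(tri$modularity, 0.5)
  expect_equal(oracle_modularity(tri$edges, tri$communities), 0.5)

  # complete graph: a single community at Q = 0
  pairs <- t(combn(letters[1:5], 2))
  k5 <- correlation_network(
    data.frame(variable_id = letters[1:5], category = "ion"),
    data.frame(from = pairs[, 1], to = pairs[, 2], r = 0.9))
  k5 <- detect_communities(k5, seed = 1)
  expect_equal(length(unique(k5$communities)), 1)
  expect_equal(k5$modularity, 0)

  # reported modularity equals the hand evaluator on random graphs
  for (s in 1:50) {
    set.seed(s)
    n <- 12
    pairs <- t(combn(sprintf("n%02d", 1:n), 2))
    take <- sample(nrow(pairs), 20)
    nodes <- data.frame(variable_id = sprintf("n%02d", 1:n),
                        category = "ion")
    edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2],
                        r = runif(20, -1, 1))
    net <- detect_communities(correlation_network(nodes, edges), seed = s)
    expect_equal(net$modularity,
                 oracle_modularity(net$edges, net$communities),
                 tolerance = 1e-9)
  }
  # determinism under a fixed seed
  net1 <- detect_communities(correlation_network(nodes, edges), seed = 7)
  net2 <- detect_communities(correlation_network(nodes, edges), seed = 7)
  expect_identical(net1$communities, net2$communities)

  empty <- build_network(toy_corr(diag(2),
                                  cats = c("ion", "ion"),
                                  ids = c("x", "y")), mode = "all")
  expect_error(detect_communities(empty), "at least one edge")
})

test_that("generalists are ranked by degree with lexicographic ties and negative fractions", {
  star <- correlation_network(
    data.frame(variable_id = c("hub", "a", "b", "c"), category = "ion"),
    data.frame(from = "hub", to = c("a", "b", "c"), r = c(0.9, -0.9, -0.9)))
  gen <- identify_generalists(star, 1)
  expect_equal(gen$variable_id, "hub")
  expect_equal(gen$negative_fraction, 2 / 3)

  # 8 negative of 11 edges: the reported 72.7% generalist profile
  ids <- c("g", sprintf("x%02d", 1:11))
  n11 <- correlation_network(
    data.frame(variable_id = ids, category = c("enzyme", rep("ion", 11))),
    data.frame(from = "g", to = ids[-1],
               r = c(rep(-0.9, 8), rep(0.9, 3))))
  expect_equal(identify_generalists(n11, 1)$negative_fraction, 8 / 11,
               tolerance = 1e-9)
  expect_equal(round(100 * identify_generalists(n11, 1)$negative_fraction, 1),
               72.7)

  # tie below the hub: alphabetical order breaks it
  tie <- correlation_network(
    data.frame(variable_id = c("zeta", "alpha", "mid"), category = "ion"),
    data.frame(from = c("zeta", "alpha"), to = c("mid", "mid"), r = 0.9))
  expect_equal(identify_generalists(tie)$variable_id,
               c("mid", "alpha", "zeta"))
})

test_that("exports round-trip through GraphML and produce valid GEXF", {
  d <- generate_dataset(synth_config(seed = 19))
  comb <- combine_tables(d$ions, d$enzymes)
  ids <- d$metadata$sample_id[d$metadata$fertilization == "COF"]
  net <- build_network(pearson_matrix(comb, ids), mode = "enzyme-ion")
  net <- detect_communities(net, seed = 1)

  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- import_network(f)
  expect_setequal(back$nodes$variable_id, net$nodes$variable_id)
  key <- function(n) paste(pmin(n$edges$from, n$edges$to),
                           pmax(n$edges$from, n$edges$to))
  expect_setequal(key(back), key(net))
  idx <- match(net$nodes$variable_id, back$nodes$variable_id)
  expect_equal(back$nodes$category[idx], net$nodes$category)
  expect_equal(back$nodes$degree[idx], net$nodes$degree)
  r_back <- setNames(back$edges$r, key(back))
  expect_equal(unname(r_back[key(net)]), net$edges$r, tolerance = 1e-6)
  expect_true(all(back$edges$sign %in% c("positive", "negative")))

  fe <- withr::local_tempfile(fileext = ".gexf")
  export_network(net, fe, "gexf")
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(fe)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               nrow(net$edges))

  # an edgeless network still exports a valid document
  empty <- correlation_network(
    data.frame(variable_id = "a", category = "ion"),
    data.frame(from = character(), to = character(), r = numeric()))
  fg <- withr::local_tempfile(fileext = ".gexf")
  export_network(empty, fg, "gexf")
  expect_equal(length(xml2::xml_find_all(xml2::read_xml(fg),
                                         "//d1:edge",
                                         xml2::xml_ns(xml2::read_xml(fg)))),
               0)
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})
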