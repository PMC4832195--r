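#' Pearson correlation matrix with significance
#'
#' Computes all pairwise Pearson product-moment correlations between the
#' variables of a sample table (optionally on a subset of samples, e.g.
#' the 12 samples of one fertilization group) together with two-sided
#' p-values from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees
#' of freedom.  Zero-variance variables cannot be correlated and are
#' dropped with a warning, recorded in the result.
#'
#' @param table a [sample_table()] (categories are carried through) or
#'   numeric matrix.
#' @param sample_subset optional character vector of sample ids (or
#'   logical/integer row index).
#' @return Object of class `correlation_result`: `variable_ids`,
#'   `category`, `r`, `p` (square symmetric matrices), `n_obs`,
#'   `dropped` (zero-variance variables).
#' @export
pearson_matrix <- function(table, sample_subset = NULL) {
  x <- as.matrix(table)
  cats <- attr(table, "category")
  if (is.null(cats)) cats <- rep("ion", ncol(x))
  if (!is.null(sample_subset)) x <- x[sample_subset, , drop = FALSE]
  n <- nrow(x)
  if (n < 4L) stop("need >= 4 samples for correlation inference")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
    keep <- v > 0
    x <- x[, keep, drop = FALSE]
    cats <- cats[keep]
  }
  r <- stats::cor(x)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 0   # |r| = 1
  diag(p) <- 0
  structure(list(variable_ids = colnames(x), category = cats,
                 r = r, p = p, n_obs = n, dropped = dropped),
            class = "correlation_result")
}

#' Construct a co-occurrence network from node and edge tables
#'
#' Low-level constructor used by [build_network()] and available for
#' assembling a network with known topology (e.g. to compute summary
#' statistics of a published node/edge count).
#'
#' @param nodes data frame with columns `variable_id` and `category`.
#' @param edges data frame with columns `from`, `to`, `r` (correlation
#'   value; its sign labels the edge).
#' @param mode label for the network flavor (`"enzyme-ion"`, `"ion-ion"`,
#'   `"all"`).
#' @param r_cutoff,p_cutoff the admission thresholds the edges satisfy.
#' @return Object of class `correlation_network`: `nodes` (with degree),
#'   `edges` (with sign), the admission parameters, and an igraph
#'   representation in `$graph`.
#' @export
correlation_network <- function(nodes, edges, mode = "all",
                                r_cutoff = NA_real_, p_cutoff = NA_real_) {
  stopifnot(all(c("variable_id", "category") %in% names(nodes)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "r") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    key <- apply(cbind(pmin(edges$from, edges$to),
                       pmax(edges$from, edges$to)), 1, paste,
                 collapse = "\r")
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes$variable_id))
      stop("edge endpoints must be listed in 'nodes'")
    edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "r", "sign"), drop = FALSE],
    directed = FALSE,
    vertices = nodes[, c("variable_id", "category"), drop = FALSE])
  nodes$degree <- as.integer(igraph::degree(g)[nodes$variable_id])
  structure(list(nodes = nodes, edges = edges, graph = g, mode = mode,
                 r_cutoff = r_cutoff, p_cutoff = p_cutoff),
            class = "correlation_network")
}

#' Build a thresholded co-occurrence network
#'
#' Admits an edge between two variables exactly when \eqn{|r| >}
#' `r_cutoff` and \eqn{p <} `p_cutoff` (default 0.58 and 0.05; the
#' magnitude rule, not signed r, so strong negative correlations become
#' negative edges).  In `"enzyme-ion"` mode only enzyme-to-ion pairs are
#' eligible (no enzyme-enzyme or ion-ion edges); in `"ion-ion"` mode only
#' ion-ion pairs; `"all"` admits every pair.  Variables left without any
#' admitted edge are excluded from the node list, matching the
#' convention that a co-occurrence graph counts only connected nodes.
#'
#' @param corr a [pearson_matrix()] result.
#' @param r_cutoff correlation-magnitude threshold in \[0, 1\).
#' @param p_cutoff significance threshold in (0, 1\].
#' @param mode `"enzyme-ion"`, `"ion-ion"` or `"all"`.
#' @return A [correlation_network()].
#' @export
build_network <- function(corr, r_cutoff = 0.58, p_cutoff = 0.05,
                          mode = c("enzyme-ion", "ion-ion", "all")) {
  stopifnot(inherits(corr, "correlation_result"))
  mode <- match.arg(mode)
  if (!is.finite(r_cutoff) || r_cutoff < 0 || r_cutoff >= 1)
    stop("r_cutoff must lie in [0, 1)")
  if (!is.finite(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1)
    stop("p_cutoff must lie in (0, 1]")
  ids <- corr$variable_ids
  cats <- corr$category
  edges <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      eligible <- switch(mode,
        "enzyme-ion" = cats[i] != cats[j],
        "ion-ion" = cats[i] == "ion" && cats[j] == "ion",
        "all" = TRUE)
      if (eligible && abs(corr$r[i, j]) > r_cutoff &&
          corr$p[i, j] < p_cutoff)
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = ids[j], r = corr$r[i, j],
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), r = numeric(),
               stringsAsFactors = FALSE)
  keep <- switch(mode,
    "enzyme-ion" = rep(TRUE, length(ids)),
    "ion-ion" = cats == "ion",
    "all" = rep(TRUE, length(ids)))
  connected <- ids %in% c(edges$from, edges$to)
  nodes <- data.frame(variable_id = ids, category = cats,
                      stringsAsFactors = FALSE)[keep & connected, ,
                                                drop = FALSE]
  correlation_network(nodes, edges, mode = mode, r_cutoff = r_cutoff,
                      p_cutoff = p_cutoff)
}

#' Summary statistics of a co-occurrence network
#'
#' Node, edge and sign counts, both average-degree conventions
#' (`average_degree_paper` = edges / nodes, the convention under which a
#' 19-node, 88-edge graph has average degree 4.632;
#' `average_degree_standard` = 2 edges / nodes), average shortest-path
#' length over connected pairs, diameter (maximum over components), the
#' cumulative degree distribution (fraction of nodes with degree at
#' least d), and, when communities have been detected, their number and
#' modularity.
#'
#' @param net a [correlation_network()].
#' @return List of class `network_stats`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  g <- net$graph
  n_nodes <- sum(net$nodes$degree > 0)
  n_edges <- nrow(net$edges)
  n_pos <- sum(net$edges$sign == "positive")
  deg <- net$nodes$degree[net$nodes$degree > 0]
  if (n_edges > 0L) {
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE)
    degs <- sort(unique(c(0L, deg)))
    cum <- vapply(degs, function(d) mean(deg >= d), numeric(1))
    names(cum) <- degs
  } else {
    apl <- NA_real_; diam <- NA_real_
    cum <- c("0" = 1)
  }
  structure(list(
    n_nodes = n_nodes, n_edges = n_edges,
    n_positive = n_pos, n_negative = n_edges - n_pos,
    average_degree_paper = if (n_nodes > 0) n_edges / n_nodes else NA_real_,
    average_degree_standard = if (n_nodes > 0) 2 * n_edges / n_nodes else NA_real_,
    average_path_length = apl, diameter = diam,
    cumulative_degree_distribution = cum,
    n_communities = if (!is.null(net$communities))
      length(unique(net$communities)) else NA_integer_,
    modularity = if (!is.null(net$modularity)) net$modularity else NA_real_),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges (%d positive, %d negative)\n",
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative))
  cat(sprintf("  average degree: %.3f (edges/nodes), %.3f (2*edges/nodes)\n",
              x$average_degree_paper, x$average_degree_standard))
  cat(sprintf("  average path length %.3f, diameter %s\n",
              x$average_path_length, format(x$diameter)))
  if (!is.na(x$n_communities))
    cat(sprintf("  modularity %.3f with %d communities\n",
                x$modularity, x$n_communities))
  invisible(x)
}

#' Community detection by modularity optimization
#'
#' Runs Louvain multi-level modularity optimization (the algorithm
#' behind Gephi's modularity tool) on the unweighted, unsigned graph and
#' reports the partition and its Newman modularity
#' \deqn{Q = \sum_c \left( e_c/m - (d_c/2m)^2 \right).}
#' The seed fixes the random vertex order, making the result
#' deterministic.
#'
#' @param net a [correlation_network()] with at least one edge.
#' @param seed integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return `net` with `$communities` (named membership vector) and
#'   `$modularity` filled in.
#' @export
detect_communities <- function(net, seed = 1L, resolution = 1) {
  stopifnot(inherits(net, "correlation_network"))
  if (nrow(net$edges) == 0L)
    stop("community detection requires at least one edge")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- igraph::delete_vertices(net$graph,
                               which(igraph::degree(net$graph) == 0))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  membership <- igraph::membership(cl)
  net$communities <- stats::setNames(as.integer(membership),
                                     names(membership))
  net$modularity <- igraph::modularity(g, membership)
  net
}

#' Rank network generalists
#'
#' Sorts nodes by degree (descending, ties broken alphabetically by
#' variable id) and reports each node's fraction of negative incident
#' edges; the top-ranked node is the network's generalist.
#'
#' @param net a [correlation_network()].
#' @param top_k how many nodes to return (default all).
#' @return Data frame with `variable_id`, `category`, `degree`,
#'   `n_negative`, `negative_fraction`.
#' @export
identify_generalists <- function(net, top_k = nrow(net$nodes)) {
  stopifnot(inherits(net, "correlation_network"))
  nodes <- net$nodes
  neg <- vapply(nodes$variable_id, function(v) {
    inc <- net$edges$from == v | net$edges$to == v
    sum(net$edges$sign[inc] == "negative")
  }, integer(1))
  out <- data.frame(variable_id = nodes$variable_id,
                    category = nodes$category,
                    degree = nodes$degree,
                    n_negative = unname(neg),
                    negative_fraction = ifelse(nodes$degree > 0,
                                               unname(neg) / nodes$degree,
                                               NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$variable_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Export a network for Gephi
#'
#' Writes GraphML (re-importable with [import_network()]), GEXF, or a
#' tab-separated edge list.  Node attributes: category, degree,
#' community (when detected); edge attributes: r and sign.
#'
#' @param net a [correlation_network()].
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "gexf", "edgelist")) {
  stopifnot(inherits(net, "correlation_network"))
  format <- match.arg(format)
  g <- net$graph
  if (!is.null(net$communities))
    igraph::V(g)$community <-
      as.integer(net$communities[igraph::V(g)$name])
  igraph::V(g)$degree <- as.integer(igraph::degree(g))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

write_gexf <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  nodes <- net$nodes
  com <- net$communities
  node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
    vid <- nodes$variable_id[i]
    sprintf(paste0(
      '      <node id="%s" label="%s">\n        <attvalues>\n',
      '          <attvalue for="category" value="%s"/>\n',
      '          <attvalue for="degree" value="%d"/>\n%s',
      '        </attvalues>\n      </node>'),
      esc(vid), esc(vid), nodes$category[i], nodes$degree[i],
      if (!is.null(com))
        sprintf('          <attvalue for="community" value="%d"/>\n',
                com[vid]) else "")
  }, character(1))
  edges <- net$edges
  edge_xml <- if (nrow(edges) > 0)
    vapply(seq_len(nrow(edges)), function(i) {
      sprintf(paste0(
        '      <edge id="%d" source="%s" target="%s">\n',
        '        <attvalues>\n',
        '          <attvalue for="r" value="%.12g"/>\n',
        '          <attvalue for="sign" value="%s"/>\n',
        '        </attvalues>\n      </edge>'),
        i - 1L, esc(edges$from[i]), esc(edges$to[i]), edges$r[i],
        edges$sign[i])
    }, character(1)) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="category" title="category" type="string"/>',
    '      <attribute id="degree" title="degree" type="integer"/>',
    '      <attribute id="community" title="community" type="integer"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="r" title="r" type="double"/>',
    '      <attribute id="sign" title="sign" type="string"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    edges <- data.frame(from = el$from, to = el$to, r = el$r,
                        stringsAsFactors = FALSE)
    correlation_network(
      data.frame(variable_id = nodes$name, category = nodes$category,
                 stringsAsFactors = FALSE), edges)
  } else {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- data.frame(variable_id = unique(c(edges$from, edges$to)),
                        category = "ion", stringsAsFactors = FALSE)
    correlation_network(nodes, edges[, c("from", "to", "r")])
  }
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network (%s mode, |r| > %s, p < %s)\n",
              x$mode, format(x$r_cutoff), format(x$p_cutoff)))
  print(network_stats(x))
  invisible(x)
}
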