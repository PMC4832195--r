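#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: either paths to an ion
#' table, an enzyme table and a metadata CSV, or `generate = TRUE` with a
#' [synth_config()]; per-stage parameters; a global seed fanned out to
#' per-stage substreams by fixed offsets (ordination +1, VPA +2,
#' networks +3) so stages can be re-run in isolation reproducibly.
#'
#' @param ion_path,enzyme_path,metadata_path input files (ignored when
#'   `generate` is `TRUE`).
#' @param generate generate synthetic data instead of reading files.
#' @param synth a [synth_config()] used when `generate` is `TRUE`; its
#'   seed is overridden by `seed`.
#' @param seed global integer seed.
#' @param k NMDS dimension.
#' @param n_restarts NMDS restarts.
#' @param n_permutations permutations for the VPA tests.
#' @param r_cutoff,p_cutoff network admission thresholds.
#' @param lambda response-ratio CI multiplier.
#' @param outdir optional output directory; when set, [run_pipeline()]
#'   writes all artifacts there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ion_path = NULL, enzyme_path = NULL,
                            metadata_path = NULL, generate = FALSE,
                            synth = synth_config(), seed = 1L,
                            k = 2L, n_restarts = 20L,
                            n_permutations = 199L,
                            r_cutoff = 0.58, p_cutoff = 0.05,
                            lambda = 1.96, outdir = NULL) {
  if (!generate &&
      (is.null(ion_path) || is.null(enzyme_path) || is.null(metadata_path)))
    stop("either set generate = TRUE or provide ion, enzyme and metadata paths")
  structure(list(ion_path = ion_path, enzyme_path = enzyme_path,
                 metadata_path = metadata_path, generate = generate,
                 synth = synth, seed = as.integer(seed), k = k,
                 n_restarts = n_restarts,
                 n_permutations = n_permutations,
                 r_cutoff = r_cutoff, p_cutoff = p_cutoff,
                 lambda = lambda, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synth`
#' mapping holds [synth_config()] arguments for generated runs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth
  y$synth <- NULL
  y <- y[names(y) %in% names(formals(pipeline_config))]
  if (!is.null(synth_args))
    y$synth <- do.call(synth_config, synth_args)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading or generation, design summary, NMDS
#' ordination of the Bray-Curtis matrices of the ion and enzyme tables,
#' three-way variance partitioning (pH, site, fertilization) of the
#' Hellinger-transformed tables, the response-ratio table over all
#' variables, and the four co-occurrence networks (CF and COF, each in
#' enzyme-ion and ion-ion mode) with community detection.  Identical
#' configuration and seed give an identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return List of class `report_bundle` with elements `design`,
#'   `ordination` (`$ions`, `$enzymes`), `vpa` (`$ions`, `$enzymes`),
#'   `rr`, `networks` (named `CF_enzyme_ion`, `COF_enzyme_ion`,
#'   `CF_ion_ion`, `COF_ion_ion`), `network_stats` (one row each),
#'   `data`, and `run` metadata.  When `config$outdir` is set the bundle
#'   is also written there via [write_report()].
#' @examples
#' \donttest{
#' bundle <- run_pipeline(pipeline_config(generate = TRUE, seed = 7,
#'                                        n_permutations = 49))
#' bundle$ordination$ions$stress
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (config$generate) {
    sc <- config$synth
    sc$seed <- seed
    data <- generate_dataset(sc)
  } else {
    ions <- read_sample_table(config$ion_path, category = "ion")
    enzymes <- read_sample_table(config$enzyme_path, category = "enzyme")
    metadata <- read_metadata(config$metadata_path)
    data <- list(ions = ions, enzymes = enzymes, metadata = metadata,
                 truth = NULL)
  }
  md <- data$metadata
  design <- summarize_design(md)

  ord <- lapply(list(ions = data$ions, enzymes = data$enzymes),
                function(tab)
                  nmds(bray_curtis(tab), k = config$k,
                       n_restarts = config$n_restarts,
                       seed = seed + 1L))

  idx <- match(rownames(data$ions), md$sample_id)
  blocks <- list(
    a = explanatory_block(md$pH[idx], "pH"),
    b = explanatory_block(md$site[idx], "site"),
    c = explanatory_block(md$fertilization[idx], "fertilization"))
  vpa <- lapply(list(ions = data$ions, enzymes = data$enzymes),
                function(tab)
                  variance_partition(hellinger(tab), blocks$a, blocks$b,
                                     blocks$c,
                                     n_permutations = config$n_permutations,
                                     seed = seed + 2L))

  rr <- rr_table(data$ions, data$enzymes, md, lambda = config$lambda)

  combined <- combine_tables(data$ions, data$enzymes)
  networks <- list()
  for (grp in c("CF", "COF")) {
    ids <- md$sample_id[md$fertilization == grp]
    corr <- pearson_matrix(combined, sample_subset = ids)
    for (mode in c("enzyme-ion", "ion-ion")) {
      net <- build_network(corr, r_cutoff = config$r_cutoff,
                           p_cutoff = config$p_cutoff, mode = mode)
      if (nrow(net$edges) > 0)
        net <- detect_communities(net, seed = seed + 3L)
      networks[[paste(grp, gsub("-", "_", mode), sep = "_")]] <- net
    }
  }
  net_stats <- lapply(networks, network_stats)

  bundle <- structure(list(
    design = design, ordination = ord, vpa = vpa, rr = rr,
    networks = networks, network_stats = net_stats, data = data,
    run = list(seed = seed,
               r_cutoff = config$r_cutoff, p_cutoff = config$p_cutoff,
               lambda = config$lambda,
               package_version = as.character(utils::packageVersion("soilionet")))),
    class = "report_bundle")
  if (!is.null(config$outdir)) write_report(bundle, config$outdir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits stable, machine-readable artifacts under `path`: the generated
#' or input tables (`ions.csv`, `enzymes.csv`, `metadata.csv`,
#' `truth.csv` when synthetic), per-stage tables
#' (`ordination_<set>_coordinates.tsv`, `vpa.tsv`,
#' `response_ratios.tsv`, `network_stats.tsv`), GraphML files for the
#' four networks, and a key-value `summary.yaml`.
#'
#' @param bundle a [run_pipeline()] result.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(path, f)

  write_sample_table(bundle$data$ions, fp("ions.csv"))
  write_sample_table(bundle$data$enzymes, fp("enzymes.csv"))
  utils::write.csv(as.data.frame(bundle$data$metadata), fp("metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$data$truth))
    truth_report(bundle$data$truth, fp("truth.csv"))

  for (set in names(bundle$ordination)) {
    o <- bundle$ordination[[set]]
    co <- data.frame(sample_id = rownames(o$coordinates),
                     format(o$coordinates, digits = 12),
                     goodness_of_fit = format(o$per_sample_fit, digits = 12))
    utils::write.table(co, fp(sprintf("ordination_%s_coordinates.tsv", set)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  vrows <- do.call(rbind, lapply(names(bundle$vpa), function(set) {
    v <- bundle$vpa[[set]]
    data.frame(response = set, fraction = names(v$fractions),
               percent = format(100 * unname(v$fractions), digits = 10),
               p_value = format(v$pvalues[names(v$fractions)], digits = 6),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(vrows, fp("vpa.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  rr <- as.data.frame(bundle$rr)
  num <- vapply(rr, is.numeric, TRUE)
  rr[num] <- lapply(rr[num], function(col) format(col, digits = 12))
  utils::write.table(rr, fp("response_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  srows <- do.call(rbind, lapply(names(bundle$network_stats), function(nm) {
    s <- bundle$network_stats[[nm]]
    data.frame(network = nm, n_nodes = s$n_nodes, n_edges = s$n_edges,
               n_positive = s$n_positive, n_negative = s$n_negative,
               average_degree_paper = format(s$average_degree_paper, digits = 10),
               average_path_length = format(s$average_path_length, digits = 10),
               diameter = s$diameter,
               modularity = format(s$modularity, digits = 10),
               n_communities = s$n_communities,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(srows, fp("network_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$networks))
    export_network(bundle$networks[[nm]],
                   fp(sprintf("network_%s.graphml", nm)), "graphml")

  summary <- list(
    seed = bundle$run$seed,
    n_samples = bundle$design$n_samples_total,
    balanced = bundle$design$balanced,
    stress_ions = bundle$ordination$ions$stress,
    stress_enzymes = bundle$ordination$enzymes$stress,
    total_explained_ions = bundle$vpa$ions$total_explained,
    residual_ions = bundle$vpa$ions$residual,
    total_explained_enzymes = bundle$vpa$enzymes$total_explained,
    residual_enzymes = bundle$vpa$enzymes$residual,
    n_significant_rr = sum(bundle$rr$significant, na.rm = TRUE))
  yaml::write_yaml(summary, fp("summary.yaml"))
  invisible(path)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Soil ionome/enzyme analysis report\n\n")
  print(x$design)
  cat(sprintf("\nNMDS stress: ions %.4f, enzymes %.4f\n",
              x$ordination$ions$stress, x$ordination$enzymes$stress))
  cat(sprintf("VPA explained: ions %.2f%%, enzymes %.2f%%\n",
              100 * x$vpa$ions$total_explained,
              100 * x$vpa$enzymes$total_explained))
  cat(sprintf("Response ratios: %d of %d variables significant\n",
              sum(x$rr$significant, na.rm = TRUE), nrow(x$rr)))
  for (nm in names(x$network_stats)) {
    s <- x$network_stats[[nm]]
    cat(sprintf("%-16s %2d nodes, %3d edges (%d+/%d-), modularity %s\n",
                nm, s$n_nodes, s$n_edges, s$n_positive, s$n_negative,
                ifelse(is.na(s$modularity), "NA",
                       sprintf("%.3f", s$modularity))))
  }
  invisible(x)
}
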