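# Configuration-driven end-to-end pipeline:
# simulate/ingest -> preprocess -> static network -> environmental edge
# removal -> subnetworks -> classification -> vertical profiles -> topology,
# with per-stage outputs and a run manifest (files, checksums, seeds).

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the canonical defaults:
#' sample filter at 2000 reads, ASV filters at >100 total reads and >= 20
#' samples, CLR pseudocount 1, Jaccard threshold 0.20 (strict), class
#' thresholds 0.7 / 0.5 / 0.2, interaction-information test at alpha 0.05
#' with 10000 permutations. A `simulate` block (arguments to
#' [sim_config()]) substitutes for real input; alternatively set
#' `input_dir` to a fixture directory or `edge_list` to an exported
#' network.
#'
#' @param simulate list of [sim_config()] arguments (default: empty list =
#'   generator defaults), or `NULL` when `input_dir` is given.
#' @param input_dir fixture directory for [read_fixture()], or `NULL`.
#' @param network `"truth"` (planted-truth network with decoys),
#'   `"standin"` (built-in inference) or a path to an edge-list TSV.
#' @param n_background_edges decoy edges for the truth network.
#' @param min_reads,min_total_reads,min_samples,pseudocount preprocessing.
#' @param jaccard_threshold strict subnetwork Jaccard threshold in [0, 1].
#' @param class_thresholds named vector (global, prevalent, low_frequency).
#' @param alpha,ii_iterations,bins environmental edge-removal settings.
#' @param factors environmental factors to test.
#' @param ms_region enclosed-sea region name.
#' @param seed master seed for every stochastic stage.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), input_dir = NULL,
                            network = "truth", n_background_edges = 30,
                            min_reads = 2000, min_total_reads = 100,
                            min_samples = 20, pseudocount = 1,
                            jaccard_threshold = 0.20,
                            class_thresholds = c(global = 0.7,
                                                 prevalent = 0.5,
                                                 low_frequency = 0.2),
                            alpha = 0.05, ii_iterations = 10000, bins = 4,
                            factors = c("temperature", "salinity",
                                        "fluorescence", "no3", "po4",
                                        "sio2"),
                            ms_region = "MS", seed = 1) {
  cfg <- as.list(environment())
  if (is.null(simulate) && is.null(input_dir)) {
    stop2("either a simulate block or an input_dir is required")
  }
  for (thr in c(cfg$jaccard_threshold, cfg$class_thresholds, cfg$alpha)) {
    if (!is.numeric(thr) || thr < 0 || thr > 1) {
      stop2("thresholds and alpha must lie in [0, 1]")
    }
  }
  if (!all(c("global", "prevalent", "low_frequency") %in%
           names(cfg$class_thresholds))) {
    stop2("class_thresholds must name global, prevalent and low_frequency")
  }
  if (cfg$ii_iterations < 1 || cfg$bins < 2) {
    stop2("ii_iterations must be >= 1 and bins >= 2")
  }
  if (length(cfg$factors) < 1) stop2("at least one environmental factor")
  class(cfg) <- "pipeline_config"
  cfg
}

combine_asv_tables <- function(prok, euk) {
  asv_table(rbind(prok$counts, euk$counts[, colnames(prok$counts),
                                          drop = FALSE]),
            c(prok$domain, euk$domain),
            c(prok$taxonomy %||% setNames(rep("", nrow(prok$counts)),
                                          rownames(prok$counts)),
              euk$taxonomy %||% setNames(rep("", nrow(euk$counts)),
                                         rownames(euk$counts))))
}

write_stage <- function(df, outdir, file) {
  if (is.null(outdir)) return(NULL)
  path <- file.path(outdir, file)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full pipeline
#'
#' Executes every stage under one configuration and master seed. With an
#' output directory, each stage writes its tables and a JSON run manifest
#' records every output file with an MD5 checksum; identical
#' configurations and seeds reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (`NULL` for in-memory only).
#' @param verbose print stage progress.
#' @return list with the per-stage objects (`dataset`, `filtered`, `clr`,
#'   `static`, `removal`, `subnets`, `prevalence_all`,
#'   `prevalence_region_layer`, `classified` (+`classified_no_ms`),
#'   `summary`, `vertical`, `metrics`, `dissimilarity`, `mst`, `clusters`,
#'   `composition`, `recovery`) and the `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  files <- character(0)
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  # -- stage 1: data --------------------------------------------------------
  say("stage 1/7: data")
  dataset <- if (!is.null(config$input_dir)) {
    read_fixture(config$input_dir)
  } else {
    generate_dataset(do.call(sim_config,
                             utils::modifyList(list(seed = config$seed),
                                               config$simulate)))
  }
  md <- dataset$metadata

  # -- stage 2: preprocessing ----------------------------------------------
  say("stage 2/7: preprocessing")
  prep <- lapply(list(prok = dataset$prok_counts, euk = dataset$euk_counts),
                 function(tab) {
    tab <- filter_samples(tab, config$min_reads)
    filter_asvs(tab, config$min_total_reads, config$min_samples)
  })
  common <- intersect(colnames(prep$prok$counts), colnames(prep$euk$counts))
  prep <- lapply(prep, subset_asv_table, samples = common)
  md <- md[md$sample %in% common, , drop = FALSE]
  clr <- merge_domain_tables(clr_transform(prep$prok, config$pseudocount),
                             clr_transform(prep$euk, config$pseudocount))
  counts <- combine_asv_tables(prep$prok, prep$euk)

  # -- stage 3: static network ---------------------------------------------
  say("stage 3/7: static network")
  static <- if (identical(config$network, "truth")) {
    truth_static_network(dataset, config$n_background_edges, config$seed)
  } else if (identical(config$network, "standin")) {
    infer_standin_network(clr, alpha = config$alpha, seed = config$seed)
  } else {
    import_network(config$network, counts$domain)
  }
  lost <- !(static$edges$a %in% rownames(counts$counts) &
            static$edges$b %in% rownames(counts$counts))
  if (any(lost)) {
    say("  dropping ", sum(lost), " edge(s) with filtered-out endpoints")
    static$edges <- static$edges[!lost, , drop = FALSE]
  }
  static <- remove_isolated_nodes(static)
  files <- c(files, write_stage(static$edges, outdir, "static_network.tsv"))

  # -- stage 4: environmental edge removal ---------------------------------
  # MI/II run on depth-normalized (relative) abundances per domain table:
  # raw counts of same-table ASVs share the sample's sequencing depth as a
  # common factor, which inflates pairwise MI and masks the
  # data-processing-inequality ordering
  say("stage 4/7: environmental edge removal")
  relab <- function(m) sweep(m, 2, pmax(1, colSums(m)), "/")
  rel <- rbind(relab(prep$prok$counts), relab(prep$euk$counts))
  removal <- remove_env_driven_edges(static, rel, md,
                                     factors = config$factors,
                                     bins = config$bins,
                                     n_iter = config$ii_iterations,
                                     alpha = config$alpha,
                                     seed = config$seed)
  static_final <- remove_isolated_nodes(removal$network)
  files <- c(files,
             write_stage(removal$report$per_factor, outdir,
                         "env_removal_per_factor.tsv"),
             write_stage(removal$report$per_edge, outdir,
                         "env_removal_per_edge.tsv"),
             write_stage(static_final$edges, outdir, "static_final.tsv"))

  # -- stage 5: sample-specific subnetworks --------------------------------
  say("stage 5/7: subnetworks")
  subnets <- derive_all(counts, md, static_final, config$jaccard_threshold)
  long <- do.call(rbind, lapply(subnets$subnetworks, function(s)
    if (nrow(s$edges)) cbind(sample = s$sample, s$edges) else NULL))
  files <- c(files, write_stage(long, outdir, "subnetworks_long.tsv"),
             write_stage(subnets$jaccard, outdir, "jaccard_table.tsv"))

  # -- stage 6: prevalence, classification, vertical profiles --------------
  say("stage 6/7: classification")
  prev_all <- prevalence(subnets, "all")
  prev_rl <- prevalence(subnets, "region_layer")
  layers <- intersect(LAYER_VOCABULARY, unique(md$layer))
  classified <- lapply(layers, function(l)
    classify_layer(prev_rl, l, include_ms = TRUE, ms_region = config$ms_region,
                   thresholds = config$class_thresholds))
  classified_no_ms <- lapply(layers, function(l)
    classify_layer(prev_rl, l, include_ms = FALSE,
                   ms_region = config$ms_region,
                   thresholds = config$class_thresholds))
  names(classified) <- names(classified_no_ms) <- layers
  summary_tab <- classification_summary(classified, classified_no_ms)
  vertical <- lapply(sort(unique(md$region)), function(r)
    vertical_profile(prev_rl, r, layers = LAYER_VOCABULARY,
                     domains = counts$domain))
  names(vertical) <- sort(unique(md$region))
  recovery <- if (!is.null(dataset$truth) && nrow(dataset$truth)) {
    planted_recovery(dataset$truth, classified, removal$report$removed)
  } else NULL
  files <- c(files,
             write_stage(prev_all, outdir, "prevalence_all.tsv"),
             write_stage(prev_rl, outdir, "prevalence_region_layer.tsv"),
             write_stage(do.call(rbind, classified), outdir,
                         "classification_with_ms.tsv"),
             write_stage(do.call(rbind, classified_no_ms), outdir,
                         "classification_no_ms.tsv"),
             write_stage(summary_tab, outdir, "classification_summary.tsv"))
  if (!is.null(recovery)) {
    files <- c(files, write_stage(recovery, outdir, "planted_recovery.tsv"))
  }

  # -- stage 7: topology ----------------------------------------------------
  say("stage 7/7: topology")
  metrics <- do.call(rbind, lapply(subnets$subnetworks, network_metrics,
                                   domains = counts$domain))
  rownames(metrics) <- NULL
  dm <- dissimilarity_matrix(subnets)
  nsn <- build_nsn(dm)
  mst <- minimum_spanning_tree(nsn)
  clusters <- cluster_subnetworks(dm)
  composition <- cluster_composition(clusters$assignment, md)
  files <- c(files,
             write_stage(metrics, outdir, "network_metrics.tsv"),
             write_stage(data.frame(sample = rownames(dm), dm,
                                    check.names = FALSE),
                         outdir, "dissimilarity.tsv"),
             write_stage(mst, outdir, "mst.tsv"),
             write_stage(data.frame(sample = names(clusters$assignment),
                                    cluster = clusters$assignment),
                         outdir, "clusters.tsv"),
             write_stage(composition, outdir, "cluster_composition.tsv"))

  manifest <- list(
    seed = config$seed,
    n_samples = nrow(md),
    stages = c("data", "preprocess", "static_network", "env_removal",
               "subnetworks", "classification", "topology"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = if (length(files)) {
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    } else NULL)
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(dataset = dataset, metadata = md, filtered = prep,
                 clr = clr, counts = counts, static = static,
                 removal = removal, static_final = static_final,
                 subnets = subnets, prevalence_all = prev_all,
                 prevalence_region_layer = prev_rl,
                 classified = classified,
                 classified_no_ms = classified_no_ms,
                 summary = summary_tab, vertical = vertical,
                 metrics = metrics, dissimilarity = dm, nsn = nsn,
                 mst = mst, clusters = clusters, composition = composition,
                 recovery = recovery, manifest = manifest,
                 config = config))
}

#' Human- and machine-readable run summary
#'
#' Re-derives the headline accounting of a finished run: per-layer class
#' counts and percentages in both enclosed-sea modes (with the internal
#' sum-to-present identity asserted), the static network size and sign
#' split, and the cluster composition.
#'
#' @param run result of [run_pipeline()].
#' @return list with `class_table`, `network` (node/edge/sign counts),
#'   `clusters`; printed compactly by `print()`.
#' @export
summary_report <- function(run) {
  stopifnot(is.list(run), !is.null(run$summary))
  st <- run$static_final$edges
  for (l in unique(run$summary$layer)) {
    tab <- run$summary[run$summary$layer == l, ]
    cnt <- function(cl) tab$count[tab$class == cl]
    stopifnot(cnt("global") + cnt("prevalent") + cnt("low_frequency") +
                cnt("regional") + cnt("other") == cnt("present"))
  }
  structure(list(
    class_table = run$summary,
    network = data.frame(
      n_nodes = nrow(run$static_final$nodes),
      n_edges = nrow(st),
      n_positive = sum(st$sign == "positive"),
      n_negative = sum(st$sign == "negative"),
      pct_positive = round(100 * sum(st$sign == "positive") /
                             max(1, nrow(st)), 1),
      n_subnetworks = length(run$subnets$subnetworks)),
    clusters = run$composition), class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Static network:", x$network$n_nodes, "nodes,", x$network$n_edges,
      sprintf("edges (%.1f%% positive); %d subnetworks\n",
              x$network$pct_positive, x$network$n_subnetworks))
  cat("Classified associations per layer:\n")
  wide <- stats::reshape(x$class_table[, c("layer", "class", "count")],
                         idvar = "class", timevar = "layer",
                         direction = "wide")
  print(wide, row.names = FALSE)
  cat(nrow(x$clusters), "clusters\n")
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the arguments of [pipeline_config()] (a `simulate` block
#' substitutes for real inputs, matching no-download testability).
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  args <- yaml::read_yaml(path)
  if (!is.null(args$class_thresholds)) {
    args$class_thresholds <- unlist(args$class_thresholds)
  }
  do.call(pipeline_config, args)
}
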