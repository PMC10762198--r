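# Synthetic multi-region, multi-depth dataset generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: six ocean regions (one enclosed sea with a warm deep layer) times
# four ordered depth layers, zero-inflated overdispersed ASV counts for two
# marker-gene tables (prokaryotes and eukaryotes), smooth environmental
# gradients with missing values, and a planted-truth ledger of association
# pairs with global, regional, layer-specific, environmentally-driven and
# negative structure.

#' Simulation configuration
#'
#' Defaults emulate the sampling design of a tropical/subtropical ocean
#' survey at desk scale: 6 regions (the first one, "MS", standing for an
#' enclosed sea with a warm bathypelagic) x 4 ordered depth layers
#' (SRF, DCM, MES, BAT), a moderate number of samples per region-layer cell
#' and a few hundred ASVs per domain.
#'
#' @param n_regions number of regions (default 6; the first is flagged as
#'   the enclosed sea and named "MS" when the default vocabulary fits).
#' @param regions optional character vector of region names (overrides
#'   `n_regions`).
#' @param layers ordered depth-layer vocabulary (surface to bottom).
#' @param samples_per_cell scalar, or a regions x layers integer matrix, of
#'   samples per region-layer cell. A cell set to 0 must be explicit
#'   (matrix form); a scalar 0 is a configuration error.
#' @param n_asvs_prok,n_asvs_euk ASVs per domain table.
#' @param reads_range length-2 range of per-sample sequencing depth.
#' @param n_global_pairs,n_regional_pairs,n_layer_pairs,n_env_driven_pairs,n_negative_pairs
#'   planted association counts per class.
#' @param co_occurrence_strength latent correlation of planted pair members,
#'   in \[0, 1\].
#' @param zero_inflation probability that a non-zero count is dropped after
#'   the multinomial draw (independent dropout).
#' @param occupancy_planted marginal presence probability of a planted-pair
#'   member within its active scope.
#' @param background_occupancy length-2 range from which each background
#'   ASV's presence probability is drawn; the defaults make background
#'   pairs cosmopolitan (present in most region-layer cells), leaving
#'   one-region patterns to the planted regional pairs.
#' @param seed integer RNG seed; all output is deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_regions = 6,
                       regions = NULL,
                       layers = c("SRF", "DCM", "MES", "BAT"),
                       samples_per_cell = 12,
                       n_asvs_prok = 120,
                       n_asvs_euk = 80,
                       reads_range = c(5000, 50000),
                       n_global_pairs = 20,
                       n_regional_pairs = 12,
                       n_layer_pairs = 8,
                       n_env_driven_pairs = 15,
                       n_negative_pairs = 10,
                       co_occurrence_strength = 0.9,
                       zero_inflation = 0.02,
                       occupancy_planted = 0.97,
                       background_occupancy = c(0.45, 0.70),
                       seed = 1) {
  if (is.null(regions)) {
    defaults <- c("MS", "NAO", "SAO", "NPO", "SPO", "IO")
    regions <- if (n_regions <= length(defaults)) defaults[seq_len(n_regions)]
               else c(defaults, paste0("R", seq_len(n_regions - length(defaults))))
  }
  cfg <- list(regions = regions, enclosed_region = regions[1],
              layers = layers, samples_per_cell = samples_per_cell,
              n_asvs_prok = n_asvs_prok, n_asvs_euk = n_asvs_euk,
              reads_range = reads_range,
              n_global_pairs = n_global_pairs,
              n_regional_pairs = n_regional_pairs,
              n_layer_pairs = n_layer_pairs,
              n_env_driven_pairs = n_env_driven_pairs,
              n_negative_pairs = n_negative_pairs,
              co_occurrence_strength = co_occurrence_strength,
              zero_inflation = zero_inflation,
              occupancy_planted = occupancy_planted,
              background_occupancy = background_occupancy,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_asvs_prok, cfg$n_asvs_euk, cfg$n_global_pairs,
              cfg$n_regional_pairs, cfg$n_layer_pairs,
              cfg$n_env_driven_pairs, cfg$n_negative_pairs)
  if (any(counts < 0)) stop2("all counts must be >= 0")
  if (cfg$co_occurrence_strength < 0 || cfg$co_occurrence_strength > 1) {
    stop2("co_occurrence_strength must be in [0, 1]")
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1) {
    stop2("zero_inflation must be in [0, 1)")
  }
  if (anyDuplicated(cfg$layers) || length(cfg$layers) < 1) {
    stop2("layers must be a non-empty, strictly ordered vocabulary")
  }
  if (anyDuplicated(cfg$regions)) stop2("duplicate region names")
  if (length(cfg$reads_range) != 2 || cfg$reads_range[1] > cfg$reads_range[2] ||
      cfg$reads_range[1] < 1) {
    stop2("reads_range must be an increasing positive range")
  }
  spc <- cfg$samples_per_cell
  if (is.matrix(spc)) {
    if (!all(dim(spc) == c(length(cfg$regions), length(cfg$layers)))) {
      stop2("samples_per_cell matrix must be regions x layers")
    }
    if (any(spc < 0)) stop2("negative cell sample count")
  } else {
    if (length(spc) != 1 || spc < 1) {
      stop2("zero samples in every region-layer cell; pass a matrix to ",
            "leave specific cells empty")
    }
  }
  n_planted_asvs <- 2 * (cfg$n_global_pairs + cfg$n_regional_pairs +
                         cfg$n_layer_pairs + cfg$n_env_driven_pairs +
                         cfg$n_negative_pairs)
  if (n_planted_asvs > cfg$n_asvs_prok + cfg$n_asvs_euk) {
    stop2("not enough ASVs to host the planted pairs")
  }
  invisible(cfg)
}

# Per-cell sample counts as a regions x layers matrix.
cell_sample_matrix <- function(cfg) {
  spc <- cfg$samples_per_cell
  if (!is.matrix(spc)) {
    spc <- matrix(spc, nrow = length(cfg$regions), ncol = length(cfg$layers))
  }
  dimnames(spc) <- list(cfg$regions, cfg$layers)
  spc
}

# Environmental fields (true values, before missing-value masking). The
# enclosed sea gets a warm, salty deep layer; nutrients increase with depth.
simulate_environment <- function(metadata, cfg) {
  layer <- metadata$layer
  enclosed <- metadata$region == cfg$enclosed_region
  lbase <- function(v) v[match(layer, cfg$layers)]
  n <- nrow(metadata)

  temp_base <- lbase(c(25, 19, 11, 3)[seq_along(cfg$layers)])
  temp_base[enclosed & layer %in% cfg$layers[-(1:2)]] <-
    c(14, 13.8)[match(layer[enclosed & layer %in% cfg$layers[-(1:2)]],
                      cfg$layers[-(1:2)])]
  region_off <- stats::rnorm(length(cfg$regions), 0, 0.8)
  names(region_off) <- cfg$regions
  metadata$temperature <- temp_base + region_off[metadata$region] +
    stats::rnorm(n, 0, 0.7)
  metadata$salinity <- 35.2 + 2.8 * enclosed + stats::rnorm(n, 0, 0.25)
  metadata$fluorescence <- lbase(c(0.25, 1.6, 0.04, 0.02)[seq_along(cfg$layers)]) *
    exp(stats::rnorm(n, 0, 0.3))
  no3_base <- lbase(c(0.4, 2, 16, 21)[seq_along(cfg$layers)])
  no3_base[enclosed] <- no3_base[enclosed] * 0.6
  metadata$no3 <- no3_base * exp(stats::rnorm(n, 0, 0.25))
  metadata$po4 <- metadata$no3 / 16 * exp(stats::rnorm(n, 0, 0.15))
  metadata$sio2 <- lbase(c(1, 3, 20, 30)[seq_along(cfg$layers)]) *
    exp(stats::rnorm(n, 0, 0.25))
  metadata
}

#' Generate a synthetic multi-region, multi-depth dataset
#'
#' Latent-factor model: each ASV is either background (independent presence
#' with an ASV-specific occupancy, log-normal abundance when present) or a
#' member of a planted pair. Planted pair members share a standard-normal
#' latent factor scaled by `co_occurrence_strength`; a member is present
#' when its latent exceeds the occupancy threshold, so presence/absence
#' co-occurrence is directly detectable by a Jaccard condition. Regional
#' (layer-specific) pairs are structurally absent outside their home region
#' (layer). Environmentally-driven pairs replace the shared factor by a
#' standardized environmental gradient, making the two members conditionally
#' independent given the factor. Negative pairs load on the shared factor
#' with opposite signs. Counts are drawn per domain table by multinomial
#' sampling of the per-sample relative abundances at a uniform random read
#' depth, followed by independent dropout (`zero_inflation`).
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset`: list with `prok_counts` and `euk_counts`
#'   ([asv_table]s), `metadata` (one row per sample: region, layer, depth_m
#'   and six environmental variables with a few missing values), `truth`
#'   (planted-pair ledger: asv_a, asv_b, class, scope, rho) and `config`.
#' @export
generate_dataset <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  spc <- cell_sample_matrix(cfg)
  if (all(spc == 0)) stop2("zero samples in every region-layer cell")
  cells <- expand.grid(region = cfg$regions, layer = cfg$layers,
                       stringsAsFactors = FALSE)
  cells$n <- spc[cbind(cells$region, cells$layer)]
  metadata <- data.frame(
    sample = sprintf("S%03d", seq_len(sum(cells$n))),
    region = rep(cells$region, cells$n),
    layer = rep(cells$layer, cells$n),
    stringsAsFactors = FALSE)
  depth_rng <- list(SRF = c(3, 5), DCM = c(60, 120),
                    MES = c(250, 900), BAT = c(1200, 4000))
  metadata$depth_m <- round(vapply(metadata$layer, function(l) {
    r <- depth_rng[[l]] %||% c(3, 5)
    stats::runif(1, r[1], r[2])
  }, numeric(1)))
  metadata <- simulate_environment(metadata, cfg)
  n_samples <- nrow(metadata)

  asv_ids <- c(sprintf("Prok_%03d", seq_len(cfg$n_asvs_prok)),
               sprintf("Euk_%03d", seq_len(cfg$n_asvs_euk)))
  domain <- c(sample(c("Archaea", "Bacteria"), cfg$n_asvs_prok,
                     replace = TRUE, prob = c(0.15, 0.85)),
              rep("Eukaryota", cfg$n_asvs_euk))
  names(domain) <- asv_ids
  taxonomy <- setNames(paste0(domain, ";Clade_", seq_along(asv_ids) %% 17),
                       asv_ids)

  # --- planted-pair ledger -------------------------------------------------
  pair_classes <- c(rep("global", cfg$n_global_pairs),
                    rep("regional", cfg$n_regional_pairs),
                    rep("layer", cfg$n_layer_pairs),
                    rep("env", cfg$n_env_driven_pairs),
                    rep("negative", cfg$n_negative_pairs))
  n_pairs <- length(pair_classes)
  planted_asvs <- sample(asv_ids, 2 * n_pairs)
  truth <- data.frame(
    asv_a = planted_asvs[seq_len(n_pairs) * 2 - 1],
    asv_b = planted_asvs[seq_len(n_pairs) * 2],
    class = pair_classes,
    scope = rep(NA_character_, n_pairs),
    rho = rep(cfg$co_occurrence_strength, n_pairs),
    stringsAsFactors = FALSE)
  if (cfg$n_regional_pairs > 0) {
    truth$scope[truth$class == "regional"] <-
      rep(cfg$regions, length.out = cfg$n_regional_pairs)
  }
  if (cfg$n_layer_pairs > 0) {
    truth$scope[truth$class == "layer"] <-
      rep(cfg$layers, length.out = cfg$n_layer_pairs)
  }
  env_factors <- c("temperature", "no3")
  if (cfg$n_env_driven_pairs > 0) {
    truth$scope[truth$class == "env"] <-
      rep(env_factors, length.out = cfg$n_env_driven_pairs)
  }

  # --- latent abundances ---------------------------------------------------
  n_asvs <- length(asv_ids)
  rho <- cfg$co_occurrence_strength
  present <- matrix(FALSE, n_asvs, n_samples, dimnames = list(asv_ids, NULL))
  zmat <- matrix(0, n_asvs, n_samples, dimnames = list(asv_ids, NULL))
  mu <- stats::rnorm(n_asvs, 0, 1)
  names(mu) <- asv_ids

  is_planted <- asv_ids %in% planted_asvs
  occ_bg <- stats::runif(n_asvs, cfg$background_occupancy[1],
                         cfg$background_occupancy[2])
  for (i in which(!is_planted)) {
    z <- stats::rnorm(n_samples)
    present[i, ] <- stats::runif(n_samples) < occ_bg[i]
    zmat[i, ] <- z
  }

  thr_planted <- stats::qnorm(1 - cfg$occupancy_planted)
  for (p in seq_len(n_pairs)) {
    a <- truth$asv_a[p]; b <- truth$asv_b[p]
    cls <- truth$class[p]
    mu[c(a, b)] <- stats::rnorm(2, 1.0, 0.3)  # keep planted members countable
    if (cls == "env") {
      evar <- metadata[[truth$scope[p]]]
      g <- as.numeric(scale(evar))
      # nutrients increase with depth while the planted latent should rise
      # toward the factor's high end either way; orientation is irrelevant
      za <- rho * g + sqrt(1 - rho^2) * stats::rnorm(n_samples)
      zb <- rho * g + sqrt(1 - rho^2) * stats::rnorm(n_samples)
      thr <- stats::qnorm(0.5)  # occupancy 0.5, driven by the gradient
      pa <- za > thr; pb <- zb > thr
    } else {
      g <- stats::rnorm(n_samples)
      za <- rho * g + sqrt(1 - rho^2) * stats::rnorm(n_samples)
      sgn <- if (cls == "negative") -1 else 1
      zb <- sgn * rho * g + sqrt(1 - rho^2) * stats::rnorm(n_samples)
      # co-excluding taxa get a moderate occupancy so their rare joint
      # presence stays below any co-occurrence condition
      thr <- if (cls == "negative") stats::qnorm(1 - 0.35) else thr_planted
      pa <- za > thr; pb <- zb > thr
    }
    scope_mask <- rep(TRUE, n_samples)
    if (cls == "regional") scope_mask <- metadata$region == truth$scope[p]
    if (cls == "layer")    scope_mask <- metadata$layer == truth$scope[p]
    present[a, ] <- pa & scope_mask
    present[b, ] <- pb & scope_mask
    zmat[a, ] <- za
    zmat[b, ] <- zb
  }

  rel <- exp(mu + 0.6 * zmat) * present

  # --- multinomial counts per domain table, then dropout -------------------
  draw_counts <- function(ids) {
    w <- rel[ids, , drop = FALSE]
    depth <- round(stats::runif(n_samples, cfg$reads_range[1],
                                cfg$reads_range[2]))
    counts <- matrix(0L, length(ids), n_samples,
                     dimnames = list(ids, metadata$sample))
    for (s in seq_len(n_samples)) {
      ws <- w[, s]
      if (sum(ws) > 0) {
        counts[, s] <- stats::rmultinom(1, depth[s], ws)[, 1]
      }
    }
    if (cfg$zero_inflation > 0) {
      nz <- which(counts > 0)
      drop <- nz[stats::runif(length(nz)) < cfg$zero_inflation]
      counts[drop] <- 0L
    }
    counts
  }
  prok_ids <- asv_ids[seq_len(cfg$n_asvs_prok)]
  euk_ids <- setdiff(asv_ids, prok_ids)
  prok_counts <- draw_counts(prok_ids)
  euk_counts <- draw_counts(euk_ids)

  # mask a few environmental values, emulating incomplete measurements
  for (v in c("temperature", "salinity")) {
    miss <- stats::runif(n_samples) < 0.005
    metadata[[v]][miss] <- NA_real_
  }
  metadata$fluorescence[stats::runif(n_samples) < 0.01] <- NA_real_
  for (v in c("no3", "po4", "sio2")) {
    miss <- stats::runif(n_samples) < 0.08
    metadata[[v]][miss] <- NA_real_
  }

  structure(list(
    prok_counts = asv_table(prok_counts, domain[prok_ids], taxonomy[prok_ids]),
    euk_counts = asv_table(euk_counts, domain[euk_ids], taxonomy[euk_ids]),
    metadata = metadata,
    truth = truth,
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples (%d regions x %d layers), %d prok + %d euk ASVs, %d planted pairs\n",
              nrow(x$metadata), length(unique(x$metadata$region)),
              length(unique(x$metadata$layer)),
              nrow(x$prok_counts$counts), nrow(x$euk_counts$counts),
              nrow(x$truth)))
  invisible(x)
}

#' Build a static association network from the planted truth
#'
#' Turns the planted-truth ledger into a static network: every planted pair
#' becomes an edge (negative pairs with a negative score) and
#' `n_background_edges` decoy edges are added between background ASVs so
#' that downstream classification faces non-planted competition. Decoys
#' are the most strongly correlated background pairs (depth-normalized
#' abundances), mirroring how a real static network's edges come to exist:
#' an inference tool only emits pairs that showed an association signal,
#' so even its spurious edges carry observed correlation rather than pure
#' independence. The decoy score is that observed correlation.
#'
#' @param dataset a `synthetic_dataset`.
#' @param n_background_edges decoy edges between unplanted ASVs.
#' @param seed RNG seed (planted-edge scores and candidate subsampling).
#' @return a [static_network]; per-edge truth classes (planted class or
#'   "background") are attached as `attr(net, "edge_class")`, keyed by the
#'   canonical edge key.
#' @export
truth_static_network <- function(dataset, n_background_edges = 30, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  set.seed(derive_seed(seed, "truth-net"))
  truth <- dataset$truth
  planted <- unique(c(truth$asv_a, truth$asv_b))
  score <- stats::runif(nrow(truth), 0.3, 0.9)
  score[truth$class == "negative"] <- -score[truth$class == "negative"]
  edges <- data.frame(a = truth$asv_a, b = truth$asv_b, score = score,
                      stringsAsFactors = FALSE)
  cls <- truth$class
  if (n_background_edges > 0) {
    relab <- function(m) sweep(m, 2, pmax(1, colSums(m)), "/")
    rel <- rbind(relab(dataset$prok_counts$counts),
                 relab(dataset$euk_counts$counts))
    pool <- setdiff(rownames(rel), planted)
    cors <- stats::cor(t(rel[pool, , drop = FALSE]))
    cors[!upper.tri(cors)] <- 0
    cors[is.na(cors)] <- 0
    ord <- order(abs(cors), decreasing = TRUE)[seq_len(n_background_edges)]
    idx <- arrayInd(ord, dim(cors))
    add <- data.frame(a = pool[idx[, 1]], b = pool[idx[, 2]],
                      score = cors[ord], stringsAsFactors = FALSE)
    edges <- rbind(edges, add)
    cls <- c(cls, rep("background", n_background_edges))
  }
  domains <- c(dataset$prok_counts$domain, dataset$euk_counts$domain)
  net <- static_network(edges, domains)
  # classes keyed canonically so reordering inside the constructor is safe
  attr(net, "edge_class") <- setNames(cls, edge_key(edges$a, edges$b))
  net
}

#' Write a synthetic dataset as a plain-text fixture directory
#'
#' Emits `prok_counts.tsv`, `euk_counts.tsv` (asv_id, domain, taxonomy, then
#' one integer column per sample), `metadata.tsv` (empty cell = missing
#' value) and `truth.tsv`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_counts <- function(tab, file) {
    df <- data.frame(asv_id = rownames(tab$counts),
                     domain = unname(tab$domain),
                     taxonomy = unname(tab$taxonomy %||%
                                       rep("", nrow(tab$counts))),
                     tab$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(directory, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_counts(dataset$prok_counts, "prok_counts.tsv")
  write_counts(dataset$euk_counts, "euk_counts.tsv")
  md <- dataset$metadata
  num <- vapply(md, is.numeric, logical(1))
  md[num] <- lapply(md[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  })
  utils::write.table(md, file.path(directory, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(dataset$truth, file.path(directory, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(directory)
}

read_fixture_counts <- function(path) {
  if (!file.exists(path)) stop2("missing fixture file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("asv_id", "domain", "taxonomy")
  if (!all(need %in% names(df)[1:3])) {
    stop2(path, ": first columns must be asv_id, domain, taxonomy")
  }
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  if (any(is.na(counts)) || any(counts != floor(counts)) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts != floor(counts) | counts < 0,
                 arr.ind = TRUE)[1, ]
    stop2(path, ": non-integer or negative count at row ", bad[1] + 1,
          " column ", bad[2] + 3)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$asv_id
  tax <- df$taxonomy
  tax[is.na(tax)] <- ""
  asv_table(counts, setNames(df$domain, df$asv_id), setNames(tax, df$asv_id))
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return a `synthetic_dataset` (without the generating `config`).
#' @export
read_fixture <- function(directory) {
  if (!dir.exists(directory)) stop2("fixture directory not found: ", directory)
  prok <- read_fixture_counts(file.path(directory, "prok_counts.tsv"))
  euk <- read_fixture_counts(file.path(directory, "euk_counts.tsv"))
  md_path <- file.path(directory, "metadata.tsv")
  if (!file.exists(md_path)) stop2("missing fixture file: ", md_path)
  metadata <- utils::read.delim(md_path, stringsAsFactors = FALSE, na.strings = "")
  truth_path <- file.path(directory, "truth.tsv")
  if (!file.exists(truth_path)) stop2("missing fixture file: ", truth_path)
  truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE,
                             na.strings = "NA")
  if (nrow(truth)) truth$scope <- as.character(truth$scope)
  samples <- metadata$sample
  for (nm in c("prok_counts.tsv", "euk_counts.tsv")) {
    tab <- if (nm == "prok_counts.tsv") prok else euk
    if (!identical(colnames(tab$counts), samples)) {
      stop2(nm, ": sample ids do not match metadata.tsv")
    }
  }
  planted <- c(truth$asv_a, truth$asv_b)
  known <- c(rownames(prok$counts), rownames(euk$counts))
  if (!all(planted %in% known)) {
    stop2("truth.tsv references unknown ASVs: ",
          paste(setdiff(planted, known), collapse = ", "))
  }
  structure(list(prok_counts = prok, euk_counts = euk, metadata = metadata,
                 truth = truth, config = NULL), class = "synthetic_dataset")
}
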