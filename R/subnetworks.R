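# Sample-specific subnetwork derivation. An edge {A, B} of the static
# network enters the subnetwork of sample s (region R, layer L) iff
#   (i)   it is a static-network edge,
#   (ii)  both A and B have count > 0 in s, and
#   (iii) the region-and-layer Jaccard index J_RL of the pair is strictly
#         above the threshold (default 20%; edges at or below are removed).
# Nodes are endpoints of retained edges (no isolated nodes).

#' Region- and layer-specific Jaccard co-occurrence of edge pairs
#'
#' For every (region, layer) group of samples and every edge, the fraction
#' of the group's samples where both endpoints are present (count > 0) out
#' of the samples where at least one is present. An empty union is recorded
#' as missing (`NA`), never as 0.
#'
#' @param counts an [asv_table] covering every edge endpoint.
#' @param metadata data.frame with `sample`, `region`, `layer`.
#' @param edges data.frame with columns `a`, `b` (e.g. a static network's
#'   `$edges`).
#' @return data.frame: region, layer, a, b, n_both, n_either, jaccard.
#' @export
jaccard_table <- function(counts, metadata, edges) {
  stopifnot(inherits(counts, "asv_table"))
  endpoints <- unique(c(edges$a, edges$b))
  missing <- setdiff(endpoints, rownames(counts$counts))
  if (length(missing)) {
    stop2("edge endpoints absent from the count table: ",
          paste(missing, collapse = ", "))
  }
  if (!all(metadata$sample %in% colnames(counts$counts))) {
    stop2("metadata lists samples absent from the count table")
  }
  presence <- counts$counts[endpoints, metadata$sample, drop = FALSE] > 0
  groups <- split(seq_len(nrow(metadata)),
                  list(region = metadata$region, layer = metadata$layer),
                  drop = TRUE)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    pa <- presence[edges$a, idx, drop = FALSE]
    pb <- presence[edges$b, idx, drop = FALSE]
    n_both <- rowSums(pa & pb)
    n_either <- rowSums(pa | pb)
    rl <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(region = rl[1], layer = rl[2], a = edges$a, b = edges$b,
               n_both = unname(n_both), n_either = unname(n_either),
               jaccard = ifelse(n_either > 0, n_both / n_either, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Fast lookup: jaccard values keyed by "region|layer" -> named vector by edge.
jaccard_lookup <- function(jt) {
  key <- paste(jt$region, jt$layer, sep = "\r")
  split(setNames(jt$jaccard, edge_key(jt$a, jt$b)), key)
}

#' Derive one sample-specific subnetwork
#'
#' @param sample sample id (must appear in `metadata` and `counts`).
#' @param counts an [asv_table].
#' @param metadata data.frame with `sample`, `region`, `layer`.
#' @param static a [static_network].
#' @param jt Jaccard table from [jaccard_table()] (computed on the full
#'   sample set); if `NULL` it is computed on the fly.
#' @param threshold strict Jaccard threshold (default 0.20): an edge with
#'   J_RL exactly at the threshold is excluded, as is an undefined J_RL.
#' @return a `subnetwork`: list with `sample`, `region`, `layer`, `edges`
#'   (a, b, score) and `nodes`.
#' @export
derive_subnetwork <- function(sample, counts, metadata, static, jt = NULL,
                              threshold = 0.20) {
  stopifnot(inherits(static, "static_network"))
  row <- metadata[metadata$sample == sample, , drop = FALSE]
  if (nrow(row) != 1) stop2("sample not found in metadata: ", sample)
  if (!sample %in% colnames(counts$counts)) {
    stop2("sample not found in the count table: ", sample)
  }
  if (is.null(jt)) jt <- jaccard_table(counts, metadata, static$edges)
  jl <- jaccard_lookup(jt)
  build_subnetwork(sample, row$region, row$layer,
                   counts$counts[, sample] > 0, static, jl, threshold)
}

build_subnetwork <- function(sample, region, layer, present, static, jl,
                             threshold) {
  edges <- static$edges
  jvec <- jl[[paste(region, layer, sep = "\r")]]
  j <- jvec[edge_key(edges$a, edges$b)]
  keep <- !is.na(j) & j > threshold &
    present[edges$a] & present[edges$b]
  keep[is.na(keep)] <- FALSE
  sub_edges <- edges[keep, c("a", "b", "score"), drop = FALSE]
  rownames(sub_edges) <- NULL
  structure(list(sample = sample, region = region, layer = layer,
                 edges = sub_edges,
                 nodes = sort(unique(c(sub_edges$a, sub_edges$b)))),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> sample %s (%s/%s): %d nodes, %d edges\n",
              x$sample, x$region, x$layer, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Derive all sample-specific subnetworks
#'
#' @inheritParams derive_subnetwork
#' @return a `subnetwork_set`: list with `subnetworks` (named list, one per
#'   metadata sample), `metadata`, `static`, `jaccard` (the Jaccard table)
#'   and `threshold`.
#' @export
derive_all <- function(counts, metadata, static, threshold = 0.20) {
  stopifnot(inherits(counts, "asv_table"), inherits(static, "static_network"))
  jt <- jaccard_table(counts, metadata, static$edges)
  jl <- jaccard_lookup(jt)
  presence <- counts$counts[, metadata$sample, drop = FALSE] > 0
  subs <- lapply(seq_len(nrow(metadata)), function(i) {
    build_subnetwork(metadata$sample[i], metadata$region[i],
                     metadata$layer[i], presence[, i], static, jl, threshold)
  })
  names(subs) <- metadata$sample
  structure(list(subnetworks = subs, metadata = metadata, static = static,
                 jaccard = jt, threshold = threshold),
            class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  sizes <- vapply(x$subnetworks, function(s) nrow(s$edges), integer(1))
  cat(sprintf("<subnetwork_set> %d subnetworks (J > %.2f), edges per subnetwork: median %d [%d, %d]\n",
              length(x$subnetworks), x$threshold,
              as.integer(stats::median(sizes)), min(sizes), max(sizes)))
  invisible(x)
}

#' Robustness of the Jaccard condition to subsampling
#'
#' Within each (region, layer) group with at least two samples, draws
#' random subsets containing each `fraction` of the group's samples
#' (sizes rounded up, so no subset is empty), recomputes the Jaccard index
#' on the subset, and compares the edges passing `J > threshold` with those
#' passing on the full group: the size ratio (kept-in-subset over
#' kept-on-all) and the fraction of the full group's kept edges that are
#' also kept in the subset. Single-sample groups are skipped with a notice.
#'
#' @param counts an [asv_table].
#' @param metadata data.frame with `sample`, `region`, `layer`.
#' @param static a [static_network].
#' @param fractions subset fractions (default 0.1 to 0.9 by 0.1).
#' @param reps random subsets per (group, fraction) (default 1000).
#' @param threshold strict Jaccard threshold (default 0.20).
#' @param seed master seed; each (group, fraction) derives an independent
#'   stream, so results are reproducible under any evaluation order.
#' @return data.frame: region, layer, fraction, subset_size, mean and sd of
#'   the two metrics across reps.
#' @export
subsample_robustness <- function(counts, metadata, static,
                                 fractions = seq(0.1, 0.9, by = 0.1),
                                 reps = 1000, threshold = 0.20, seed = 1) {
  stopifnot(inherits(counts, "asv_table"), inherits(static, "static_network"))
  edges <- static$edges
  endpoints <- unique(c(edges$a, edges$b))
  presence <- counts$counts[endpoints, metadata$sample, drop = FALSE] > 0
  groups <- split(seq_len(nrow(metadata)),
                  list(region = metadata$region, layer = metadata$layer),
                  drop = TRUE)
  kept_edges <- function(idx) {
    pa <- presence[edges$a, idx, drop = FALSE]
    pb <- presence[edges$b, idx, drop = FALSE]
    n_both <- rowSums(pa & pb)
    n_either <- rowSums(pa | pb)
    which(n_either > 0 & n_both / n_either > threshold)
  }
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    rl <- strsplit(g, ".", fixed = TRUE)[[1]]
    if (length(idx) < 2) {
      message("skipping ", rl[1], "/", rl[2], ": only one sample")
      next
    }
    full_kept <- kept_edges(idx)
    for (f in fractions) {
      size <- ceiling(f * length(idx))
      set.seed(derive_seed(seed, "robustness", g, sprintf("%.6f", f)))
      ratio <- numeric(reps)
      ident <- numeric(reps)
      for (r in seq_len(reps)) {
        sub_idx <- idx[sample.int(length(idx), size)]
        sub_kept <- kept_edges(sub_idx)
        if (length(full_kept) == 0) {
          ratio[r] <- NA_real_; ident[r] <- NA_real_
        } else {
          ratio[r] <- length(sub_kept) / length(full_kept)
          ident[r] <- length(intersect(sub_kept, full_kept)) / length(full_kept)
        }
      }
      out[[length(out) + 1]] <- data.frame(
        region = rl[1], layer = rl[2], fraction = f, subset_size = size,
        n_samples = length(idx),
        mean_kept_ratio = mean(ratio), sd_kept_ratio = stats::sd(ratio),
        mean_identity_kept = mean(ident), sd_identity_kept = stats::sd(ident),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
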