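# Recovery of the planted truth: how well the pipeline's classification and
# environmental edge filter recover what the generator planted.

precision_recall <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  list(precision = if (length(predicted)) tp / length(predicted) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       tp = tp, n_predicted = length(predicted), n_truth = length(truth))
}

#' Planted-truth recovery of spatial classes and environmental filtering
#'
#' Scores the per-layer classification against the classes the planted
#' design implies, micro-averaged over layers. Expected global in layer L:
#' the planted global pairs (planted in every region and layer) plus the
#' layer-specific pairs whose home layer is L — within its home layer a
#' layer-specific pair spans all regions at high prevalence, so the global
#' definition is the correct call for it there. Expected regional: the
#' planted regional pairs, in every layer of their home region.
#' Environmentally-driven pairs are scored by the removal metric only
#' (removed set vs. planted env pairs) and are excluded from the spatial
#' scoring universe, since their expected spatial class depends on whether
#' the filter caught them.
#'
#' @param truth planted-pair ledger of a `synthetic_dataset`.
#' @param classified list of [classify_layer()] results (one per layer,
#'   enclosed sea included).
#' @param removed character vector of removed edge keys (from
#'   [remove_env_driven_edges()]'s report), or `NULL` to skip.
#' @return data.frame: class, precision, recall, tp, n_predicted, n_truth.
#' @export
planted_recovery <- function(truth, classified, removed = NULL) {
  truth_key <- edge_key(truth$asv_a, truth$asv_b)
  env_keys <- truth_key[truth$class == "env"]
  expected <- function(cls, layer) {
    if (cls == "global") {
      truth_key[truth$class == "global" |
                  (truth$class == "layer" & truth$scope == layer)]
    } else {
      truth_key[truth$class == "regional"]
    }
  }
  out <- list()
  for (cls in c("global", "regional")) {
    pred <- character(0)
    tr <- character(0)
    for (cl in classified) {
      layer <- unique(cl$layer)
      keys <- edge_key(cl$a, cl$b)
      pk <- keys[cl$class == cls & !(keys %in% env_keys)]
      pred <- c(pred, paste(layer, pk))
      tr <- c(tr, paste(layer, expected(cls, layer)))
    }
    pr <- precision_recall(pred, tr)
    out[[cls]] <- data.frame(class = cls, precision = pr$precision,
                             recall = pr$recall, tp = pr$tp,
                             n_predicted = pr$n_predicted,
                             n_truth = pr$n_truth)
  }
  if (!is.null(removed)) {
    pr <- precision_recall(removed, env_keys)
    out$env <- data.frame(class = "env_driven_removed",
                          precision = pr$precision, recall = pr$recall,
                          tp = pr$tp, n_predicted = pr$n_predicted,
                          n_truth = pr$n_truth)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
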