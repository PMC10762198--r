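# Information-theoretic detection of environmentally-driven edges.
#
# An association between ASVs A and B is suspected to be driven by an
# environmental factor E when (a) the interaction information
# II = CMI(A;B|E) - MI(A;B) is negative (the factor explains, i.e. makes
# redundant, part of the pairwise association) with permutation support,
# and (b) the data-processing inequality flags the A-B link as the weakest
# of the triplet. An edge is removed when BOTH verdicts agree for at least
# one factor; factors are evaluated independently on the samples where they
# are measured.

#' Equal-frequency discretization
#'
#' Bins a numeric vector into (at most) `bins` equal-frequency levels.
#' Heavily tied values (e.g. structural zeros) collapse bins, so the
#' effective number of levels can be smaller. Constant vectors map to a
#' single level.
#'
#' @param x numeric vector.
#' @param bins requested number of bins (>= 2).
#' @return integer codes in `1:bins`.
#' @export
discretize_ef <- function(x, bins = 4) {
  if (bins < 2) stop2("bins must be >= 2")
  ux <- unique(x)
  if (length(ux) <= 1) return(rep(1L, length(x)))
  if (length(ux) <= bins) {
    return(as.integer(factor(x, levels = sort(ux))))
  }
  # a dominant tie (e.g. structural zeros) gets its own bin, so the
  # remaining values keep their resolution instead of being crowded into
  # the top bins by mass
  counts <- tabulate(match(x, ux))
  if (max(counts) / length(x) >= 1 / bins) {
    mode_val <- ux[which.max(counts)]
    is_mode <- x == mode_val
    rest <- x[!is_mode]
    codes <- integer(length(x))
    codes[is_mode] <- 1L
    codes[!is_mode] <- if (bins >= 3) 1L + discretize_ef(rest, bins - 1L)
                       else 2L
    return(as.integer(factor(codes)))
  }
  # equal-frequency by rank; ties share their first occurrence's rank
  r <- rank(x, ties.method = "min")
  codes <- as.integer(ceiling(r * bins / length(x)))
  as.integer(factor(codes))
}

# Plug-in MI (nats) from a joint count matrix.
mi_from_counts <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(tab > 0, arr.ind = TRUE)
  sum(p[nz] * log(p[nz] / (px[nz[, 1]] * py[nz[, 2]])))
}

mi_disc <- function(a, b, Ba, Bb) {
  tab <- matrix(tabulate((a - 1L) * Bb + b, nbins = Ba * Bb),
                nrow = Ba, ncol = Bb, byrow = TRUE)
  mi_from_counts(tab)
}

cmi_disc <- function(a, b, e, Ba, Bb, Be) {
  n <- length(a)
  tab <- tabulate((e - 1L) * (Ba * Bb) + (a - 1L) * Bb + b,
                  nbins = Be * Ba * Bb)
  arr <- array(tab, dim = c(Bb, Ba, Be))  # [b, a, e]
  total <- 0
  for (k in seq_len(Be)) {
    m <- arr[, , k]
    ne <- sum(m)
    if (ne > 0) total <- total + ne / n * mi_from_counts(t(m))
  }
  total
}

#' Mutual information of two samples (plug-in, nats)
#'
#' Both vectors are discretized by equal-frequency binning and the plug-in
#' (maximum-likelihood) mutual information of the joint distribution is
#' returned, in nats. Constant vectors carry no entropy and give 0.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param bins equal-frequency bins (default 4; see the methods vignette
#'   for why a small fixed bin count is used).
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 4) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (length(x) < 3) stop2("need at least 3 observations")
  a <- discretize_ef(x, bins)
  b <- discretize_ef(y, bins)
  max(0, mi_disc(a, b, max(a), max(b)))
}

#' Interaction information of an ASV pair given an environmental factor
#'
#' `II = CMI(A;B|E) - MI(A;B)` on equal-frequency-discretized vectors,
#' restricted to the samples where the factor is measured. Negative II
#' signals redundancy: the factor explains part of the A-B association.
#'
#' @param a,b numeric abundance vectors.
#' @param env numeric factor vector (missing values allowed; those samples
#'   are dropped).
#' @param bins equal-frequency bins (default 4).
#' @return II in nats, with attribute `n_used` (samples retained) and
#'   `low_confidence` set when fewer than `bins^2` usable samples remain.
#' @export
interaction_information <- function(a, b, env, bins = 4) {
  if (length(a) != length(b) || length(a) != length(env)) {
    stop2("a, b and env must have equal length")
  }
  keep <- !is.na(env) & !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]; e <- env[keep]
  low_conf <- FALSE
  if (length(a) < bins^2) {
    warn2("only ", length(a), " usable samples for ", bins,
          " bins; interaction information flagged low-confidence")
    low_conf <- TRUE
  }
  if (length(a) < 3) {
    return(structure(0, n_used = length(a), low_confidence = TRUE))
  }
  ca <- discretize_ef(a, bins)
  cb <- discretize_ef(b, bins)
  ce <- discretize_ef(e, bins)
  ii <- cmi_disc(ca, cb, ce, max(ca), max(cb), max(ce)) -
    mi_disc(ca, cb, max(ca), max(cb))
  structure(ii, n_used = length(a), low_confidence = low_conf)
}

#' Permutation test for negative interaction information
#'
#' Permutes the environmental factor across samples and recomputes II. The
#' one-sided p-value is the (add-one corrected) fraction of permuted
#' replicates with II less than or equal to the observed II. The plug-in
#' CMI term carries a positive finite-sample bias (roughly the number of
#' extra cells over 2n), so the raw II of an unrelated triplet sits above
#' zero; the permutation replicates estimate exactly that null level, and
#' the bias-corrected `ii_centered = ii - mean(ii_perm)` is the quantity
#' whose sign is interpretable. The verdict is significant only when the
#' centered II is negative AND p <= alpha; a synergistic triplet (II above
#' its null level) is never significant, whatever the p-value.
#'
#' @param a,b,env as in [interaction_information()].
#' @param bins equal-frequency bins.
#' @param n_iter permutations (default 10000; a warning is given below 100).
#' @param alpha significance threshold (default 0.05).
#' @param seed RNG seed; identical seeds give identical p-values.
#' @return list with `ii` (raw plug-in), `ii_centered`, `p_value`,
#'   `significant`, `n_iter`.
#' @export
ii_permutation_test <- function(a, b, env, bins = 4, n_iter = 10000,
                                alpha = 0.05, seed = 1) {
  if (n_iter < 100) warn2("n_iter < 100 gives a coarse p-value")
  keep <- !is.na(env) & !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]; e <- env[keep]
  if (length(a) < 3) {
    return(list(ii = 0, ii_centered = 0, p_value = 1, significant = FALSE,
                n_iter = n_iter))
  }
  ca <- discretize_ef(a, bins)
  cb <- discretize_ef(b, bins)
  ce <- discretize_ef(e, bins)
  Ba <- max(ca); Bb <- max(cb); Be <- max(ce)
  mi_ab <- mi_disc(ca, cb, Ba, Bb)
  ii_obs <- cmi_disc(ca, cb, ce, Ba, Bb, Be) - mi_ab
  set.seed(seed)
  hits <- 0L
  perm_sum <- 0
  for (i in seq_len(n_iter)) {
    ep <- ce[sample.int(length(ce))]
    ii_p <- cmi_disc(ca, cb, ep, Ba, Bb, Be) - mi_ab
    perm_sum <- perm_sum + ii_p
    if (ii_p <= ii_obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_iter + 1)
  centered <- unname(ii_obs - perm_sum / n_iter)
  list(ii = unname(ii_obs), ii_centered = centered, p_value = p,
       significant = centered < 0 && p <= alpha, n_iter = n_iter)
}

#' Data-processing inequality verdict for a triplet
#'
#' In the triplet (A, B, E), the A-B edge is flagged as potentially indirect
#' when its mutual information is strictly the smallest of the three; ties
#' are not flagged.
#'
#' @param mi_ab,mi_ae,mi_be non-negative mutual informations.
#' @return logical: is the A-B link the strict minimum?
#' @export
data_processing_inequality <- function(mi_ab, mi_ae, mi_be) {
  stopifnot(mi_ab >= 0, mi_ae >= 0, mi_be >= 0)
  mi_ab < mi_ae && mi_ab < mi_be
}

#' Remove environmentally-driven edges from a static network
#'
#' For each environmental factor (evaluated independently, on the samples
#' where that factor is measured), an edge is flagged when the interaction
#' information permutation test is significant AND the data-processing
#' inequality marks the edge as the weakest link of its (A, B, factor)
#' triplet. The removed set is the union of the per-factor flags.
#'
#' @param net a [static_network].
#' @param abund numeric abundance matrix (ASVs x samples) covering every
#'   edge endpoint; typically the filtered count table.
#' @param env_table data.frame of per-sample environmental values, rows
#'   aligned with `colnames(abund)` (a `sample` column is honoured).
#' @param factors character vector of `env_table` columns to test.
#' @param bins equal-frequency bins (default 4).
#' @param n_iter permutations per test (default 10000).
#' @param alpha significance threshold (default 0.05).
#' @param seed master seed; each factor derives its own stream, so a
#'   factor's verdicts do not depend on which other factors are run.
#' @return list with `network` (edges removed; nodes untouched — call
#'   [remove_isolated_nodes()] to finalize) and `report`: `per_factor`
#'   (factor, n_flagged, fraction) and `per_edge` (one row per edge x
#'   factor: II, p-value, DPI verdict, flagged).
#' @export
remove_env_driven_edges <- function(net, abund, env_table,
                                    factors = c("temperature", "salinity",
                                                "fluorescence", "no3",
                                                "po4", "sio2"),
                                    bins = 4, n_iter = 10000, alpha = 0.05,
                                    seed = 1) {
  stopifnot(inherits(net, "static_network"))
  missing_factors <- setdiff(factors, names(env_table))
  if (length(missing_factors)) {
    stop2("factor(s) not in env_table: ", paste(missing_factors, collapse = ", "))
  }
  if ("sample" %in% names(env_table) && !is.null(colnames(abund))) {
    env_table <- env_table[match(colnames(abund), env_table$sample), ,
                           drop = FALSE]
  }
  missing_nodes <- setdiff(c(net$edges$a, net$edges$b), rownames(abund))
  if (length(missing_nodes)) {
    stop2("edge endpoints missing from the abundance matrix: ",
          paste(missing_nodes, collapse = ", "))
  }

  edges <- net$edges
  n_edges <- nrow(edges)
  per_edge <- list()
  flagged_any <- rep(FALSE, n_edges)
  per_factor <- data.frame(factor = character(0), n_flagged = integer(0),
                           fraction = numeric(0))

  for (f in factors) {
    evals <- env_table[[f]]
    usable <- !is.na(evals)
    if (!any(usable)) {
      warn2("factor '", f, "' has no measured values; skipped")
      next
    }
    fseed <- derive_seed(seed, "ended", f)
    rows <- data.frame(a = edges$a, b = edges$b, factor = f,
                       ii = NA_real_, p_value = NA_real_,
                       dpi = NA, flagged = FALSE,
                       stringsAsFactors = FALSE)
    for (i in seq_len(n_edges)) {
      av <- abund[edges$a[i], usable]
      bv <- abund[edges$b[i], usable]
      ev <- evals[usable]
      test <- ii_permutation_test(av, bv, ev, bins = bins, n_iter = n_iter,
                                  alpha = alpha, seed = fseed + i)
      mi_ab <- mutual_information(av, bv, bins)
      mi_ae <- mutual_information(av, ev, bins)
      mi_be <- mutual_information(bv, ev, bins)
      dpi <- data_processing_inequality(mi_ab, mi_ae, mi_be)
      rows$ii[i] <- test$ii
      rows$p_value[i] <- test$p_value
      rows$dpi[i] <- dpi
      rows$flagged[i] <- test$significant && dpi
    }
    per_edge[[f]] <- rows
    flagged_any <- flagged_any | rows$flagged
    per_factor <- rbind(per_factor,
                        data.frame(factor = f, n_flagged = sum(rows$flagged),
                                   fraction = sum(rows$flagged) / n_edges))
  }

  net$edges <- edges[!flagged_any, , drop = FALSE]
  rownames(net$edges) <- NULL
  list(network = net,
       report = list(per_factor = per_factor,
                     per_edge = do.call(rbind, c(per_edge,
                                                 make.row.names = FALSE)),
                     removed = edge_key(edges$a, edges$b)[flagged_any]))
}
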