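# Spatial recurrence of associations: prevalence per grouping, five-way
# spatial classes per depth layer (global / prevalent / low-frequency /
# regional / other, plus absent), highly-prevalent sets, domain-pair
# categories, vertical first-appearance profiles, and the per-layer summary
# accounting table.

LAYER_VOCABULARY <- c("SRF", "DCM", "MES", "BAT")

# Layers that take part in per-layer classification; epipelagic samples that
# belong to neither the surface nor the DCM sublayer carry this tag: they
# get subnetworks but are excluded from layer-specific classification.
EPI_OTHER <- "EPI_OTHER"

#' Association prevalence
#'
#' Fraction of subnetworks containing each static-network edge, either over
#' all subnetworks (`grouping = "all"`) or within each (region, layer)
#' combination. Edges never appearing get prevalence 0.
#'
#' @param subnets a `subnetwork_set` from [derive_all()].
#' @param grouping "all" or "region_layer".
#' @return data.frame. For "all": a, b, n_present, n_subnetworks,
#'   prevalence. For "region_layer": region, layer, a, b, n_present,
#'   n_subnetworks, prevalence.
#' @export
prevalence <- function(subnets, grouping = c("all", "region_layer")) {
  stopifnot(inherits(subnets, "subnetwork_set"))
  grouping <- match.arg(grouping)
  if (length(subnets$subnetworks) == 0) stop2("empty subnetwork set")
  edges <- subnets$static$edges
  keys <- edge_key(edges$a, edges$b)
  count_in <- function(subs) {
    tallies <- setNames(integer(length(keys)), keys)
    for (s in subs) {
      if (nrow(s$edges)) {
        k <- edge_key(s$edges$a, s$edges$b)
        tallies[k] <- tallies[k] + 1L
      }
    }
    tallies
  }
  if (grouping == "all") {
    n <- length(subnets$subnetworks)
    tal <- count_in(subnets$subnetworks)
    return(data.frame(a = edges$a, b = edges$b, n_present = unname(tal),
                      n_subnetworks = n, prevalence = unname(tal) / n,
                      stringsAsFactors = FALSE))
  }
  md <- subnets$metadata
  groups <- split(md$sample, list(region = md$region, layer = md$layer),
                  drop = TRUE)
  out <- lapply(names(groups), function(g) {
    rl <- strsplit(g, ".", fixed = TRUE)[[1]]
    subs <- subnets$subnetworks[groups[[g]]]
    tal <- count_in(subs)
    data.frame(region = rl[1], layer = rl[2], a = edges$a, b = edges$b,
               n_present = unname(tal), n_subnetworks = length(subs),
               prevalence = unname(tal) / length(subs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify the associations of one depth layer
#'
#' Hierarchical assignment from the per-region prevalences p_r of the layer
#' (strict thresholds): global if min p_r > 0.7 over the considered
#' regions; else prevalent if min p_r > 0.5; else low-frequency if
#' min p_r > 0.2; else regional(r) if the edge appears in exactly one
#' region of the layer and in none of the others; else other. Edges absent
#' from every region of the layer but present in some other layer are
#' "absent"; edges in no subnetwork anywhere are dropped.
#'
#' The global / prevalent / low-frequency thresholds are evaluated over all
#' regions sampled in the layer, or with the enclosed sea excluded
#' (`include_ms = FALSE`). Regional status is always judged against all
#' sampled regions of the layer, so the regional set does not depend on the
#' mode and the per-layer accounting identity holds in both modes.
#'
#' @param pt region-layer prevalence table from
#'   `prevalence(subnets, "region_layer")`.
#' @param layer depth layer to classify.
#' @param include_ms consider the enclosed sea in the threshold classes?
#' @param ms_region name of the enclosed-sea region (default "MS").
#' @param thresholds named vector: global, prevalent, low_frequency.
#' @return data.frame: a, b, class, region (for regional edges), mode.
#' @export
classify_layer <- function(pt, layer, include_ms = TRUE, ms_region = "MS",
                           thresholds = c(global = 0.7, prevalent = 0.5,
                                          low_frequency = 0.2)) {
  stopifnot(all(c("region", "layer", "a", "b", "prevalence") %in% names(pt)))
  pt <- pt[pt$layer != EPI_OTHER, , drop = FALSE]
  lp <- pt[pt$layer == layer, , drop = FALSE]
  if (nrow(lp) == 0) stop2("layer not present in the prevalence table: ", layer)
  regions <- sort(unique(lp$region))
  considered <- if (include_ms) regions else setdiff(regions, ms_region)
  if (length(considered) == 0) stop2("no regions left to classify against")

  key <- edge_key(lp$a, lp$b)
  pmat <- matrix(NA_real_, nrow = length(unique(key)), ncol = length(regions),
                 dimnames = list(unique(key), regions))
  pmat[cbind(key, lp$region)] <- lp$prevalence
  pmat[is.na(pmat)] <- 0

  # presence in the other layers decides "absent" vs "never present"
  other <- pt[pt$layer != layer, , drop = FALSE]
  present_elsewhere <- unique(edge_key(other$a, other$b)[other$prevalence > 0])

  min_considered <- apply(pmat[, considered, drop = FALSE], 1, min)
  n_regions_present <- rowSums(pmat > 0)
  present_here <- n_regions_present > 0

  class <- rep("other", nrow(pmat))
  class[min_considered > thresholds["global"]] <- "global"
  class[class == "other" & min_considered > thresholds["prevalent"]] <- "prevalent"
  class[class == "other" & min_considered > thresholds["low_frequency"]] <- "low_frequency"
  regional <- class == "other" & n_regions_present == 1
  class[regional] <- "regional"
  class[!present_here] <- ifelse(rownames(pmat)[!present_here] %in%
                                   present_elsewhere, "absent", "never_present")

  region_of <- rep(NA_character_, nrow(pmat))
  if (any(regional)) {
    region_of[regional] <- regions[apply(pmat[regional, , drop = FALSE] > 0,
                                         1, which)]
  }
  ab <- do.call(rbind, strsplit(rownames(pmat), "|", fixed = TRUE))
  out <- data.frame(a = ab[, 1], b = ab[, 2], layer = layer, class = class,
                    region = region_of,
                    mode = if (include_ms) "with_MS" else "no_MS",
                    stringsAsFactors = FALSE)
  out[out$class != "never_present", , drop = FALSE]
}

#' Highly prevalent edges of one region-layer group
#'
#' Edges whose prevalence in the given single region and layer is strictly
#' above the threshold (default: over 70% of the group's subnetworks).
#'
#' @param pt region-layer prevalence table.
#' @param region,layer group selectors.
#' @param threshold strict prevalence threshold (default 0.7).
#' @return data.frame of the qualifying edges (a, b, prevalence).
#' @export
highly_prevalent <- function(pt, region, layer, threshold = 0.7) {
  grp <- pt[pt$region == region & pt$layer == layer, , drop = FALSE]
  if (nrow(grp) == 0) stop2("no such region-layer group: ", region, "/", layer)
  grp <- grp[grp$prevalence > threshold,
             c("a", "b", "prevalence"), drop = FALSE]
  rownames(grp) <- NULL
  grp
}

#' Domain-pair category of an edge
#'
#' "among prokaryotes" when both endpoints are Archaea or Bacteria, "among
#' eukaryotes" when both are Eukaryota, "between domains" otherwise. The
#' refined tag keeps the Arc/Bac/Euk pair.
#'
#' @param a,b endpoint ASV ids.
#' @param domains named character vector of domain labels.
#' @return data.frame: a, b, category, refined.
#' @export
domain_pair <- function(a, b, domains) {
  da <- domains[a]
  db <- domains[b]
  if (anyNA(da) || anyNA(db)) {
    stop2("missing domain label for: ",
          paste(unique(c(a[is.na(da)], b[is.na(db)])), collapse = ", "))
  }
  short <- c(Archaea = "Arc", Bacteria = "Bac", Eukaryota = "Euk")
  pk <- function(d) d %in% c("Archaea", "Bacteria")
  category <- ifelse(pk(da) & pk(db), "prok_prok",
                     ifelse(da == "Eukaryota" & db == "Eukaryota",
                            "euk_euk", "cross_domain"))
  refined <- vapply(seq_along(a), function(i)
    paste(sort(c(short[[da[i]]], short[[db[i]]])), collapse = "-"),
    character(1))
  data.frame(a = a, b = b, category = category, refined = refined,
             stringsAsFactors = FALSE)
}

#' Vertical first-appearance profile of a region
#'
#' For each edge present somewhere in the region, the presence vector over
#' the ordered layers (prevalence > 0 in that region-layer), the earliest
#' (shallowest) layer of appearance, and per-layer summaries: the fraction
#' of each layer's present edges that appear there for the first time, and
#' the edges present throughout the sampled water column. Layers never
#' sampled in the region are not assessable and are reported as `NA`
#' presence (distinct from absent).
#'
#' @param pt region-layer prevalence table.
#' @param region region to profile.
#' @param layers ordered layer vocabulary (surface first).
#' @param domains optional named domain vector; adds the domain-pair tag.
#' @return list with `profile` (a, b, one presence column per layer,
#'   first_layer, and optionally category), `layer_summary` (layer,
#'   n_present, n_first, fraction_first) and `throughout` (edges present in
#'   every sampled layer).
#' @export
vertical_profile <- function(pt, region, layers = LAYER_VOCABULARY,
                             domains = NULL) {
  rp <- pt[pt$region == region & pt$layer %in% layers, , drop = FALSE]
  if (nrow(rp) == 0) stop2("region has no sampled layers: ", region)
  sampled <- intersect(layers, unique(rp$layer))
  key <- edge_key(rp$a, rp$b)
  ukey <- unique(key)
  pres <- matrix(NA, nrow = length(ukey), ncol = length(layers),
                 dimnames = list(ukey, layers))
  pres[cbind(key, rp$layer)] <- rp$prevalence > 0
  seen <- rowSums(pres[, sampled, drop = FALSE], na.rm = TRUE) > 0
  pres <- pres[seen, , drop = FALSE]
  first_idx <- apply(pres[, sampled, drop = FALSE], 1,
                     function(v) which(v)[1])
  first_layer <- sampled[first_idx]
  ab <- do.call(rbind, strsplit(rownames(pres), "|", fixed = TRUE))
  profile <- data.frame(a = ab[, 1], b = ab[, 2], pres,
                        first_layer = first_layer,
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(domains)) {
    profile$category <- domain_pair(profile$a, profile$b, domains)$category
  }
  layer_summary <- do.call(rbind, lapply(sampled, function(l) {
    n_present <- sum(pres[, l], na.rm = TRUE)
    n_first <- sum(first_layer == l & pres[, l], na.rm = TRUE)
    data.frame(layer = l, n_present = n_present, n_first = n_first,
               fraction_first = if (n_present > 0) n_first / n_present
                                else NA_real_,
               stringsAsFactors = FALSE)
  }))
  throughout <- profile[rowSums(pres[, sampled, drop = FALSE]) ==
                          length(sampled), c("a", "b"), drop = FALSE]
  rownames(profile) <- rownames(throughout) <- NULL
  list(profile = profile, layer_summary = layer_summary,
       throughout = throughout, sampled_layers = sampled)
}

#' Per-layer classification summary (accounting table)
#'
#' Counts and percentages per class per layer, in both enclosed-sea modes,
#' in the shape of a classified-associations table: threshold classes with
#' and without the enclosed sea, the regional block broken down by region,
#' the residual "other" class per mode, and the present/absent totals. The
#' identity "classified (incl. other) = present" is asserted internally.
#' Percentages are of present associations, rounded half-even to 2
#' decimals.
#'
#' @param with_ms list of [classify_layer()] results (one per layer,
#'   `include_ms = TRUE`).
#' @param no_ms matching list with `include_ms = FALSE`.
#' @return data.frame: layer, class, count, pct.
#' @export
classification_summary <- function(with_ms, no_ms) {
  stopifnot(length(with_ms) == length(no_ms))
  rows <- list()
  for (i in seq_along(with_ms)) {
    cw <- with_ms[[i]]
    cn <- no_ms[[i]]
    layer <- unique(cw$layer)
    stopifnot(length(layer) == 1, identical(unique(cn$layer), layer))
    present_w <- cw[cw$class != "absent", , drop = FALSE]
    n_present <- nrow(present_w)
    n_absent <- sum(cw$class == "absent")
    cnt <- function(df, cls) sum(df$class == cls)
    n_regional <- cnt(present_w, "regional")
    regional_by <- table(present_w$region[present_w$class == "regional"])
    mk <- function(class, count) data.frame(
      layer = layer, class = class, count = count,
      pct = if (n_present > 0) round2(100 * count / n_present) else NA_real_,
      stringsAsFactors = FALSE)
    other_w <- n_present - cnt(present_w, "global") -
      cnt(present_w, "prevalent") - cnt(present_w, "low_frequency") -
      n_regional
    present_n <- cn[cn$class != "absent", , drop = FALSE]
    stopifnot(nrow(present_n) == n_present)  # present set is mode-invariant
    other_n <- n_present - cnt(present_n, "global") -
      cnt(present_n, "prevalent") - cnt(present_n, "low_frequency") -
      n_regional
    rows[[i]] <- rbind(
      mk("global", cnt(present_w, "global")),
      mk("prevalent", cnt(present_w, "prevalent")),
      mk("low_frequency", cnt(present_w, "low_frequency")),
      mk("global_no_ms", cnt(present_n, "global")),
      mk("prevalent_no_ms", cnt(present_n, "prevalent")),
      mk("low_frequency_no_ms", cnt(present_n, "low_frequency")),
      mk("regional", n_regional),
      do.call(rbind, lapply(names(regional_by), function(r)
        mk(paste0("regional_", r), as.integer(regional_by[[r]])))),
      mk("other", other_w),
      mk("other_no_ms", other_n),
      mk("present", n_present),
      mk("absent", n_absent))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
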