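# The published per-layer classification table and headline network
# statistics of the global-ocean interactome study the pipeline re-creates,
# bundled as plain text, plus the arithmetic identities the reporting code
# must reproduce exactly (class counts summing to the present totals,
# regional counts summing per region, and the printed percentages).

#' Published per-layer classification table
#'
#' The printed classified-associations-per-depth-layer table (counts and
#' printed percentages per class for the surface, DCM, mesopelagic and
#' bathypelagic layers), as bundled with the package.
#'
#' @return data.frame with a `class` column, one count column per layer and
#'   one `<layer>_pct` column per layer.
#' @export
published_class_table <- function() {
  utils::read.delim(system.file("extdata",
                                "table1_classified_associations.tsv",
                                package = "pelagicnets"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published headline network statistics
#'
#' @return named numeric vector (node/edge counts, sign split, printed
#'   percentages, MST size, cluster counts).
#' @export
published_network_stats <- function() {
  df <- utils::read.delim(system.file("extdata",
                                      "published_network_stats.tsv",
                                      package = "pelagicnets"),
                          stringsAsFactors = FALSE)
  setNames(df$value, df$quantity)
}

#' Accounting identities of the published classification table
#'
#' Recomputes, per layer, the sums the table legend promises: threshold
#' classes + regional + other = present (in both enclosed-sea modes, with
#' the mode-specific "other" as the residual), the per-region regional
#' counts summing to the regional total, and present + absent constant
#' across layers (the static network's edge count). The residual "other"
#' is returned alongside the printed value, so a printed typo shows up as
#' a mismatch between the two without breaking the arithmetic.
#'
#' @param tab a table in the shape of [published_class_table()].
#' @return data.frame, one row per layer: the five identity checks and the
#'   recomputed residuals.
#' @export
class_table_accounting <- function(tab = published_class_table()) {
  layers <- grep("_pct$", names(tab), value = TRUE, invert = TRUE)
  layers <- setdiff(layers, "class")
  cnt <- function(cl, l) tab[[l]][tab$class == cl]
  regional_regions <- grep("^regional_", tab$class, value = TRUE)
  out <- lapply(layers, function(l) {
    present <- cnt("present", l)
    with_ms_sum <- cnt("global", l) + cnt("prevalent", l) +
      cnt("low_frequency", l) + cnt("regional", l) + cnt("other", l)
    other_no_ms_residual <- present - cnt("global_no_ms", l) -
      cnt("prevalent_no_ms", l) - cnt("low_frequency_no_ms", l) -
      cnt("regional", l)
    regional_sum <- sum(vapply(regional_regions, cnt, numeric(1), l = l))
    data.frame(layer = l,
               present = present,
               with_ms_sum = with_ms_sum,
               with_ms_ok = with_ms_sum == present,
               other_no_ms_residual = other_no_ms_residual,
               other_no_ms_printed = cnt("other_no_ms", l),
               no_ms_printed_ok = other_no_ms_residual ==
                 cnt("other_no_ms", l),
               regional_sum = regional_sum,
               regional_ok = regional_sum == cnt("regional", l),
               total = present + cnt("absent", l),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recompute the published percentages from their counts
#'
#' Percentage of present associations per class and layer, rounded
#' half-even to two decimals as in the printed table. For the one cell
#' whose printed count fails the accounting residual (a typo), the
#' residual count is used.
#'
#' @param tab a table in the shape of [published_class_table()].
#' @return data.frame: class, layer, count, pct (recomputed), pct_printed.
#' @export
class_table_percentages <- function(tab = published_class_table()) {
  acc <- class_table_accounting(tab)
  layers <- acc$layer
  rows <- list()
  for (l in layers) {
    present <- tab[[l]][tab$class == "present"]
    for (cl in setdiff(tab$class, c("present", "absent"))) {
      count <- tab[[l]][tab$class == cl]
      if (cl == "other_no_ms") {
        count <- acc$other_no_ms_residual[acc$layer == l]
      }
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, layer = l, count = count,
        pct = round2(100 * count / present),
        pct_printed = tab[[paste0(l, "_pct")]][tab$class == cl],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Headline percentage identities
#'
#' The printed one-decimal percentages recomputed from their printed
#' counts: the positive-edge fractions of the initial and final static
#' networks, the fraction of basin surface associations absent from the
#' enclosed sea, and the fraction of surface-dominated topology clusters.
#'
#' @return data.frame: quantity, numerator, denominator, pct (recomputed,
#'   1 decimal), pct_printed.
#' @export
headline_percentages <- function() {
  s <- published_network_stats()
  mk <- function(q, num, den, printed) data.frame(
    quantity = q, numerator = num, denominator = den,
    pct = round(100 * num / den, 1), pct_printed = printed,
    stringsAsFactors = FALSE)
  rbind(
    mk("initial_positive", s[["initial_positive"]], s[["initial_edges"]],
       s[["initial_positive_pct_printed"]]),
    mk("static_positive", s[["static_positive"]], s[["static_edges"]],
       s[["static_positive_pct_printed"]]),
    mk("static_negative", s[["static_negative"]], s[["static_edges"]],
       s[["static_negative_pct_printed"]]),
    mk("ms_absence", s[["srf_basin_assoc_absent_in_ms"]],
       s[["srf_present"]], s[["ms_absence_pct_printed"]]),
    mk("surface_dominated_clusters", s[["surface_dominated_clusters"]],
       s[["n_clusters"]], s[["surface_dominated_pct_printed"]]))
}
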