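# Prevalence, spatial classes, domain pairs, vertical profiles, summary.

# Build a subnetwork_set by hand: a static net of named edges and a
# per-sample list of which edges each subnetwork contains.
manual_subnet_set <- function(md, static, contains) {
  subs <- lapply(seq_len(nrow(md)), function(i) {
    keys <- contains[[md$sample[i]]] %||% character(0)
    sel <- pelagicnets:::edge_key(static$edges$a, static$edges$b) %in% keys
    e <- static$edges[sel, c("a", "b", "score")]
    structure(list(sample = md$sample[i], region = md$region[i],
                   layer = md$layer[i], edges = e,
                   nodes = sort(unique(c(e$a, e$b)))), class = "subnetwork")
  })
  names(subs) <- md$sample
  structure(list(subnetworks = subs, metadata = md, static = static,
                 jaccard = NULL, threshold = 0.2), class = "subnetwork_set")
}

two_region_setup <- function() {
  md <- expand.grid(region = c("MS", "NAO"), layer = c("SRF", "MES"),
                    idx = 1:4, stringsAsFactors = FALSE)
  md$sample <- sprintf("%s_%s_%d", md$region, md$layer, md$idx)
  static <- static_network(data.frame(a = c("x", "x", "p"),
                                      b = c("y", "z", "q"),
                                      score = c(0.5, 0.4, -0.2)))
  list(md = md[, c("sample", "region", "layer")], static = static)
}

test_that("prevalence counts fractions exactly, including zeros", {
  s <- two_region_setup()
  # edge x|y in all 8 SRF subnetworks' samples; x|z in 2 of 8; p|q nowhere
  contains <- list()
  for (smp in s$md$sample[s$md$layer == "SRF"]) contains[[smp]] <- "x|y"
  contains[["MS_SRF_1"]] <- c("x|y", "x|z")
  contains[["MS_SRF_2"]] <- c("x|y", "x|z")
  subs <- manual_subnet_set(s$md, s$static, contains)
  pa <- prevalence(subs, "all")
  expect_equal(pa$prevalence[pa$a == "x" & pa$b == "y"], 8 / 16)
  expect_equal(pa$prevalence[pa$a == "p"], 0)
  prl <- prevalence(subs, "region_layer")
  expect_equal(prl$prevalence[prl$region == "MS" & prl$layer == "SRF" &
                                prl$a == "x" & prl$b == "z"], 0.5)
  expect_equal(prl$prevalence[prl$region == "NAO" & prl$layer == "SRF" &
                                prl$a == "x" & prl$b == "y"], 1)
})

# Direct construction of a prevalence table for classification tests.
ptab <- function(layer, ...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(region = r$region, layer = layer, a = r$a, b = r$b,
               n_present = NA, n_subnetworks = 10, prevalence = r$p,
               stringsAsFactors = FALSE)))
}

prev_for <- function(pvec, layer = "SRF", a = "x", b = "y",
                     regions = c("MS", "NAO", "SAO", "NPO", "SPO", "IO")) {
  do.call(rbind, lapply(seq_along(regions), function(i)
    data.frame(region = regions[i], layer = layer, a = a, b = b,
               n_present = NA, n_subnetworks = 10, prevalence = pvec[i],
               stringsAsFactors = FALSE)))
}

test_that("the classification hierarchy follows the prevalence bands", {
  cases <- list(
    list(p = c(0.75, 0.8, 0.9, 0.71, 0.99, 0.72), want = "global"),
    list(p = c(0.6, 0.9, 0.55, 0.8, 0.51, 0.7), want = "prevalent"),
    list(p = c(0.3, 0.25, 0.5, 0.21, 0.9, 0.4), want = "low_frequency"),
    list(p = c(0.3, 0, 0, 0, 0, 0), want = "regional"),
    list(p = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7), want = "prevalent"),  # not > 0.7
    list(p = c(0.15, 0.4, 0.3, 0.3, 0.3, 0.3), want = "other"))
  for (cs in cases) {
    got <- classify_layer(prev_for(cs$p), "SRF")
    expect_equal(got$class, cs$want, info = paste(cs$p, collapse = ","))
  }
  reg <- classify_layer(prev_for(c(0.3, 0, 0, 0, 0, 0)), "SRF")
  expect_equal(reg$region, "MS")
})

test_that("absent means present in another layer but nowhere in this one", {
  pt <- rbind(prev_for(rep(0, 6), layer = "SRF"),
              prev_for(c(0.4, 0, 0, 0, 0, 0), layer = "MES"),
              prev_for(rep(0, 6), layer = "SRF", a = "ghost", b = "gone"),
              prev_for(rep(0, 6), layer = "MES", a = "ghost", b = "gone"))
  srf <- classify_layer(pt, "SRF")
  expect_equal(srf$class[srf$a == "x"], "absent")
  expect_false("ghost" %in% srf$a)  # in no subnetwork anywhere: dropped
})

test_that("excluding the enclosed sea relaxes but never revokes global", {
  # global without MS but not with it: MS prevalence at or below 0.7
  pt <- prev_for(c(0.25, 0.9, 0.8, 0.95, 0.75, 0.85))
  expect_equal(classify_layer(pt, "SRF", include_ms = TRUE)$class,
               "low_frequency")
  expect_equal(classify_layer(pt, "SRF", include_ms = FALSE)$class, "global")
  # property: on random tables, with-MS global implies no-MS global
  set.seed(23)
  for (i in 1:200) {
    p <- round(runif(6), 2)
    w <- classify_layer(prev_for(p), "SRF", include_ms = TRUE)$class
    n <- classify_layer(prev_for(p), "SRF", include_ms = FALSE)$class
    if (w == "global") expect_equal(n, "global")
    if (n == "global" && w != "global") expect_lte(p[1], 0.7)
  }
})

test_that("every present edge gets exactly one class (partition property)", {
  set.seed(24)
  regions <- c("MS", "NAO", "SAO", "NPO", "SPO", "IO")
  pt <- do.call(rbind, lapply(sprintf("e%02d", 1:40), function(e) {
    p <- ifelse(runif(6) < 0.3, 0, round(runif(6), 2))
    prev_for(p, a = e, b = paste0(e, "b"))
  }))
  cl <- classify_layer(pt, "SRF")
  expect_equal(anyDuplicated(paste(cl$a, cl$b)), 0)
  expect_true(all(cl$class %in% c("global", "prevalent", "low_frequency",
                                  "regional", "other", "absent")))
  # nesting: global would pass the prevalent band, prevalent the low one
  pmin <- tapply(pt$prevalence, pt$a, min)[cl$a]
  expect_true(all(pmin[cl$class == "global"] > 0.5))
  expect_true(all(pmin[cl$class == "prevalent"] > 0.2))
})

test_that("highly prevalent edges respect the strict 70% cut", {
  pt <- rbind(prev_for(c(0.71, rep(0, 5))),
              prev_for(c(0.70, rep(0, 5)), a = "u", b = "v"))
  hp <- highly_prevalent(pt, "MS", "SRF")
  expect_equal(nrow(hp), 1)
  expect_equal(hp$a, "x")
  expect_equal(nrow(highly_prevalent(pt, "MS", "SRF", threshold = 0)), 2)
  expect_error(highly_prevalent(pt, "XX", "SRF"), "no such")
})

test_that("domain pairs group archaea with bacteria as prokaryotes", {
  dom <- c(arc = "Archaea", bac = "Bacteria", euk1 = "Eukaryota",
           euk2 = "Eukaryota")
  dp <- domain_pair(c("arc", "euk1", "bac"), c("bac", "euk2", "euk1"), dom)
  expect_equal(dp$category, c("prok_prok", "euk_euk", "cross_domain"))
  expect_equal(dp$refined, c("Arc-Bac", "Euk-Euk", "Bac-Euk"))
  expect_error(domain_pair("arc", "zz", dom), "missing domain")
})

test_that("vertical profiles find first appearances and full-column edges", {
  mk <- function(pv, a, b) do.call(rbind, lapply(seq_along(pv), function(i)
    data.frame(region = "NAO", layer = c("SRF", "DCM", "MES", "BAT")[i],
               a = a, b = b, n_present = NA, n_subnetworks = 5,
               prevalence = pv[i], stringsAsFactors = FALSE)))
  pt <- rbind(mk(c(0, 0.4, 0, 0.2), "x", "y"),    # first in DCM
              mk(c(0.9, 0.5, 0.2, 0.1), "w", "z"), # throughout
              mk(c(0, 0, 0, 0), "n", "o"))         # nowhere: excluded
  vp <- vertical_profile(pt, "NAO")
  expect_equal(vp$profile$first_layer[vp$profile$a == "x"], "DCM")
  expect_equal(nrow(vp$profile), 2)
  expect_equal(vp$throughout$a, "w")
  # DCM holds x (new there) and w (carried from SRF): half are first seen
  expect_equal(vp$layer_summary$fraction_first[vp$layer_summary$layer == "DCM"],
               0.5)
  expect_equal(vp$layer_summary$fraction_first[vp$layer_summary$layer == "BAT"],
               0)
})

test_that("summary accounting reproduces the sum-to-present identity", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 10, seed = 20)
  subs <- derive_all(counts, d$metadata, net, 0.2)
  prl <- prevalence(subs, "region_layer")
  layers <- c("SRF", "DCM")
  w <- lapply(layers, function(l) classify_layer(prl, l, include_ms = TRUE))
  n <- lapply(layers, function(l) classify_layer(prl, l, include_ms = FALSE))
  tab <- classification_summary(w, n)
  for (l in layers) {
    t <- tab[tab$layer == l, ]
    cnt <- function(cl) t$count[t$class == cl]
    expect_equal(cnt("global") + cnt("prevalent") + cnt("low_frequency") +
                   cnt("regional") + cnt("other"), cnt("present"))
    expect_equal(cnt("global_no_ms") + cnt("prevalent_no_ms") +
                   cnt("low_frequency_no_ms") + cnt("regional") +
                   cnt("other_no_ms"), cnt("present"))
    reg_cols <- grep("^regional_", t$class)
    expect_equal(sum(t$count[reg_cols]), cnt("regional"))
    expect_equal(t$pct[t$class == "present"], 100)
  }
})
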