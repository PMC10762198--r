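# Network metrics, orbit counting, dissimilarity, NSN/MST, clustering.

subnet_of <- function(edges, sample = "s", region = "R", layer = "SRF",
                      score = 0.5) {
  e <- if (nrow(edges)) cbind(edges, score = score) else
    data.frame(a = character(0), b = character(0), score = numeric(0))
  structure(list(sample = sample, region = region, layer = layer,
                 edges = e, nodes = sort(unique(c(edges$a, edges$b)))),
            class = "subnetwork")
}

path_graph <- function(nodes) data.frame(a = nodes[-length(nodes)],
                                         b = nodes[-1],
                                         stringsAsFactors = FALSE)

test_that("metrics match closed forms on canonical graphs", {
  k4 <- subnet_of(data.frame(a = c("a", "a", "a", "b", "b", "c"),
                             b = c("b", "c", "d", "c", "d", "d")))
  m <- network_metrics(k4)
  expect_equal(m$edge_density, 1)
  expect_equal(m$transitivity, 1)
  expect_equal(m$average_path_length, 1)

  p4 <- subnet_of(path_graph(c("a", "b", "c", "d")))
  m <- network_metrics(p4)
  expect_equal(m$edge_density, 0.5)
  expect_equal(m$transitivity, 0)
  expect_equal(m$average_path_length, 10 / 6)

  star <- subnet_of(data.frame(a = "hub", b = c("l1", "l2", "l3")))
  expect_equal(network_metrics(star)$assortativity_degree, -1)
})

test_that("degenerate metrics are missing, never zero", {
  single <- subnet_of(data.frame(a = "a", b = "b"), score = -0.3)
  m <- network_metrics(single)
  expect_true(is.na(m$transitivity))          # no connected triple
  expect_true(is.na(m$assortativity_degree))  # zero degree variance
  expect_true(is.na(m$mean_positive_strength))  # only a negative edge
  expect_equal(m$n_edges, 1)
})

test_that("metrics agree with independent hand computations on random graphs", {
  # oracle: BFS shortest paths + triple counting, no igraph involved
  oracle_apl <- function(edges, nodes) {
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    adj[cbind(edges$a, edges$b)] <- TRUE
    adj[cbind(edges$b, edges$a)] <- TRUE
    dsum <- 0; npairs <- 0
    for (s in nodes) {
      dist <- setNames(rep(Inf, length(nodes)), nodes)
      dist[s] <- 0
      frontier <- s
      while (length(frontier)) {
        nxt <- character(0)
        for (v in frontier) {
          for (w in nodes[adj[v, ]]) if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
        frontier <- nxt
      }
      reach <- dist[is.finite(dist) & dist > 0]
      dsum <- dsum + sum(reach)
      npairs <- npairs + length(reach)
    }
    if (npairs == 0) NA_real_ else dsum / npairs
  }
  oracle_transitivity <- function(edges, nodes) {
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    adj[cbind(edges$a, edges$b)] <- TRUE
    adj[cbind(edges$b, edges$a)] <- TRUE
    closed <- 0; triples <- 0
    for (v in nodes) {
      nb <- nodes[adj[v, ]]
      if (length(nb) < 2) next
      for (pair in utils::combn(nb, 2, simplify = FALSE)) {
        triples <- triples + 1
        if (adj[pair[1], pair[2]]) closed <- closed + 1
      }
    }
    if (triples == 0) NA_real_ else closed / triples
  }
  set.seed(41)
  for (i in 1:25) {
    nodes <- sprintf("n%02d", 1:8)
    edges <- random_graph_edges(8, 0.4, nodes)
    if (nrow(edges) == 0) next
    sub <- subnet_of(edges)
    sub$nodes <- nodes  # keep isolated nodes in the comparison graph
    m <- network_metrics(sub)
    expect_equal(m$average_path_length, oracle_apl(edges, nodes),
                 tolerance = 1e-9)
    tr <- oracle_transitivity(edges, nodes)
    if (is.na(tr)) expect_true(is.na(m$transitivity))
    else expect_equal(m$transitivity, tr, tolerance = 1e-9)
  }
})

test_that("domain assortativity hits the bipartite and split extremes", {
  dom <- c(e1 = "Eukaryota", e2 = "Eukaryota", p1 = "Bacteria",
           p2 = "Archaea")
  bip <- subnet_of(data.frame(a = c("e1", "e1", "e2", "e2"),
                              b = c("p1", "p2", "p1", "p2")))
  expect_equal(assortativity_domain(bip, dom), -1)
  split <- subnet_of(data.frame(a = c("e1", "p1"), b = c("e2", "p2")))
  expect_equal(assortativity_domain(split, dom), 1)
  mono <- subnet_of(data.frame(a = "p1", b = "p2"))
  expect_true(is.na(assortativity_domain(mono, dom)))
})

test_that("orbit counts match enumeration on canonical small graphs", {
  tri <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
  orb <- orbit_counts(tri)
  expect_equal(unname(orb[, "O3"]), c(1, 1, 1))
  expect_equal(unname(orb[, "O1"]), c(0, 0, 0))

  p3 <- path_graph(c("a", "b", "c"))
  orb <- orbit_counts(p3)
  expect_equal(unname(orb[c("a", "c"), "O1"]), c(1, 1))
  expect_equal(unname(orb["b", "O2"]), 1)

  empty <- data.frame(a = character(0), b = character(0))
  expect_true(all(orbit_counts(empty, nodes = c("x", "y")) == 0))
})

test_that("orbit counts equal the brute-force enumerator on all 6-node graphs", {
  # sampled exhaustively across densities; plus every graph on 4 nodes
  for (g in all_graphs_on(4)) {
    nodes <- letters[1:4]
    expect_identical(orbit_counts(g, nodes), oracle_orbit_counts(g, nodes))
  }
  set.seed(42)
  for (i in 1:30) {
    nodes <- letters[1:6]
    g <- random_graph_edges(6, runif(1, 0.2, 0.9), nodes)
    expect_identical(orbit_counts(g, nodes), oracle_orbit_counts(g, nodes))
  }
})

test_that("dissimilarity is a relabeling-invariant pseudo-distance", {
  set.seed(43)
  for (i in 1:20) {
    g1 <- random_graph_edges(7, 0.5)
    g2 <- random_graph_edges(7, 0.3)
    d12 <- network_dissimilarity(g1, g2)
    expect_gte(d12, 0)
    expect_equal(network_dissimilarity(g2, g1), d12)
    expect_equal(network_dissimilarity(g1, g1), 0)
    # relabeled copy at distance zero
    perm <- setNames(sample(sprintf("m%02d", 1:7)),
                     sprintf("n%02d", 1:7))
    g1p <- data.frame(a = unname(perm[g1$a]), b = unname(perm[g1$b]))
    expect_equal(network_dissimilarity(g1, g1p), 0, tolerance = 1e-12)
  }
  tri <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
  p3 <- path_graph(c("x", "y", "z"))
  expect_gt(network_dissimilarity(tri, p3), 0)
})

test_that("the NSN is complete and mirrors the dissimilarity matrix", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 5, seed = 21)
  subs <- derive_all(counts, d$metadata[1:10, ], net, 0.2)
  dm <- dissimilarity_matrix(subs)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  nsn <- build_nsn(dm)
  expect_equal(nrow(nsn$edges), choose(10, 2))
  expect_equal(nsn$edges$weight,
               dm[cbind(nsn$edges$a, nsn$edges$b)])
})

test_that("the MST is optimal, deterministic, and sized n-1", {
  k4 <- data.frame(a = c("a", "a", "a", "b", "b", "c"),
                   b = c("b", "c", "d", "c", "d", "d"),
                   weight = c(1, 2, 3, 4, 5, 6))
  mst <- minimum_spanning_tree(k4)
  expect_equal(attr(mst, "total_weight"), 6)
  expect_setequal(paste(mst$a, mst$b), c("a b", "a c", "a d"))

  # brute-force minimum on random graphs with up to 7 nodes
  set.seed(44)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    e <- random_graph_edges(n, 1)  # complete, always connected
    e$weight <- round(runif(nrow(e)), 2)
    mst <- minimum_spanning_tree(e)
    expect_equal(nrow(mst), n - 1)
    expect_equal(attr(mst, "total_weight"), oracle_mst_weight(e),
                 tolerance = 1e-12)
    # cross-check against the reference graph library
    g <- igraph::graph_from_data_frame(e, directed = FALSE)
    ref <- igraph::mst(g, weights = igraph::E(g)$weight)
    expect_equal(attr(mst, "total_weight"),
                 sum(igraph::E(ref)$weight), tolerance = 1e-12)
  }

  # all-equal weights: any tree is optimal; the pick must be reproducible
  e <- random_graph_edges(5, 1)
  e$weight <- 1
  expect_identical(minimum_spanning_tree(e), minimum_spanning_tree(e))

  disc <- data.frame(a = c("a", "c"), b = c("b", "d"), weight = 1)
  expect_error(minimum_spanning_tree(disc), "disconnected")
})

test_that("clustering separates planted graph families deterministically", {
  # two homogeneous topology families with a wide gap: rings vs stars of
  # varying size (within-family graphlet signatures nearly coincide)
  cycle_graph <- function(n) {
    nodes <- sprintf("c%02d", 1:n)
    data.frame(a = nodes, b = nodes[c(2:n, 1)], stringsAsFactors = FALSE)
  }
  star_graph <- function(n) data.frame(a = "hub", b = sprintf("l%02d", 1:n),
                                       stringsAsFactors = FALSE)
  subs <- c(
    lapply(1:12, function(i) subnet_of(cycle_graph(8 + i %% 4),
                                       sample = paste0("ring", i))),
    lapply(1:12, function(i) subnet_of(star_graph(7 + i %% 4),
                                       sample = paste0("star", i))))
  dm <- dissimilarity_matrix(subs)
  cl <- cluster_subnetworks(dm, min_cluster_size = 5, eps = 0.5)
  expect_equal(cl$n_clusters, 2)
  a <- cl$assignment
  expect_true(all(table(a[a > 0]) >= 5))
  ring_cl <- unique(a[paste0("ring", 1:12)])
  star_cl <- unique(a[paste0("star", 1:12)])
  expect_length(setdiff(ring_cl, 0), 1)
  expect_length(setdiff(star_cl, 0), 1)
  expect_false(any(setdiff(ring_cl, 0) %in% setdiff(star_cl, 0)))
  # identical input -> identical assignment
  expect_identical(
    cluster_subnetworks(dm, min_cluster_size = 5, eps = 0.5)$assignment,
    cl$assignment)
  # fewer subnetworks than the minimum size: all noise, with a warning
  expect_warning(tiny <- cluster_subnetworks(dm[1:3, 1:3]), "noise")
  expect_equal(tiny$n_clusters, 0)
})

test_that("cluster composition fractions sum to one and label dominance", {
  md <- data.frame(sample = sprintf("s%02d", 1:10),
                   region = rep(c("MS", "NAO"), 5),
                   layer = c(rep("SRF", 7), rep("BAT", 3)))
  assignment <- setNames(c(rep(1L, 10)), md$sample)
  comp <- cluster_composition(assignment, md)
  expect_equal(comp$size, 10)
  expect_equal(comp$layer_SRF, 0.7)
  expect_equal(comp$dominant_layer, "SRF")
  expect_equal(comp$layer_SRF + comp$layer_BAT, 1)
  expect_equal(comp$region_MS + comp$region_NAO, 1)
  none <- cluster_composition(setNames(rep(0L, 10), md$sample), md)
  expect_equal(nrow(none), 0)
})
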