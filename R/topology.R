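# Per-subnetwork topology: eight global metrics, graphlet-orbit counting
# (all orbits of connected graphlets with up to 4 nodes), a label-free
# graphlet-correlation network dissimilarity, the complete network-
# similarity network (NSN) with its minimum spanning tree, and a
# deterministic embedding + density-based clustering of subnetworks.

subnetwork_igraph <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  igraph::graph_from_data_frame(sub$edges[, c("a", "b")], directed = FALSE,
                                vertices = sub$nodes)
}

na_if_nan <- function(x) if (is.nan(x)) NA_real_ else x

#' Eight per-subnetwork topology metrics
#'
#' Number of nodes and edges; edge density (actual over possible edges);
#' average path length (mean shortest-path length over connected node
#' pairs); transitivity (probability that a node's neighbours are
#' connected); degree assortativity; Euk-Prok (nominal) assortativity; and
#' the mean of the positive association scores. Metrics that are undefined
#' on a degenerate input (no connected pair, no connected triple, zero
#' degree variance, a single domain, no positive edge) are reported as
#' `NA`, never as 0.
#'
#' @param sub a `subnetwork`.
#' @param domains named domain vector covering the subnetwork's nodes
#'   (needed for the Euk-Prok assortativity; `NULL` leaves it `NA`).
#' @return one-row data.frame with the eight metrics (plus the sample id).
#' @export
network_metrics <- function(sub, domains = NULL) {
  n <- length(sub$nodes)
  m <- nrow(sub$edges)
  if (n >= 2) {
    g <- subnetwork_igraph(sub)
    density <- m / (n * (n - 1) / 2)
    apl <- na_if_nan(igraph::mean_distance(g, directed = FALSE,
                                           unconnected = TRUE))
    trans <- na_if_nan(igraph::transitivity(g, type = "global"))
    assort_deg <- na_if_nan(suppressWarnings(igraph::assortativity_degree(g)))
  } else {
    density <- apl <- trans <- assort_deg <- NA_real_
  }
  assort_dom <- if (!is.null(domains)) assortativity_domain(sub, domains)
                else NA_real_
  pos <- sub$edges$score[sub$edges$score > 0]
  data.frame(sample = sub$sample, n_nodes = n, n_edges = m,
             edge_density = density, average_path_length = apl,
             transitivity = trans, assortativity_degree = assort_deg,
             assortativity_euk_prok = assort_dom,
             mean_positive_strength = if (length(pos)) mean(pos) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Euk-Prok nominal assortativity
#'
#' Categorical assortativity on the two-label partition of nodes into
#' prokaryotes (Archaea + Bacteria) and eukaryotes: positive when
#' eukaryotes tend to connect to eukaryotes and prokaryotes to
#' prokaryotes, -1 for a perfectly disassortative (bipartite) pattern.
#' Undefined (`NA`) when the subnetwork carries a single label.
#'
#' @param sub a `subnetwork`.
#' @param domains named character vector of domain labels per node.
#' @return assortativity coefficient, or `NA`.
#' @export
assortativity_domain <- function(sub, domains) {
  if (length(sub$nodes) < 2 || nrow(sub$edges) == 0) return(NA_real_)
  lab <- ifelse(domains[sub$nodes] == "Eukaryota", "Euk", "Prok")
  if (anyNA(lab)) stop2("missing domain label for a subnetwork node")
  if (length(unique(lab)) < 2) return(NA_real_)
  g <- subnetwork_igraph(sub)
  na_if_nan(suppressWarnings(
    igraph::assortativity_nominal(g, as.integer(factor(lab)))))
}

# ---- graphlet orbits -------------------------------------------------------

# Adjacency as a list of sorted integer neighbour vectors.
adjacency_list <- function(edges, nodes) {
  idx <- seq_along(nodes)
  names(idx) <- nodes
  adj <- vector("list", length(nodes))
  for (i in idx) adj[[i]] <- integer(0)
  if (nrow(edges)) {
    ia <- idx[edges$a]
    ib <- idx[edges$b]
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

# Classify a connected induced subgraph on 3 or 4 vertices and add its
# orbit contributions. Orbits follow the usual numbering of connected
# graphlets with 2-4 nodes: 0 edge; 1/2 path ends/centre; 3 triangle;
# 4/5 four-path ends/middles; 6/7 star leaves/centre; 8 four-cycle;
# 9/10/11 tailed triangle tail/base/hub; 12/13 diamond rim/hub; 14 clique.
orbit_accumulate <- function(orb, vs, adj) {
  k <- length(vs)
  deg <- vapply(vs, function(v) sum(adj[[v]] %in% vs), integer(1))
  m <- sum(deg) / 2
  if (k == 3) {
    if (m == 3) {
      orb[vs, "O3"] <- orb[vs, "O3"] + 1L
    } else {                      # path on 3 nodes
      orb[vs[deg == 2], "O2"] <- orb[vs[deg == 2], "O2"] + 1L
      orb[vs[deg == 1], "O1"] <- orb[vs[deg == 1], "O1"] + 1L
    }
  } else {
    if (m == 3 && max(deg) == 3) {          # star
      orb[vs[deg == 1], "O6"] <- orb[vs[deg == 1], "O6"] + 1L
      orb[vs[deg == 3], "O7"] <- orb[vs[deg == 3], "O7"] + 1L
    } else if (m == 3) {                    # path
      orb[vs[deg == 1], "O4"] <- orb[vs[deg == 1], "O4"] + 1L
      orb[vs[deg == 2], "O5"] <- orb[vs[deg == 2], "O5"] + 1L
    } else if (m == 4 && max(deg) == 2) {   # cycle
      orb[vs, "O8"] <- orb[vs, "O8"] + 1L
    } else if (m == 4) {                    # tailed triangle
      orb[vs[deg == 1], "O9"] <- orb[vs[deg == 1], "O9"] + 1L
      orb[vs[deg == 2], "O10"] <- orb[vs[deg == 2], "O10"] + 1L
      orb[vs[deg == 3], "O11"] <- orb[vs[deg == 3], "O11"] + 1L
    } else if (m == 5) {                    # diamond
      orb[vs[deg == 2], "O12"] <- orb[vs[deg == 2], "O12"] + 1L
      orb[vs[deg == 3], "O13"] <- orb[vs[deg == 3], "O13"] + 1L
    } else {                                # K4
      orb[vs, "O14"] <- orb[vs, "O14"] + 1L
    }
  }
  orb
}

# ESU enumeration of connected induced subgraphs of a given size: each
# subset is produced exactly once (extension sets restricted to vertices
# larger than the root and outside the current exclusive neighbourhood).
enumerate_connected_subsets <- function(adj, size, visit) {
  n <- length(adj)
  extend <- function(sub, ext, root) {
    if (length(sub) == size) {
      visit(sub)
      return(invisible(NULL))
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      excl <- unique(unlist(adj[sub]))
      new_nb <- setdiff(adj[[w]], c(excl, sub, w))
      extend(c(sub, w), c(ext, new_nb[new_nb > root]), root)
    }
  }
  for (v in seq_len(n)) {
    extend(v, adj[[v]][adj[[v]] > v], v)
  }
  invisible(NULL)
}

#' Per-node orbit counts over graphlets with up to 4 nodes
#'
#' Exact counts, by enumeration of connected induced subgraphs (each
#' counted once), of the 15 automorphism orbits of the connected 2-, 3-
#' and 4-node graphlets. Orbit 0 is the degree.
#'
#' @param edges data.frame with columns `a`, `b` (simple undirected graph),
#'   or a `subnetwork`.
#' @param nodes node ids (defaults to the endpoints present in `edges`).
#' @return integer matrix, nodes x orbits `O0` ... `O14`.
#' @export
orbit_counts <- function(edges, nodes = NULL) {
  if (inherits(edges, "subnetwork")) {
    nodes <- edges$nodes
    edges <- edges$edges
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  orb <- matrix(0L, nrow = length(nodes), ncol = 15,
                dimnames = list(nodes, paste0("O", 0:14)))
  if (length(nodes) == 0) return(orb)
  adj <- adjacency_list(edges, nodes)
  orb[, "O0"] <- vapply(adj, length, integer(1))
  env <- environment()
  for (size in c(3L, 4L)) {
    if (length(nodes) >= size) {
      enumerate_connected_subsets(adj, size, function(vs) {
        env$orb <- orbit_accumulate(env$orb, vs, adj)
      })
    }
  }
  orb
}

# Spearman orbit-correlation matrix over the 11 non-redundant orbits; a
# dummy node with unit counts is appended so that constant orbit columns
# still yield a defined correlation.
GCD_ORBITS <- paste0("O", c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11))

orbit_correlation <- function(orb) {
  k <- length(GCD_ORBITS)
  if (nrow(orb) < 2) return(diag(k))
  x <- rbind(orb[, GCD_ORBITS, drop = FALSE], 1)
  cc <- suppressWarnings(stats::cor(x, method = "spearman"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Label-free network dissimilarity (graphlet correlation distance)
#'
#' Distance between the graphlet-orbit Spearman-correlation matrices of two
#' graphs (11 non-redundant orbits of the graphlets with up to 4 nodes):
#' the Euclidean norm of the upper-triangle difference. It is
#' non-negative, zero for identical (in particular, node-relabelled)
#' topologies, symmetric, and ignores node identities entirely. Graphs with
#' fewer than 2 nodes are compared through an identity correlation matrix
#' (and so are at distance 0 from each other).
#'
#' @param a,b `subnetwork`s, or plain edge data.frames with columns
#'   `a`, `b`.
#' @return non-negative dissimilarity.
#' @export
network_dissimilarity <- function(a, b) {
  ca <- orbit_correlation(orbit_counts(a))
  cb <- orbit_correlation(orbit_counts(b))
  ut <- upper.tri(ca)
  sqrt(sum((ca[ut] - cb[ut])^2))
}

#' Pairwise dissimilarity matrix over a subnetwork set
#'
#' @param subs a `subnetwork_set` (or plain list of `subnetwork`s).
#' @return symmetric matrix with zero diagonal, labelled by sample id.
#' @export
dissimilarity_matrix <- function(subs) {
  if (inherits(subs, "subnetwork_set")) subs <- subs$subnetworks
  n <- length(subs)
  if (n < 2) stop2("need at least 2 subnetworks")
  corrs <- lapply(subs, function(s) orbit_correlation(orbit_counts(s)))
  ids <- vapply(subs, function(s) s$sample, character(1))
  ut <- upper.tri(corrs[[1]])
  flat <- vapply(corrs, function(m) m[ut], numeric(sum(ut)))
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((flat[, (i + 1):n, drop = FALSE] - flat[, i])^2))
    dm[i, (i + 1):n] <- d
    dm[(i + 1):n, i] <- d
  }
  dm
}

#' Network similarity network (NSN)
#'
#' The complete weighted graph whose nodes are subnetworks and whose edge
#' weights are their pairwise topology dissimilarities.
#'
#' @param subs a `subnetwork_set`, or a precomputed dissimilarity matrix.
#' @return list with `edges` (data.frame a, b, weight; n(n-1)/2 rows) and
#'   `dissimilarity` (the matrix).
#' @export
build_nsn <- function(subs) {
  dm <- if (is.matrix(subs)) subs else dissimilarity_matrix(subs)
  if (nrow(dm) < 2) stop2("need at least 2 subnetworks")
  ids <- rownames(dm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  edges <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                      weight = dm[idx], stringsAsFactors = FALSE)
  list(edges = edges, dissimilarity = dm)
}

#' Minimum spanning tree of a weighted graph
#'
#' Kruskal's algorithm with a deterministic tie-break: candidate edges are
#' taken in lexicographic (weight, endpoint, endpoint) order, so equal-
#' weight solutions always resolve the same way across runs.
#'
#' @param x an NSN from [build_nsn()], a dissimilarity matrix, or an edge
#'   data.frame with columns `a`, `b`, `weight`.
#' @return data.frame of the n-1 tree edges (a, b, weight), with the total
#'   weight in `attr(, "total_weight")`.
#' @export
minimum_spanning_tree <- function(x) {
  edges <- if (is.matrix(x)) build_nsn(x)$edges
           else if (is.list(x) && !is.null(x$edges)) x$edges
           else x
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  edges <- canonicalise_edges(edges)
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  ord <- order(edges$weight, edges$a, edges$b)
  parent <- seq_len(n)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  picked <- integer(0)
  for (k in ord) {
    ra <- find(match(edges$a[k], nodes))
    rb <- find(match(edges$b[k], nodes))
    if (ra != rb) {
      parent[ra] <- rb
      picked <- c(picked, k)
      if (length(picked) == n - 1) break
    }
  }
  if (length(picked) != n - 1) {
    stop2("graph is disconnected: no spanning tree exists")
  }
  out <- edges[picked, c("a", "b", "weight"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_weight") <- sum(out$weight)
  out
}

# ---- clustering ------------------------------------------------------------

# Plain DBSCAN on a Euclidean embedding: core points have at least min_pts
# points (self included) within eps; clusters are the connected components
# of core points at range eps, with border points attached to the
# first-reached core cluster. Fully deterministic.
dbscan_embed <- function(emb, eps, min_pts) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  cluster <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    cluster[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (cluster[k] == 0L) {
          cluster[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  cluster
}

#' Cluster subnetworks by topology
#'
#' Embeds the dissimilarity matrix into `n_components` dimensions by
#' classical multidimensional scaling, then runs a density-based scan on
#' the embedding: points with at least `min_samples` neighbours within
#' `eps` are cores, clusters are eps-connected components, points in no
#' cluster are noise (cluster 0), and clusters smaller than
#' `min_cluster_size` are dissolved into noise. The default `eps` is twice
#' the median distance to the `min_samples`-th nearest neighbour, a scale
#' at which locally dense families stay connected while well-separated
#' families do not merge. The whole procedure is deterministic.
#'
#' @param dm symmetric dissimilarity matrix.
#' @param n_components embedding dimensions (default 10).
#' @param min_samples core-point neighbour threshold (default 3).
#' @param min_cluster_size smallest reported cluster (default 5).
#' @param eps neighbourhood radius; `NULL` for the data-driven default.
#' @return list with `assignment` (named integer vector; 0 = noise),
#'   `n_clusters`, `eps`, `embedding`.
#' @export
cluster_subnetworks <- function(dm, n_components = 10, min_samples = 3,
                                min_cluster_size = 5, eps = NULL) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < min_cluster_size) {
    warn2("fewer subnetworks than the minimum cluster size; all noise")
    return(list(assignment = setNames(rep(0L, n), rownames(dm)),
                n_clusters = 0L, eps = NA_real_, embedding = NULL))
  }
  k <- min(n_components, n - 1)
  emb <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k))
  if (is.null(eps)) {
    d <- as.matrix(stats::dist(emb))
    knn <- apply(d, 1, function(r) sort(r)[min_samples + 1])
    eps <- 2 * stats::median(knn)
    if (eps == 0) eps <- .Machine$double.eps
  }
  cluster <- dbscan_embed(emb, eps, min_pts = min_samples)
  sizes <- table(cluster[cluster > 0])
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  cluster[cluster %in% small] <- 0L
  # renumber surviving clusters consecutively, in order of first appearance
  surv <- unique(cluster[cluster > 0])
  cluster <- ifelse(cluster > 0, match(cluster, surv), 0L)
  list(assignment = setNames(as.integer(cluster), rownames(dm)),
       n_clusters = length(surv), eps = eps, embedding = emb)
}

#' Per-cluster composition by depth layer and region
#'
#' @param assignment named cluster vector from [cluster_subnetworks()]
#'   (names are sample ids; 0 = noise, excluded).
#' @param metadata data.frame with `sample`, `region`, `layer`.
#' @param dominance_threshold fraction above which a cluster is labelled
#'   "<layer>-dominated" (default 0.5, strict).
#' @return data.frame: cluster, size, one fraction column per layer and
#'   per region, and `dominant_layer` (`NA` when no layer dominates).
#' @export
cluster_composition <- function(assignment, metadata,
                                dominance_threshold = 0.5) {
  keep <- assignment > 0
  if (!any(keep)) {
    return(data.frame(cluster = integer(0), size = integer(0)))
  }
  md <- metadata[match(names(assignment)[keep], metadata$sample), ,
                 drop = FALSE]
  cl <- assignment[keep]
  layers <- sort(unique(metadata$layer))
  regions <- sort(unique(metadata$region))
  out <- lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    size <- sum(sel)
    lf <- vapply(layers, function(l) sum(md$layer[sel] == l) / size,
                 numeric(1))
    rf <- vapply(regions, function(r) sum(md$region[sel] == r) / size,
                 numeric(1))
    dom <- if (max(lf) > dominance_threshold) layers[which.max(lf)]
           else NA_character_
    row <- data.frame(cluster = k, size = size, t(lf), t(rf),
                      dominant_layer = dom, stringsAsFactors = FALSE)
    names(row)[3:(2 + length(layers))] <- paste0("layer_", layers)
    names(row)[(3 + length(layers)):(2 + length(layers) + length(regions))] <-
      paste0("region_", regions)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
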