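# Shared fixtures and independent oracles, built in code at test time.

# A small dataset: 3 regions x 2 layers, quick enough for per-test reuse.
tiny_sim_config <- function(seed = 101, ...) {
  args <- utils::modifyList(list(
    n_regions = 3, layers = c("SRF", "DCM"), samples_per_cell = 8,
    n_asvs_prok = 40, n_asvs_euk = 25,
    n_global_pairs = 3, n_regional_pairs = 2, n_layer_pairs = 1,
    n_env_driven_pairs = 2, n_negative_pairs = 1,
    seed = seed), list(...))
  do.call(sim_config, args)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(tiny_sim_config())
    cache
  }
})

# Hand-rolled asv_table: deterministic integer counts.
toy_table <- function(counts, domains = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- paste0("A", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(domains)) domains <- rep("Bacteria", nrow(m))
  asv_table(m, setNames(domains, rownames(m)))
}

# ---- independent oracles ---------------------------------------------------

# Plug-in MI by explicit contingency counting over discretized codes
# (independent of the tabulate-based production path).
oracle_mi_codes <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  mi
}

oracle_cmi_codes <- function(a, b, e) {
  n <- length(e)
  cmi <- 0
  for (z in unique(e)) {
    sel <- e == z
    cmi <- cmi + sum(sel) / n * oracle_mi_codes(a[sel], b[sel])
  }
  cmi
}

# Brute-force subnetwork derivation: literal per-edge evaluation of the
# three conditions, no shared code with derive_all().
oracle_subnetwork_edges <- function(sample_id, counts, metadata, static,
                                    threshold = 0.2) {
  md <- metadata[metadata$sample == sample_id, ]
  grp <- metadata$sample[metadata$region == md$region &
                           metadata$layer == md$layer]
  kept <- character(0)
  for (i in seq_len(nrow(static$edges))) {
    a <- static$edges$a[i]; b <- static$edges$b[i]
    if (counts$counts[a, sample_id] == 0) next
    if (counts$counts[b, sample_id] == 0) next
    both <- sum(counts$counts[a, grp] > 0 & counts$counts[b, grp] > 0)
    either <- sum(counts$counts[a, grp] > 0 | counts$counts[b, grp] > 0)
    if (either == 0) next
    if (both / either > threshold) kept <- c(kept, paste(sort(c(a, b)), collapse = "|"))
  }
  sort(kept)
}

# Brute-force per-node orbit counts: enumerate every 3- and 4-subset with
# combn, keep connected induced subgraphs, classify by degree sequence.
oracle_orbit_counts <- function(edges, nodes) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(edges$a, edges$b)] <- TRUE
    adj[cbind(edges$b, edges$a)] <- TRUE
  }
  orb <- matrix(0L, length(nodes), 15, dimnames = list(nodes, paste0("O", 0:14)))
  orb[, 1] <- as.integer(rowSums(adj))
  connected <- function(sub) {
    seen <- sub[1]
    repeat {
      nxt <- unique(c(seen, sub[colSums(adj[seen, sub, drop = FALSE]) > 0]))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(sub)
  }
  add <- function(vs, orbit) orb[vs, orbit] <<- orb[vs, orbit] + 1L
  if (length(nodes) >= 3) {
    for (sub in utils::combn(nodes, 3, simplify = FALSE)) {
      if (!connected(sub)) next
      deg <- rowSums(adj[sub, sub, drop = FALSE])
      if (sum(deg) / 2 == 3) add(sub, "O3")
      else { add(sub[deg == 1], "O1"); add(sub[deg == 2], "O2") }
    }
  }
  if (length(nodes) >= 4) {
    for (sub in utils::combn(nodes, 4, simplify = FALSE)) {
      if (!connected(sub)) next
      deg <- rowSums(adj[sub, sub, drop = FALSE])
      m <- sum(deg) / 2
      if (m == 3 && max(deg) == 3) { add(sub[deg == 1], "O6"); add(sub[deg == 3], "O7") }
      else if (m == 3) { add(sub[deg == 1], "O4"); add(sub[deg == 2], "O5") }
      else if (m == 4 && max(deg) == 2) add(sub, "O8")
      else if (m == 4) { add(sub[deg == 1], "O9"); add(sub[deg == 2], "O10"); add(sub[deg == 3], "O11") }
      else if (m == 5) { add(sub[deg == 2], "O12"); add(sub[deg == 3], "O13") }
      else add(sub, "O14")
    }
  }
  orb
}

# Brute-force MST weight: enumerate all spanning trees of a small graph by
# trying every (n-1)-edge subset.
oracle_mst_weight <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  best <- Inf
  for (sub in utils::combn(seq_len(nrow(edges)), n - 1, simplify = FALSE)) {
    sel <- edges[sub, ]
    comp <- seq_len(n)
    names(comp) <- nodes
    for (i in seq_len(nrow(sel))) {
      ca <- comp[sel$a[i]]; cb <- comp[sel$b[i]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (length(unique(comp)) == 1) best <- min(best, sum(sel$weight))
  }
  best
}

# Random simple graph as an edge data.frame over given node names.
random_graph_edges <- function(n, p, nodes = sprintf("n%02d", seq_len(n))) {
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(a = pairs[1, keep], b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# All non-isomorphic-agnostic graphs on exactly `n` labelled nodes, as edge
# subsets of K_n (used exhaustively for small n).
all_graphs_on <- function(n) {
  nodes <- letters[seq_len(n)]
  pairs <- utils::combn(nodes, 2)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    data.frame(a = pairs[1, keep], b = pairs[2, keep],
               stringsAsFactors = FALSE)
  })
}
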