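# The single static association network: import from an external edge list,
# a documented stand-in inference (correlation + permutation null + BH), and
# node bookkeeping. Environmentally-driven edge removal lives in
# R/information.R alongside the information-theoretic machinery it uses.

#' Static association network
#'
#' An undirected, signed, weighted network over ASVs. Edges are deduplicated
#' and stored with lexicographically sorted endpoints; self-loops and
#' duplicate edges with contradictory scores are rejected. The sign of an
#' edge is the sign of its score.
#'
#' @param edges data.frame with columns `a`, `b`, `score`.
#' @param node_domains optional named character vector of domain labels per
#'   ASV id ("Archaea", "Bacteria", "Eukaryota"); if supplied, every edge
#'   endpoint must be covered.
#' @return object of class `static_network`: list with `nodes`
#'   (data.frame: asv, domain) and `edges` (data.frame: a, b, score, sign).
#' @export
static_network <- function(edges, node_domains = NULL) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "score") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  if (any(edges$a == edges$b)) {
    stop2("self-loop(s) on: ",
          paste(unique(edges$a[edges$a == edges$b]), collapse = ", "))
  }
  edges <- canonicalise_edges(edges)
  key <- edge_key(edges$a, edges$b)
  if (anyDuplicated(key)) {
    split_scores <- split(edges$score, key)
    contradictory <- names(split_scores)[vapply(split_scores, function(s)
      length(unique(s)) > 1, logical(1))]
    if (length(contradictory)) {
      stop2("duplicate edges with contradictory scores: ",
            paste(contradictory, collapse = ", "))
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  node_ids <- sort(unique(c(edges$a, edges$b)))
  if (!is.null(node_domains)) {
    missing <- setdiff(node_ids, names(node_domains))
    if (length(missing)) {
      stop2("edge endpoints without a domain label: ",
            paste(missing, collapse = ", "))
    }
    nodes <- data.frame(asv = node_ids,
                        domain = unname(node_domains[node_ids]),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(asv = node_ids, domain = NA_character_,
                        stringsAsFactors = FALSE)
  }
  edges$sign <- ifelse(edges$score >= 0, "positive", "negative")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  pos <- sum(x$edges$sign == "positive")
  cat(sprintf("<static_network> %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges), pos, nrow(x$edges) - pos))
  invisible(x)
}

#' Import a static network from a tab-delimited edge list
#'
#' Reads a TSV with (at least) three columns: the two endpoint ASV ids and
#' the signed association score. The canonical input is the exported edge
#' list of an external network-inference tool.
#'
#' @param edge_list_file path to the edge list.
#' @param node_domains optional named domain vector (see [static_network]);
#'   when given, unknown ASV ids in the file are an error.
#' @return a [static_network].
#' @export
import_network <- function(edge_list_file, node_domains = NULL) {
  if (!file.exists(edge_list_file)) {
    stop2("edge list not found: ", edge_list_file)
  }
  df <- utils::read.delim(edge_list_file, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop2(edge_list_file, ": need at least 3 columns (a, b, score)")
  names(df)[1:3] <- c("a", "b", "score")
  if (!is.numeric(df$score)) stop2(edge_list_file, ": score column is not numeric")
  static_network(df[, c("a", "b", "score")], node_domains)
}

#' Write a static network as an edge-list TSV
#' @param net a [static_network].
#' @param file output path.
#' @export
write_network <- function(net, file) {
  stopifnot(inherits(net, "static_network"))
  utils::write.table(net$edges[, c("a", "b", "score")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Remove isolated nodes
#'
#' Finalizes a network so every remaining node has degree >= 1.
#'
#' @param net a [static_network].
#' @return the network without edge-less nodes.
#' @export
remove_isolated_nodes <- function(net) {
  stopifnot(inherits(net, "static_network"))
  keep <- net$nodes$asv %in% c(net$edges$a, net$edges$b)
  net$nodes <- net$nodes[keep, , drop = FALSE]
  rownames(net$nodes) <- NULL
  net
}

#' Stand-in association inference
#'
#' A deliberately simple replacement for an external network-inference tool:
#' pairwise Pearson correlation of CLR-transformed abundances, tested
#' against a permutation null (each ASV's sample order permuted
#' independently; null correlations pooled over pairs) with
#' Benjamini-Hochberg control at `alpha`. The edge score is the observed
#' correlation. This is not equivalent to conditional-independence-based
#' inference; the canonical route into the pipeline is [import_network()].
#'
#' @param clr a merged `clr_table` (see [merge_domain_tables()]).
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param n_perm permutations pooled into the null (default 200).
#' @param seed RNG seed.
#' @return a [static_network].
#' @export
infer_standin_network <- function(clr, alpha = 0.01, n_perm = 200, seed = 1) {
  stopifnot(inherits(clr, "clr_table"))
  x <- clr$values
  if (ncol(x) < 20) stop2("need at least 20 samples for the stand-in inference")
  constant <- apply(x, 1, stats::sd) == 0
  if (any(constant)) {
    warn2("excluding ", sum(constant), " constant ASV row(s)")
    x <- x[!constant, , drop = FALSE]
  }
  if (nrow(x) < 2) stop2("fewer than 2 usable ASVs")
  set.seed(derive_seed(seed, "standin"))
  xt <- t(x)
  obs <- stats::cor(xt)
  ut <- upper.tri(obs)
  obs_r <- abs(obs[ut])

  n <- ncol(x)
  null_r <- numeric(0)
  # pooled null: permute every ASV independently, keep each replicate's
  # upper triangle (capped so the pool stays within memory)
  keep_per_perm <- max(1L, min(length(obs_r),
                               ceiling(5e6 / max(1, n_perm))))
  for (b in seq_len(n_perm)) {
    xp <- apply(xt, 2, sample)
    rp <- abs(stats::cor(xp)[ut])
    if (length(rp) > keep_per_perm) rp <- sample(rp, keep_per_perm)
    null_r <- c(null_r, rp)
  }
  null_sorted <- sort(null_r)
  m <- length(null_sorted)
  # one-sided p against the pooled null, add-one corrected
  p <- (m - findInterval(obs_r, null_sorted) + 1) / (m + 1)
  p_adj <- stats::p.adjust(p, method = "BH")

  idx <- which(ut, arr.ind = TRUE)
  sig <- p_adj <= alpha
  edges <- data.frame(a = rownames(x)[idx[sig, 1]],
                      b = rownames(x)[idx[sig, 2]],
                      score = obs[ut][sig],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    return(structure(list(nodes = data.frame(asv = character(0),
                                             domain = character(0)),
                          edges = data.frame(a = character(0), b = character(0),
                                             score = numeric(0),
                                             sign = character(0))),
                     class = "static_network"))
  }
  static_network(edges, clr$domain)
}
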