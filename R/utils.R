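# Internal helpers shared across modules.

#' Canonical undirected edge key
#'
#' Edges are unordered ASV pairs; a canonical "a|b" key (lexicographically
#' sorted endpoints) is used everywhere an edge indexes a table.
#'
#' @param a,b character vectors of endpoint ids (recycled together).
#' @return character vector of keys.
#' @keywords internal
edge_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}

# Sort endpoint columns of an edge data.frame into canonical (a <= b) order.
canonicalise_edges <- function(edges) {
  swap <- edges$a > edges$b
  if (any(swap)) {
    tmp <- edges$a[swap]
    edges$a[swap] <- edges$b[swap]
    edges$b[swap] <- tmp
  }
  edges
}

# Deterministic small integer seed derived from a base seed and a label,
# kept below 2^31 so it is always a valid R seed.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147480009
  as.integer(h)
}

# round() in R is already round-half-even; this fixes the digits and keeps
# the value numeric (formatting to strings happens at the reporting edge).
round2 <- function(x, digits = 2) round(x, digits = digits)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
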