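# Abundance-table container and the compositional preprocessing steps:
# sample read-depth filter, rare-ASV filter, centered log-ratio transform,
# and the merge of the prokaryotic and eukaryotic tables.

#' ASV abundance table
#'
#' A minimal container for an ASV-by-sample read-count matrix together with
#' the per-ASV domain (Archaea, Bacteria or Eukaryota) and an optional
#' taxonomy lineage string.
#'
#' @param counts non-negative integer matrix, ASVs in rows (rownames = ASV
#'   ids), samples in columns (colnames = sample ids).
#' @param domain character vector, one of "Archaea", "Bacteria", "Eukaryota"
#'   per ASV; either named by ASV id or in row order.
#' @param taxonomy optional character vector of lineage strings.
#' @return an object of class `asv_table`.
#' @export
asv_table <- function(counts, domain, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop2("counts must have ASV rownames")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop2("counts must have sample colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop2("duplicate ASV ids")
  if (anyDuplicated(colnames(counts))) stop2("duplicate sample ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop2("counts must be non-negative integers")
  }
  if (!is.null(names(domain))) domain <- domain[rownames(counts)]
  if (length(domain) != nrow(counts) || anyNA(domain)) {
    stop2("domain must cover every ASV")
  }
  bad <- setdiff(unique(domain), c("Archaea", "Bacteria", "Eukaryota"))
  if (length(bad)) stop2("unknown domain label(s): ", paste(bad, collapse = ", "))
  names(domain) <- rownames(counts)
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- taxonomy[rownames(counts)]
    names(taxonomy) <- rownames(counts)
  }
  structure(list(counts = counts, domain = domain, taxonomy = taxonomy),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d ASVs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$domain)),
                            as.integer(table(x$domain))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

# Subset an asv_table by ASV ids and/or sample ids, keeping annotations.
subset_asv_table <- function(tab, asvs = NULL, samples = NULL) {
  counts <- tab$counts
  if (!is.null(asvs)) counts <- counts[asvs, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  asv_table(counts, tab$domain[rownames(counts)],
            if (!is.null(tab$taxonomy)) tab$taxonomy[rownames(counts)])
}

#' Drop shallow samples
#'
#' Keeps samples whose total read count reaches `min_reads` (boundary
#' inclusive: a sample with exactly `min_reads` reads is kept). Column order
#' is preserved; an empty result is allowed.
#'
#' @param table an [asv_table].
#' @param min_reads minimum total reads per sample (default 2000).
#' @return filtered [asv_table].
#' @export
filter_samples <- function(table, min_reads = 2000) {
  stopifnot(inherits(table, "asv_table"))
  keep <- colSums(table$counts) >= min_reads
  subset_asv_table(table, samples = colnames(table$counts)[keep])
}

#' Drop rare ASVs
#'
#' Keeps ASVs whose total read count across all samples is strictly above
#' `min_total_reads` and that are present (count > 0) in at least
#' `min_samples` samples. Presence is evaluated on the table as given, so
#' run [filter_samples()] first to reproduce the usual ordering
#' (samples filtered before ASVs).
#'
#' @param table an [asv_table].
#' @param min_total_reads strict lower bound on the ASV's total reads
#'   (default 100: an ASV totalling exactly 100 reads is removed).
#' @param min_samples minimum number of samples with a non-zero count
#'   (default 20, boundary inclusive).
#' @return filtered [asv_table].
#' @export
filter_asvs <- function(table, min_total_reads = 100, min_samples = 20) {
  stopifnot(inherits(table, "asv_table"))
  total <- rowSums(table$counts)
  npres <- rowSums(table$counts > 0)
  keep <- total > min_total_reads & npres >= min_samples
  subset_asv_table(table, asvs = rownames(table$counts)[keep])
}

#' Centered log-ratio transform
#'
#' Per sample, `value_i = log(c_i + pc) - mean_j log(c_j + pc)` over the
#' ASVs of the table, in natural-log units; each sample's transformed values
#' sum to zero. Counts are zero-heavy, so a pseudocount (default +1 read)
#' keeps the logs finite; the transform should be applied separately per
#' domain table before merging.
#'
#' @param table an [asv_table].
#' @param pseudocount positive real added to every count (default 1).
#' @return a `clr_table`: list with `values` (same axes as the counts),
#'   `domain` and `taxonomy`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "asv_table"))
  if (pseudocount <= 0) stop2("pseudocount must be > 0")
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0) {
    stop2("cannot CLR-transform an empty table")
  }
  if (nrow(table$counts) == 1) {
    warn2("single-ASV table: CLR transform is degenerate (all zeros)")
  }
  lg <- log(table$counts + pseudocount)
  values <- sweep(lg, 2, colMeans(lg), "-")
  structure(list(values = values, domain = table$domain,
                 taxonomy = table$taxonomy),
            class = "clr_table")
}

#' @export
print.clr_table <- function(x, ...) {
  cat(sprintf("<clr_table> %d ASVs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Merge the prokaryotic and eukaryotic CLR tables
#'
#' Row-concatenates two CLR tables over an identical sample set (each
#' transformed separately, so compositional closure stays within domain).
#'
#' @param prok,euk `clr_table` objects with identical sample id sets.
#' @return merged `clr_table` (samples in `prok`'s column order).
#' @export
merge_domain_tables <- function(prok, euk) {
  stopifnot(inherits(prok, "clr_table"), inherits(euk, "clr_table"))
  if (nrow(euk$values) == 0) return(prok)
  if (nrow(prok$values) == 0) return(euk)
  sp <- colnames(prok$values)
  se <- colnames(euk$values)
  if (!setequal(sp, se)) {
    stop2("sample sets differ; only in prok: ",
          paste(setdiff(sp, se), collapse = ", "),
          "; only in euk: ", paste(setdiff(se, sp), collapse = ", "))
  }
  if (length(intersect(rownames(prok$values), rownames(euk$values)))) {
    stop2("ASV ids overlap between the two tables")
  }
  values <- rbind(prok$values, euk$values[, sp, drop = FALSE])
  tax <- NULL
  if (!is.null(prok$taxonomy) || !is.null(euk$taxonomy)) {
    tax <- c(prok$taxonomy %||% setNames(rep(NA_character_, nrow(prok$values)),
                                         rownames(prok$values)),
             euk$taxonomy %||% setNames(rep(NA_character_, nrow(euk$values)),
                                        rownames(euk$values)))
  }
  structure(list(values = values,
                 domain = c(prok$domain, euk$domain),
                 taxonomy = tax),
            class = "clr_table")
}
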