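#' Construct an OTU table
#'
#' Bundles a samples x OTUs matrix of non-negative integer read counts with
#' per-sample metadata (site, month, nucleic-acid fraction). The fraction
#' distinguishes the total community (rDNA, 16S gene amplicons) from the
#' active community (rRNA, reverse-transcribed transcripts).
#'
#' @param counts integer matrix, samples in rows (unique rownames = sample
#'   ids), OTUs in columns (unique colnames = OTU ids).
#' @param metadata data.frame with one row per sample (matched by rowname or
#'   a `sample_id` column) and columns `site`, `month` (1-12) and
#'   `fraction` (`"rDNA"` or `"rRNA"`).
#' @return An object of class `otu_table`: a list with elements `counts`
#'   and `metadata`.
#' @export
otu_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_bad("counts must have unique sample rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_bad("counts must have unique OTU colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_bad("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) rownames(metadata) <- metadata$sample_id
  need <- c("site", "month", "fraction")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop_bad("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(rownames(metadata), rownames(counts)))
    stop_bad("metadata rows must match count-matrix samples")
  metadata <- metadata[rownames(counts), , drop = FALSE]
  if (!all(metadata$fraction %in% c("rDNA", "rRNA")))
    stop_bad("fraction must be 'rDNA' or 'rRNA'")
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.double(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Remove rare OTUs
#'
#' Drops every OTU that occurs in at most one sample of the dataset, or
#' whose summed reads across all samples are below `min_reads`. Samples are
#' never removed.
#'
#' @param x an [otu_table].
#' @param min_reads minimum total reads for an OTU to be kept (default 10).
#' @param min_occurrence minimum number of samples with a nonzero count
#'   (default 2, i.e. singleton-occurrence OTUs are dropped).
#' @return A filtered [otu_table] with the same samples.
#' @export
filter_otus <- function(x, min_reads = 10, min_occurrence = 2) {
  stopifnot(inherits(x, "otu_table"))
  if (ncol(x$counts) == 0L || nrow(x$counts) == 0L)
    stop_bad("empty OTU table")
  occ <- colSums(x$counts > 0)
  tot <- colSums(x$counts)
  keep <- occ >= min_occurrence & tot >= min_reads
  otu_table(x$counts[, keep, drop = FALSE], x$metadata)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads uniformly without replacement down to
#' `depth` reads, equalizing sequencing effort before composition analyses.
#'
#' @param x an [otu_table]; every sample must hold at least `depth` reads.
#' @param depth target reads per sample (default 16000).
#' @param seed integer seed; rarefaction is deterministic given the seed.
#' @return An [otu_table] in which every sample sums exactly to `depth`.
#' @export
rarefy <- function(x, depth = 16000, seed) {
  stopifnot(inherits(x, "otu_table"))
  if (missing(seed)) stop_bad("`seed` is required for rarefaction")
  tot <- rowSums(x$counts)
  shallow <- tot < depth
  if (any(shallow))
    stop_bad("sample(s) shallower than depth ", depth, ": ",
             paste(rownames(x$counts)[shallow], collapse = ", "))
  # depth feasibility is validated above; rrarefy's own data heuristics
  # (e.g. "no small counts") do not apply to validated integer tables
  sub <- with_seed(seed, suppressWarnings(vegan::rrarefy(x$counts, depth)))
  storage.mode(sub) <- "integer"
  otu_table(sub, x$metadata)
}

#' Relative abundance (percent)
#'
#' @param x an [otu_table] or non-negative count matrix.
#' @return Matrix of per-sample proportional abundances; rows sum to 100.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop_bad("zero-sum sample(s): ",
             paste(rownames(m)[tot <= 0], collapse = ", "))
  sweep(m, 1, tot, "/") * 100
}

#' Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over OTUs. A pair of
#' all-zero samples has an undefined (0/0) dissimilarity; it is reported as
#' 0 with a warning (identical emptiness treated as identity).
#'
#' @param x non-negative abundance matrix (samples in rows) or [otu_table]
#'   (its counts are used).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2L) stop_bad("need at least 2 samples")
  if (any(m < 0)) stop_bad("Bray-Curtis requires non-negative abundances")
  # empty rows surface as NA pairs, reported below with our own warning
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis undefined, set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering of community profiles; the linkage default is
#' complete, matching the default of `hclust()`.
#'
#' @param d a `dist` object or square symmetric matrix with zero diagonal.
#' @param linkage one of `"complete"`, `"average"`, `"single"`.
#' @return An `hclust` object (leaves = input labels).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
      stop_bad("dissimilarity matrix must be square and symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop_bad("dissimilarity diagonal must be zero")
    d <- as.dist(d)
  }
  hclust(d, method = linkage)
}

#' Serialize a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the clustering.
#'
#' @param hc an `hclust` object.
#' @param path optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
as_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
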