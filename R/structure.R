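#' Group-specific dominance thresholds
#'
#' Biomass cut-offs below which taxa are excluded from the multivariate
#' community analysis: 10 mg m^-3 for plankton, 10 x 10^3 mg m^-2 for
#' benthic macroalgae, 1 mg m^-2 for benthic microalgae.
#'
#' @param organism_group one of `"plankton"`, `"benthic_macroalgae"`,
#'   `"benthic_microalgae"`.
#' @return numeric threshold in the table's biomass units.
#' @export
dominance_threshold <- function(organism_group = c("plankton",
                                                   "benthic_macroalgae",
                                                   "benthic_microalgae")) {
  organism_group <- match.arg(organism_group)
  switch(organism_group,
         plankton = 10,
         benthic_macroalgae = 10e3,
         benthic_microalgae = 1)
}

#' Filter dominant taxa by habitat-mean biomass
#'
#' A taxon is dominant when its mean biomass reaches the group threshold in
#' at least one habitat; only dominants enter clustering, ordination and
#' key-species selection.
#'
#' @param x a `community_table`.
#' @param threshold numeric cut-off, or an organism-group name understood by
#'   [dominance_threshold()].
#' @param partition a [habitat_partition()]; computed from `x` when omitted.
#' @return list with `taxa` (retained ids), `habitat_means` (retained taxa x
#'   habitats mean-biomass matrix), `dominants` (named list: habitat ->
#'   taxa at/above threshold in that habitat) and `threshold`.
#' @export
filter_dominants <- function(x, threshold = "plankton", partition = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (is.character(threshold)) threshold <- dominance_threshold(threshold)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  if (is.null(partition)) partition <- habitat_partition(x)
  means <- habitat_means(x, partition)
  keep <- apply(means, 1, max) >= threshold
  if (!any(keep))
    stop("no taxon reaches the dominance threshold (", threshold,
         "); review the threshold for this organism group")
  means <- means[keep, , drop = FALSE]
  dominants <- lapply(colnames(means), function(h)
    rownames(means)[means[, h] >= threshold])
  names(dominants) <- colnames(means)
  list(taxa = rownames(means), habitat_means = means,
       dominants = dominants, threshold = threshold)
}

#' log10(x + 1) transform
#'
#' The standard variance-stabilising transform applied to biomass before
#' clustering and ordination.
#'
#' @param m non-negative numeric matrix or vector.
#' @return elementwise log10(m + 1).
#' @export
log_transform <- function(m) {
  if (any(m < 0)) stop("log_transform requires non-negative input")
  log10(m + 1)
}

#' Extract communities by Ward clustering
#'
#' Agglomerative hierarchical clustering of taxa (rows) with Ward's
#' minimum-variance criterion on Euclidean distances, cut into `k`
#' communities labelled a, b, c, ... in order of first appearance. Input is
#' normally the log-transformed taxon x habitat-mean matrix of dominants.
#'
#' @param m numeric matrix, taxa in rows (>= 2 rows).
#' @param k number of communities (default 3). Must not exceed the number of
#'   taxa. When all rows are identical the geometry is degenerate: any k > 1
#'   is refused with a zero-distance warning and a single community is
#'   returned.
#' @return An object of class `community_assignment`: list with `assignment`
#'   (named character vector taxon -> label), `k`, `hclust` (the full
#'   linkage object) and `heights` (non-decreasing merge heights).
#' @export
ward_communities <- function(m, k = 3) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("ward_communities requires at least 2 taxa")
  if (k < 1 || k > nrow(m))
    stop("ward_communities: k = ", k, " exceeds the number of taxa (",
         nrow(m), ")")
  d <- stats::dist(m, method = "euclidean")
  if (max(d) == 0) {
    if (k > 1) {
      warning("all taxa are at zero distance; returning a single community")
      k <- 1
    }
    assignment <- stats::setNames(rep("a", nrow(m)), rownames(m))
    return(structure(list(assignment = assignment, k = 1, hclust = NULL,
                          heights = numeric(0)),
                     class = "community_assignment"))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  # relabel in order of first appearance so labels are reproducible
  first <- unique(grp)
  labels <- stats::setNames(letters[seq_along(first)], first)
  assignment <- stats::setNames(labels[as.character(grp)], names(grp))
  structure(list(assignment = assignment, k = k, hclust = hc,
                 heights = hc$height),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community_assignment: %d taxa in %d communities\n",
              length(x$assignment), x$k))
  print(table(x$assignment))
  invisible(x)
}

#' PCA ordination of dominant taxa over habitat variables
#'
#' Principal component analysis of the (log-transformed) taxon x
#' habitat-mean matrix on the covariance matrix: habitat variables are
#' centred but not rescaled, since after the log transform the habitat
#' columns are commensurate. The sign of each component is fixed so that its
#' largest-magnitude habitat loading is positive.
#'
#' @param m numeric matrix, taxa in rows (>= 3), habitats in columns (>= 2).
#' @param scale. use the correlation matrix instead of the covariance matrix
#'   (default `FALSE`).
#' @return An object of class `ordination_result`: list with `scores` (taxon
#'   scores), `loadings` (habitat loadings) and `explained_variance`
#'   (fractions over all components, summing to 1).
#' @export
pca_ordination <- function(m, scale. = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("pca_ordination requires at least 3 taxa")
  if (ncol(m) < 2) stop("pca_ordination requires at least 2 habitat variables")
  if (all(apply(m, 2, stats::var) == 0))
    stop("matrix has zero variance in every habitat variable")
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- p$sdev^2 / sum(p$sdev^2)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance = ev),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("ordination_result: explained variance ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
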