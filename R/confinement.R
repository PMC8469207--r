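#' Index of relative biotope confinement
#'
#' Fidelity of a species to a habitat, computed from its quantity in the
#' habitat (`n_ij`), its quantity over all collections (`n_i`), the habitat
#' total (`N_j`) and the grand total (`N`):
#'
#'   F_ij = (n_ij * N - n_i * N_j) / (n_ij * N + n_i * N_j - 2 * n_ij * N_j)
#'
#' The index ranges from -1 (species absent from the habitat) to +1 (the
#' species occurs only in that habitat); 0 indicates indifference, i.e. the
#' species' share of the habitat equals its share of the whole survey.
#'
#' @param n_ij species quantity (biomass) in habitat j, `>= 0`.
#' @param n_i species quantity over all habitats, `> 0`, with `n_ij <= n_i`.
#' @param N_j total quantity of all species in habitat j, `> 0`,
#'   with `n_ij <= N_j`.
#' @param N grand total over all habitats, with `N_j < N` (the habitat must
#'   be a proper subset of the survey).
#' @return Numeric in \[-1, +1\] (vectorised with recycling).
#' @export
confinement_index <- function(n_ij, n_i, N_j, N) {
  k <- cbind(n_ij, n_i, N_j, N)           # recycles to common length
  n_ij <- k[, 1]; n_i <- k[, 2]; N_j <- k[, 3]; N <- k[, 4]
  if (any(!is.finite(k))) stop("all arguments must be finite")
  eps <- sqrt(.Machine$double.eps)
  if (any(n_ij < 0) || any(n_i <= 0) || any(N_j <= 0) || any(N <= 0))
    stop("require n_ij >= 0, n_i > 0, N_j > 0, N > 0")
  if (any(n_ij > n_i * (1 + eps)) || any(n_ij > N_j * (1 + eps)))
    stop("require n_ij <= n_i and n_ij <= N_j")
  if (any(n_i > N * (1 + eps)) || any(N_j >= N))
    stop("require n_i <= N and N_j < N (habitat must be a proper subset)")
  den <- n_ij * N + n_i * N_j - 2 * n_ij * N_j
  if (any(den == 0))
    stop("degenerate partition: zero denominator (n_ij = n_i = N_j)")
  f <- (n_ij * N - n_i * N_j) / den
  # the endpoints are analytically exact: F = -1 iff n_ij = 0 and
  # F = +1 iff n_ij = n_i; evaluate them directly so rounding in the
  # rearranged denominator cannot perturb them
  f[n_ij == 0] <- -1
  f[n_ij == n_i] <- 1
  unname(f)
}

#' Biotope-confinement table over all taxa and habitats
#'
#' Pools biomass per taxon within each habitat and evaluates the confinement
#' index for every (taxon, habitat) pair. Taxa with zero total biomass are
#' omitted (the index is undefined for them).
#'
#' @param x a `community_table`.
#' @param partition a [habitat_partition()] with at least two habitats;
#'   computed from `x` when omitted.
#' @return An object of class `confinement_result`: list with `F` (taxa x
#'   habitats matrix), and the pooled inputs `n_ij`, `n_i`, `N_j`, `N`.
#' @export
confinement_table <- function(x, partition = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (is.null(partition)) partition <- habitat_partition(x)
  if (length(partition) < 2)
    stop("confinement index undefined for a single-habitat partition (N_j = N)")
  n_ij <- vapply(partition, function(sids)
    rowSums(x$biomass[, sids, drop = FALSE]), numeric(nrow(x$biomass)))
  if (nrow(x$biomass) == 1)
    n_ij <- matrix(n_ij, nrow = 1,
                   dimnames = list(rownames(x$biomass), names(partition)))
  keep <- rowSums(n_ij) > 0
  n_ij <- n_ij[keep, , drop = FALSE]
  n_i <- rowSums(n_ij)
  N_j <- colSums(n_ij)
  N <- sum(N_j)
  if (N <= 0) stop("grand total biomass must be positive")
  Fm <- matrix(NA_real_, nrow(n_ij), ncol(n_ij), dimnames = dimnames(n_ij))
  for (j in seq_len(ncol(n_ij))) {
    Fm[, j] <- confinement_index(n_ij[, j], n_i, N_j[j], N)
  }
  structure(list(F = Fm, n_ij = n_ij, n_i = n_i, N_j = N_j, N = N),
            class = "confinement_result")
}

#' @export
print.confinement_result <- function(x, ...) {
  cat(sprintf("confinement_result: %d taxa x %d habitats, grand total %.4g\n",
              nrow(x$F), ncol(x$F), x$N))
  print(round(x$F, 3))
  invisible(x)
}

#' Key-species selection from confinement values
#'
#' Within each habitat, the key species are the dominant taxa attaining the
#' maximum confinement index, provided that maximum is positive. Exact ties
#' at the maximum all qualify; when no dominant has a positive index the
#' habitat's key set is empty.
#'
#' @param conf a `confinement_result`.
#' @param dominants named list mapping habitat id to the character vector of
#'   its dominant taxon ids (see [filter_dominants()]).
#' @return Named list: habitat id -> character vector of key taxon ids.
#' @export
select_key_species <- function(conf, dominants) {
  stopifnot(inherits(conf, "confinement_result"))
  habs <- colnames(conf$F)
  out <- stats::setNames(vector("list", length(habs)), habs)
  for (h in habs) {
    dom <- intersect(dominants[[h]], rownames(conf$F))
    if (length(dom) == 0) { out[[h]] <- character(0); next }
    f <- conf$F[dom, h]
    mx <- max(f)
    out[[h]] <- if (mx > 0) dom[f == mx] else character(0)
  }
  out
}

#' Export a confinement table as CSV
#'
#' One row per taxon, one column of F values (rounded to 3 decimals, the
#' customary reporting precision) per habitat, plus an `is_key` flag naming
#' the habitats in which the taxon is a key species.
#'
#' @param conf a `confinement_result`.
#' @param path output CSV path.
#' @param key_species optional result of [select_key_species()].
#' @param digits rounding for the F columns (default 3).
#' @return the exported data frame, invisibly.
#' @export
write_confinement_csv <- function(conf, path, key_species = NULL, digits = 3) {
  df <- data.frame(taxon_id = rownames(conf$F),
                   round(conf$F, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(key_species)) {
    df$is_key <- vapply(df$taxon_id, function(t) {
      habs <- names(key_species)[vapply(key_species, function(k) t %in% k,
                                        logical(1))]
      paste(habs, collapse = ";")
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
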