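#' Construct a community table
#'
#' A community table is the universal input of the package: a taxon x sample
#' matrix of non-negative biomass values (mass per unit volume for plankton,
#' mass per unit area for benthos), an optional abundance matrix of identical
#' shape, and per-sample metadata.
#'
#' @param biomass numeric matrix, taxa in rows and samples in columns; row
#'   names are taxon ids, column names are sample ids. All entries must be
#'   finite and non-negative.
#' @param samples data frame of sample metadata with at least columns
#'   `sample_id` (unique, matching the biomass columns) and `habitat_id`
#'   (non-empty). Optional columns: `station_id`, `stratum` (depth-layer
#'   label), `replicate`.
#' @param abundance optional numeric matrix (individuals per unit
#'   volume/area) with the same dimnames as `biomass`.
#' @param unit_kind `"per_volume"` (e.g. mg m^-3, plankton) or `"per_area"`
#'   (e.g. mg m^-2, benthos). Metadata only; no conversion is ever applied.
#'
#' @return An object of class `community_table`.
#' @export
community_table <- function(biomass, samples, abundance = NULL,
                            unit_kind = c("per_volume", "per_area")) {
  unit_kind <- match.arg(unit_kind)
  biomass <- as.matrix(biomass)
  storage.mode(biomass) <- "double"
  if (is.null(rownames(biomass)) || is.null(colnames(biomass)))
    stop("biomass matrix must carry taxon row names and sample column names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("station_id", "stratum")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  if (!"replicate" %in% names(samples)) samples$replicate <- NA_integer_
  if (!all(c("sample_id", "habitat_id") %in% names(samples)))
    stop("samples must contain 'sample_id' and 'habitat_id' columns")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (any(is.na(samples$habitat_id) | !nzchar(samples$habitat_id)))
    stop("every sample must have a non-empty habitat_id")
  if (!setequal(colnames(biomass), samples$sample_id))
    stop("biomass column names and samples$sample_id must match")
  samples <- samples[match(colnames(biomass), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  check_quant_matrix(biomass, "biomass")
  if (!is.null(abundance)) {
    abundance <- as.matrix(abundance)
    storage.mode(abundance) <- "double"
    if (!identical(dim(abundance), dim(biomass)))
      stop("abundance matrix must have the same shape as biomass")
    if (!is.null(rownames(abundance)) &&
        !identical(rownames(abundance), rownames(biomass)))
      abundance <- abundance[rownames(biomass), colnames(biomass), drop = FALSE]
    dimnames(abundance) <- dimnames(biomass)
    check_quant_matrix(abundance, "abundance")
  }

  structure(
    list(biomass = biomass, abundance = abundance, samples = samples,
         unit_kind = unit_kind),
    class = "community_table"
  )
}

check_quant_matrix <- function(m, what) {
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s contains negative or non-finite values, e.g. cell (%s, %s)",
                 what, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(m)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples (%s)\n",
              nrow(x$biomass), ncol(x$biomass), x$unit_kind))
  cat(sprintf("  habitats: %s\n",
              paste(unique(x$samples$habitat_id), collapse = ", ")))
  if (!is.null(x$abundance)) cat("  abundance matrix present\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$biomass)

#' Partition samples into habitats
#'
#' Builds the habitat partition used by all per-habitat computations: a named
#' list mapping each habitat id to its sample ids, ordered by first
#' appearance in the sample metadata. The sets are disjoint and jointly cover
#' every sample.
#'
#' @param x a `community_table` or its `samples` data frame.
#' @return A named list of character vectors, class `habitat_partition`.
#' @export
habitat_partition <- function(x) {
  samples <- if (inherits(x, "community_table")) x$samples else x
  ord <- unique(samples$habitat_id)
  part <- split(samples$sample_id, factor(samples$habitat_id, levels = ord))
  structure(part, class = "habitat_partition")
}

#' Read a community table from delimited text
#'
#' Two dialects are supported. Wide: first column `taxon_id`, remaining
#' columns one per sample. Long: columns `taxon_id`, `sample_id`, `value`
#' (and optionally `abundance`); taxon x sample cells absent from a long file
#' are zeros (absence), not missing data.
#'
#' @param path path to a CSV/TSV file (UTF-8, "." decimal separator).
#' @param format `"wide"` or `"long"`.
#' @param samples sample metadata: a data frame or a path to a sample-sheet
#'   CSV (`sample_id, habitat_id, station_id, stratum, replicate`). When
#'   omitted, all samples are placed in a single habitat `"all"`.
#' @param abundance for wide format, an optional path to a second matrix file
#'   of identical layout holding abundances.
#' @param unit_kind passed to [community_table()].
#' @param sep field separator, `","` by default.
#' @return A validated [community_table()].
#' @export
read_community_table <- function(path, format = c("wide", "long"),
                                 samples = NULL, abundance = NULL,
                                 unit_kind = "per_volume", sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    biomass <- wide_to_matrix(raw)
    ab <- NULL
    if (!is.null(abundance)) {
      ab <- wide_to_matrix(utils::read.table(abundance, header = TRUE, sep = sep,
                                             stringsAsFactors = FALSE,
                                             check.names = FALSE))
    }
  } else {
    need <- c("taxon_id", "sample_id", "value")
    if (!all(need %in% names(raw)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    key <- paste(raw$taxon_id, raw$sample_id, sep = " / ")
    if (anyDuplicated(key))
      stop("duplicated (taxon, sample) pair in long file: ",
           key[duplicated(key)][1])
    taxa <- unique(raw$taxon_id)
    sids <- unique(raw$sample_id)
    biomass <- matrix(0, nrow = length(taxa), ncol = length(sids),
                      dimnames = list(taxa, sids))
    biomass[cbind(match(raw$taxon_id, taxa), match(raw$sample_id, sids))] <-
      raw$value
    ab <- NULL
    if ("abundance" %in% names(raw)) {
      ab <- matrix(0, nrow = length(taxa), ncol = length(sids),
                   dimnames = list(taxa, sids))
      ab[cbind(match(raw$taxon_id, taxa), match(raw$sample_id, sids))] <-
        raw$abundance
    }
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(biomass), habitat_id = "all",
                          stringsAsFactors = FALSE)
  } else if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_sheet(samples)
  }
  community_table(biomass, samples, abundance = ab, unit_kind = unit_kind)
}

wide_to_matrix <- function(raw) {
  if (names(raw)[1] != "taxon_id")
    stop("wide format requires 'taxon_id' as the first column")
  if (anyDuplicated(raw$taxon_id))
    stop("duplicated taxon_id in wide file: ",
         raw$taxon_id[duplicated(raw$taxon_id)][1])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- raw$taxon_id
  m
}

#' Write a community table to wide CSV
#'
#' Wide layout (first column `taxon_id`) is the canonical output dialect.
#' Values are written at full double precision so that a write/read
#' round-trip reproduces decimal text of up to 15 significant digits.
#'
#' @param x a `community_table`.
#' @param path output file.
#' @param what `"biomass"` or `"abundance"`.
#' @export
write_community_table <- function(x, path, what = c("biomass", "abundance")) {
  what <- match.arg(what)
  m <- x[[what]]
  if (is.null(m)) stop("table has no ", what, " matrix")
  df <- data.frame(taxon_id = rownames(m),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `habitat_id` and optionally
#'   `station_id`, `stratum`, `replicate`.
#' @return data frame.
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character",
                                 habitat_id = "character"))
}

#' Read a taxon registry
#'
#' The registry drives all indicator computations: one row per taxon with
#' its higher group, trophic/saprobic guild flags and, for indicator
#' species, the saprobic valence s_i on the 0-4.5 scale.
#'
#' @param path CSV with columns `taxon_id, name, higher_group, eutrophic,
#'   oligotrophic, mesosaprobiont, endemic, saprobic_valence` (empty valence
#'   means the taxon is not a saprobity indicator).
#' @return data frame of class `taxon_registry`.
#' @export
read_taxon_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  taxon_registry(reg)
}

#' Construct/validate a taxon registry
#'
#' @param reg data frame; see [read_taxon_registry()] for required columns.
#' @return the validated data frame, class `taxon_registry`.
#' @export
taxon_registry <- function(reg) {
  reg <- as.data.frame(reg, stringsAsFactors = FALSE)
  need <- c("taxon_id", "higher_group", "eutrophic", "oligotrophic",
            "mesosaprobiont", "endemic")
  miss <- setdiff(need, names(reg))
  if (length(miss)) stop("registry missing columns: ", paste(miss, collapse = ", "))
  if (!"name" %in% names(reg)) reg$name <- reg$taxon_id
  if (!"saprobic_valence" %in% names(reg)) reg$saprobic_valence <- NA_real_
  for (fl in c("eutrophic", "oligotrophic", "mesosaprobiont", "endemic"))
    reg[[fl]] <- as.logical(reg[[fl]])
  reg$saprobic_valence <- as.numeric(reg$saprobic_valence)
  if (anyDuplicated(reg$taxon_id))
    stop("duplicated taxon_id in registry")
  if (any(reg$eutrophic & reg$oligotrophic, na.rm = TRUE))
    stop("a taxon cannot be flagged both eutrophic and oligotrophic")
  sv <- reg$saprobic_valence
  if (any(!is.na(sv) & (sv < 0 | sv > 4.5)))
    stop("saprobic_valence must lie in [0, 4.5]")
  reg$is_indicator <- !is.na(sv)
  class(reg) <- c("taxon_registry", "data.frame")
  reg
}

#' Integrate depth strata / replicates into one sample per group
#'
#' Combines samples taken at different depth layers (or replicates) of the
#' same station into one integral sample by taking the arithmetic mean of
#' each taxon's value across the group, mirroring the standard practice of
#' averaging a 0-15 m water column into a single station value before
#' community analysis.
#'
#' @param x a `community_table`.
#' @param by grouping keys, a subset of `c("station_id", "habitat_id")`.
#'   Default groups by station within habitat.
#' @return A new `community_table` with one sample per group; `stratum` and
#'   `replicate` are cleared. Groups whose key contains `NA` are dropped
#'   with a warning.
#' @export
integrate_strata <- function(x, by = c("station_id", "habitat_id")) {
  stopifnot(inherits(x, "community_table"))
  by <- match.arg(by, c("station_id", "habitat_id"), several.ok = TRUE)
  s <- x$samples
  keydf <- s[, by, drop = FALSE]
  incomplete <- !stats::complete.cases(keydf)
  if (any(incomplete)) {
    warning(sum(incomplete), " sample(s) with missing grouping keys excluded")
    s <- s[!incomplete, , drop = FALSE]
    keydf <- keydf[!incomplete, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no samples left to integrate")
  key <- do.call(paste, c(keydf, sep = "/"))
  key <- factor(key, levels = unique(key))
  groups <- split(seq_len(nrow(s)), key)

  bio <- x$biomass[, s$sample_id, drop = FALSE]
  agg <- function(m) {
    out <- vapply(groups, function(idx) rowMeans(m[, idx, drop = FALSE]),
                  numeric(nrow(m)))
    if (nrow(m) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(m), names(groups)))
    out
  }
  new_bio <- agg(bio)
  new_ab <- if (!is.null(x$abundance))
    agg(x$abundance[, s$sample_id, drop = FALSE]) else NULL

  first <- vapply(groups, `[`, integer(1), 1)
  new_samples <- data.frame(
    sample_id = levels(key),
    habitat_id = s$habitat_id[first],
    station_id = if ("station_id" %in% by) s$station_id[first] else NA_character_,
    stratum = NA_character_,
    replicate = NA_integer_,
    stringsAsFactors = FALSE
  )
  colnames(new_bio) <- new_samples$sample_id
  if (!is.null(new_ab)) colnames(new_ab) <- new_samples$sample_id
  community_table(new_bio, new_samples, abundance = new_ab,
                  unit_kind = x$unit_kind)
}

#' Per-habitat total biomass with standard errors
#'
#' Sums biomass over taxa within each sample, then averages the per-sample
#' totals within each habitat. The standard error is the sample standard
#' deviation of the totals divided by sqrt(n); it is reported as `NA` for
#' single-sample habitats.
#'
#' @param x a `community_table`.
#' @param partition a [habitat_partition()]; computed from `x` when omitted.
#' @return data frame with columns `habitat_id, n_samples, mean, se`.
#' @export
total_biomass <- function(x, partition = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (is.null(partition)) partition <- habitat_partition(x)
  totals <- colSums(x$biomass)
  res <- lapply(names(partition), function(h) {
    v <- totals[partition[[h]]]
    n <- length(v)
    if (n == 0) stop("habitat ", h, " has no samples")
    data.frame(habitat_id = h, n_samples = n, mean = mean(v),
               se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-habitat mean biomass per taxon
#'
#' @param x a `community_table`.
#' @param partition a [habitat_partition()]; computed from `x` when omitted.
#' @return taxa x habitats matrix of mean biomass.
#' @export
habitat_means <- function(x, partition = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (is.null(partition)) partition <- habitat_partition(x)
  out <- vapply(partition, function(sids)
    rowMeans(x$biomass[, sids, drop = FALSE]), numeric(nrow(x$biomass)))
  if (nrow(x$biomass) == 1)
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(x$biomass), names(partition)))
  out
}
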