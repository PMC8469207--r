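#' Build a pipeline run configuration
#'
#' @param table,registry,samples input file paths (community table in wide
#'   CSV, taxon registry CSV, sample sheet CSV); alternatively pass a
#'   `scenario` to run on synthetic data.
#' @param abundance optional wide CSV of abundances (same layout as `table`).
#' @param scenario a [synthetic_scenario()]; overrides the file inputs.
#' @param organism_group dominance-threshold group, see
#'   [dominance_threshold()]; or give `threshold` directly.
#' @param threshold explicit dominance threshold (overrides
#'   `organism_group`).
#' @param k number of communities for Ward clustering.
#' @param shannon_base logarithm base for the Shannon index.
#' @param integrate grouping keys for [integrate_strata()], or `NULL` to
#'   skip stratum integration.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest (and used to
#'   re-generate a scenario when `scenario` carries no seed of its own).
#' @return list of class `run_config`.
#' @export
run_config <- function(table = NULL, registry = NULL, samples = NULL,
                       abundance = NULL, scenario = NULL,
                       organism_group = "plankton", threshold = NULL,
                       k = 3, shannon_base = exp(1),
                       integrate = NULL, out_dir = "littora_out",
                       seed = 1L) {
  if (is.null(scenario) && is.null(table))
    stop("run_config needs either input files or a scenario")
  if (is.null(threshold)) threshold <- dominance_threshold(organism_group)
  structure(list(table = table, registry = registry, samples = samples,
                 abundance = abundance, scenario = scenario,
                 organism_group = organism_group, threshold = threshold,
                 k = k, shannon_base = shannon_base, integrate = integrate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full assessment pipeline
#'
#' Orchestrates load (or simulate) -> stratum integration -> dominant
#' filtering -> Ward clustering and PCA ordination -> biotope confinement
#' and key species -> trophic indicators -> higher-taxon composition ->
#' dominance curves (when abundance is available), and writes every result
#' as CSV plus a machine-readable JSON manifest into `config$out_dir`.
#' Re-running with an identical configuration produces byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all intermediate results and
#'   `files` (the paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$scenario)) {
    gen <- with_stage("generate_community", generate_community(config$scenario))
    tab <- gen$table; registry <- gen$registry
  } else {
    tab <- with_stage("read_community_table",
                      read_community_table(config$table, format = "wide",
                                           samples = config$samples,
                                           abundance = config$abundance))
    registry <- with_stage("read_taxon_registry",
                           read_taxon_registry(config$registry))
  }
  if (!is.null(config$integrate))
    tab <- with_stage("integrate_strata",
                      integrate_strata(tab, by = config$integrate))
  partition <- habitat_partition(tab)

  dom <- with_stage("filter_dominants",
                    filter_dominants(tab, threshold = config$threshold,
                                     partition = partition))
  lmat <- log_transform(dom$habitat_means)
  cl <- with_stage("ward_communities", ward_communities(lmat, k = config$k))
  ord <- with_stage("pca_ordination", pca_ordination(lmat))
  conf <- with_stage("confinement_table", confinement_table(tab, partition))
  keys <- with_stage("select_key_species",
                     select_key_species(conf, dom$dominants))
  trophic <- with_stage("build_trophic_report",
                        build_trophic_report(tab, registry, partition,
                                             shannon_base = config$shannon_base))
  higher <- with_stage("summarize_higher_taxa",
                       summarize_higher_taxa(tab, registry, partition))
  curves <- NULL
  if (!is.null(tab$abundance))
    curves <- with_stage("dominance_curves", dominance_curves(tab, partition))

  files <- character(0)
  wr <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }
  wr("confinement.csv",
     function(p) write_confinement_csv(conf, p, key_species = keys))
  wr("indicators.csv",
     function(p) utils::write.csv(trophic, p, row.names = FALSE, quote = FALSE))
  wr("communities.csv", function(p) {
    hab_max <- colnames(dom$habitat_means)[max.col(dom$habitat_means,
                                                   ties.method = "first")]
    utils::write.csv(
      data.frame(taxon_id = dom$taxa, community = unname(cl$assignment[dom$taxa]),
                 habitat_of_max_biomass = hab_max, stringsAsFactors = FALSE),
      p, row.names = FALSE, quote = FALSE)
  })
  wr("ordination_scores.csv", function(p)
    utils::write.csv(data.frame(taxon_id = rownames(ord$scores), ord$scores,
                                stringsAsFactors = FALSE),
                     p, row.names = FALSE, quote = FALSE))
  wr("ordination_loadings.csv", function(p)
    utils::write.csv(data.frame(habitat_id = rownames(ord$loadings),
                                ord$loadings,
                                explained_variance = ord$explained_variance,
                                stringsAsFactors = FALSE),
                     p, row.names = FALSE, quote = FALSE))
  wr("higher_taxa.csv",
     function(p) utils::write.csv(higher, p, row.names = FALSE, quote = FALSE))
  if (!is.null(curves)) {
    wr("dominance_curves.csv", function(p) write_dominance_csv(curves, p))
    files <- c(files, file.path(config$out_dir,
                                "dominance_curves.csv.summary.csv"))
  }

  cfg_plain <- config
  cfg_plain$scenario <- if (!is.null(config$scenario))
    unclass(config$scenario) else NULL
  manifest <- list(
    package = "littora",
    version = as.character(utils::packageVersion("littora")),
    seed = config$seed,
    config = unclass(cfg_plain),
    files = c(basename(files), "manifest.json")
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, manifest_path)

  invisible(list(table = tab, registry = registry, partition = partition,
                 dominants = dom, communities = cl, ordination = ord,
                 confinement = conf, key_species = keys, trophic = trophic,
                 higher_taxa = higher, curves = curves, files = files))
}

#' Higher-taxon composition of total biomass
#'
#' Per habitat, the percentage of total biomass contributed by each higher
#' taxonomic group of the registry; the percentages sum to 100 within each
#' habitat.
#'
#' @param x a `community_table`.
#' @param registry a [taxon_registry()] resolving `higher_group` for every
#'   taxon (unresolved taxa are grouped as `"unknown"`).
#' @param partition a [habitat_partition()]; computed from `x` when omitted.
#' @return data frame with columns `habitat_id, higher_group, biomass,
#'   percent`.
#' @export
summarize_higher_taxa <- function(x, registry, partition = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (is.null(partition)) partition <- habitat_partition(x)
  grp <- registry$higher_group[match(rownames(x$biomass), registry$taxon_id)]
  grp[is.na(grp)] <- "unknown"
  out <- do.call(rbind, lapply(names(partition), function(h) {
    pooled <- rowSums(x$biomass[, partition[[h]], drop = FALSE])
    by_grp <- tapply(pooled, grp, sum)
    tot <- sum(by_grp)
    if (tot <= 0) stop("habitat ", h, " has zero total biomass")
    data.frame(habitat_id = h, higher_group = names(by_grp),
               biomass = as.numeric(by_grp),
               percent = 100 * as.numeric(by_grp) / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bundled taxon-richness listing
#'
#' A small fixture recording the published per-group taxon counts of a
#' three-habitat coastal survey of Lake Baikal (plankton and benthic flora
#' by higher group), used for bookkeeping checks of summary tables.
#'
#' @return data frame with columns `component, subgroup, higher_group,
#'   n_taxa`.
#' @export
richness_listing <- function() {
  path <- system.file("extdata", "richness_listing.csv", package = "littora")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled example taxon registry (synthetic valences)
#'
#' A small registry covering dominant taxa of the Lake Baikal coastal zone
#' (phyto-/zooplankton, benthic macro- and microalgae) with guild flags and
#' saprobic valences. The valences are synthetic placeholders chosen to be
#' plausible for each guild, NOT authoritative values from the published
#' saprobic-organism lists; real analyses must supply a registry built from
#' those lists.
#'
#' @return a [taxon_registry()].
#' @export
example_baikal_registry <- function() {
  read_taxon_registry(system.file("extdata", "baikal_registry_synthetic.csv",
                                  package = "littora"))
}
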