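#' Shannon diversity index
#'
#' H = -sum p_k log(p_k) over the positive entries of `values`, with p_k the
#' share of entry k in the total. Computed on biomass proportions in this
#' package (community surveys report biomass as the more stable quantity).
#'
#' @param values non-negative quantities (typically biomass per taxon);
#'   zeros are skipped.
#' @param base logarithm base; natural log by default.
#' @return H >= 0; at most `log(length(positive values), base)`.
#' @export
shannon_diversity <- function(values, base = exp(1)) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  v <- values[values > 0]
  if (length(v) == 0) stop("all values are zero: diversity undefined")
  p <- v / sum(v)
  -sum(p * log(p, base = base))
}

#' Pantle-Buck saprobity index (Sladecek form)
#'
#' S = sum(s_i * h_i) / sum(h_i): the occurrence-frequency-weighted mean of
#' the saprobic valences of the indicator species present. Invariant under
#' uniform rescaling of the weights and always bounded by the valence
#' extremes of the contributing indicators.
#'
#' @param s saprobic valences s_i of the indicators present.
#' @param h positive occurrence weights h_i (frequency of occurrence in the
#'   habitat's samples, in the default weighting).
#' @return The saprobity index S.
#' @export
saprobity_index <- function(s, h) {
  if (length(s) == 0) stop("no indicator species: saprobity undefined")
  if (length(s) != length(h)) stop("s and h must have equal length")
  if (any(!is.finite(s)) || any(!is.finite(h)) || any(h <= 0))
    stop("valences must be finite and weights strictly positive")
  sum(s * h) / sum(h)
}

#' Saprobic zone classification
#'
#' Maps a saprobity index onto the four saprobic zones of the 0.50-4.50
#' scale: oligosaprobic (0.50-1.50), beta-mesosaprobic (1.51-2.50),
#' alpha-mesosaprobic (2.51-3.50), polysaprobic (3.51-4.50). The published
#' two-decimal interval endpoints leave gaps such as (1.50, 1.51); the
#' boundaries are implemented at the midpoints (1.505, 2.505, 3.505) so that
#' every S in \[0.50, 4.50\] classifies and two-decimal values keep their
#' printed zone. Values outside the scale return `"out_of_range"`.
#'
#' @param S numeric vector of saprobity indices.
#' @return Character vector with values among `oligosaprobic`,
#'   `beta_mesosaprobic`, `alpha_mesosaprobic`, `polysaprobic`,
#'   `out_of_range`.
#' @export
classify_saprobic_zone <- function(S) {
  if (any(!is.finite(S))) stop("S must be finite")
  zone <- rep("out_of_range", length(S))
  zone[S >= 0.50 & S < 1.505] <- "oligosaprobic"
  zone[S >= 1.505 & S < 2.505] <- "beta_mesosaprobic"
  zone[S >= 2.505 & S < 3.505] <- "alpha_mesosaprobic"
  zone[S >= 3.505 & S <= 4.50] <- "polysaprobic"
  zone
}

round_half_up <- function(x) floor(x + 0.5)

#' Format a ratio in small-integer "x:y" style
#'
#' Reporting convention for guild ratios: a raw ratio r >= 1 prints as
#' "round(r):1" and r < 1 as "1:round(1/r)", rounding half away from zero.
#'
#' @param raw the raw ratio; `NA` passes through, `Inf` prints as the
#'   `inf_label`.
#' @param inf_label label used when the denominator count/biomass is zero.
#' @return character scalar.
#' @export
format_ratio <- function(raw, inf_label = "Inf:0") {
  if (is.na(raw)) return(NA_character_)
  if (is.infinite(raw)) return(inf_label)
  if (raw >= 1) paste0(round_half_up(raw), ":1")
  else paste0("1:", round_half_up(1 / raw))
}

#' Eutrophic/oligotrophic species-count ratio (E/O)
#'
#' Counts the eutrophic-flagged and oligotrophic-flagged taxa among those
#' present and returns their ratio. Depends only on presence/absence, not on
#' biomass.
#'
#' @param registry a [taxon_registry()].
#' @param present_taxa taxon ids present (positive biomass) in the habitat.
#' @return list with `n_eutrophic`, `n_oligotrophic`, `raw` (NA when both
#'   counts are zero, Inf when only oligotrophic is zero) and `formatted`.
#' @export
eo_ratio <- function(registry, present_taxa) {
  reg <- registry[registry$taxon_id %in% present_taxa, , drop = FALSE]
  ne <- sum(reg$eutrophic, na.rm = TRUE)
  no <- sum(reg$oligotrophic, na.rm = TRUE)
  raw <- if (ne == 0 && no == 0) NA_real_
         else if (no == 0) Inf
         else ne / no
  list(n_eutrophic = ne, n_oligotrophic = no, raw = raw,
       formatted = format_ratio(raw, inf_label = paste0(ne, ":0")))
}

#' Mesosaprobiont/endemic biomass ratio (M/E)
#'
#' A eutrophication indicator: the pooled biomass of mesosaprobiont-flagged
#' taxa over the pooled biomass of endemic-flagged taxa within a habitat.
#' Values above 1 signal that pollution-tolerant forms outweigh the lake's
#' endemics. Invariant under a global rescaling of all biomass.
#'
#' @param x a `community_table`.
#' @param registry a [taxon_registry()].
#' @param sample_ids the habitat's sample ids.
#' @return list with `biomass_mesosaprobiont`, `biomass_endemic`, `raw`
#'   (Inf with a `"M:0"` sentinel format when endemic biomass is zero and
#'   mesosaprobiont biomass positive; NA when both are zero) and `formatted`.
#' @export
me_ratio <- function(x, registry, sample_ids) {
  sub <- x$biomass[, sample_ids, drop = FALSE]
  tot <- rowSums(sub)
  meso <- registry$taxon_id[registry$mesosaprobiont %in% TRUE]
  ende <- registry$taxon_id[registry$endemic %in% TRUE]
  bm <- sum(tot[intersect(names(tot), meso)])
  be <- sum(tot[intersect(names(tot), ende)])
  raw <- if (bm == 0 && be == 0) NA_real_
         else if (be == 0) Inf
         else bm / be
  list(biomass_mesosaprobiont = bm, biomass_endemic = be, raw = raw,
       formatted = format_ratio(raw, inf_label = "M:0"))
}

#' Per-habitat trophic/saprobity indicator report
#'
#' Assembles the standard indicator block for every habitat: taxon richness,
#' Shannon diversity on pooled biomass, number of indicator species present,
#' saprobity index with saprobic zone, E/O and M/E ratios, and total biomass
#' with standard error. The saprobity weight h_i of each indicator is, by
#' default, the number of the habitat's samples in which it occurs; pass a
#' custom `h_fun` for other weighting schemes (e.g. abundance classes).
#'
#' @param x a `community_table`.
#' @param registry a [taxon_registry()]; taxa absent from the registry
#'   trigger a warning and contribute only to richness/diversity.
#' @param partition a [habitat_partition()]; computed from `x` when omitted.
#' @param shannon_base logarithm base for H (natural log by default).
#' @param h_fun function(occurrence_matrix) -> weights: receives the
#'   indicator x sample logical occurrence matrix for the habitat and
#'   returns one positive weight per indicator. Default: row counts of
#'   occupied samples.
#' @return data frame of class `trophic_report`, one row per habitat, with
#'   columns `habitat_id, n_samples, n_taxa, shannon_H, n_indicator_species,
#'   saprobity_S, saprobic_zone, eo_raw, eo_formatted, me_raw, me_formatted,
#'   biomass_mean, biomass_se`. Habitats without indicator species get `NA`
#'   saprobity fields.
#' @export
build_trophic_report <- function(x, registry, partition = NULL,
                                 shannon_base = exp(1), h_fun = NULL) {
  stopifnot(inherits(x, "community_table"))
  registry <- taxon_registry(registry)
  if (is.null(partition)) partition <- habitat_partition(x)
  unknown <- setdiff(rownames(x$biomass), registry$taxon_id)
  if (length(unknown))
    warning("taxa absent from registry (treated as non-indicator): ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
  if (is.null(h_fun)) h_fun <- function(occ) rowSums(occ)

  tb <- total_biomass(x, partition)
  rows <- lapply(names(partition), function(h) {
    sids <- partition[[h]]
    sub <- x$biomass[, sids, drop = FALSE]
    pooled <- rowSums(sub)
    present <- names(pooled)[pooled > 0]
    n_taxa <- length(present)
    H <- if (n_taxa > 0) shannon_diversity(pooled, base = shannon_base)
         else NA_real_
    ind <- registry[registry$is_indicator &
                      registry$taxon_id %in% present, , drop = FALSE]
    if (nrow(ind) > 0) {
      occ <- sub[ind$taxon_id, , drop = FALSE] > 0
      hgt <- h_fun(occ)
      S <- saprobity_index(ind$saprobic_valence, hgt)
      zone <- classify_saprobic_zone(S)
    } else {
      S <- NA_real_; zone <- NA_character_
    }
    eo <- eo_ratio(registry, present)
    me <- me_ratio(x, registry, sids)
    bt <- tb[tb$habitat_id == h, ]
    data.frame(habitat_id = h, n_samples = length(sids), n_taxa = n_taxa,
               shannon_H = H, n_indicator_species = nrow(ind),
               saprobity_S = S, saprobic_zone = zone,
               eo_raw = eo$raw, eo_formatted = eo$formatted,
               me_raw = me$raw, me_formatted = me$formatted,
               biomass_mean = bt$mean, biomass_se = bt$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trophic_report", "data.frame")
  out
}
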