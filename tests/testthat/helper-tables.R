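# Small deterministic fixtures used across test files.

make_table <- function(biomass, habitats, abundance = NULL, stratum = NULL,
                       station = NULL) {
  biomass <- as.matrix(biomass)
  if (is.null(rownames(biomass)))
    rownames(biomass) <- sprintf("t%02d", seq_len(nrow(biomass)))
  if (is.null(colnames(biomass)))
    colnames(biomass) <- sprintf("s%02d", seq_len(ncol(biomass)))
  samples <- data.frame(sample_id = colnames(biomass),
                        habitat_id = rep_len(habitats, ncol(biomass)),
                        stringsAsFactors = FALSE)
  if (!is.null(stratum)) samples$stratum <- rep_len(stratum, ncol(biomass))
  if (!is.null(station)) samples$station_id <- rep_len(station, ncol(biomass))
  community_table(biomass, samples, abundance = abundance)
}

random_table <- function(n_taxa, n_samples, n_habitats = 2, seed = 42) {
  set.seed(seed)
  m <- matrix(round(stats::rlnorm(n_taxa * n_samples), 6),
              nrow = n_taxa,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  make_table(m, habitats = paste0("H", rep_len(seq_len(n_habitats), n_samples)))
}

simple_registry <- function(taxa, eutrophic = FALSE, oligotrophic = FALSE,
                            mesosaprobiont = FALSE, endemic = FALSE,
                            valence = NA_real_, higher_group = "Chlorophyta") {
  taxon_registry(data.frame(
    taxon_id = taxa, name = taxa,
    higher_group = rep_len(higher_group, length(taxa)),
    eutrophic = rep_len(eutrophic, length(taxa)),
    oligotrophic = rep_len(oligotrophic, length(taxa)),
    mesosaprobiont = rep_len(mesosaprobiont, length(taxa)),
    endemic = rep_len(endemic, length(taxa)),
    saprobic_valence = rep_len(valence, length(taxa)),
    stringsAsFactors = FALSE))
}
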