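test_that("Shannon index matches closed forms and an independent oracle", {
  expect_equal(shannon_diversity(c(1, 0, 0)), 0)
  expect_equal(shannon_diversity(c(1, 1, 1, 1)), log(4))
  expect_error(shannon_diversity(c(0, 0)), "all values are zero")
  expect_error(shannon_diversity(c(-1, 2)), "non-negative")

  set.seed(8)
  v <- rlnorm(30)
  # direct-summation oracle
  p <- v / sum(v)
  expect_equal(shannon_diversity(v), -sum(p * log(p)), tolerance = 1e-12)
  # cross-check against vegan's implementation
  expect_equal(shannon_diversity(v), unname(vegan::diversity(v)),
               tolerance = 1e-12)
  # base option
  expect_equal(shannon_diversity(v, base = 2),
               shannon_diversity(v) / log(2))
})

test_that("Shannon index is permutation invariant and maximal when even", {
  set.seed(9)
  v <- rlnorm(12)
  expect_equal(shannon_diversity(v), shannon_diversity(rev(v)))
  expect_lt(shannon_diversity(v), log(12))
  expect_equal(shannon_diversity(rep(3.7, 12)), log(12))
})

test_that("saprobity index is the weighted mean of valences", {
  expect_equal(saprobity_index(c(2, 2, 2), c(5, 1, 9)), 2)
  expect_equal(saprobity_index(c(1, 3), c(1, 1)), 2)
  expect_equal(saprobity_index(c(1, 3), c(3, 1)), 1.5)   # (1*3 + 3*1) / 4
  expect_error(saprobity_index(numeric(0), numeric(0)), "no indicator")
  expect_error(saprobity_index(c(1, 2), c(1, 0)), "positive")
})

test_that("saprobity index is h-scale invariant and bounded by valences", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    s <- runif(n, 0, 4.5)
    h <- runif(n, 0.1, 9)
    S <- saprobity_index(s, h)
    expect_equal(S, saprobity_index(s, h * runif(1, 0.01, 50)))
    expect_gte(S, min(s))
    expect_lte(S, max(s))
  }
})

test_that("saprobic zones match the published interval statement", {
  expect_identical(classify_saprobic_zone(1.47), "oligosaprobic")
  expect_identical(classify_saprobic_zone(1.60), "beta_mesosaprobic")
  expect_identical(classify_saprobic_zone(2.17), "beta_mesosaprobic")
  expect_identical(classify_saprobic_zone(0.10), "out_of_range")
  expect_identical(classify_saprobic_zone(4.51), "out_of_range")
  # zone index is monotone over the scale
  S <- seq(0.50, 4.50, by = 0.01)
  z <- classify_saprobic_zone(S)
  lvl <- c("oligosaprobic", "beta_mesosaprobic", "alpha_mesosaprobic",
           "polysaprobic")
  idx <- match(z, lvl)
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
})

test_that("E/O ratio counts presences and formats small-integer style", {
  reg <- taxon_registry(data.frame(
    taxon_id = paste0("t", 1:8), name = paste0("t", 1:8),
    higher_group = "Chlorophyta",
    eutrophic = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    oligotrophic = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    mesosaprobiont = FALSE, endemic = FALSE,
    saprobic_valence = NA_real_))
  r <- eo_ratio(reg, paste0("t", 1:8))          # E = 4, O = 2
  expect_equal(r$raw, 2)
  expect_identical(r$formatted, "2:1")

  r2 <- eo_ratio(reg, c("t1", "t2", "t5", "t6"))  # E = 2, O = 2
  expect_identical(r2$formatted, "1:1")

  r3 <- eo_ratio(reg, c("t1", "t2", "t3", "t5"))  # E = 3, O = 1
  expect_equal(r3$raw, 3)
  expect_identical(r3$formatted, "3:1")

  r4 <- eo_ratio(reg, c("t1", "t5", "t6"))        # E = 1, O = 2 -> 1:2
  expect_equal(r4$raw, 0.5)
  expect_identical(r4$formatted, "1:2")

  r5 <- eo_ratio(reg, c("t1", "t7"))              # O = 0
  expect_identical(r5$raw, Inf)
  expect_identical(r5$formatted, "1:0")

  r6 <- eo_ratio(reg, c("t7", "t8"))              # both 0: undefined
  expect_true(is.na(r6$raw))
})

test_that("M/E ratio compares guild biomass and is scale invariant", {
  m <- matrix(c(600, 100, 50), ncol = 1,
              dimnames = list(c("meso", "ende", "other"), "s1"))
  tab <- make_table(m, habitats = "H1")
  reg <- taxon_registry(data.frame(
    taxon_id = c("meso", "ende", "other"), name = c("meso", "ende", "other"),
    higher_group = "Chlorophyta",
    eutrophic = FALSE, oligotrophic = FALSE,
    mesosaprobiont = c(TRUE, FALSE, FALSE),
    endemic = c(FALSE, TRUE, FALSE),
    saprobic_valence = NA_real_))
  r <- me_ratio(tab, reg, "s1")
  expect_equal(r$raw, 6)
  expect_identical(r$formatted, "6:1")

  # RD-style endemic dominance: M = 100, E = 4700 -> 1:47
  m2 <- m; m2["meso", 1] <- 100; m2["ende", 1] <- 4700
  r2 <- me_ratio(make_table(m2, habitats = "H1"), reg, "s1")
  expect_equal(r2$raw, 100 / 4700)
  expect_identical(r2$formatted, "1:47")

  # equal guild biomass
  m3 <- m; m3["meso", 1] <- 100
  expect_identical(me_ratio(make_table(m3, habitats = "H1"), reg, "s1")$formatted,
                   "1:1")

  # zero endemic biomass: infinite ratio with sentinel format
  m4 <- m; m4["ende", 1] <- 0
  r4 <- me_ratio(make_table(m4, habitats = "H1"), reg, "s1")
  expect_identical(r4$raw, Inf)
  expect_identical(r4$formatted, "M:0")

  # global rescaling leaves the ratio unchanged
  r5 <- me_ratio(make_table(m * 1000, habitats = "H1"), reg, "s1")
  expect_equal(r5$raw, r$raw)
})

test_that("trophic report assembles all indicator fields per habitat", {
  m <- matrix(rlnorm(19 * 4, meanlog = 1), nrow = 19,
              dimnames = list(sprintf("t%02d", 1:19), paste0("s", 1:4)))
  tab <- make_table(m, habitats = c("H1", "H1", "H2", "H2"))
  reg <- simple_registry(rownames(m), valence = 1.0, mesosaprobiont = TRUE)
  rep <- build_trophic_report(tab, reg)
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$saprobity_S, c(1.0, 1.0))     # constant valence
  expect_identical(rep$n_taxa, c(19L, 19L))
  expect_true(all(rep$shannon_H <= log(19)))
  expect_identical(rep$saprobic_zone, c("oligosaprobic", "oligosaprobic"))
  # totals agree with total_biomass
  tb <- total_biomass(tab)
  expect_equal(rep$biomass_mean, tb$mean)
  expect_equal(rep$biomass_se, tb$se)
})

test_that("habitats without indicators get missing saprobity fields", {
  tab <- random_table(5, 4, n_habitats = 2, seed = 21)
  reg <- simple_registry(rownames(tab$biomass))   # no valences
  rep <- build_trophic_report(tab, reg)
  expect_true(all(is.na(rep$saprobity_S)))
  expect_true(all(is.na(rep$saprobic_zone)))
  expect_identical(rep$n_indicator_species, c(0L, 0L))
})

test_that("unknown taxa trigger a warning but not failure", {
  tab <- random_table(5, 2, n_habitats = 1, seed = 22)
  reg <- simple_registry(rownames(tab$biomass)[1:3], valence = 2)
  expect_warning(rep <- build_trophic_report(tab, reg), "absent from registry")
  expect_identical(rep$n_taxa, 5L)
})

test_that("report recovers a planted mean valence on synthetic data", {
  sc <- synthetic_scenario(n_taxa = 30, habitats = c(A = 3L, B = 3L),
                           indicator_fraction = 1, valence_mean = 2.2,
                           valence_sd = 0.3, seed = 31)
  gen <- generate_community(sc)
  rep <- build_trophic_report(gen$table, gen$registry)
  expect_true(all(abs(rep$saprobity_S - 2.2) <= 0.15))
})
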