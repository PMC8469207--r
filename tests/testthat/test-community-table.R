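test_that("community_table validates its inputs", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  s <- data.frame(sample_id = c("s1", "s2"), habitat_id = "H1")
  tab <- community_table(m, s)
  expect_s3_class(tab, "community_table")
  expect_identical(dim(tab), c(3L, 2L))

  m_neg <- m; m_neg["b", "s2"] <- -1
  expect_error(community_table(m_neg, s), "b.*s2")
  expect_error(community_table(m, data.frame(sample_id = c("s1", "s1"),
                                             habitat_id = "H1")),
               "duplicated sample_id")
  expect_error(community_table(m, data.frame(sample_id = c("s1", "s2"),
                                             habitat_id = c("H1", ""))),
               "habitat_id")
  expect_error(community_table(m, s, abundance = m[1:2, , drop = FALSE]),
               "same shape")
})

test_that("wide and long readers parse and validate delimited tables", {
  # all-zero wide table: identity case
  wide <- tempfile(fileext = ".csv")
  writeLines(c("taxon_id,s1,s2", "a,0,0", "b,0,0", "c,0,0"), wide)
  tab <- read_community_table(wide, format = "wide")
  expect_identical(dim(tab), c(3L, 2L))
  expect_true(all(tab$biomass == 0))

  # duplicated (taxon, sample) pair in long form names the pair
  long <- tempfile(fileext = ".csv")
  writeLines(c("taxon_id,sample_id,value", "a,s1,3", "a,s1,4"), long)
  expect_error(read_community_table(long, format = "long"), "a / s1")

  # absent long-form cells are zeros
  writeLines(c("taxon_id,sample_id,value", "a,s1,3", "b,s2,4"), long)
  tab <- read_community_table(long, format = "long")
  expect_equal(tab$biomass["a", "s2"], 0)
  expect_equal(tab$biomass["b", "s1"], 0)

  # negative value rejected with the offending cell named
  writeLines(c("taxon_id,s1", "a,-2"), wide)
  expect_error(read_community_table(wide, format = "wide"), "a.*s1")
})

test_that("write/read round-trip reproduces a random table exactly", {
  tab <- random_table(12, 6, n_habitats = 3, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_community_table(tab, path)
  back <- read_community_table(path, format = "wide", samples = tab$samples)
  expect_identical(back$biomass, tab$biomass)
})

test_that("integrate_strata averages depth layers within a station", {
  m <- matrix(c(10, 20, 30, 40,
                 1,  1,  1,  1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  tab <- make_table(m, habitats = "H1", stratum = c("0m", "5m", "10m", "15m"),
                    station = "st1")
  out <- integrate_strata(tab)
  expect_identical(ncol(out$biomass), 1L)
  expect_equal(unname(out$biomass["a", 1]), 25)       # arithmetic mean
  expect_equal(unname(out$biomass["b", 1]), 1)
  expect_true(is.na(out$samples$stratum[1]))

  # single-sample group: values unchanged
  one <- make_table(m[, 1, drop = FALSE], habitats = "H1",
                    stratum = "0m", station = "st1")
  expect_equal(unname(integrate_strata(one)$biomass[, 1]),
               unname(m[, 1]))
})

test_that("integrate_strata is idempotent and linear in column sums", {
  tab <- random_table(8, 9, n_habitats = 3, seed = 11)
  tab$samples$station_id <- rep(c("stA", "stB", "stC"), each = 3)
  tab$samples$habitat_id <- rep(c("H1", "H2", "H3"), each = 3)
  once <- integrate_strata(tab)
  twice <- integrate_strata(once)
  expect_equal(twice$biomass, once$biomass)

  # column sums of the integrated table = group-wise means of column sums
  orig_tot <- colSums(tab$biomass)
  grp <- split(orig_tot, tab$samples$station_id)
  expected <- vapply(grp, mean, numeric(1))
  got <- colSums(once$biomass)
  expect_equal(unname(got[order(names(got))]),
               unname(expected[order(names(expected))]))
})

test_that("total_biomass reports per-habitat mean and standard error", {
  m <- matrix(c(60, 120, 180,
                40,  80, 120), nrow = 2, byrow = TRUE)
  tab <- make_table(m, habitats = "H1")     # totals 100, 200, 300
  tb <- total_biomass(tab)
  expect_equal(tb$mean, 200)
  expect_equal(tb$se, 100 / sqrt(3))        # 57.735...

  one <- make_table(m[, 1, drop = FALSE], habitats = "H1")
  tb1 <- total_biomass(one)
  expect_equal(tb1$mean, 100)
  expect_true(is.na(tb1$se))

  # invariant under taxon reordering
  tab2 <- make_table(m[2:1, ], habitats = "H1")
  expect_equal(total_biomass(tab2)$mean, tb$mean)
  expect_equal(total_biomass(tab2)$se, tb$se)
})

test_that("total_biomass recovers the generator mean within 3 SE at n = 50", {
  sc <- synthetic_scenario(n_taxa = 20, habitats = c(H1 = 50L),
                           preferred = NA, enrichment = 1,
                           noise_sigma_log10 = 0.15, seed = 101)
  gen <- generate_community(sc)
  tb <- total_biomass(gen$table)
  # per-cell noise is 10^N(0, s): mean multiplier exp((s*ln10)^2 / 2)
  s <- 0.15 * log(10)
  truth <- sum(gen$truth$baseline) * exp(s^2 / 2)
  expect_lt(abs(tb$mean - truth), 3 * tb$se)
})

test_that("registry validation enforces guild and valence invariants", {
  expect_error(simple_registry("a", eutrophic = TRUE, oligotrophic = TRUE),
               "both eutrophic and oligotrophic")
  expect_error(simple_registry("a", valence = 5.2), "0, 4.5")
  reg <- simple_registry(c("a", "b"), valence = c(2, NA))
  expect_identical(reg$is_indicator, c(TRUE, FALSE))
})
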