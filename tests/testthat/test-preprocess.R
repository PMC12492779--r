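test_that("identity allometric coefficients leave abundances unchanged", {
  ab <- data.frame(plot_id = "p1", species_id = c("g1", "f1"),
                   abundance = c(0.2, 0.8),
                   abundance_type = "biomass_fraction")
  gm <- c(g1 = "graminoid", f1 = "forb")
  out <- biomass_to_cover(ab, gm, allometric_model())
  expect_equal(out$abundance, c(0.2, 0.8))
  expect_identical(unique(out$abundance_type), "percent_cover")
})

test_that("the biomass-to-cover map is monotone within a group", {
  ab <- data.frame(plot_id = "p1",
                   species_id = c("g1", "g2", "g3"),
                   abundance = c(0.1, 0.3, 0.6),
                   abundance_type = "biomass_fraction")
  gm <- c(g1 = "graminoid", g2 = "graminoid", g3 = "graminoid")
  m <- allometric_model(a = c(graminoid = 0.7, forb = 0),
                        b = c(graminoid = 0.8, forb = 1))
  out <- biomass_to_cover(ab, gm, m)
  expect_true(all(diff(out$abundance) > 0))
})

test_that("generator's inverse map round-trips through biomass_to_cover", {
  # a common slope keeps the per-plot renormalization of biomass
  # fractions group-neutral, so the forward map recovers the covers
  m <- allometric_model(a = c(graminoid = 0.4, forb = -0.2),
                        b = c(graminoid = 0.9, forb = 0.9))
  cfg <- scenario_config(n_areas = 6, pool_size = 100, area_richness = 40,
                         mean_richness = 12, allometric = m, n_synonyms = 0,
                         seed = 11)
  ds <- generate_dataset(cfg)
  gm <- setNames(ds$species$group, ds$species$species_id)
  out <- standardize_fractional_cover(biomass_to_cover(ds$abundance, gm, m))
  # historical plots recover the generator's true relative covers; the
  # resurvey (already cover) plots pass through standardization only
  hist_ids <- ds$plots$plot_id[ds$plots$survey == "historical"]
  cfg_id <- scenario_config(n_areas = 6, pool_size = 100,
                            area_richness = 40, mean_richness = 12,
                            n_synonyms = 0, seed = 11)
  ds_id <- generate_dataset(cfg_id)
  out_id <- standardize_fractional_cover(ds_id$abundance)
  for (pid in hist_ids[1:4]) {
    got <- plot_abundances(out, pid)
    want <- plot_abundances(out_id, pid)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-6)
  }
})

test_that("unmapped species and zero biomass are handled", {
  ab <- data.frame(plot_id = "p1", species_id = c("g1", "x9"),
                   abundance = c(0.5, 0.5),
                   abundance_type = "biomass_fraction")
  expect_error(biomass_to_cover(ab, c(g1 = "graminoid")), "x9")
  ab2 <- data.frame(plot_id = "p1", species_id = c("g1", "g2"),
                    abundance = c(0.5, 0),
                    abundance_type = "biomass_fraction")
  expect_message(
    out <- biomass_to_cover(ab2, c(g1 = "graminoid", g2 = "graminoid")),
    "zero-biomass")
  expect_identical(out$species_id, "g1")
})

test_that("fractional-cover standardization matches the printed formula", {
  ab <- data.frame(plot_id = "p1", species_id = c("a", "b", "c"),
                   abundance = c(2, 3, 5), abundance_type = "percent_cover")
  out <- standardize_fractional_cover(ab)
  expect_equal(out$abundance, c(20, 30, 50))
  # already standardized input is unchanged (idempotence)
  out2 <- standardize_fractional_cover(out)
  expect_equal(out2$abundance, out$abundance)
  # single species takes the full 100
  one <- data.frame(plot_id = "p", species_id = "s", abundance = 7,
                    abundance_type = "percent_cover")
  expect_equal(standardize_fractional_cover(one)$abundance, 100)
  # per-plot sums are exactly 100 on mixed multi-plot input
  t <- toy_tables()
  st <- standardize_fractional_cover(t$abundance)
  sums <- tapply(st$abundance, st$plot_id, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)),
               tolerance = 1e-6)
  zero <- data.frame(plot_id = "p", species_id = "s", abundance = 0,
                     abundance_type = "percent_cover")
  expect_error(standardize_fractional_cover(zero), "zero total")
})

test_that("richness correction adds exactly 0.9 to resurvey plots", {
  t <- toy_tables()
  r <- corrected_richness(t$abundance, t$plots)
  expect_equal(r$richness[r$plot_id == "A_H1"], 3)
  expect_equal(r$richness[r$plot_id == "A_R1"], 2.9)
  # a resurvey twin with the historical species set differs by 0.9 exactly
  ab <- rbind(t$abundance,
              data.frame(plot_id = "A_R9",
                         species_id = c("poa1", "car1", "forb1"),
                         abundance = c(10, 20, 30),
                         abundance_type = "percent_cover"))
  pl <- rbind(t$plots,
              data.frame(plot_id = "A_R9", area_id = "A",
                         survey = "resurvey", elevation_m = 600,
                         area_m2 = 5000))
  r2 <- corrected_richness(ab, pl)
  expect_equal(r2$richness[r2$plot_id == "A_R9"] -
                 r2$richness[r2$plot_id == "A_H1"], 0.9)
  # degenerate empty resurvey plot is 0.9, with a log message
  pl3 <- rbind(pl, data.frame(plot_id = "A_R0", area_id = "A",
                              survey = "resurvey", elevation_m = 600,
                              area_m2 = 5000))
  expect_message(r3 <- corrected_richness(ab, pl3), "A_R0")
  expect_equal(r3$richness[r3$plot_id == "A_R0"], 0.9)
})

test_that("taxon harmonization merges aggregates additively", {
  ab <- data.frame(plot_id = "p1",
                   species_id = c("Festuca_rubra", "Festuca_rubra_aggA"),
                   abundance = c(10, 5), abundance_type = "percent_cover")
  map <- data.frame(observed_name = c("Festuca_rubra", "Festuca_rubra_aggA"),
                    accepted_name = "Festuca_rubra_agg")
  out <- harmonize_taxa(ab, map)
  expect_identical(out$species_id, "Festuca_rubra_agg")
  expect_equal(out$abundance, 15)
  # identity map leaves plots unchanged
  t <- toy_tables()
  idmap <- data.frame(observed_name = t$species$species_id,
                      accepted_name = t$species$species_id)
  out2 <- harmonize_taxa(t$abundance, idmap)
  expect_equal(sort(out2$abundance), sort(t$abundance$abundance))
  # unmapped names pass through with a warning
  expect_warning(harmonize_taxa(ab, idmap), "pass through")
})

test_that("merging reduces richness by merged-minus-aggregate count", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12
    sp <- sprintf("s%02d", 1:n)
    ab <- data.frame(plot_id = "p", species_id = sp,
                     abundance = runif(n, 1, 10),
                     abundance_type = "percent_cover")
    n_agg <- sample(2:4, 1)
    merged <- sample(sp, sample(4:8, 1))
    targets <- sample(sprintf("agg%d", 1:n_agg), length(merged),
                      replace = TRUE)
    map <- data.frame(observed_name = sp, accepted_name = sp)
    map$accepted_name[match(merged, map$observed_name)] <- targets
    out <- harmonize_taxa(ab, map)
    expect_equal(
      length(unique(out$species_id)),
      n - length(merged) + length(unique(targets)))
    expect_equal(sum(out$abundance), sum(ab$abundance))
  }
})
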