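# deterministic balanced toy: every area has the same plot count in both
# surveys, so the mixed-model survey estimate must equal the simple
# difference of survey means
balanced_toy <- function(delta = 2, n_areas = 4, n_plots = 3) {
  set.seed(99)
  base <- rnorm(n_areas, 10, 2)
  rows <- list()
  for (a in seq_len(n_areas)) {
    vals <- base[a] + rnorm(n_plots, 0, 0.5)
    rows[[a]] <- data.frame(
      area_id = paste0("A", a),
      survey = rep(c("historical", "resurvey"), each = n_plots),
      value = c(vals, vals + delta))
  }
  do.call(rbind, rows)
}

test_that("balanced designs recover the shift as a difference of means", {
  d <- balanced_toy(delta = 2.5)
  eff <- suppressWarnings(fit_survey_lmm(d, "toy"))
  diff_means <- mean(d$value[d$survey == "resurvey"]) -
    mean(d$value[d$survey == "historical"])
  expect_equal(eff$estimate, diff_means, tolerance = 1e-8)
  expect_equal(eff$estimate, 2.5, tolerance = 1e-8)
  expect_equal(eff$percent_change,
               100 * diff_means / mean(d$value[d$survey == "historical"]),
               tolerance = 1e-6)
  expect_lt(eff$p, 0.001)
})

test_that("transformations are applied and back-transformed", {
  d <- balanced_toy(delta = 3)
  eff <- suppressWarnings(fit_survey_lmm(d, "toy", "log1p"))
  expect_equal(eff$transformation, "log1p")
  # estimate lives on the log scale, means on the data scale
  expect_equal(eff$mean_historical,
               expm1(mean(log1p(d$value[d$survey == "historical"]))),
               tolerance = 1e-6)
  expect_error(fit_survey_lmm(d[d$survey == "historical", ], "toy"),
               "both surveys")
})

test_that("per-area deltas subtract historical from resurvey means", {
  d <- data.frame(area_id = c("A", "A", "A", "B", "B", "C"),
                  survey = c("historical", "resurvey", "resurvey",
                             "historical", "resurvey", "historical"),
                  value = c(10, 8, 8, 5, 5, 7),
                  elevation_m = c(500, 500, 500, 900, 900, 1200))
  expect_message(out <- delta_by_area(d), "C")
  expect_equal(out$delta[out$area_id == "A"], -2)
  expect_equal(out$delta[out$area_id == "B"], 0)
  expect_false("C" %in% out$area_id)
  expect_equal(out$elevation_m, c(500, 900))
  # random data: groupby-mean oracle
  set.seed(6)
  rd <- data.frame(area_id = rep(paste0("A", 1:6), each = 4),
                   survey = rep(c("historical", "resurvey"), 12),
                   value = rnorm(24, 10))
  out2 <- delta_by_area(rd)
  for (a in unique(rd$area_id)) {
    want <- mean(rd$value[rd$area_id == a & rd$survey == "resurvey"]) -
      mean(rd$value[rd$area_id == a & rd$survey == "historical"])
    expect_equal(out2$delta[out2$area_id == a], want, tolerance = 1e-12)
  }
})

test_that("delta-elevation regression recovers exact lines", {
  el <- seq(400, 2400, length.out = 20)
  deltas <- data.frame(area_id = seq_along(el), elevation_m = el,
                       delta = -8.4 + 0.003 * el)
  fit <- suppressWarnings(fit_delta_elevation(deltas))
  expect_equal(fit$a, -8.4, tolerance = 1e-9)
  expect_equal(fit$b, 0.003, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
  expect_error(fit_delta_elevation(deltas[1:2, ]), "3")
  const <- data.frame(delta = 1:5, elevation_m = rep(1000, 5))
  expect_error(fit_delta_elevation(const), "constant")
})

test_that("crossing elevations are the fitted-line roots", {
  # stress-tolerance contrast: crossing near 1850-1860 m
  expect_equal(crossing_elevation(list(a = -0.13, b = 7.0e-5)),
               1857.143, tolerance = 1e-3)
  expect_lt(abs(crossing_elevation(list(a = -0.13, b = 7.0e-5)) - 1863),
            10)
  # mowing-tolerance contrast: crossing near 1816 m
  expect_lt(abs(crossing_elevation(list(a = 0.8, b = -4.4e-4)) - 1816),
            10)
  expect_equal(crossing_elevation(list(a = 0, b = 0.5)), 0)
  expect_warning(na <- crossing_elevation(list(a = 1, b = 0)), "slope")
  expect_true(is.na(na))
  # agreement with the fitted model's root to machine precision
  el <- seq(400, 2400, length.out = 30)
  set.seed(2)
  deltas <- data.frame(elevation_m = el,
                       delta = -0.5 + 3e-4 * el + rnorm(30, 0, 0.05))
  fit <- fit_delta_elevation(deltas)
  x0 <- crossing_elevation(fit)
  expect_equal(fit$a + fit$b * x0, 0, tolerance = 1e-12)
})

test_that("banding partitions areas with the remainder in the lowest bands", {
  mk <- function(n) data.frame(area_id = sprintf("A%03d", 1:n),
                               elevation_m = seq(300, 2500,
                                                 length.out = n))
  b277 <- assign_bands(mk(277))
  expect_equal(b277$bands$n, c(26, 26, rep(25, 9)))
  expect_equal(assign_bands(mk(275))$bands$n, rep(25, 11))
  # 280 = 11 x 25 + 5: the five lowest bands absorb the remainder
  expect_equal(assign_bands(mk(280))$bands$n,
               c(rep(26, 5), rep(25, 6)))
  # partition: no area lost or duplicated; medians non-decreasing
  expect_setequal(b277$assignment$area_id, mk(277)$area_id)
  expect_false(anyDuplicated(b277$assignment$area_id) > 0)
  expect_true(all(diff(b277$bands$median_elevation) >= 0))
  expect_error(assign_bands(mk(8)), "fewer")
})

test_that("band gamma contrast selects one plot per area and survey", {
  t <- toy_tables()
  # single-area band: gamma is that plot's richness
  g1 <- band_gamma_contrast(t$abundance, t$plots, "A", seed = 1)
  expect_equal(g1$gamma_historical, 3)
  expect_equal(g1$gamma_resurvey, 2)
  # determinism under the seed
  cfg <- scenario_config(n_areas = 8, pool_size = 100, area_richness = 40,
                         mean_richness = 12, n_synonyms = 0, seed = 13)
  ds <- generate_dataset(cfg)
  a_ids <- unique(ds$plots$area_id)
  g2 <- band_gamma_contrast(ds$abundance, ds$plots, a_ids, seed = 5)
  g3 <- band_gamma_contrast(ds$abundance, ds$plots, a_ids, seed = 5)
  expect_identical(g2, g3)
  # oversized band: one area skipped under the seed
  g4 <- band_gamma_contrast(ds$abundance, ds$plots, a_ids, seed = 5,
                            n_areas_use = length(a_ids) - 1)
  expect_equal(length(g4$areas_used), length(a_ids) - 1)
  # area missing a survey is skipped with a warning
  pl <- t$plots[t$plots$plot_id != "B_R1", ]
  expect_warning(g5 <- band_gamma_contrast(t$abundance, pl, c("A", "B"),
                                           seed = 1), "B")
  expect_identical(g5$areas_used, "A")
})

test_that("band beta contrast is near zero for mirrored surveys", {
  # resurvey plots duplicate the historical plots exactly
  set.seed(44)
  n_areas <- 6
  rows <- list(); meta <- list()
  sp <- sprintf("s%02d", 1:30)
  for (a in seq_len(n_areas)) {
    k <- 8
    picks <- sample(sp, k)
    ab <- runif(k, 1, 10)
    for (sv in c("H", "R")) {
      pid <- sprintf("A%d_%s1", a, sv)
      rows[[pid]] <- data.frame(plot_id = pid, species_id = picks,
                                abundance = ab,
                                abundance_type = "percent_cover")
      meta[[pid]] <- data.frame(
        plot_id = pid, area_id = paste0("A", a),
        survey = if (sv == "H") "historical" else "resurvey",
        elevation_m = 500 + 100 * a, area_m2 = 5000)
    }
  }
  ab <- do.call(rbind, rows); pl <- do.call(rbind, meta)
  d <- identity_distance(sp)
  bp <- survey_beta_pairs(ab, pl, d)
  eff <- suppressWarnings(band_beta_contrast(bp))
  expect_equal(eff$estimate, 0, tolerance = 1e-9)
  # too few pairs: skipped
  expect_message(
    expect_null(band_beta_contrast(bp[c(1, 16), ])), "skipped")
})

test_that("permuting survey labels removes the beta contrast", {
  cfg <- scenario_config(n_areas = 10, pool_size = 100,
                         area_richness = 40, mean_richness = 12,
                         homogenization = 0.4, n_synonyms = 0, seed = 23)
  ds <- generate_dataset(cfg)
  ab <- standardize_fractional_cover(ds$abundance)
  d <- identity_distance(sort(unique(ab$species_id)))
  bp <- survey_beta_pairs(ab, ds$plots, d)
  obs <- band_beta_contrast(bp)
  # homogenized resurvey communities have lower taxonomic beta
  expect_lt(obs$estimate, 0)
  set.seed(61)
  null_p <- replicate(20, {
    perm <- bp
    perm$survey <- sample(perm$survey)
    band_beta_contrast(perm)$p
  })
  expect_gte(mean(null_p > 0.05), 0.8)
})

test_that("pseudo-turnover separates temporal change from relocation noise", {
  # all plots identical: difference 0
  ab <- do.call(rbind, lapply(c("H1", "R1", "R2"), function(s)
    data.frame(plot_id = paste0("A_", s), species_id = c("x", "y"),
               abundance = c(30, 70), abundance_type = "percent_cover")))
  pl <- data.frame(plot_id = c("A_H1", "A_R1", "A_R2"), area_id = "A",
                   survey = c("historical", "resurvey", "resurvey"),
                   elevation_m = 500, area_m2 = 1000)
  out <- suppressWarnings(suppressMessages(pseudo_turnover_check(ab, pl)))
  expect_equal(out$per_area$difference, 0)
  # historical disjoint from identical resurvey plots: difference 1
  ab2 <- ab
  ab2$species_id[ab2$plot_id == "A_H1"] <- c("p", "q")
  out2 <- suppressWarnings(suppressMessages(pseudo_turnover_check(ab2, pl)))
  expect_equal(out2$per_area$bc_between_surveys, 1)
  expect_equal(out2$per_area$bc_within_resurvey, 0)
  expect_equal(out2$per_area$difference, 1)
  # areas without enough plots are skipped; none eligible errors
  one <- pl[1:2, ]
  expect_error(suppressMessages(pseudo_turnover_check(ab[1:4, ], one)),
               "resurvey plots")
})
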