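# Synthetic paired resurvey datasets: potential areas along an elevation
# gradient, >=1 historical plot (biomass fractions) and 3-5 modern plots
# (percent cover) per area, drawn from an elevation-structured species
# pool with configurable, elevation-dependent change signals and a stored
# ground truth.

#' Number of resurvey plots for a potential area
#'
#' Plot count scales with the grassland area still available, reflecting
#' that relocation error grows with area: fewer than 10,000 m2 gets 3
#' plots, 10,000--100,000 m2 (inclusive at both edges) gets 4, larger
#' areas get 5. Never fewer than `min_plots`, the number of historical
#' plots sharing the area.
#'
#' @param area_m2 positive area(s) in m2.
#' @param min_plots lower bound supplied by the caller (default 1).
#' @return integer plot count(s) in 3..5 (or `min_plots` if larger).
#' @export
plots_for_area <- function(area_m2, min_plots = 1L) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("area_m2 must be positive", call. = FALSE)
  }
  n <- ifelse(area_m2 < 10000, 3L, ifelse(area_m2 <= 100000, 4L, 5L))
  as.integer(pmax(n, min_plots))
}

#' Minimum distance between resurvey plots
#'
#' The anti-autocorrelation spacing rule: the fourth root of the
#' potential-area size.
#'
#' @param area_m2 positive area(s) in m2.
#' @return distance(s) in m.
#' @export
min_plot_distance <- function(area_m2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("area_m2 must be positive", call. = FALSE)
  }
  area_m2^0.25
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults emulate the study conditions: 277 potential areas over
#' 322--2497 m, an expected richness loss of 38% at the 500 m reference
#' and 11% at 2000 m (interpolated linearly in elevation and clamped
#' outside), a Poaceae abundance tilt, and positive shifts of the
#' nutrient and mowing-tolerance indicator CWMs that reverse sign above a
#' crossing elevation of about 1800 m.
#'
#' @param n_areas number of potential areas (>= 2).
#' @param elevation_range c(min, max) elevation in m.
#' @param pool_size species-pool size.
#' @param decline_at_low,decline_at_high expected richness loss fractions
#'   at the reference elevations `elev_ref` (each in \[0, 1)).
#' @param elev_ref c(low, high) reference elevations in m for the decline
#'   interpolation.
#' @param poaceae_shift multiplicative abundance inflation of Poaceae in
#'   resurvey plots (0 = none).
#' @param indicator_shift named numeric of additive CWM target shifts at
#'   the low reference elevation (names among the seven indicators), or
#'   `NULL` for none.
#' @param indicator_crossing elevation (m) where the indicator effect
#'   crosses zero, or `NULL` for an elevation-independent effect.
#' @param homogenization fraction in \[0, 1): resurvey assembly is
#'   restricted to the widest-niche share `1 - homogenization` of the
#'   pool, lowering between-plot turnover.
#' @param noise_sd lognormal sd of plot-level richness noise.
#' @param mean_richness expected species count of a 0.09 m2 plot.
#' @param area_richness species count of a potential area's community,
#'   from which its plots subsample; controls how similar plots of one
#'   area are (relocation noise).
#' @param p_second_historical probability that an area holds a second
#'   historical plot (the historical records do not report this; it is a
#'   knob).
#' @param overlooked_mean expected number of species missed by visual
#'   cover estimation relative to lab biomass sorting (default 0.9,
#'   matching the richness detection correction).
#' @param n_synonyms number of pool species given observed-name variants
#'   to exercise taxon harmonization.
#' @param allometric [allometric_model()] used to convert the generated
#'   true covers of historical plots into biomass fractions (its forward
#'   application inverts this exactly).
#' @param seed integer; fully determines the dataset.
#' @return validated `scenario_config` object.
#' @export
scenario_config <- function(n_areas = 277L,
                            elevation_range = c(322, 2497),
                            pool_size = 300L,
                            decline_at_low = 0.38,
                            decline_at_high = 0.11,
                            elev_ref = c(500, 2000),
                            poaceae_shift = 0.47,
                            indicator_shift = c(nutrients = 0.5,
                                                mowing_tolerance = 0.5),
                            indicator_crossing = 1800,
                            homogenization = 0,
                            noise_sd = 0.1,
                            mean_richness = 18,
                            area_richness = 45,
                            p_second_historical = 0.5,
                            overlooked_mean = 0.9,
                            n_synonyms = 5L,
                            allometric = allometric_model(),
                            seed = 1L) {
  stopifnot(n_areas >= 2, pool_size >= 20,
            length(elevation_range) == 2L,
            elevation_range[1] < elevation_range[2],
            decline_at_low >= 0, decline_at_low < 1,
            decline_at_high >= 0, decline_at_high < 1,
            elev_ref[1] < elev_ref[2],
            poaceae_shift >= 0,
            homogenization >= 0, homogenization < 1,
            noise_sd >= 0, mean_richness >= 5,
            area_richness >= mean_richness + 5,
            area_richness <= pool_size / 2,
            p_second_historical >= 0, p_second_historical <= 1,
            overlooked_mean >= 0)
  if (!is.null(indicator_shift)) {
    bad <- setdiff(names(indicator_shift), INDICATOR_NAMES)
    if (length(bad) > 0L) {
      stop("unknown indicator(s) in indicator_shift: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    n_areas = as.integer(n_areas), elevation_range = elevation_range,
    pool_size = as.integer(pool_size), decline_at_low = decline_at_low,
    decline_at_high = decline_at_high, elev_ref = elev_ref,
    poaceae_shift = poaceae_shift, indicator_shift = indicator_shift,
    indicator_crossing = indicator_crossing,
    homogenization = homogenization, noise_sd = noise_sd,
    mean_richness = mean_richness, area_richness = as.integer(area_richness),
    p_second_historical = p_second_historical,
    overlooked_mean = overlooked_mean, n_synonyms = as.integer(n_synonyms),
    allometric = allometric, seed = as.integer(seed)),
    class = "scenario_config")
}

# Linear interpolation of the intensification-driven loss fraction
# between the two reference elevations, clamped outside.
intensity_at <- function(elevation, config) {
  f <- (elevation - config$elev_ref[1]) / diff(config$elev_ref)
  f <- clamp(f, 0, 1)
  config$decline_at_low + f * (config$decline_at_high - config$decline_at_low)
}

FORB_FAMILIES <- c("Asteraceae", "Fabaceae", "Rosaceae", "Apiaceae",
                   "Caryophyllaceae", "Ranunculaceae", "Plantaginaceae",
                   "Lamiaceae", "Campanulaceae", "Gentianaceae")

generate_species_pool <- function(config) {
  n <- config$pool_size
  fam_levels <- c("Poaceae", "Cyperaceae", "Juncaceae", FORB_FAMILIES)
  fam_w <- c(0.18, 0.05, 0.03, rep(0.74 / length(FORB_FAMILIES),
                                   length(FORB_FAMILIES)))
  family <- sample(fam_levels, n, replace = TRUE, prob = fam_w)
  graminoid <- family %in% c("Poaceae", "Cyperaceae", "Juncaceae")
  er <- config$elevation_range
  lo <- er[1] - 300; hi <- er[2] + 300
  opt <- stats::runif(n, lo, hi)
  width <- stats::runif(n, 200, 600)
  temperature <- clamp(round(1 + 4 * (hi - opt) / (hi - lo) +
                               stats::rnorm(n, 0, 0.5)), 1, 5)
  nutrients <- sample(1:5, n, replace = TRUE)
  mowing_tolerance <- clamp(round(nutrients + stats::rnorm(n, 0, 1)), 1, 5)
  hemeroby <- clamp(round(nutrients + stats::rnorm(n, 0, 1)), 1, 5)
  elev01 <- (opt - lo) / (hi - lo)
  score_c <- nutrients
  score_s <- (6 - nutrients) + 3 * elev01
  score_r <- as.numeric(mowing_tolerance)
  csr <- vapply(seq_len(n), function(i) {
    paste(sample(c("c", "s", "r"), 3, replace = TRUE,
                 prob = c(score_c[i], score_s[i], score_r[i])),
          collapse = "")
  }, character(1))
  s_frac <- csr_decompose(csr)$s
  sens <- clamp(0.5 * s_frac + 0.5 * (5 - nutrients) / 4 +
                  stats::rnorm(n, 0, 0.1), 0, 1)
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    family = family,
    group = ifelse(graminoid, "graminoid", "forb"),
    taxon_group = ifelse(family == "Poaceae", "Poaceae",
                         ifelse(family %in% c("Cyperaceae", "Juncaceae"),
                                "CypJunc", "Forb")),
    elevation_optimum = opt, niche_width = width,
    sla = stats::rlnorm(n, log(20), 0.4),
    height = stats::rlnorm(n, log(0.3), 0.6),
    seed_mass = stats::rlnorm(n, log(1), 1),
    temperature = temperature,
    light = sample(1:5, n, replace = TRUE),
    moisture = sample(1:5, n, replace = TRUE),
    reaction = sample(1:5, n, replace = TRUE),
    nutrients = nutrients, mowing_tolerance = mowing_tolerance,
    hemeroby = hemeroby, csr = csr,
    intensification_sensitivity = sens,
    stringsAsFactors = FALSE)
}

# Exponentially tilt an abundance vector so the weighted mean of `v`
# moves by `shift` (clamped to the attainable range); one-dimensional
# root finding in the tilt parameter.
tilt_to_shift <- function(p, v, shift) {
  if (shift == 0 || length(unique(v)) == 1L) return(p)
  p0 <- p / sum(p)
  target <- clamp(sum(p0 * v) + shift,
                  min(v) + 1e-6, max(v) - 1e-6)
  f <- function(theta) {
    w <- p0 * exp(theta * (v - mean(v)))
    sum(w * v) / sum(w) - target
  }
  theta <- tryCatch(stats::uniroot(f, c(-20, 20))$root,
                    error = function(e) NA_real_)
  if (is.na(theta)) return(p)
  p * exp(theta * (v - mean(v)))
}

# Family-structured random ultrametric tree: confamilials cluster.
simulate_pool_tree <- function(pool) {
  n <- nrow(pool)
  d <- matrix(stats::runif(n * n, 2, 3), n, n)
  same <- outer(pool$family, pool$family, `==`)
  d[same] <- stats::runif(sum(same), 0.2, 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(pool$species_id, pool$species_id)
  ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
}

# One plot from an area community: weighted subsample of `n_target`
# species, with plot-level lognormal abundance noise on top of the area
# abundance profile.
subsample_plot <- function(area_ab, n_target, plot_noise_sd = 0.6) {
  n_target <- max(3L, min(as.integer(n_target), length(area_ab)))
  pick <- sample(length(area_ab), n_target, prob = area_ab)
  ab <- area_ab[pick] * stats::rlnorm(n_target, 0, plot_noise_sd)
  ab / sum(ab)
}

#' Generate a paired historical/resurvey dataset
#'
#' Builds the full synthetic study: a species pool with
#' elevation-structured occurrence, potential areas spread over the
#' elevation range, >=1 historical plot per area with biomass-fraction
#' abundances, `plots_for_area()` resurvey plots with percent-cover
#' abundances subject to the configured change signals, a
#' family-constrained random phylogeny, a synonym map, and a truth record
#' holding every realized expectation. Identical configurations (same
#' seed) give identical output.
#'
#' @param config a [scenario_config()].
#' @return object of class `resurvey_dataset`: list with `abundance`,
#'   `plots`, `species`, `tree`, `synonyms`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("config must be a scenario_config", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  pool <- generate_species_pool(config)
  if (config$pool_size < 4 * config$mean_richness) {
    stop("species pool too small to populate plots at the requested ",
         "richness", call. = FALSE)
  }
  tree <- simulate_pool_tree(pool)

  er <- config$elevation_range
  areas <- data.frame(
    area_id = sprintf("A%03d", seq_len(config$n_areas)),
    elevation_m = seq(er[1], er[2], length.out = config$n_areas),
    area_m2 = clamp(stats::rlnorm(config$n_areas, log(2e4), 1.3),
                    500, 5e6),
    stringsAsFactors = FALSE)

  mean_sens <- mean(pool$intensification_sensitivity)
  n_keep <- ceiling((1 - config$homogenization) * nrow(pool))
  wide_ok <- rank(-pool$niche_width, ties.method = "first") <= n_keep
  sens <- pool$intensification_sensitivity

  ab_rows <- list(); plot_rows <- list(); truth_rows <- list()
  for (a in seq_len(config$n_areas)) {
    e <- areas$elevation_m[a]
    w_occ <- exp(-(e - pool$elevation_optimum)^2 /
                   (2 * pool$niche_width^2)) + 1e-9
    I_e <- intensity_at(e, config)
    n_hist <- 1L + stats::rbinom(1L, 1L, config$p_second_historical)
    n_res <- plots_for_area(areas$area_m2[a], min_plots = n_hist)
    R_a <- max(6, round(stats::rnorm(1, config$mean_richness, 2)))

    shift_scale <- if (is.null(config$indicator_crossing)) 1 else
      (config$indicator_crossing - e) /
      (config$indicator_crossing - config$elev_ref[1])

    # the area's historical community: weighted pool sample with a
    # lognormal abundance profile shared by its plots
    comm_idx <- sample(nrow(pool), config$area_richness, prob = w_occ)
    comm_ab <- stats::setNames(stats::rlnorm(length(comm_idx), 0, 1),
                               pool$species_id[comm_idx])

    for (j in seq_len(n_hist)) {
      pid <- sprintf("%s_H%d", areas$area_id[a], j)
      n_t <- round(R_a * exp(stats::rnorm(1, 0, config$noise_sd)))
      cover <- subsample_plot(comm_ab, n_t)
      grp <- pool$group[match(names(cover), pool$species_id)]
      biomass <- cover_to_biomass_fraction(100 * cover, grp,
                                           config$allometric)
      ab_rows[[pid]] <- data.frame(
        plot_id = pid, species_id = names(biomass),
        abundance = as.numeric(biomass),
        abundance_type = "biomass_fraction", stringsAsFactors = FALSE)
      plot_rows[[pid]] <- data.frame(
        plot_id = pid, area_id = areas$area_id[a], survey = "historical",
        elevation_m = e, area_m2 = areas$area_m2[a],
        stringsAsFactors = FALSE)
    }

    # the modern community: intensification removes sensitive species at
    # the elevation-dependent rate, replaced from the (possibly
    # homogenized) pool; Poaceae inflation and indicator tilts follow
    keep_p <- clamp(1 - I_e * sens[comm_idx] / mean_sens, 0.02, 1)
    keep <- stats::runif(length(comm_idx)) < keep_p
    res_ab <- comm_ab[keep]
    # top up so the modern community holds ~ (1 - I_e) x area_richness
    # species: removal beyond the configured loss is compensated by
    # colonizers drawn from the (possibly homogenized) pool
    n_refill <- round((1 - I_e) * length(comm_idx)) - sum(keep)
    if (n_refill > 0L) {
      w_new <- w_occ * pmax(1 - I_e * sens / mean_sens, 0)
      w_new[!wide_ok] <- 0
      w_new[comm_idx[keep]] <- 0
      w_new <- w_new + 1e-12
      new_idx <- sample(nrow(pool), n_refill, prob = w_new)
      res_ab <- c(res_ab, stats::setNames(
        stats::rlnorm(length(new_idx), 0, 1),
        pool$species_id[new_idx]))
    }
    if (config$homogenization > 0) {
      ok <- wide_ok[match(names(res_ab), pool$species_id)]
      if (any(ok)) res_ab <- res_ab[ok]
    }
    if (config$poaceae_shift > 0) {
      poa <- pool$taxon_group[match(names(res_ab),
                                    pool$species_id)] == "Poaceae"
      res_ab[poa] <- res_ab[poa] * (1 + config$poaceae_shift)
    }
    if (!is.null(config$indicator_shift) && shift_scale != 0) {
      for (ind in names(config$indicator_shift)) {
        v <- pool[[ind]][match(names(res_ab), pool$species_id)]
        res_ab <- tilt_to_shift(res_ab, v,
                                config$indicator_shift[[ind]] * shift_scale)
      }
    }

    for (j in seq_len(n_res)) {
      pid <- sprintf("%s_R%d", areas$area_id[a], j)
      n_t <- round(R_a * (1 - I_e) * exp(stats::rnorm(1, 0,
                                                      config$noise_sd)))
      cover <- subsample_plot(res_ab, n_t)
      overlooked <- min(stats::rpois(1, config$overlooked_mean),
                        length(cover) - 1L)
      if (overlooked > 0L) {
        cover <- cover[order(cover, decreasing = TRUE)]
        cover <- cover[seq_len(length(cover) - overlooked)]
      }
      total <- stats::runif(1, 70, 110)
      pc <- total * cover / sum(cover)
      ab_rows[[pid]] <- data.frame(
        plot_id = pid, species_id = names(pc), abundance = as.numeric(pc),
        abundance_type = "percent_cover", stringsAsFactors = FALSE)
      plot_rows[[pid]] <- data.frame(
        plot_id = pid, area_id = areas$area_id[a], survey = "resurvey",
        elevation_m = e, area_m2 = areas$area_m2[a],
        stringsAsFactors = FALSE)
    }
    truth_rows[[a]] <- data.frame(
      area_id = areas$area_id[a], elevation_m = e,
      expected_loss_fraction = I_e, n_historical = n_hist,
      n_resurvey = n_res, stringsAsFactors = FALSE)
  }

  abundance <- do.call(rbind, c(ab_rows, list(make.row.names = FALSE)))
  plots <- do.call(rbind, c(plot_rows, list(make.row.names = FALSE)))

  # observed-name variants for a few species in historical records, to
  # exercise taxon harmonization downstream
  synonyms <- data.frame(observed_name = pool$species_id,
                         accepted_name = pool$species_id,
                         stringsAsFactors = FALSE)
  if (config$n_synonyms > 0L) {
    syn_sp <- sample(pool$species_id, min(config$n_synonyms, nrow(pool)))
    variants <- paste0(syn_sp, "_obs")
    synonyms <- rbind(synonyms,
                      data.frame(observed_name = variants,
                                 accepted_name = syn_sp,
                                 stringsAsFactors = FALSE))
    hist_ids <- plots$plot_id[plots$survey == "historical"]
    cand <- which(abundance$species_id %in% syn_sp &
                    abundance$plot_id %in% hist_ids)
    flip <- cand[stats::runif(length(cand)) < 0.5]
    abundance$species_id[flip] <-
      paste0(abundance$species_id[flip], "_obs")
  }

  truth <- list(
    areas = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
    decline_at_low = config$decline_at_low,
    decline_at_high = config$decline_at_high,
    elev_ref = config$elev_ref,
    poaceae_shift = config$poaceae_shift,
    indicator_shift = config$indicator_shift,
    indicator_crossing = config$indicator_crossing,
    mean_richness = config$mean_richness,
    seed = config$seed)

  structure(list(abundance = abundance, plots = plots, species = pool,
                 tree = tree, synonyms = synonyms, truth = truth,
                 config = config),
            class = "resurvey_dataset")
}

#' @export
print.resurvey_dataset <- function(x, ...) {
  cat("Synthetic resurvey dataset\n")
  cat("  areas:      ", x$config$n_areas, " (",
      paste(round(x$config$elevation_range), collapse = "-"), " m)\n",
      sep = "")
  cat("  plots:      ", nrow(x$plots), " (",
      sum(x$plots$survey == "historical"), " historical, ",
      sum(x$plots$survey == "resurvey"), " resurvey)\n", sep = "")
  cat("  pool size:  ", nrow(x$species), "\n", sep = "")
  cat("  seed:       ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `abundance.csv`, `plots.csv`, `species.csv`, `synonyms.csv`,
#' `tree.nwk` and `truth.json` into `dir`.
#'
#' @param dataset a `resurvey_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "resurvey_dataset")) {
    stop("not a resurvey_dataset", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$abundance, file.path(dir, "abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$synonyms, file.path(dir, "synonyms.csv"),
                   row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding the CSV/Newick/JSON files.
#' @return list with `abundance`, `plots`, `species`, `synonyms`, `tree`,
#'   `truth`.
#' @export
read_dataset <- function(dir) {
  out <- list(
    abundance = utils::read.csv(file.path(dir, "abundance.csv")),
    plots = utils::read.csv(file.path(dir, "plots.csv")),
    species = utils::read.csv(file.path(dir, "species.csv")),
    synonyms = utils::read.csv(file.path(dir, "synonyms.csv")),
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE))
  check_abundance_table(out$abundance)
  check_plot_table(out$plots)
  out
}
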