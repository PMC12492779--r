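# End-to-end orchestration: preprocess -> distances -> diversity ->
# community metrics -> inference, with tidy CSV outputs and a run
# manifest.

#' Run the full resurvey analysis pipeline
#'
#' Executes every stage on either a synthetic scenario or a dataset
#' directory written by [write_dataset()]: taxon harmonization, the
#' biomass-to-cover transformation, fractional-cover standardization,
#' detection-corrected richness, the three dissimilarity matrices, Rao
#' alpha diversity per facet, community metrics, survey-contrast mixed
#' models, per-area delta regressions on elevation, elevational banding
#' with beta and gamma contrasts, and the pseudo-turnover check. All
#' randomness (gamma plot selection) derives from `seed`.
#'
#' @param config a [scenario_config()] for synthetic mode; ignored when
#'   `input_dir` is given.
#' @param input_dir directory of CSV/Newick inputs (see
#'   [read_dataset()]); mutually exclusive with synthetic mode.
#' @param outdir optional output directory for the tidy CSVs and the
#'   manifest JSON.
#' @param seed seed for selection randomness (default: the scenario
#'   seed, or 1 for file input).
#' @param n_bands elevational bands for the beta/gamma contrasts.
#' @param do_bands,do_pseudo_turnover toggles for the band-level and
#'   pseudo-turnover stages.
#' @param transformations named list metric -> transformation (see
#'   [fit_survey_lmm()]); unlisted metrics use `"identity"`.
#' @return invisible list with all stage results (`dataset`, `abundance`
#'   (standardized), `richness`, `alpha`, `metrics`, `survey_effects`,
#'   `delta_fits`, `band_beta`, `band_gamma`, `pseudo_turnover`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = scenario_config(), input_dir = NULL,
                         outdir = NULL, seed = NULL, n_bands = 11L,
                         do_bands = TRUE, do_pseudo_turnover = TRUE,
                         transformations = list()) {
  if (is.null(input_dir)) {
    ds <- generate_dataset(config)
    seed <- seed %||% config$seed
    allom <- config$allometric
  } else {
    ds <- read_dataset(input_dir)
    seed <- seed %||% 1L
    allom <- allometric_model()
  }
  species <- ds$species
  plots <- ds$plots

  ab <- harmonize_taxa(ds$abundance, ds$synonyms)
  group_map <- stats::setNames(species$group, species$species_id)
  ab <- biomass_to_cover(ab, group_map, allom)
  ab <- standardize_fractional_cover(ab)

  richness <- corrected_richness(ab, plots)

  pool <- sort(unique(ab$species_id))
  d_tax <- identity_distance(pool)
  d_fun <- rescale_unit(gower_trait_distance(
    species[species$species_id %in% pool, ]))
  d_phy <- rescale_unit(subset_distance(cophenetic_distance(ds$tree), pool))
  dists <- list(taxonomic = d_tax, functional = d_fun, phylogenetic = d_phy)

  alpha <- do.call(rbind, lapply(names(dists), function(fc) {
    out <- plot_alpha_diversity(ab, dists[[fc]])
    out$facet <- fc
    out
  }))

  metrics <- plot_metrics(ab, species)

  meta_cols <- plots[, c("plot_id", "survey", "area_id", "elevation_m")]
  value_tables <- list(
    richness = data.frame(plot_id = richness$plot_id,
                          value = richness$richness))
  for (fc in names(dists)) {
    sub <- alpha[alpha$facet == fc, ]
    value_tables[[paste0("rao_", fc)]] <-
      data.frame(plot_id = sub$plot_id, value = sub$rao_q)
  }
  for (mt in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == mt, ]
    value_tables[[mt]] <- data.frame(plot_id = sub$plot_id,
                                     value = sub$value)
  }

  survey_effects <- list(); deltas <- list(); delta_fits <- list()
  for (mt in names(value_tables)) {
    d <- merge(value_tables[[mt]], meta_cols, by = "plot_id")
    d <- d[!is.na(d$value), , drop = FALSE]
    tr <- transformations[[mt]] %||% "identity"
    survey_effects[[mt]] <- withCallingHandlers(
      fit_survey_lmm(d, metric = mt, transformation = tr),
      warning = function(w) invokeRestart("muffleWarning"))
    dl <- suppressMessages(delta_by_area(d))
    deltas[[mt]] <- cbind(metric = mt, dl)
    fit <- fit_delta_elevation(dl)
    delta_fits[[mt]] <- data.frame(
      metric = mt, intercept = fit$a, slope = fit$b,
      r2_adj = fit$r2_adj, p_slope = fit$p_slope, n = fit$n,
      crossing_elevation_m = if (fit$b != 0) -fit$a / fit$b else NA_real_)
  }

  band_beta <- NULL; band_gamma <- NULL
  if (do_bands && length(unique(plots$area_id)) >= n_bands) {
    areas <- plots[!duplicated(plots$area_id),
                   c("area_id", "elevation_m")]
    ba <- assign_bands(areas, n_bands = n_bands)
    n_gamma_areas <- min(ba$bands$n)
    bb_rows <- list(); bg_rows <- list()
    for (b in ba$bands$band) {
      a_ids <- ba$assignment$area_id[ba$assignment$band == b]
      p_ids <- plots$plot_id[plots$area_id %in% a_ids]
      for (fc in names(dists)) {
        bp <- tryCatch(
          survey_beta_pairs(ab, plots, dists[[fc]], plot_ids = p_ids),
          error = function(e) NULL)
        eff <- if (is.null(bp)) NULL else
          suppressMessages(band_beta_contrast(bp))
        if (!is.null(eff)) {
          bb_rows[[paste(b, fc)]] <- data.frame(
            band = b, facet = fc,
            median_elevation = ba$bands$median_elevation[b],
            estimate = eff$estimate, se = eff$se, p = eff$p,
            percent_change = eff$percent_change)
        }
      }
      bg <- suppressWarnings(band_gamma_contrast(
        ab, plots, a_ids, seed = seed + b,
        n_areas_use = n_gamma_areas))
      bg_rows[[b]] <- data.frame(
        band = b, median_elevation = ba$bands$median_elevation[b],
        gamma_historical = bg$gamma_historical,
        gamma_resurvey = bg$gamma_resurvey,
        n_areas = length(bg$areas_used))
    }
    band_beta <- do.call(rbind, c(bb_rows, list(make.row.names = FALSE)))
    band_gamma <- do.call(rbind, c(bg_rows, list(make.row.names = FALSE)))
  }

  pseudo <- NULL
  if (do_pseudo_turnover) {
    pseudo <- suppressMessages(suppressWarnings(
      pseudo_turnover_check(ab, plots)))
  }

  manifest <- list(
    seed = seed,
    n_areas = length(unique(plots$area_id)),
    n_plots = nrow(plots),
    n_species = length(pool),
    synthetic = is.null(input_dir),
    package_version = as.character(utils::packageVersion("resurveydiv")),
    r_version = as.character(getRversion()))

  result <- list(
    dataset = ds, abundance = ab, richness = richness, alpha = alpha,
    metrics = metrics,
    survey_effects = survey_effects,
    area_deltas = do.call(rbind, c(deltas, list(make.row.names = FALSE))),
    delta_fits = do.call(rbind, c(delta_fits,
                                  list(make.row.names = FALSE))),
    band_beta = band_beta, band_gamma = band_gamma,
    pseudo_turnover = pseudo, manifest = manifest)

  if (!is.null(outdir)) write_results(result, outdir)
  invisible(result)
}

#' Elevation-dependent richness loss fractions
#'
#' Estimates the fractional richness loss at given elevations from
#' per-plot richness values: the per-area resurvey-minus-historical
#' deltas are regressed on elevation, the historical area means likewise,
#' and the loss fraction at elevation e is
#' `-delta_hat(e) / historical_hat(e)`.
#'
#' @param data data frame with `plot_id`, `value` (richness), `survey`,
#'   `area_id`, `elevation_m`.
#' @param at elevations (m) at which to evaluate the loss.
#' @return list: `loss_fraction` (named by elevation), `delta_fit` (the
#'   [fit_delta_elevation()] object), `historical_fit` (lm of historical
#'   area means on elevation).
#' @export
richness_loss_at <- function(data, at = c(500, 2000)) {
  deltas <- suppressMessages(delta_by_area(data))
  fit <- fit_delta_elevation(deltas)
  hist_means <- stats::aggregate(
    value ~ area_id + elevation_m,
    data = data[data$survey == "historical", ], FUN = mean)
  hfit <- stats::lm(value ~ elevation_m, data = hist_means)
  pred_h <- stats::predict(hfit, data.frame(elevation_m = at))
  loss <- -(fit$a + fit$b * at) / pred_h
  list(loss_fraction = stats::setNames(loss, at), delta_fit = fit,
       historical_fit = hfit)
}

#' Survey effects as a tidy table
#'
#' @param effects list of `survey_effect` objects (e.g.
#'   `run_pipeline(...)$survey_effects`).
#' @return data frame, one row per metric.
#' @export
survey_effects_table <- function(effects) {
  do.call(rbind, c(lapply(effects, function(e) data.frame(
    metric = e$metric, transformation = e$transformation,
    estimate = e$estimate, se = e$se, df = e$df, p = e$p,
    mean_historical = e$mean_historical,
    mean_resurvey = e$mean_resurvey,
    percent_change = e$percent_change,
    fallback_random_effect = e$fallback_random_effect, n = e$n)),
    list(make.row.names = FALSE)))
}

write_results <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
  w(survey_effects_table(result$survey_effects), "survey_effects.csv")
  w(result$area_deltas, "area_deltas.csv")
  w(result$delta_fits, "delta_fits.csv")
  w(result$band_beta, "band_contrasts.csv")
  w(result$band_gamma, "band_gamma.csv")
  if (!is.null(result$pseudo_turnover)) {
    w(result$pseudo_turnover$per_area, "pseudo_turnover.csv")
  }
  w(result$alpha, "alpha_diversity.csv")
  w(result$metrics, "plot_metrics.csv")
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
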