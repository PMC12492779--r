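# Statistical layer: survey-contrast mixed models, per-area deltas and
# their elevation dependence, elevational banding with beta/gamma
# contrasts, zero-crossing elevations, and the pseudo-turnover check.

TRANSFORMS <- list(
  identity = list(f = identity, inv = identity),
  log1p    = list(f = log1p, inv = expm1),
  sqrt     = list(f = sqrt, inv = function(x) x^2),
  logit    = list(f = function(x) stats::qlogis(clamp(x, 1e-6, 1 - 1e-6)),
                  inv = stats::plogis)
)

#' Survey contrast via a linear mixed model
#'
#' Fits `value ~ survey + (1 | area_id) + (1 | area_id:survey)` with the
#' historical survey as reference: the area intercept carries the shared
#' site baseline (historical and resurvey plots of one potential area
#' are paired), and the area-by-survey interaction intercept treats the
#' plots of one survey within one area as pseudo-replicates of a shared
#' level. P-values use the Satterthwaite degree-of-freedom
#' approximation. If the fit is singular (typically a zero interaction
#' variance) the model falls back to an area-level random intercept
#' (recorded in the result, with a warning).
#'
#' @param data data frame with columns `value`, `survey`, `area_id`.
#' @param metric label carried into the result.
#' @param transformation one of `"identity"`, `"log1p"`, `"sqrt"`,
#'   `"logit"`, applied to `value` before fitting; marginal means are
#'   back-transformed for the percent change.
#' @return object of class `survey_effect`: estimate (resurvey minus
#'   historical on the analysis scale), `se`, `df`, `p`, back-transformed
#'   marginal means and `percent_change`.
#' @export
fit_survey_lmm <- function(data, metric = "value",
                           transformation = "identity") {
  need <- c("value", "survey", "area_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr <- TRANSFORMS[[match.arg(transformation, names(TRANSFORMS))]]
  d <- data.frame(
    y = tr$f(data$value),
    survey = factor(data$survey, levels = SURVEY_LEVELS),
    area_id = factor(data$area_id))
  both <- tapply(d$survey, d$area_id,
                 function(s) length(unique(s)) == 2L)
  if (sum(both, na.rm = TRUE) < 2L) {
    stop("need >= 2 areas with both surveys", call. = FALSE)
  }

  fit <- suppressMessages(
    lmerTest::lmer(y ~ survey + (1 | area_id) + (1 | area_id:survey),
                   data = d, REML = TRUE))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular area x survey fit; falling back to area-level ",
            "random intercept", call. = FALSE)
    fit <- suppressMessages(
      lmerTest::lmer(y ~ survey + (1 | area_id), data = d, REML = TRUE))
    fallback <- TRUE
  }
  co <- stats::coef(summary(fit))
  est <- co["surveyresurvey", "Estimate"]
  hist_mean <- co["(Intercept)", "Estimate"]
  bt_hist <- tr$inv(hist_mean)
  bt_res <- tr$inv(hist_mean + est)
  structure(list(
    metric = metric, transformation = transformation,
    estimate = est, se = co["surveyresurvey", "Std. Error"],
    df = co["surveyresurvey", "df"], p = co["surveyresurvey", "Pr(>|t|)"],
    mean_historical = bt_hist, mean_resurvey = bt_res,
    percent_change = if (bt_hist != 0)
      100 * (bt_res - bt_hist) / bt_hist else NA_real_,
    fallback_random_effect = fallback, n = nrow(d)),
    class = "survey_effect")
}

#' @export
print.survey_effect <- function(x, ...) {
  cat(sprintf(
    "Survey effect [%s]: %.4g (se %.3g, df %.1f, p %.3g)\n",
    x$metric, x$estimate, x$se, x$df, x$p))
  cat(sprintf("  historical %.4g -> resurvey %.4g (%+.1f%%)%s\n",
              x$mean_historical, x$mean_resurvey, x$percent_change,
              if (x$fallback_random_effect)
                " [area-level random intercept]" else ""))
  invisible(x)
}

#' Per-area resurvey-minus-historical differences
#'
#' For every potential area with plots in both surveys, the mean of the
#' resurvey plot values minus the mean of the historical plot values.
#' One-survey areas are skipped with a message.
#'
#' @param data data frame with `value`, `survey`, `area_id` and
#'   optionally `elevation_m`.
#' @return data frame `area_id`, `delta` (and `elevation_m` if supplied).
#' @export
delta_by_area <- function(data) {
  need <- c("value", "survey", "area_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  means <- stats::aggregate(value ~ area_id + survey, data = data,
                            FUN = mean)
  wide <- stats::reshape(means, idvar = "area_id", timevar = "survey",
                         direction = "wide")
  skip <- is.na(wide$value.historical) | is.na(wide$value.resurvey)
  if (any(skip)) {
    message("skipping area(s) with one survey only: ",
            paste(wide$area_id[skip], collapse = ", "))
  }
  out <- data.frame(area_id = wide$area_id[!skip],
                    delta = wide$value.resurvey[!skip] -
                      wide$value.historical[!skip],
                    stringsAsFactors = FALSE)
  if ("elevation_m" %in% names(data)) {
    ev <- data[!duplicated(data$area_id), c("area_id", "elevation_m")]
    out$elevation_m <- ev$elevation_m[match(out$area_id, ev$area_id)]
  }
  out[order(out$area_id), , drop = FALSE]
}

#' Linear regression of per-area deltas on elevation
#'
#' Ordinary least squares of `delta` on `elevation_m`.
#'
#' @param deltas data frame with `delta` and `elevation_m` (n >= 3, non
#'   constant elevation).
#' @return object of class `linear_fit`: `a` (intercept), `b` (slope per
#'   m), `r2_adj`, `p_slope`, `n`.
#' @export
fit_delta_elevation <- function(deltas) {
  if (!all(c("delta", "elevation_m") %in% names(deltas))) {
    stop("deltas needs columns delta, elevation_m", call. = FALSE)
  }
  if (nrow(deltas) < 3L) stop("need at least 3 areas", call. = FALSE)
  if (stats::var(deltas$elevation_m) == 0) {
    stop("elevation is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(delta ~ elevation_m, data = deltas)
  sm <- summary(fit)
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 r2_adj = sm$adj.r.squared,
                 p_slope = sm$coefficients["elevation_m", "Pr(>|t|)"],
                 n = nrow(deltas), model = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "delta = %.4g %+.4g x m   (R2 adj. = %.3f, p_slope = %.3g, n = %d)\n",
    x$a, x$b, x$r2_adj, x$p_slope, x$n))
  invisible(x)
}

#' Elevation where a fitted delta line crosses zero
#'
#' Root of the fitted line, `-a/b`: the elevation at which the two
#' surveys are expected to be equal for the metric.
#'
#' @param fit a `linear_fit` (or any list with `a` and `b`).
#' @return elevation in m, or `NA` with a warning when the slope is zero.
#' @export
crossing_elevation <- function(fit) {
  if (fit$b == 0) {
    warning("zero slope: crossing elevation undefined", call. = FALSE)
    return(NA_real_)
  }
  -fit$a / fit$b
}

#' Assign potential areas to elevational bands
#'
#' Orders areas by ascending elevation and partitions them into
#' `n_bands` contiguous bands. When the count does not divide evenly the
#' remainder is absorbed by the lowest bands, so 277 areas give band
#' sizes 26, 26, 25 x 9.
#'
#' @param areas data frame with `area_id`, `elevation_m`.
#' @param n_bands number of bands (default 11).
#' @return object of class `band_assignment`: `assignment` (`area_id`,
#'   `elevation_m`, `band`) and `bands` (`band`, `n`,
#'   `median_elevation`).
#' @export
assign_bands <- function(areas, n_bands = 11L) {
  if (!all(c("area_id", "elevation_m") %in% names(areas))) {
    stop("areas needs columns area_id, elevation_m", call. = FALSE)
  }
  n <- nrow(areas)
  if (n < n_bands) stop("fewer areas than bands", call. = FALSE)
  ord <- order(areas$elevation_m, areas$area_id)
  base <- n %/% n_bands
  r <- n - base * n_bands
  sizes <- rep(base, n_bands)
  if (r > 0L) sizes[seq_len(r)] <- base + 1L
  band <- rep(seq_len(n_bands), times = sizes)
  assignment <- data.frame(area_id = areas$area_id[ord],
                           elevation_m = areas$elevation_m[ord],
                           band = band, stringsAsFactors = FALSE)
  bands <- data.frame(
    band = seq_len(n_bands), n = sizes,
    median_elevation = as.numeric(
      tapply(assignment$elevation_m, assignment$band, stats::median)))
  structure(list(assignment = assignment, bands = bands),
            class = "band_assignment")
}

#' Survey contrast of pairwise beta diversity within a band
#'
#' Mixed model on pair-level beta values (`value ~ survey +
#' (1 | area_pair)`), the potential-area pair as random factor. Input is
#' typically one band's rows of [survey_beta_pairs()].
#'
#' @param beta_pairs data frame with `beta_additive` (or the column named
#'   in `value_col`), `survey`, `area_pair`.
#' @param value_col which beta scale to model (default
#'   `"beta_additive"`).
#' @param min_pairs minimum pairs per survey; below it the band is
#'   skipped (returns `NULL` with a message).
#' @return `survey_effect` for the band, or `NULL`.
#' @export
band_beta_contrast <- function(beta_pairs, value_col = "beta_additive",
                               min_pairs = 3L) {
  counts <- table(beta_pairs$survey)
  if (length(counts) < 2L || any(counts < min_pairs)) {
    message("too few beta pairs for a survey contrast; band skipped")
    return(NULL)
  }
  d <- data.frame(
    y = beta_pairs[[value_col]],
    survey = factor(beta_pairs$survey, levels = SURVEY_LEVELS),
    area_pair = factor(beta_pairs$area_pair))
  fit <- if (nlevels(droplevels(d$area_pair)) > 1L)
    suppressMessages(
      lmerTest::lmer(y ~ survey + (1 | area_pair), data = d,
                     REML = TRUE)) else NULL
  fallback <- FALSE
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    lmfit <- stats::lm(y ~ survey, data = d)
    co <- stats::coef(summary(lmfit))
    est <- co["surveyresurvey", "Estimate"]
    hist_mean <- co["(Intercept)", "Estimate"]
    out <- list(metric = value_col, transformation = "identity",
                estimate = est, se = co["surveyresurvey", "Std. Error"],
                df = lmfit$df.residual,
                p = co["surveyresurvey", "Pr(>|t|)"],
                mean_historical = hist_mean,
                mean_resurvey = hist_mean + est,
                percent_change = if (hist_mean != 0)
                  100 * est / hist_mean else NA_real_,
                fallback_random_effect = TRUE, n = nrow(d))
    return(structure(out, class = "survey_effect"))
  }
  co <- stats::coef(summary(fit))
  est <- co["surveyresurvey", "Estimate"]
  hist_mean <- co["(Intercept)", "Estimate"]
  structure(list(
    metric = value_col, transformation = "identity", estimate = est,
    se = co["surveyresurvey", "Std. Error"],
    df = co["surveyresurvey", "df"], p = co["surveyresurvey", "Pr(>|t|)"],
    mean_historical = hist_mean, mean_resurvey = hist_mean + est,
    percent_change = if (hist_mean != 0)
      100 * est / hist_mean else NA_real_,
    fallback_random_effect = fallback, n = nrow(d)),
    class = "survey_effect")
}

#' Band-level gamma richness contrast
#'
#' Randomly selects one plot per potential area and survey (seeded), so
#' both surveys contribute the same number of plots, and returns the
#' union species richness of each survey's selection. If the band holds
#' more areas than `n_areas_use`, a random subset of areas is used
#' (mirroring the skipping of one area in oversized bands).
#'
#' @param abundance long abundance table.
#' @param plots plot metadata.
#' @param area_ids areas forming the band.
#' @param seed integer seed for the plot selection.
#' @param n_areas_use number of areas to keep (default: all eligible).
#' @return list `gamma_historical`, `gamma_resurvey`, `areas_used`.
#' @export
band_gamma_contrast <- function(abundance, plots, area_ids, seed,
                                n_areas_use = NULL) {
  check_plot_table(plots)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  sub <- plots[plots$area_id %in% area_ids, , drop = FALSE]
  eligible <- vapply(split(sub$survey, sub$area_id),
                     function(s) all(SURVEY_LEVELS %in% s), logical(1))
  dropped <- names(eligible)[!eligible]
  if (length(dropped) > 0L) {
    warning("area(s) missing a survey skipped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  use <- names(eligible)[eligible]
  if (length(use) == 0L) stop("no eligible areas in band", call. = FALSE)
  n_use <- min(n_areas_use %||% length(use), length(use))
  if (n_use < length(use)) use <- sort(sample(use, n_use))

  pick <- character(0)
  sel <- list(historical = character(0), resurvey = character(0))
  for (a in use) {
    for (sv in SURVEY_LEVELS) {
      ids <- sub$plot_id[sub$area_id == a & sub$survey == sv]
      chosen <- if (length(ids) == 1L) ids else sample(ids, 1L)
      sel[[sv]] <- c(sel[[sv]], chosen)
    }
  }
  list(gamma_historical = gamma_band_richness(abundance, sel$historical),
       gamma_resurvey = gamma_band_richness(abundance, sel$resurvey),
       areas_used = use)
}

#' Pseudo-turnover check via Bray-Curtis dissimilarity
#'
#' For every potential area with at least two resurvey plots and one
#' historical plot, compares the mean Bray-Curtis dissimilarity between
#' historical and resurvey plots (temporal + relocation signal) with the
#' mean dissimilarity among the resurvey plots (relocation signal alone).
#' A positive difference indicates genuine temporal change beyond
#' relocation noise. The overall contrast is estimated with a mixed model
#' on all pair values (`bc ~ pair type + (1 | area)`).
#'
#' @param abundance long abundance table (standardized covers).
#' @param plots plot metadata.
#' @return list: `per_area` (`area_id`, `bc_between_surveys`,
#'   `bc_within_resurvey`, `difference`) and `effect` (a
#'   `survey_effect`-like contrast of between-survey minus
#'   within-resurvey dissimilarity).
#' @export
pseudo_turnover_check <- function(abundance, plots) {
  check_plot_table(plots)
  per_area <- list(); pair_rows <- list()
  for (a in unique(plots$area_id)) {
    hp <- plots$plot_id[plots$area_id == a & plots$survey == "historical"]
    rp <- plots$plot_id[plots$area_id == a & plots$survey == "resurvey"]
    if (length(rp) < 2L || length(hp) < 1L) {
      message("area ", a, " ineligible for pseudo-turnover check; skipped")
      next
    }
    vecs <- lapply(stats::setNames(c(hp, rp), c(hp, rp)),
                   function(p) plot_abundances(abundance, p))
    between <- unlist(lapply(hp, function(h)
      vapply(rp, function(r) bray_curtis(vecs[[h]], vecs[[r]]),
             numeric(1))))
    within <- utils::combn(rp, 2L, function(pr)
      bray_curtis(vecs[[pr[1]]], vecs[[pr[2]]]))
    per_area[[a]] <- data.frame(
      area_id = a, bc_between_surveys = mean(between),
      bc_within_resurvey = mean(within),
      difference = mean(between) - mean(within),
      stringsAsFactors = FALSE)
    pair_rows[[a]] <- data.frame(
      area_id = a,
      value = c(between, within),
      survey = c(rep("resurvey", length(between)),   # between-survey pairs
                 rep("historical", length(within))), # within-resurvey pairs
      stringsAsFactors = FALSE)
  }
  if (length(per_area) == 0L) {
    stop("no area has >= 2 resurvey plots and >= 1 historical plot",
         call. = FALSE)
  }
  pairs <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  # reuse the survey-contrast machinery: "resurvey" codes between-survey
  # pairs, "historical" the within-resurvey baseline, so the estimate is
  # (between-survey BC) - (within-resurvey BC); needs >= 2 eligible areas
  effect <- if (length(per_area) >= 2L)
    fit_survey_lmm(pairs, metric = "pseudo_turnover") else NULL
  list(per_area = do.call(rbind, c(per_area,
                                   list(make.row.names = FALSE))),
       effect = effect)
}
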