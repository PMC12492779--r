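# Community-level characteristics: community-weighted means of ecological
# indicator values, Grime CSR life-strategy composition, and cover shares
# of the three grassland taxon groups.

INDICATOR_NAMES <- c("temperature", "light", "moisture", "reaction",
                     "nutrients", "mowing_tolerance", "hemeroby")

#' Community-weighted mean of a species attribute
#'
#' Abundance-weighted mean of a per-species value over one plot. Species
#' with a missing value are dropped and the weights renormalized over the
#' covered species; the covered share of total abundance is reported so
#' poorly covered plots can be flagged downstream.
#'
#' @param p named nonnegative abundance vector.
#' @param values named numeric vector of species values, `NA` allowed.
#' @return list with `value` (NA if no species has a value) and
#'   `coverage` (fraction of abundance carried by covered species).
#' @export
community_weighted_mean <- function(p, values) {
  p <- as_relabund(p)
  v <- values[names(p)]
  ok <- !is.na(v)
  if (!any(ok)) return(list(value = NA_real_, coverage = 0))
  cov <- sum(p[ok])
  list(value = sum(p[ok] * v[ok]) / cov, coverage = cov)
}

#' Decompose Grime CSR strategy strings
#'
#' A three-letter code over {c, s, r} is decomposed into fractional
#' coordinates on the strategy simplex: each dimension is the count of
#' its letter divided by 3, so e.g. `"ssr"` gives c = 0, s = 2/3,
#' r = 1/3 and the three always sum to 1.
#'
#' @param strategy character vector of CSR codes (case-insensitive);
#'   names, if present, identify species in error messages.
#' @return data frame with columns `c`, `s`, `r`.
#' @export
csr_decompose <- function(strategy) {
  s <- tolower(strategy)
  bad <- !grepl("^[csr]{3}$", s)
  if (any(bad)) {
    who <- if (!is.null(names(strategy))) names(strategy)[bad] else
      strategy[bad]
    stop("malformed CSR code(s): ", paste(unique(who), collapse = ", "),
         call. = FALSE)
  }
  letters3 <- strsplit(s, "")
  out <- t(vapply(letters3, function(x) {
    c(c = sum(x == "c"), s = sum(x == "s"), r = sum(x == "r")) / 3
  }, numeric(3)))
  out <- as.data.frame(out)
  rownames(out) <- names(strategy)
  out
}

#' Cover proportions of the three grassland taxon groups
#'
#' Percent of total abundance in (i) Poaceae, (ii) Cyperaceae and
#' Juncaceae combined, and (iii) forbs (all other families).
#'
#' @param p named nonnegative abundance vector.
#' @param family_map named character vector `species -> family`.
#' @return named numeric `poaceae_pct`, `cypjunc_pct`, `forb_pct`,
#'   summing to 100.
#' @export
group_proportions <- function(p, family_map) {
  p <- as_relabund(p)
  miss <- setdiff(names(p), names(family_map))
  if (length(miss) > 0L) {
    stop("species without family assignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fam <- family_map[names(p)]
  grp <- ifelse(fam == "Poaceae", "poaceae_pct",
                ifelse(fam %in% c("Cyperaceae", "Juncaceae"),
                       "cypjunc_pct", "forb_pct"))
  out <- c(poaceae_pct = 0, cypjunc_pct = 0, forb_pct = 0)
  sums <- tapply(p, grp, sum)
  out[names(sums)] <- 100 * as.numeric(sums)
  out
}

#' Per-plot community metrics table
#'
#' Computes, for every plot: community-weighted means of the seven
#' indicator values, the abundance-weighted CSR composition, and the
#' taxon-group cover shares. Plots whose CWM coverage falls below
#' `coverage_warn` are flagged with a warning.
#'
#' @param abundance long abundance table.
#' @param species species attribute table (`species_id`, `family`, the
#'   indicator columns, `csr`).
#' @param coverage_warn flag threshold for the covered abundance share
#'   behind a CWM (default 0.8).
#' @return tidy data frame `plot_id`, `metric`, `value`,
#'   `coverage_fraction`.
#' @export
plot_metrics <- function(abundance, species, coverage_warn = 0.8) {
  check_abundance_table(abundance)
  if (!"species_id" %in% names(species)) {
    stop("species table needs species_id", call. = FALSE)
  }
  fam <- stats::setNames(species$family, species$species_id)
  csr_tab <- csr_decompose(stats::setNames(species$csr, species$species_id))
  plot_ids <- unique(abundance$plot_id)
  res <- vector("list", length(plot_ids))
  low_cov <- character(0)
  for (k in seq_along(plot_ids)) {
    pid <- plot_ids[k]
    p <- plot_abundances(abundance, pid)
    rows <- list()
    for (ind in intersect(INDICATOR_NAMES, names(species))) {
      vals <- stats::setNames(species[[ind]], species$species_id)
      cwm <- community_weighted_mean(p, vals)
      if (!is.na(cwm$value) && cwm$coverage < coverage_warn) {
        low_cov <- c(low_cov, paste0(pid, "/", ind))
      }
      rows[[ind]] <- data.frame(plot_id = pid, metric = paste0("cwm_", ind),
                                value = cwm$value,
                                coverage_fraction = cwm$coverage)
    }
    for (dim in c("c", "s", "r")) {
      vals <- stats::setNames(csr_tab[[dim]], rownames(csr_tab))
      cwm <- community_weighted_mean(p, vals)
      rows[[paste0("csr_", dim)]] <-
        data.frame(plot_id = pid, metric = paste0("csr_", dim),
                   value = cwm$value, coverage_fraction = cwm$coverage)
    }
    gp <- group_proportions(p, fam)
    rows$groups <- data.frame(plot_id = pid, metric = names(gp),
                              value = as.numeric(gp), coverage_fraction = 1)
    res[[k]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (length(low_cov) > 0L) {
    warning("CWM coverage below ", coverage_warn, " for: ",
            paste(utils::head(low_cov, 5L), collapse = ", "),
            if (length(low_cov) > 5L) ", ..." else "", call. = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Expected warming-driven shift in the temperature indicator CWM
#'
#' Converts an observed warming into the expected change of the
#' community-weighted temperature indicator, using the elevational
#' gradient of the indicator and the atmospheric lapse rate: a warming of
#' `warming_c` degrees is thermally equivalent to a downslope displacement
#' of `warming_c / |lapse|` hundred metres, each shifting the indicator by
#' `|gradient|`.
#'
#' @param warming_c warming in degrees Celsius (default 2).
#' @param lapse_rate_c temperature lapse rate in degrees Celsius per
#'   100 m (default -0.65).
#' @param indicator_gradient temperature-indicator change per 100 m of
#'   elevation (default -0.098).
#' @return expected additive CWM shift (about 0.3 for the defaults).
#' @export
expected_temperature_indicator_shift <- function(warming_c = 2,
                                                 lapse_rate_c = -0.65,
                                                 indicator_gradient = -0.098) {
  if (lapse_rate_c == 0) stop("lapse rate must be nonzero", call. = FALSE)
  warming_c / abs(lapse_rate_c) * abs(indicator_gradient)
}
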