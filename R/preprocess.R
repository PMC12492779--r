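# Preprocessing: make the historical (biomass) and modern (cover) surveys
# comparable on a common fractional-cover scale, and apply the richness
# detection correction for the methodological difference between lab
# biomass sorting and visual cover estimation.

#' Allometric biomass-to-cover model
#'
#' A log--log linear map from fractional dry biomass to percent cover,
#' fitted separately for graminoids and forbs:
#' \deqn{cover = exp(a_g + b_g \log(biomass))}
#' The coefficients come from calibration plots sampled with both methods
#' and are supplied by the user; the default is the identity map
#' (`a = 0`, `b = 1`), under which cover is proportional to biomass.
#'
#' @param a named numeric, intercepts for `graminoid` and `forb`.
#' @param b named numeric, slopes for `graminoid` and `forb`; must be
#'   strictly positive so the map is monotone.
#' @return object of class `allometric_model`.
#' @export
allometric_model <- function(a = c(graminoid = 0, forb = 0),
                             b = c(graminoid = 1, forb = 1)) {
  groups <- c("graminoid", "forb")
  if (!all(groups %in% names(a)) || !all(groups %in% names(b))) {
    stop("coefficients must be named for both 'graminoid' and 'forb'",
         call. = FALSE)
  }
  if (any(b[groups] <= 0)) {
    stop("slopes must be strictly positive (monotone transformation)",
         call. = FALSE)
  }
  structure(list(a = a[groups], b = b[groups]), class = "allometric_model")
}

#' Transform biomass fractions to percent cover
#'
#' Applies the group-specific allometric regression to every historical
#' record. Zero-biomass rows are dropped (with a message); species without
#' a graminoid/forb assignment are an error.
#'
#' @param abundance long abundance table with
#'   `abundance_type == "biomass_fraction"` rows to transform.
#' @param group_map named character vector `species_id -> "graminoid"|"forb"`,
#'   or a data frame with columns `species_id`, `group`.
#' @param model an [allometric_model()].
#' @return abundance table with transformed rows marked `percent_cover`.
#' @export
biomass_to_cover <- function(abundance, group_map,
                             model = allometric_model()) {
  check_abundance_table(abundance)
  if (!inherits(model, "allometric_model")) {
    stop("'model' must be an allometric_model", call. = FALSE)
  }
  if (is.data.frame(group_map)) {
    group_map <- stats::setNames(as.character(group_map$group),
                                 group_map$species_id)
  }
  idx <- abundance$abundance_type == "biomass_fraction"
  if (!any(idx)) return(abundance)

  zero <- idx & abundance$abundance == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-biomass record(s)")
    abundance <- abundance[!zero, , drop = FALSE]
    idx <- abundance$abundance_type == "biomass_fraction"
  }

  sp <- unique(abundance$species_id[idx])
  unmapped <- setdiff(sp, names(group_map))
  if (length(unmapped) > 0L) {
    stop("species without graminoid/forb group: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  g <- group_map[abundance$species_id[idx]]
  bad <- !g %in% c("graminoid", "forb")
  if (any(bad)) {
    stop("invalid group labels for: ",
         paste(unique(abundance$species_id[idx][bad]), collapse = ", "),
         call. = FALSE)
  }
  abundance$abundance[idx] <-
    exp(model$a[g] + model$b[g] * log(abundance$abundance[idx]))
  abundance$abundance_type[idx] <- "percent_cover"
  abundance
}

# Inverse of biomass_to_cover for one plot's cover vector; used by the
# synthetic generator so the forward transformation round-trips exactly.
cover_to_biomass_fraction <- function(cover, groups, model) {
  biomass <- exp((log(cover) - model$a[groups]) / model$b[groups])
  biomass / sum(biomass)
}

#' Standardize plot abundances to fractional cover
#'
#' Rescales every plot so its abundances sum to 100
#' (cover of species / summed cover x 100). Idempotent.
#'
#' @param abundance long abundance table; all plots must have positive
#'   total abundance.
#' @return abundance table with `abundance_type = "fractional_cover"`.
#' @export
standardize_fractional_cover <- function(abundance) {
  check_abundance_table(abundance)
  tot <- tapply(abundance$abundance, abundance$plot_id, sum)
  if (any(tot <= 0)) {
    stop("plot(s) with zero total abundance: ",
         paste(names(tot)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  abundance$abundance <-
    100 * abundance$abundance / as.numeric(tot[as.character(abundance$plot_id)])
  abundance$abundance_type <- "fractional_cover"
  abundance
}

#' Detection-corrected species richness per plot
#'
#' Counts species with positive abundance and adds 0.9 to every resurvey
#' plot, compensating for the higher overlooking probability of visual
#' cover estimation relative to sorting cut biomass in the lab (on average
#' 0.9 more species per plot are recovered by the lab method).
#'
#' @param abundance long abundance table.
#' @param plots plot metadata with `plot_id`, `survey`.
#' @return data frame `plot_id`, `survey`, `richness` (non-integer for
#'   resurvey plots).
#' @export
corrected_richness <- function(abundance, plots) {
  check_abundance_table(abundance)
  check_plot_table(plots)
  pos <- abundance[abundance$abundance > 0, , drop = FALSE]
  counts <- tapply(pos$species_id, pos$plot_id,
                   function(s) length(unique(s)))
  out <- data.frame(plot_id = plots$plot_id, survey = plots$survey,
                    stringsAsFactors = FALSE)
  out$richness <- as.numeric(counts[as.character(out$plot_id)])
  out$richness[is.na(out$richness)] <- 0
  empty_res <- out$richness == 0 & out$survey == "resurvey"
  if (any(empty_res)) {
    message("resurvey plot(s) with zero recorded species: ",
            paste(out$plot_id[empty_res], collapse = ", "))
  }
  out$richness <- out$richness + ifelse(out$survey == "resurvey", 0.9, 0)
  out
}

#' Harmonize taxon names against a synonym/aggregate map
#'
#' Replaces observed names by their accepted (or aggregate) name and sums
#' abundances of records that collapse onto the same taxon within a plot.
#' Observed names absent from the map pass through unchanged, with a
#' warning.
#'
#' @param abundance long abundance table.
#' @param synonym_map data frame with columns `observed_name`,
#'   `accepted_name`.
#' @return harmonized abundance table.
#' @export
harmonize_taxa <- function(abundance, synonym_map) {
  check_abundance_table(abundance)
  need <- c("observed_name", "accepted_name")
  if (!all(need %in% names(synonym_map))) {
    stop("synonym_map needs columns observed_name, accepted_name",
         call. = FALSE)
  }
  map <- stats::setNames(as.character(synonym_map$accepted_name),
                         synonym_map$observed_name)
  obs <- unique(abundance$species_id)
  unmapped <- setdiff(obs, names(map))
  if (length(unmapped) > 0L) {
    warning("names not in synonym map pass through unchanged: ",
            paste(utils::head(unmapped, 5L), collapse = ", "),
            if (length(unmapped) > 5L) ", ..." else "", call. = FALSE)
    map <- c(map, stats::setNames(unmapped, unmapped))
  }
  abundance$species_id <- unname(map[abundance$species_id])
  agg <- stats::aggregate(
    abundance ~ plot_id + species_id + abundance_type,
    data = abundance, FUN = sum)
  agg[order(agg$plot_id, agg$species_id),
      c("plot_id", "species_id", "abundance", "abundance_type")]
}
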