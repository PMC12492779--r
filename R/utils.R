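#' @keywords internal
"_PACKAGE"

# Column contracts shared across the package:
#   abundance: plot_id, species_id, abundance, abundance_type
#   plots:     plot_id, area_id, survey, elevation_m, area_m2
# survey labels are always "historical" / "resurvey".

SURVEY_LEVELS <- c("historical", "resurvey")

check_abundance_table <- function(abundance) {
  need <- c("plot_id", "species_id", "abundance", "abundance_type")
  miss <- setdiff(need, names(abundance))
  if (length(miss) > 0L) {
    stop("abundance table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(abundance$abundance < 0, na.rm = TRUE)) {
    stop("abundance table contains negative abundances", call. = FALSE)
  }
  invisible(abundance)
}

check_plot_table <- function(plots) {
  need <- c("plot_id", "area_id", "survey", "elevation_m")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0L) {
    stop("plot table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(plots$survey), SURVEY_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown survey labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(plots)
}

#' Extract one plot's abundances as a named vector
#'
#' @param abundance long abundance table (`plot_id`, `species_id`,
#'   `abundance`).
#' @param plot_id single plot identifier.
#' @param drop_zero drop species with zero abundance (default `TRUE`).
#' @return named numeric vector of abundances, names are species ids.
#' @export
plot_abundances <- function(abundance, plot_id, drop_zero = TRUE) {
  rows <- abundance[abundance$plot_id == plot_id, , drop = FALSE]
  x <- rows$abundance
  names(x) <- rows$species_id
  if (drop_zero) x <- x[x > 0]
  if (anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)
    x <- stats::setNames(as.numeric(x), names(x))
  }
  x
}

#' Normalize an abundance vector to relative abundances
#'
#' @param x nonnegative named numeric vector.
#' @return vector scaled to sum to one.
#' @export
as_relabund <- function(x) {
  if (any(x < 0)) stop("abundances must be nonnegative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("abundance vector sums to zero", call. = FALSE)
  x / s
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Community matrix (plots x species) of relative abundances, zero-filled.
relabund_matrix <- function(abundance, plot_ids = NULL) {
  check_abundance_table(abundance)
  if (!is.null(plot_ids)) {
    abundance <- abundance[abundance$plot_id %in% plot_ids, , drop = FALSE]
  }
  if (nrow(abundance) == 0L) stop("no abundance rows selected", call. = FALSE)
  m <- stats::xtabs(abundance ~ plot_id + species_id, data = abundance)
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  sw <- rowSums(m)
  if (any(sw <= 0)) {
    stop("plots with zero total abundance: ",
         paste(rownames(m)[sw <= 0], collapse = ", "), call. = FALSE)
  }
  m / sw
}
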