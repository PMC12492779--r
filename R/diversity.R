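# Rao's quadratic entropy, its Jost equivalent-number correction, the
# additive alpha/beta/gamma decomposition for plot pairs, Bray-Curtis
# dissimilarity and band-level gamma richness.

#' Rao's quadratic entropy
#'
#' \deqn{Q = \sum_i \sum_j p_i p_j d_{ij}} — the expected dissimilarity
#' between two randomly drawn individuals. With identity distances this is
#' the Gini--Simpson index \eqn{1 - \sum p_i^2}.
#'
#' @param p named nonnegative abundance vector (normalized internally).
#' @param d species dissimilarity matrix covering all species in `p`.
#' @return raw Q, a scalar in \[0, max(d)\].
#' @export
rao_q <- function(p, d) {
  if (is.null(names(p))) stop("'p' must be a named vector", call. = FALSE)
  miss <- setdiff(names(p), rownames(d))
  if (length(miss) > 0L) {
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- as_relabund(p)
  dm <- d[names(p), names(p), drop = FALSE]
  if (anyNA(dm)) stop("distance matrix has NA entries for these species",
                      call. = FALSE)
  as.numeric(t(p) %*% dm %*% p)
}

#' Jost equivalent-number transform of Rao's Q
#'
#' Converts Simpson-family diversity to an effective-species scale:
#' \eqn{1 / (1 - Q)}. Requires distances bounded by 1 so that `Q < 1`.
#'
#' @param q raw Rao Q value(s) in \[0, 1).
#' @return equivalent numbers, >= 1.
#' @export
jost_equivalent <- function(q) {
  if (any(q < 0 | q >= 1)) {
    stop("Q must lie in [0, 1) for the equivalent-number transform",
         call. = FALSE)
  }
  1 / (1 - q)
}

#' Jost-corrected pairwise beta diversity for a plot pair
#'
#' Equivalent-number decomposition of diversity for two plots: mean alpha
#' \eqn{\bar\alpha_{eq}} is the average of the two plots' transformed Rao
#' values, gamma \eqn{\gamma_{eq}} is the transformed Rao value of the
#' pooled community (unweighted mean of the two relative-abundance
#' vectors), and
#' \deqn{\beta_{add} = \gamma_{eq} - \bar\alpha_{eq}, \quad
#'       \beta_{prop} = \beta_{add} / \gamma_{eq}.}
#'
#' @param p1,p2 named abundance vectors (normalized internally).
#' @param d species dissimilarity matrix with entries in \[0, 1\].
#' @return named list: `alpha_eq`, `gamma_eq`, `beta_additive`,
#'   `beta_proportional`.
#' @export
pairwise_beta <- function(p1, p2, d) {
  p1 <- as_relabund(p1)
  p2 <- as_relabund(p2)
  sp <- sort(union(names(p1), names(p2)))
  a1 <- stats::setNames(numeric(length(sp)), sp); a1[names(p1)] <- p1
  a2 <- stats::setNames(numeric(length(sp)), sp); a2[names(p2)] <- p2
  pooled <- (a1 + a2) / 2
  alpha_eq <- mean(c(jost_equivalent(rao_q(a1[a1 > 0], d)),
                     jost_equivalent(rao_q(a2[a2 > 0], d))))
  gamma_eq <- jost_equivalent(rao_q(pooled, d))
  beta_add <- gamma_eq - alpha_eq
  list(alpha_eq = alpha_eq, gamma_eq = gamma_eq,
       beta_additive = beta_add, beta_proportional = beta_add / gamma_eq)
}

#' Bray-Curtis dissimilarity between two plots
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over the union of
#' species.
#'
#' @param x,y named nonnegative abundance vectors.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (any(c(x, y) < 0)) stop("abundances must be nonnegative", call. = FALSE)
  if (sum(x) == 0 && sum(y) == 0) {
    stop("both plots are empty", call. = FALSE)
  }
  sp <- union(names(x), names(y))
  xv <- stats::setNames(numeric(length(sp)), sp); xv[names(x)] <- x
  yv <- stats::setNames(numeric(length(sp)), sp); yv[names(y)] <- y
  as.numeric(vegan::vegdist(rbind(xv, yv), method = "bray"))
}

#' Per-plot Rao alpha diversity for one facet
#'
#' @param abundance long abundance table.
#' @param d species dissimilarity matrix with entries in \[0, 1\] (use
#'   [rescale_unit()] for functional/phylogenetic distances).
#' @param plot_ids optional subset of plots.
#' @return data frame `plot_id`, `rao_q`, `equivalent_numbers`.
#' @export
plot_alpha_diversity <- function(abundance, d, plot_ids = NULL) {
  m <- relabund_matrix(abundance, plot_ids)
  miss <- setdiff(colnames(m), rownames(d))
  if (length(miss) > 0L) {
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dm <- d[colnames(m), colnames(m), drop = FALSE]
  q <- rowSums((m %*% dm) * m)
  data.frame(plot_id = rownames(m), rao_q = as.numeric(q),
             equivalent_numbers = jost_equivalent(as.numeric(q)),
             stringsAsFactors = FALSE)
}

#' Gamma richness of a plot selection
#'
#' Number of distinct species with positive abundance across the selected
#' plots (the band-level gamma proxy).
#'
#' @param abundance long abundance table.
#' @param plot_ids plots to pool.
#' @return integer richness.
#' @export
gamma_band_richness <- function(abundance, plot_ids) {
  check_abundance_table(abundance)
  if (length(plot_ids) == 0L) stop("empty plot selection", call. = FALSE)
  rows <- abundance[abundance$plot_id %in% plot_ids &
                      abundance$abundance > 0, , drop = FALSE]
  if (nrow(rows) == 0L) stop("selected plots hold no species", call. = FALSE)
  length(unique(rows$species_id))
}

#' All same-survey pairwise beta values within a plot set
#'
#' Computes the Jost-corrected additive beta for every pair of plots of
#' the same survey, excluding pairs from the same potential area (those
#' confound relocation noise with spatial turnover). Uses one pooled
#' matrix computation: with \eqn{M = P D P'} over the plot
#' relative-abundance matrix \eqn{P}, each plot's Q is a diagonal entry
#' and each pooled pair's Q is \eqn{(M_{ii} + M_{jj} + 2 M_{ij})/4}.
#'
#' @param abundance long abundance table.
#' @param plots plot metadata (`plot_id`, `area_id`, `survey`).
#' @param d species dissimilarity matrix with entries in \[0, 1\].
#' @param plot_ids optional subset of plots.
#' @param exclude_within_area drop pairs sharing a potential area
#'   (default `TRUE`).
#' @return data frame `plot_1`, `plot_2`, `survey`, `area_pair`,
#'   `beta_additive`, `beta_proportional`.
#' @export
survey_beta_pairs <- function(abundance, plots, d, plot_ids = NULL,
                              exclude_within_area = TRUE) {
  check_plot_table(plots)
  if (is.null(plot_ids)) plot_ids <- plots$plot_id
  m <- relabund_matrix(abundance, plot_ids)
  dm <- subset_distance(d, colnames(m))
  if (max(dm, na.rm = TRUE) > 1 + 1e-9) {
    stop("distances must be rescaled to [0,1] before beta decomposition",
         call. = FALSE)
  }
  big <- m %*% dm %*% t(m)
  meta <- plots[match(rownames(m), plots$plot_id), ]
  out <- list()
  for (sv in SURVEY_LEVELS) {
    ids <- which(meta$survey == sv)
    if (length(ids) < 2L) next
    pr <- utils::combn(ids, 2L)
    if (exclude_within_area) {
      keep <- meta$area_id[pr[1, ]] != meta$area_id[pr[2, ]]
      pr <- pr[, keep, drop = FALSE]
    }
    if (ncol(pr) == 0L) next
    i <- pr[1, ]; j <- pr[2, ]
    qi <- diag(big)[i]; qj <- diag(big)[j]
    qp <- (qi + qj + 2 * big[cbind(i, j)]) / 4
    alpha_eq <- (jost_equivalent(qi) + jost_equivalent(qj)) / 2
    gamma_eq <- jost_equivalent(qp)
    beta_add <- gamma_eq - alpha_eq
    ap <- paste(pmin(meta$area_id[i], meta$area_id[j]),
                pmax(meta$area_id[i], meta$area_id[j]), sep = ":")
    out[[sv]] <- data.frame(
      plot_1 = rownames(m)[i], plot_2 = rownames(m)[j], survey = sv,
      area_pair = ap, beta_additive = beta_add,
      beta_proportional = beta_add / gamma_eq, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no eligible plot pairs", call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
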