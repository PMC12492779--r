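# Species-pairwise dissimilarity matrices for the three diversity facets:
# identity (taxonomic), Gower on leaf-height-seed traits (functional) and
# cophenetic tree distance (phylogenetic).

check_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("dissimilarity must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("dissimilarity must carry identical row/column labels",
         call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12, na.rm = TRUE)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE)) {
    stop("dissimilarity must be symmetric", call. = FALSE)
  }
  if (any(d < 0, na.rm = TRUE)) {
    stop("dissimilarities must be nonnegative", call. = FALSE)
  }
  invisible(d)
}

#' Identity (taxonomic) species distance matrix
#'
#' All distinct species pairs are at distance 1, so Rao's quadratic
#' entropy reduces to the Gini--Simpson index and the Jost-corrected
#' decomposition becomes the taxonomic alpha/beta/gamma decomposition.
#'
#' @param species character vector of unique species labels.
#' @return labelled symmetric matrix with zero diagonal.
#' @export
identity_distance <- function(species) {
  if (length(species) == 0L) stop("empty species list", call. = FALSE)
  if (anyDuplicated(species)) {
    stop("duplicate species labels: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  d <- matrix(1, length(species), length(species),
              dimnames = list(species, species))
  diag(d) <- 0
  check_dissimilarity(d)
}

#' Gower distance on leaf-height-seed traits
#'
#' Computes pairwise Gower dissimilarity over specific leaf area, plant
#' height and seed mass. Height and seed mass are log10-transformed (they
#' are strongly right-skewed); every trait is then range-normalized over
#' the supplied species set, so each pair's distance is the mean of
#' \eqn{|x_{ik} - x_{jk}| / range_k} over the traits observed in both
#' species. Missing traits are handled pairwise (no imputation).
#'
#' @param traits data frame with `species_id` and the trait columns.
#' @param trait_cols trait column names (default `sla`, `height`,
#'   `seed_mass`).
#' @param log10_cols traits to log10-transform before range normalization.
#' @return labelled symmetric matrix with entries in \[0, 1\].
#' @export
gower_trait_distance <- function(traits,
                                 trait_cols = c("sla", "height", "seed_mass"),
                                 log10_cols = c("height", "seed_mass")) {
  if (!"species_id" %in% names(traits)) {
    stop("traits needs a species_id column", call. = FALSE)
  }
  miss <- setdiff(trait_cols, names(traits))
  if (length(miss) > 0L) {
    stop("missing trait columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(traits$species_id)) {
    stop("duplicate species in trait table", call. = FALSE)
  }
  x <- as.matrix(traits[, trait_cols, drop = FALSE])
  rownames(x) <- traits$species_id
  for (tc in intersect(log10_cols, trait_cols)) {
    v <- x[, tc]
    if (any(v <= 0, na.rm = TRUE)) {
      stop("trait '", tc, "' must be strictly positive for log10 transform",
           call. = FALSE)
    }
    x[, tc] <- log10(v)
  }

  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warning("excluding species with no trait data: ",
            paste(rownames(x)[all_missing], collapse = ", "), call. = FALSE)
    x <- x[!all_missing, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no species with trait data", call. = FALSE)

  n <- nrow(x)
  num <- matrix(0, n, n)
  den <- matrix(0L, n, n)
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    rng <- diff(range(v, na.rm = TRUE))
    ok <- !is.na(v)
    shared <- outer(ok, ok, `&`)
    if (rng == 0) {
      warning("trait '", colnames(x)[k],
              "' has zero range and contributes 0", call. = FALSE)
      contrib <- matrix(0, n, n)
    } else {
      contrib <- abs(outer(v, v, `-`)) / rng
      contrib[!shared] <- 0
    }
    num <- num + contrib
    den <- den + shared
  }
  no_shared <- den == 0L
  if (any(no_shared[upper.tri(no_shared)])) {
    warning("species pair(s) share no observed trait; distance set to NA",
            call. = FALSE)
  }
  d <- ifelse(den > 0L, num / pmax(den, 1L), NA_real_)
  dimnames(d) <- list(rownames(x), rownames(x))
  diag(d) <- 0
  check_dissimilarity(d)
}

#' Cophenetic (phylogenetic) species distance matrix
#'
#' Distance between two species is the sum of branch lengths on the path
#' connecting their tips in the phylogenetic tree.
#'
#' @param tree an [ape::phylo] object, or a path to / string of a Newick
#'   tree with branch lengths.
#' @return labelled symmetric matrix of patristic distances.
#' @export
cophenetic_distance <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
    if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  }
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be a phylo object or Newick input", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))
    stop("missing branch length on edge(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(rownames(d))]
  check_dissimilarity(d)
}

#' Rescale a dissimilarity matrix to the unit interval
#'
#' Divides by the maximum entry over the analysis species pool so that the
#' Jost equivalent-number transform `1/(1-Q)` is well defined for
#' functional and phylogenetic Rao values. The scaling constant is kept as
#' an attribute and reported via a message.
#'
#' @param d dissimilarity matrix.
#' @return rescaled matrix with attribute `rescale_constant`.
#' @export
rescale_unit <- function(d) {
  check_dissimilarity(d)
  mx <- max(d, na.rm = TRUE)
  if (mx <= 0) {
    attr(d, "rescale_constant") <- 1
    return(d)
  }
  out <- d / mx
  attr(out, "rescale_constant") <- mx
  message("dissimilarity rescaled to [0,1]; constant = ",
          format(mx, digits = 6))
  out
}

#' Restrict a distance matrix to a species subset
#'
#' @param d dissimilarity matrix.
#' @param species labels to keep; all must be present in `d`.
#' @return submatrix in the requested order.
#' @export
subset_distance <- function(d, species) {
  miss <- setdiff(species, rownames(d))
  if (length(miss) > 0L) {
    stop("species absent from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d[species, species, drop = FALSE]
}
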