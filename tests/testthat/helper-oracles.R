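# Independent oracles coded from first principles, kept deliberately
# separate from the package's own computation paths.

oracle_gini_simpson <- function(p) {
  p <- p / sum(p)
  1 - sum(p^2)
}

# elementwise Rao double sum
oracle_rao <- function(p, d) {
  p <- p / sum(p)
  total <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      total <- total + p[i] * p[j] * d[names(p)[i], names(p)[j]]
    }
  }
  total
}

# direct Jost-corrected additive decomposition for a plot pair
oracle_debello_beta <- function(p1, p2, d) {
  sp <- sort(union(names(p1), names(p2)))
  a1 <- setNames(numeric(length(sp)), sp); a1[names(p1)] <- p1 / sum(p1)
  a2 <- setNames(numeric(length(sp)), sp); a2[names(p2)] <- p2 / sum(p2)
  q1 <- oracle_rao(a1[a1 > 0], d)
  q2 <- oracle_rao(a2[a2 > 0], d)
  pooled <- (a1 + a2) / 2
  qg <- oracle_rao(pooled[pooled > 0], d)
  alpha <- unname(mean(c(1 / (1 - q1), 1 / (1 - q2))))
  gamma <- unname(1 / (1 - qg))
  c(alpha_eq = alpha, gamma_eq = gamma, beta_additive = gamma - alpha)
}

# elementwise Gower with pairwise trait availability
oracle_gower <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v, na.rm = TRUE)))
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0; cnt <- 0
      for (k in seq_len(ncol(x))) {
        if (is.na(x[i, k]) || is.na(x[j, k])) next
        cnt <- cnt + 1
        if (rng[k] > 0) num <- num + abs(x[i, k] - x[j, k]) / rng[k]
      }
      d[i, j] <- if (cnt > 0) num / cnt else NA_real_
    }
  }
  d
}

oracle_bray_curtis <- function(x, y) {
  sp <- union(names(x), names(y))
  xv <- setNames(numeric(length(sp)), sp); xv[names(x)] <- x
  yv <- setNames(numeric(length(sp)), sp); yv[names(y)] <- y
  sum(abs(xv - yv)) / sum(xv + yv)
}

# patristic distances as shortest paths on the tree graph
oracle_tree_distances <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g, v = as.character(seq_len(n_tip)),
                         to = as.character(seq_len(n_tip)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d[order(rownames(d)), order(colnames(d))]
}

random_abundance <- function(n, labels = sprintf("sp%02d", seq_len(n))) {
  setNames(rexp(n) + 1e-6, labels)
}

# small deterministic toy: two areas, both surveys
toy_tables <- function() {
  abundance <- data.frame(
    plot_id = c("A_H1", "A_H1", "A_H1", "A_R1", "A_R1",
                "B_H1", "B_H1", "B_R1", "B_R1", "B_R1"),
    species_id = c("poa1", "car1", "forb1", "poa1", "forb2",
                   "poa1", "forb1", "poa1", "forb1", "forb2"),
    abundance = c(0.5, 0.3, 0.2, 60, 40, 0.6, 0.4, 50, 30, 20),
    abundance_type = rep(c("biomass_fraction", "percent_cover"),
                         times = c(3, 2) + c(0, 0))[
                           c(1, 1, 1, 2, 2, 1, 1, 2, 2, 2)],
    stringsAsFactors = FALSE)
  abundance$abundance_type <-
    ifelse(grepl("_H", abundance$plot_id), "biomass_fraction",
           "percent_cover")
  plots <- data.frame(
    plot_id = c("A_H1", "A_R1", "B_H1", "B_R1"),
    area_id = c("A", "A", "B", "B"),
    survey = c("historical", "resurvey", "historical", "resurvey"),
    elevation_m = c(600, 600, 1400, 1400),
    area_m2 = c(5000, 5000, 50000, 50000),
    stringsAsFactors = FALSE)
  species <- data.frame(
    species_id = c("poa1", "car1", "forb1", "forb2"),
    family = c("Poaceae", "Cyperaceae", "Asteraceae", "Fabaceae"),
    group = c("graminoid", "graminoid", "forb", "forb"),
    sla = c(20, 15, 25, 30), height = c(0.4, 0.3, 0.2, 0.6),
    seed_mass = c(1, 0.5, 2, 4),
    temperature = c(3, 2, 4, 3), light = c(4, 3, 3, 2),
    moisture = c(3, 5, 2, 3), reaction = c(3, 3, 4, 2),
    nutrients = c(4, 2, 3, 5), mowing_tolerance = c(5, 2, 3, 4),
    hemeroby = c(4, 1, 2, 5),
    csr = c("ccr", "sss", "ssr", "ccc"),
    stringsAsFactors = FALSE)
  list(abundance = abundance, plots = plots, species = species)
}
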