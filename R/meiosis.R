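#' Simulate a single recombinant gamete
#'
#' Meiosis follows the Haldane model: per chromosome the crossover count is
#' Poisson with mean equal to the chromosome length in Morgans, crossover
#' positions are uniform, there is no interference and no obligate chiasma,
#' and chromosomes segregate independently.
#'
#' @param pop an `rrgs_pop` holding the parent.
#' @param i row index of the parent within `pop`.
#' @param map a [genetic_map] matching the marker columns.
#' @return Integer vector of alleles (0/1), one recombinant haplotype.
#' @export
recombine_gamete <- function(pop, i = 1L, map) {
  cm <- map_for_cpp(map)
  drop(cpp_gametes(pop$h1, pop$h2, as.integer(i), cm$first, cm$last, cm$pos_m))
}

#' Produce a doubled-haploid line from one parent
#'
#' A single recombinant gamete is duplicated into a fully homozygous
#' individual.
#'
#' @inheritParams recombine_gamete
#' @param subcycle sub-cycle label of the offspring.
#' @return An `rrgs_pop` with one DH individual.
#' @export
make_dh <- function(pop, i = 1L, map, subcycle = pop$subcycle) {
  g <- matrix(recombine_gamete(pop, i, map), nrow = 1)
  new_population(g, g, pop$pool, "DH", subcycle, validate = FALSE)
}

# vectorised DH production: one DH per row of `pop`
make_dh_all <- function(pop, map, subcycle = pop$subcycle) {
  cm <- map_for_cpp(map)
  g <- cpp_gametes(pop$h1, pop$h2, seq_len(n_ind(pop)),
                   cm$first, cm$last, cm$pos_m)
  new_population(g, g, pop$pool, "DH", subcycle, validate = FALSE)
}

#' Cross two individuals
#'
#' One gamete is drawn from each parent. Selfing is rejected.
#'
#' @param pop an `rrgs_pop`.
#' @param i,j row indices of the two (distinct) parents.
#' @param map a [genetic_map].
#' @param subcycle sub-cycle label of the offspring.
#' @return An `rrgs_pop` with one S0 individual.
#' @export
cross <- function(pop, i, j, map, subcycle = pop$subcycle) {
  if (i == j) stop("selfing is not allowed")
  cm <- map_for_cpp(map)
  g1 <- cpp_gametes(pop$h1, pop$h2, as.integer(i), cm$first, cm$last, cm$pos_m)
  g2 <- cpp_gametes(pop$h1, pop$h2, as.integer(j), cm$first, cm$last, cm$pos_m)
  new_population(g1, g2, pop$pool, "S0", subcycle, validate = FALSE)
}

#' Randomly pair an even number of selected individuals
#'
#' Produces a perfect matching, uniform over all matchings; each individual
#' appears in exactly one pair.
#'
#' @param ids vector of an even number of identifiers.
#' @return Two-column matrix of pairs.
#' @export
random_pairing <- function(ids) {
  k <- length(ids)
  if (k < 2 || k %% 2 != 0) stop("need an even number (>= 2) of individuals")
  matrix(ids[sample.int(k)], ncol = 2, byrow = TRUE)
}

#' Half-diallel progeny among mating units
#'
#' All k(k-1)/2 unordered pairs of units are mated; each mating contributes
#' the same number of S0 progeny (one gamete per parent unit per progeny).
#' Units are genotypes (e.g. S0 plants or intra-population single crosses)
#' that are themselves meiotically sampled.
#'
#' @param units an `rrgs_pop` holding the k mating units.
#' @param progeny_per_mating progeny per mating (paper design: 5).
#' @param map a [genetic_map].
#' @param subcycle sub-cycle label of the progeny.
#' @param n_total optional total progeny count; when given, progeny are
#'   distributed as evenly as possible over the matings instead of using
#'   `progeny_per_mating`.
#' @return An `rrgs_pop` of S0 progeny (k(k-1)/2 * progeny_per_mating rows,
#'   or `n_total` rows).
#' @export
half_diallel_progeny <- function(units, progeny_per_mating = 5, map,
                                 subcycle = units$subcycle, n_total = NULL) {
  k <- n_ind(units)
  stopifnot(k >= 2)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  n_mat <- nrow(pairs)
  if (is.null(n_total)) {
    counts <- rep(progeny_per_mating, n_mat)
  } else {
    counts <- rep(n_total %/% n_mat, n_mat)
    extra <- n_total %% n_mat
    if (extra > 0) counts[sample.int(n_mat, extra)] <- counts[1] + 1L
  }
  p1 <- rep(pairs[, 1], counts)
  p2 <- rep(pairs[, 2], counts)
  cm <- map_for_cpp(map)
  h1 <- cpp_gametes(units$h1, units$h2, p1, cm$first, cm$last, cm$pos_m)
  h2 <- cpp_gametes(units$h1, units$h2, p2, cm$first, cm$last, cm$pos_m)
  out <- new_population(h1, h2, units$pool, "S0", subcycle, validate = FALSE)
  attr(out, "cross_plan") <- data.frame(parent1 = p1, parent2 = p2)
  out
}
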