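#' Populations of diploid individuals
#'
#' A population stores the phased genotypes of its members as two haplotype
#' matrices (individuals x markers, alleles coded 0/1), a pool label, a status
#' flag (`"DH"`, `"S0"` or `"FOUNDER"`) and the sub-cycle of origin.
#'
#' @param h1,h2 integer matrices of identical dimension with entries in {0,1}.
#' @param pool pool label, typically `"F"` or `"M"`.
#' @param status one of `"DH"`, `"S0"`, `"FOUNDER"`.
#' @param subcycle integer vector `c(t, s)` identifying the sub-cycle of origin.
#' @param validate check invariants (DH/founders homozygous, binary alleles).
#' @return An object of class `rrgs_pop`.
#' @export
new_population <- function(h1, h2, pool = "F", status = "S0",
                           subcycle = c(0L, 0L), validate = TRUE) {
  stopifnot(is.matrix(h1), is.matrix(h2), all(dim(h1) == dim(h2)))
  status <- match.arg(status, c("DH", "S0", "FOUNDER"))
  if (validate) {
    if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
      stop("haplotype alleles must be coded 0/1")
    if (status %in% c("DH", "FOUNDER") && !identical(c(h1), c(h2)))
      stop(status, " individuals must be homozygous at every locus")
  }
  structure(list(h1 = h1, h2 = h2, pool = pool, status = status,
                 subcycle = as.integer(subcycle)),
            class = "rrgs_pop")
}

#' @rdname new_population
#' @param pop an `rrgs_pop`.
#' @export
n_ind <- function(pop) nrow(pop$h1)

#' Reference-allele frequencies of a population
#' @param pop an `rrgs_pop`.
#' @return Numeric vector of per-locus frequencies of the allele coded 1.
#' @export
allele_freq <- function(pop) {
  (colSums(pop$h1) + colSums(pop$h2)) / (2 * n_ind(pop))
}

#' Genotype dosage matrix (count of reference alleles, 0/1/2)
#' @param pop an `rrgs_pop`.
#' @param cols optional marker column subset.
#' @export
dosage <- function(pop, cols = NULL) {
  if (is.null(cols)) pop$h1 + pop$h2 else pop$h1[, cols, drop = FALSE] + pop$h2[, cols, drop = FALSE]
}

#' @export
print.rrgs_pop <- function(x, ...) {
  cat(sprintf("Population %s: %d %s individuals, %d markers (sub-cycle C_%d,%d)\n",
              x$pool, n_ind(x), x$status, ncol(x$h1), x$subcycle[1], x$subcycle[2]))
  invisible(x)
}

# subset rows of a population
pop_subset <- function(pop, idx) {
  new_population(pop$h1[idx, , drop = FALSE], pop$h2[idx, , drop = FALSE],
                 pop$pool, pop$status, pop$subcycle, validate = FALSE)
}

#' Founder panel of fully homozygous lines
#'
#' @param haplo integer matrix (lines x markers) with entries in {0,1}; one
#'   haplotype row per line (lines are fully homozygous).
#' @param pool pool label (`"F"` or `"M"`).
#' @param map a [genetic_map] with one row per marker column.
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(haplo, pool, map) {
  stopifnot(is.matrix(haplo), inherits(map, "genetic_map"),
            ncol(haplo) == nrow(map))
  if (!all(haplo %in% c(0L, 1L))) stop("founder alleles must be coded 0/1")
  structure(list(haplo = haplo, pool = pool, map = map),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("Founder panel %s: %d homozygous lines x %d markers\n",
              x$pool, nrow(x$haplo), ncol(x$haplo)))
  print(x$map)
  invisible(x)
}

#' Convert a founder panel to a population of homozygous individuals
#' @param panel a [founder_panel].
#' @export
as_population <- function(panel) {
  new_population(panel$haplo, panel$haplo, panel$pool, "FOUNDER",
                 validate = FALSE)
}
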