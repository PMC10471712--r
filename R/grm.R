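#' Genomic relationship matrix with origin-specific allele frequencies
#'
#' Computes G(i, j) = sum_l (x_il - 2 p_l^i)(x_jl - 2 p_l^j) divided by
#' sqrt(2 sum_l p_l^i (1 - p_l^i)) * sqrt(2 sum_l p_l^j (1 - p_l^j)),
#' where x is the reference-allele dosage (0/1/2) and p the reference-allele
#' frequency in the sub-cycle population each genotype originated from. All
#' rows of `x` share origin frequencies `p`, and all rows of `x2` share `p2`;
#' blocks between genotypes of different origins are obtained by passing both
#' sides. Loci monomorphic in an origin contribute 0 to that side's centring
#' and denominator.
#'
#' The printed form of this estimator sometimes omits the factor 2 in the
#' centring; `centre = "p"` reproduces that (x - p) variant for sensitivity
#' checks, while the default `"2p"` gives the standard scaling with DH
#' self-relationship near 2.
#'
#' @param x dosage matrix (genotypes x markers, values 0/1/2) over panel R.
#' @param p reference-allele frequencies of the origin population of the rows
#'   of `x` (same markers).
#' @param x2,p2 optional second set of genotypes with its own origin
#'   frequencies; when omitted the square matrix of `x` with itself is
#'   returned.
#' @param centre `"2p"` (default) or `"p"` (exact-as-printed variant).
#' @return Relationship matrix (rows of `x` by rows of `x2` or `x`).
#' @export
compute_grm <- function(x, p, x2 = NULL, p2 = NULL, centre = c("2p", "p")) {
  centre <- match.arg(centre)
  cf <- if (centre == "2p") 2 else 1
  den <- function(p) 2 * sum(p * (1 - p))
  ctr <- function(x, p) {
    xc <- sweep(x, 2, cf * p)
    mono <- p <= 0 | p >= 1
    if (any(mono)) xc[, mono] <- 0
    xc
  }
  d1 <- den(p)
  if (d1 <= 0) stop("all loci monomorphic in the origin of x: zero denominator")
  x1c <- ctr(x, p)
  if (is.null(x2)) {
    g <- tcrossprod(x1c) / d1
  } else {
    stopifnot(!is.null(p2), ncol(x2) == ncol(x))
    d2 <- den(p2)
    if (d2 <= 0) stop("all loci monomorphic in the origin of x2: zero denominator")
    g <- tcrossprod(x1c, ctr(x2, p2)) / sqrt(d1 * d2)
  }
  g
}

#' @rdname compute_grm
#' @param pop an `rrgs_pop`; frequencies are taken from the population
#'   itself (its origin).
#' @param cols marker columns of panel R.
#' @param ... passed to [compute_grm].
#' @export
grm_population <- function(pop, cols, ...) {
  x <- dosage(pop, cols)
  compute_grm(x, allele_freq(pop)[cols], ...)
}
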