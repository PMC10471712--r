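#' Sample QTL and marker panels
#'
#' Splits the full marker set into a QTL pool `QP` (sampled with
#' per-chromosome counts proportional to chromosome marker counts,
#' largest-remainder rounding), a QTL set `Q` drawn uniformly from `QP`, and
#' the prediction marker panel `R` containing every marker not in `QP` (QTL
#' are never usable as prediction markers).
#'
#' @param map a [genetic_map] of all markers.
#' @param n_qp size of the QTL pool (paper design: 3000).
#' @param n_q number of QTL (paper design: 1000).
#' @param seed integer seed.
#' @return List with integer marker-index vectors `q`, `qp`, `r`.
#' @export
sample_qtl_panel <- function(map, n_qp = 3000, n_q = 1000, seed = 1) {
  m <- nrow(map)
  stopifnot(n_qp <= m, n_q <= n_qp)
  set.seed(seed)
  first <- attr(map, "chr_first"); last <- attr(map, "chr_last")
  counts <- last - first + 1L
  exact <- n_qp * counts / m
  quota <- floor(exact)
  rem <- n_qp - sum(quota)
  if (rem > 0) {
    o <- order(exact - quota, decreasing = TRUE)
    quota[o[seq_len(rem)]] <- quota[o[seq_len(rem)]] + 1L
  }
  if (any(quota > counts))
    stop("a chromosome has fewer markers than its QTL-pool quota")
  qp <- unlist(lapply(seq_along(counts), function(c) {
    idx <- first[c]:last[c]
    sort(sample(idx, quota[c]))
  }))
  q <- sort(sample(qp, n_q))
  list(q = q, qp = sort(qp), r = setdiff(seq_len(m), qp))
}

#' Named dominance presets for the trait architecture
#'
#' Returns the dominance parameters (mean and variance of the degree of
#' dominance k, and the fraction of QTL carrying only dominance effects) that
#' define the trait regimes studied: `"high_tau"` places roughly a quarter of
#' the hybrid genetic variance in SCA on maize-like divergent founder pools,
#' `"low_tau"` a small share, and `"additive"` none (purely additive trait).
#'
#' @param name one of `"high_tau"`, `"low_tau"`, `"additive"`.
#' @return List with `mu_k`, `sigma2_k`, `nd_frac`.
#' @export
trait_preset <- function(name = c("high_tau", "low_tau", "additive")) {
  switch(match.arg(name),
         high_tau = list(mu_k = 0.85, sigma2_k = 0.16, nd_frac = 0.10),
         low_tau  = list(mu_k = 0.30, sigma2_k = 0.04, nd_frac = 0.00),
         additive = list(mu_k = 0.00, sigma2_k = 0.00, nd_frac = 0.00))
}

#' Assign additive and dominance effects to the QTL
#'
#' Additive effects are drawn from a Gamma distribution (shape 0.4, scale
#' 1.66); the degree of dominance k is Normal(mu_k, sigma2_k) and d = a * k.
#' A random subset Q_d of `n_d` QTL keeps its dominance effect but has its
#' additive effect replaced by zero (d is computed before zeroing). Each
#' QTL's reference allele is then oriented to the favourable direction with
#' probability 1/2 (the sign of a is flipped, d is unchanged, as under allele
#' relabelling), so neither pool starts systematically enriched.
#'
#' @param q integer vector of QTL marker indices.
#' @param mu_k,sigma2_k mean and variance of the degree of dominance.
#' @param n_d number of dominance-only QTL.
#' @param gamma_shape,gamma_scale Gamma parameters of the additive effects.
#' @param seed integer seed.
#' @return An unscaled `trait_arch` (see [scale_to_unit_variance]).
#' @export
assign_effects <- function(q, mu_k = 0, sigma2_k = 0, n_d = 0,
                           gamma_shape = 0.4, gamma_scale = 1.66, seed = 1) {
  stopifnot(n_d <= length(q), gamma_shape > 0, gamma_scale > 0)
  set.seed(seed)
  nq <- length(q)
  a <- rgamma(nq, shape = gamma_shape, scale = gamma_scale)
  k <- if (sigma2_k > 0) rnorm(nq, mu_k, sqrt(sigma2_k)) else rep(mu_k, nq)
  d <- a * k
  qd <- if (n_d > 0) sort(sample.int(nq, n_d)) else integer(0)
  a[qd] <- 0
  flip <- runif(nq) < 0.5
  a[flip] <- -a[flip]
  structure(list(q = as.integer(q), a = a, d = d, qd = qd,
                 scale = NA_real_),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("Trait architecture: %d QTL (%d dominance-only), %s\n",
              length(x$q), length(x$qd),
              if (is.na(x$scale)) "unscaled"
              else sprintf("scaled by %.4g to unit hybrid variance", x$scale)))
  invisible(x)
}

#' Scale effects so the hybrid factorial has unit genetic variance
#'
#' All additive and dominance effects are multiplied by one common factor c
#' such that the (population) variance of genotypic values over the full
#' n_F x n_M factorial between the two C_1,0 DH populations equals 1.
#'
#' @param arch an unscaled `trait_arch`.
#' @param pop_f,pop_m the C_1,0 DH populations of the two pools.
#' @return The scaled `trait_arch`, with the factor recorded in `$scale`.
#' @export
scale_to_unit_variance <- function(arch, pop_f, pop_m) {
  uf <- pop_f$h1[, arch$q, drop = FALSE]
  um <- pop_m$h1[, arch$q, drop = FALSE]
  v <- factorial_values(uf, um, arch$a, arch$d)
  s2 <- pop_var(c(v))
  if (s2 <= 0) stop("degenerate trait: zero genetic variance before scaling")
  cf <- 1 / sqrt(s2)
  arch$a <- arch$a * cf
  arch$d <- arch$d * cf
  arch$scale <- if (is.na(arch$scale)) cf else arch$scale * cf
  arch
}

#' Genotypic value of diploid genotypes at the QTL
#'
#' Uses the Falconer/Lynch-Walsh parameterisation per locus: genotypes with
#' 0, 1 or 2 reference alleles take values -a, d and +a, summed over QTL.
#'
#' @param geno matrix (individuals x QTL) or vector of dosages in {0,1,2},
#'   columns ordered as `arch$q`.
#' @param arch a `trait_arch`.
#' @return Numeric vector of genotypic values.
#' @export
genotypic_value <- function(geno, arch) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  stopifnot(ncol(geno) == length(arch$q))
  drop((geno - 1) %*% arch$a + (geno == 1) %*% arch$d)
}

# genotypic value of a population (dosages extracted at arch$q)
pop_genotypic_value <- function(pop, arch) {
  genotypic_value(dosage(pop, arch$q), arch)
}

#' Error variance implied by a heritability
#'
#' sigma_e^2 = sigma_G^2 (1 - h^2) / h^2, with sigma_G^2 = 1 in C_1,0. The
#' value is fixed at the start of the program and never re-derived in later
#' cycles.
#'
#' @param h2 broad-sense heritability of the hybrid population in C_1,0.
#' @param sigma2_g genetic variance (1 by construction).
#' @export
error_variance <- function(h2, sigma2_g = 1) {
  stopifnot(h2 > 0, h2 <= 1)
  sigma2_g * (1 - h2) / h2
}

#' Add phenotyping noise to genotypic values
#'
#' @param g vector of genotypic values.
#' @param sigma2_e error variance (see [error_variance]).
#' @return y = g + e with e ~ Normal(0, sigma2_e), independent.
#' @export
phenotype <- function(g, sigma2_e) {
  if (sigma2_e == 0) return(g)
  g + rnorm(length(g), 0, sqrt(sigma2_e))
}

#' Serialize a trait architecture to a tab-separated file
#' @param arch a `trait_arch`.
#' @param map the [genetic_map] the QTL indices refer to.
#' @param path output path.
#' @export
write_trait_architecture <- function(arch, map, path) {
  df <- data.frame(marker = map$marker[arch$q], chr = map$chr[arch$q],
                   pos_cM = map$pos_cM[arch$q], a = arch$a, d = arch$d,
                   in_Qd = seq_along(arch$q) %in% arch$qd)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# population variance (divide by N)
pop_var <- function(x) mean((x - mean(x))^2)
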