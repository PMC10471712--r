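# Hybrid genotypic values of the full factorial between homozygous parents.
# uf, um: allele-indicator matrices (parents x QTL, entries 0/1; one row per
# homozygous parent). Per locus the hybrid of parents i (pool F) and j (pool
# M) has value a*(u_i + u_j - 1) + d*(u_i XOR u_j); values are summed over
# loci in closed matrix form.
factorial_values <- function(uf, um, a, d) {
  add_f <- drop(uf %*% a)
  add_m <- drop(um %*% a)
  dm <- t(d * t(uf))             # uf scaled by d column-wise
  dom <- dm %*% t(1 - um) + t(d * t(1 - uf)) %*% t(um)
  outer(add_f, add_m, "+") - sum(a) + dom
}

#' GCA/SCA decomposition of the complete hybrid factorial
#'
#' Computes the genotypic values of all hybrids between two sets of fully
#' homozygous (DH) parents and decomposes them into the factorial mean, GCA
#' effects of either parent set, and SCA residuals. Variances are population
#' variances (divide by N), since the complete factorial is the population of
#' interest.
#'
#' @param pop_f,pop_m `rrgs_pop` objects of homozygous parents, or 0/1 allele
#'   indicator matrices (parents x QTL).
#' @param arch a `trait_arch`.
#' @return List of class `factorial_summary`: `mu`, `gca_f`, `gca_m`,
#'   `var_g`, `var_gca_f`, `var_gca_m`, `var_sca`, `tau` (percent of hybrid
#'   genetic variance due to SCA).
#' @export
factorial_decomposition <- function(pop_f, pop_m, arch) {
  uf <- parent_indicators(pop_f, arch)
  um <- parent_indicators(pop_m, arch)
  vals <- factorial_values(uf, um, arch$a, arch$d)
  mu <- mean(vals)
  gca_f <- rowMeans(vals) - mu
  gca_m <- colMeans(vals) - mu
  sca <- vals - outer(gca_f, gca_m, "+") - mu
  var_g <- pop_var(c(vals))
  out <- list(mu = mu, gca_f = gca_f, gca_m = gca_m,
              var_g = var_g,
              var_gca_f = pop_var(gca_f), var_gca_m = pop_var(gca_m),
              var_sca = mean(sca^2),
              tau = if (var_g > 0) 100 * mean(sca^2) / var_g else NA_real_)
  class(out) <- "factorial_summary"
  out
}

parent_indicators <- function(x, arch) {
  if (inherits(x, "rrgs_pop")) {
    if (!identical(c(x$h1[, arch$q]), c(x$h2[, arch$q])))
      stop("factorial parents must be homozygous at every QTL")
    x$h1[, arch$q, drop = FALSE]
  } else {
    stopifnot(is.matrix(x), ncol(x) == length(arch$q))
    x
  }
}

#' @export
print.factorial_summary <- function(x, ...) {
  cat(sprintf(paste0("Factorial %dx%d: mean %.4f, var_G %.4f ",
                     "(gcaF %.4f, gcaM %.4f, sca %.4f), tau %.1f%%\n"),
              length(x$gca_f), length(x$gca_m), x$mu, x$var_g,
              x$var_gca_f, x$var_gca_m, x$var_sca, x$tau))
  invisible(x)
}

#' Cumulative selection gain
#'
#' Difference between the factorial mean at sub-cycle (t,s) and the baseline
#' mean at C_1,0, reported in units of the baseline genetic standard
#' deviation (1 by construction of the trait scaling).
#'
#' @param summary_ts,baseline `factorial_summary` objects.
#' @export
cumulative_gain <- function(summary_ts, baseline) summary_ts$mu - baseline$mu

#' Prediction accuracy (Pearson correlation)
#'
#' @param true_values,predictions numeric vectors.
#' @param subset optional index subset.
#' @return Pearson correlation, or `NA` when either vector has zero variance.
#' @export
prediction_accuracy <- function(true_values, predictions, subset = NULL) {
  if (!is.null(subset)) {
    true_values <- true_values[subset]
    predictions <- predictions[subset]
  }
  if (sd(true_values) == 0 || sd(predictions) == 0) return(NA_real_)
  cor(true_values, predictions)
}

#' Genic variances from allele frequencies and QTL effects
#'
#' Linkage-equilibrium (genic) variance components of the hybrid factorial:
#' \deqn{\tilde\sigma^2_{gcaF} = \sum_l p^F_l(1-p^F_l)[a_l - (2p^M_l-1)d_l]^2}
#' \deqn{\tilde\sigma^2_{gcaM} = \sum_l p^M_l(1-p^M_l)[a_l - (2p^F_l-1)d_l]^2}
#' \deqn{\tilde\sigma^2_{sca} = 4\sum_l p^F_l(1-p^F_l)p^M_l(1-p^M_l)d_l^2}
#' Unlike the factorial (genetic) variances these are insensitive to
#' covariances between loci, so their ratio isolates the Bulmer effect.
#'
#' @param p_f,p_m reference-allele frequency vectors at the QTL in the two
#'   parent populations.
#' @param arch a `trait_arch`.
#' @return List of class `genic_variances`: `gca_f`, `gca_m`, `sca`, `g`.
#' @export
genic_variances <- function(p_f, p_m, arch) {
  stopifnot(length(p_f) == length(arch$q), length(p_m) == length(arch$q))
  a <- arch$a; d <- arch$d
  gca_f <- sum(p_f * (1 - p_f) * (a - (2 * p_m - 1) * d)^2)
  gca_m <- sum(p_m * (1 - p_m) * (a - (2 * p_f - 1) * d)^2)
  sca <- 4 * sum(p_f * (1 - p_f) * p_m * (1 - p_m) * d^2)
  structure(list(gca_f = gca_f, gca_m = gca_m, sca = sca,
                 g = gca_f + gca_m + sca),
            class = "genic_variances")
}

#' Genetic-to-genic variance ratios
#'
#' @param summary a `factorial_summary`.
#' @param genic a `genic_variances`.
#' @return List with `g`, `gca` (pooled F+M) and `sca` ratios; a ratio is
#'   `NA` when its genic denominator is below 1e-12.
#' @export
genic_ratios <- function(summary, genic) {
  rat <- function(num, den) if (den < 1e-12) NA_real_ else num / den
  list(g = rat(summary$var_g, genic$g),
       gca = rat(summary$var_gca_f + summary$var_gca_m,
                 genic$gca_f + genic$gca_m),
       sca = rat(summary$var_sca, genic$sca))
}

#' Modified Rogers' distance between two populations
#'
#' Euclidean allele-frequency distance for biallelic loci, scaled to [0, 1]:
#' sqrt(sum((pA - pB)^2) / (2m)).
#'
#' @param p_a,p_b reference-allele frequency vectors (same loci), or
#'   `rrgs_pop` objects.
#' @param cols optional marker subset (e.g. the prediction panel R) applied
#'   when populations are passed.
#' @export
modified_rogers_distance <- function(p_a, p_b, cols = NULL) {
  if (inherits(p_a, "rrgs_pop")) p_a <- allele_freq(p_a)[if (is.null(cols)) TRUE else cols]
  if (inherits(p_b, "rrgs_pop")) p_b <- allele_freq(p_b)[if (is.null(cols)) TRUE else cols]
  stopifnot(length(p_a) == length(p_b))
  # biallelic loci: each locus contributes (p - q)^2 for both alleles, so
  # sum_loci sum_alleles (p - q)^2 / (2 m) reduces to mean((p - q)^2)
  sqrt(mean((p_a - p_b)^2))
}

#' Genetic correlation between testcross performance and GCA
#'
#' Closed form under uncorrelated GCA and SCA-with-tester effects:
#' \deqn{r_g(TC, gca) = \sqrt{(1-\tau) / (1 + \tau(2\phi - 1))}}
#' where tau is the proportion (0-1) of hybrid genetic variance due to SCA
#' and phi the tester coefficient: 1 for an inbred tester, 1/2 for a
#' single-cross tester of unrelated lines, 0 for the whole opposite
#' population as tester.
#'
#' @param tau SCA proportion of hybrid genetic variance, in [0, 1).
#' @param phi tester coefficient in [0, 1].
#' @export
analytic_rg_tc_gca <- function(tau, phi = 1) {
  stopifnot(tau >= 0, tau < 1, phi >= 0, phi <= 1)
  sqrt((1 - tau) / (1 + tau * (2 * phi - 1)))
}

#' GCA prediction accuracy of testcross GBLUPs
#'
#' Composition of the accuracy of the GBLUPs for testcross performance with
#' the genetic correlation between testcross performance and GCA:
#' r_gca(TC) = r_u,uhat(TC) * r_g(TC, gca).
#'
#' @param r_u_uhat accuracy of the GBLUPs for TC performance.
#' @inheritParams analytic_rg_tc_gca
#' @export
rgca_tc <- function(r_u_uhat, tau, phi = 1) {
  r_u_uhat * analytic_rg_tc_gca(tau, phi)
}

#' Expected variance loss from drift in a bottlenecked recombination step
#'
#' GCA variance: 100 * (1 - (1 - 1/(2 Ne))^g) percent over g generations.
#' SCA variance depends on the product of the per-population retentions, so
#' with `squared = TRUE` the loss is 100 * (1 - retention^2).
#'
#' @param n_e effective population size of the recombined selected fraction.
#' @param n_generations number of bottlenecked generations (sub-cycles).
#' @param squared compose the retention across both parent pools (SCA).
#' @return Expected loss in percent.
#' @export
expected_drift_loss <- function(n_e, n_generations, squared = FALSE) {
  retention <- (1 - 1 / (2 * n_e))^n_generations
  if (squared) retention <- retention^2
  100 * (1 - retention)
}
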