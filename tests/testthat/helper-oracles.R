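# Brute-force mixed-model-equation solve for y = 1 mu + u + e,
# Var(u) = s2u K, Var(e) = s2e I: independent oracle for GBLUP predictions.
mme_blup <- function(y, k, s2u, s2e) {
  n <- length(y)
  x <- matrix(1, n, 1)
  z <- diag(n)
  lambda <- s2e / s2u
  ki <- solve(k + diag(1e-10, n))
  lhs <- rbind(cbind(crossprod(x), t(x) %*% z),
               cbind(t(z) %*% x, crossprod(z) + lambda * ki))
  rhs <- c(crossprod(x, y), crossprod(z, y))
  sol <- solve(lhs, rhs)
  list(mu = sol[1], u = sol[-1])
}

# Exhaustive GCA/SCA decomposition of a hybrid factorial by direct
# enumeration of every hybrid's genotypic value, locus by locus.
enumerate_factorial <- function(uf, um, a, d) {
  nf <- nrow(uf); nm <- nrow(um)
  vals <- matrix(0, nf, nm)
  for (i in seq_len(nf))
    for (j in seq_len(nm)) {
      g <- uf[i, ] + um[j, ]  # hybrid dosage 0/1/2 per locus
      vals[i, j] <- sum(a * (g - 1)) + sum(d[g == 1])
    }
  mu <- mean(vals)
  gca_f <- rowMeans(vals) - mu
  gca_m <- colMeans(vals) - mu
  sca <- sweep(sweep(vals, 1, gca_f), 2, gca_m) - mu
  pv <- function(v) mean((v - mean(v))^2)
  list(mu = mu, gca_f = gca_f, gca_m = gca_m,
       var_g = pv(c(vals)), var_gca_f = pv(gca_f), var_gca_m = pv(gca_m),
       var_sca = mean(sca^2))
}

# Small deterministic founder panel on a short map, for structural tests.
toy_panel <- function(n_lines = 8, n_markers = 40, pool = "F", seed = 1) {
  set.seed(seed)
  map <- even_map(n_chr = 2, total_cM = 160, n_markers = n_markers)
  repeat {
    h <- matrix(rbinom(n_lines * n_markers, 1, 0.5), n_lines, n_markers)
    if (all(colSums(h) > 0 & colSums(h) < n_lines)) break
  }
  founder_panel(h, pool, map)
}
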