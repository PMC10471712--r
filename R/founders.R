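#' Generate two divergent founder pools
#'
#' Emulates two heterotic pools of fully homozygous lines: a common ancestral
#' population of `effective_size` diploids is initialised with independent
#' loci (ancestral frequencies uniform on (0.05, 0.95)), random-mated for
#' `burnin_generations` to build up within-pool linkage disequilibrium, then
#' split into two pools that drift apart independently for
#' `divergence_generations` of random mating (no selfing) at the given
#' effective size. Finally `n_female` / `n_male` homozygous lines are
#' extracted from each pool (one random gamete per line, doubled), and
#' markers monomorphic across both pools jointly are removed.
#'
#' @param n_female,n_male number of lines in the female and male pool.
#' @param map a [genetic_map], e.g. [maize_like_map()].
#' @param divergence_generations generations of independent drift per pool.
#' @param effective_size diploid population size during burn-in and drift.
#' @param burnin_generations generations of shared random mating before the
#'   split (builds LD; does not separate the pools).
#' @param seed integer seed; the whole operation is reproducible.
#' @return A list with elements `F` and `M`, each a [founder_panel] sharing
#'   one (possibly marker-filtered) map.
#' @examples
#' fp <- generate_founder_pools(20, 15, maize_like_map(200),
#'                              divergence_generations = 5,
#'                              effective_size = 20, seed = 1)
#' @export
generate_founder_pools <- function(n_female, n_male, map,
                                   divergence_generations = 30,
                                   effective_size = 50,
                                   burnin_generations = 20,
                                   seed = 1) {
  stopifnot(n_female > 0, n_male > 0, effective_size >= 2,
            divergence_generations >= 0, total_map_length(map) > 0)
  set.seed(seed)
  m <- nrow(map)
  cm <- map_for_cpp(map)
  p0 <- runif(m, 0.05, 0.95)
  draw <- function(n) matrix(rbinom(n * m, 1L, rep(p0, each = n)), n, m)
  anc <- list(h1 = draw(effective_size), h2 = draw(effective_size))
  for (g in seq_len(burnin_generations))
    anc <- cpp_random_mate(anc$h1, anc$h2, effective_size,
                           cm$first, cm$last, cm$pos_m)
  drift <- function(pop) {
    for (g in seq_len(divergence_generations))
      pop <- cpp_random_mate(pop$h1, pop$h2, effective_size,
                             cm$first, cm$last, cm$pos_m)
    pop
  }
  pool_f <- drift(anc)
  pool_m <- drift(anc)
  lines_from <- function(pop, n) {
    rows <- sample.int(nrow(pop$h1), n, replace = TRUE)
    cpp_gametes(pop$h1, pop$h2, rows, cm$first, cm$last, cm$pos_m)
  }
  hf <- lines_from(pool_f, n_female)
  hm <- lines_from(pool_m, n_male)
  tot <- colSums(hf) + colSums(hm)
  keep <- tot > 0L & tot < (n_female + n_male)
  if (!any(keep))
    stop("no marker remained polymorphic across the two pools; ",
         "reduce divergence_generations or increase effective_size")
  sub_map <- genetic_map(map$chr[keep], map$pos_cM[keep], map$marker[keep])
  list(F = founder_panel(hf[, keep, drop = FALSE], "F", sub_map),
       M = founder_panel(hm[, keep, drop = FALSE], "M", sub_map))
}

#' Load a founder panel from genotype and map files
#'
#' Reads a plain tab-separated genotype matrix (rows = lines, columns =
#' markers; header row of marker names, first column of line names) together
#' with a tab-separated map file with columns `marker`, `chr`, `pos_cM`.
#' Genotype codes may be allele dosages 0/1/2 or nucleotide pairs such as
#' `"AA"`; for nucleotide codes the lexicographically larger allele is coded
#' as the reference (1) allele. Founders must be fully homozygous;
#' heterozygous calls are either rejected or set missing, and missing calls
#' are imputed to the pool major allele.
#'
#' @param genotype_path path to the genotype matrix.
#' @param map_path path to the map file.
#' @param pool pool label for the panel.
#' @param het how to treat heterozygous calls: `"error"` (default) or
#'   `"missing"` (impute like missing data).
#' @return A [founder_panel] with markers ordered by (chromosome, position).
#' @export
load_founders <- function(genotype_path, map_path, pool = "F",
                          het = c("error", "missing")) {
  het <- match.arg(het)
  stopifnot(file.exists(genotype_path), file.exists(map_path))
  geno <- read.table(genotype_path, header = TRUE, sep = "\t",
                     row.names = 1, check.names = FALSE,
                     colClasses = "character", na.strings = c("NA", "", "."))
  mp <- read.table(map_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("marker", "chr", "pos_cM")
  if (!all(need %in% names(mp)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  missing_in_map <- setdiff(colnames(geno), mp$marker)
  if (length(missing_in_map))
    stop("markers absent from map: ", paste(missing_in_map, collapse = ", "))
  map <- genetic_map(mp$chr, mp$pos_cM, mp$marker)
  map <- genetic_map(map$chr[map$marker %in% colnames(geno)],
                     map$pos_cM[map$marker %in% colnames(geno)],
                     map$marker[map$marker %in% colnames(geno)])
  g <- as.matrix(geno)[, map$marker, drop = FALSE]
  hap <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    v <- g[, j]
    ok <- !is.na(v)
    if (all(grepl("^[0-2]$", v[ok]))) {
      dose <- as.integer(v)
      if (any(dose[ok] == 1L)) {
        if (het == "error")
          stop("heterozygous call at marker ", colnames(g)[j],
               "; founders must be homozygous")
        dose[dose == 1L] <- NA_integer_
      }
      hap[, j] <- dose %/% 2L
    } else {
      al <- sort(unique(unlist(strsplit(v[ok], ""))))
      if (!all(nchar(v[ok]) == 2) || length(al) > 2)
        stop("non-biallelic genotype codes at marker ", colnames(g)[j],
             ": ", paste(unique(v[ok]), collapse = ","))
      ref <- al[length(al)]  # lexicographically larger nucleotide = allele 1
      a1 <- substr(v, 1, 1) == ref
      a2 <- substr(v, 2, 2) == ref
      hetero <- ok & (a1 != a2)
      if (any(hetero)) {
        if (het == "error")
          stop("heterozygous call at marker ", colnames(g)[j],
               "; founders must be homozygous")
        a1[hetero] <- NA
      }
      hap[, j] <- ifelse(is.na(v) | (ok & is.na(a1)), NA_integer_,
                         as.integer(a1))
    }
    if (anyNA(hap[, j])) {  # impute to pool major allele
      maj <- as.integer(mean(hap[, j], na.rm = TRUE) >= 0.5)
      if (all(is.na(hap[, j]))) maj <- 0L
      hap[is.na(hap[, j]), j] <- maj
    }
  }
  founder_panel(hap, pool, map)
}

#' Write a founder panel to tab-separated genotype and map files
#' @param panel a [founder_panel].
#' @param genotype_path,map_path output file paths.
#' @export
write_founder_panel <- function(panel, genotype_path, map_path) {
  g <- 2L * panel$haplo
  colnames(g) <- panel$map$marker
  rownames(g) <- paste0(panel$pool, seq_len(nrow(g)))
  write.table(cbind(line = rownames(g), as.data.frame(g)), genotype_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(marker = panel$map$marker, chr = panel$map$chr,
                         pos_cM = panel$map$pos_cM),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Sample an in-silico base population of DH lines from a founder panel
#'
#' Random-mates the founder lines (no selfing) to form `n` S0 genotypes under
#' the restriction that no founder contributes more than
#' `max_gametes_per_founder` gametes per parental role (at most `cap` S0 as
#' seed parent and at most `cap` as pollen parent), then simulates meiosis in
#' each S0 and doubles one random gamete into a DH line. The per-role reading
#' of the cap is what makes the reference configurations feasible (e.g. a
#' male pool of 18 founders with cap 55 yields 950 S0).
#'
#' @param panel a [founder_panel].
#' @param n number of DH lines (default 950).
#' @param max_gametes_per_founder cap on gametes contributed per founder line
#'   and parental role (default 12; raise for very small panels).
#' @param seed integer seed.
#' @return An `rrgs_pop` of `n` DH individuals (sub-cycle C_1,0) with a
#'   `founder_usage` attribute (2 x founders matrix of per-role gamete
#'   counts).
#' @export
sample_base_population <- function(panel, n = 950,
                                   max_gametes_per_founder = 12, seed = 1) {
  stopifnot(inherits(panel, "founder_panel"), n >= 1)
  nf <- nrow(panel$haplo)
  cap <- max_gametes_per_founder
  if (n > nf * cap)
    stop(sprintf(paste0("infeasible gamete cap: %d founders x cap %d < %d ",
                        "matings needed; raise the cap to at least %d"),
                 nf, cap, n, ceiling(n / nf)))
  set.seed(seed)
  pairs <- draw_founder_pairs(nf, n, cap)
  cm <- map_for_cpp(panel$map)
  # founders are homozygous, so the S0 genotype is simply the two parental
  # haplotype rows; meiosis then happens in the S0 to produce the DH gamete
  s0_h1 <- panel$haplo[pairs[, 1], , drop = FALSE]
  s0_h2 <- panel$haplo[pairs[, 2], , drop = FALSE]
  gam <- cpp_gametes(s0_h1, s0_h2, seq_len(n), cm$first, cm$last, cm$pos_m)
  pop <- new_population(gam, gam, panel$pool, "DH", c(1L, 0L),
                        validate = FALSE)
  attr(pop, "founder_usage") <- rbind(tabulate(pairs[, 1], nbins = nf),
                                      tabulate(pairs[, 2], nbins = nf))
  pop
}

# sample n founder pairs (no selfing) with per-founder, per-role usage <= cap:
# draw both parental roles from capped slot pools, then repair selfing
# conflicts by swapping pollen parents between matings
draw_founder_pairs <- function(nf, n, cap) {
  draw_role <- function() sample(rep(seq_len(nf), cap), n)
  p1 <- draw_role()
  p2 <- draw_role()
  for (attempt in 1:1000) {
    bad <- which(p1 == p2)
    if (!length(bad)) return(cbind(p1, p2))
    i <- bad[1]
    j <- sample.int(n, 1)
    if (p2[j] != p1[i] && p2[i] != p1[j]) {
      tmp <- p2[i]; p2[i] <- p2[j]; p2[j] <- tmp
    }
  }
  stop("could not satisfy the gamete cap; raise max_gametes_per_founder")
}
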