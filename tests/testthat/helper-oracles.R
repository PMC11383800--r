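# Independent brute-force oracles used to pin down the statistical
# estimators. These deliberately avoid the package's own code paths.

# pi per site by enumerating all pairs of called allele copies
oracle_site_pi <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d)
    c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

oracle_watterson <- function(S, n, L) {
  a <- 0
  for (i in 1:(n - 1)) a <- a + 1 / i
  S / a / L
}

# Tajima's D from first principles (Tajima 1989 constants, re-derived)
oracle_tajima_d <- function(pi_sum, S, n) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# WC84 theta via the ANOVA (method-of-moments) sums-of-squares route,
# a parameterisation independent of the component formulas in R/popgen.R.
oracle_wc_fst <- function(dosages, pops) {
  keep <- !is.na(dosages)
  dosages <- dosages[keep]; pops <- factor(pops[keep])
  pops <- droplevels(pops)
  r <- nlevels(pops)
  n_i <- tabulate(pops)
  p_i <- tapply(dosages, pops, function(d) sum(d) / (2 * length(d)))
  h_i <- tapply(dosages, pops, function(d) mean(d == 1))
  n_tot <- sum(n_i)
  nbar <- n_tot / r
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  pbar <- sum(n_i * p_i) / n_tot
  hbar <- sum(n_i * h_i) / n_tot
  MSP <- sum(n_i * (p_i - pbar)^2) * 2 / (r - 1)          # among pops
  MSI <- (sum(n_i * p_i * (1 - p_i)) * 2 - sum(n_i * h_i) / 2) /
    (n_tot - r)                                            # ind within pop
  MSG <- hbar / 2                                          # within ind
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# exact signed-rank two-sided p by full enumeration of sign assignments
oracle_signed_rank <- function(deltas) {
  nz <- deltas[deltas != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(r[signs == 1])
  }
  lo <- mean(vs <= v_obs); hi <- mean(vs >= v_obs)
  list(statistic = v_obs, p = min(1, 2 * min(lo, hi)))
}

# two-sided Fisher p by enumeration over all tables with fixed margins
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small helper: toy variant_set from a dosage matrix
toy_vs <- function(geno, chrom = "1", pos = NULL) {
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%02d", seq_len(ncol(geno)))
  if (is.null(pos)) pos <- seq_len(nrow(geno))
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "T")
  variant_set(sites, geno)
}

# random dosage matrix (homozygous-biased, some missing)
random_geno <- function(n_sites, n_samples, p_missing = 0.05) {
  g <- matrix(sample(c(0L, 1L, 2L), n_sites * n_samples, replace = TRUE,
                     prob = c(0.5, 0.2, 0.3)),
              nrow = n_sites)
  g[runif(length(g)) < p_missing] <- NA_integer_
  colnames(g) <- sprintf("S%02d", seq_len(n_samples))
  g
}
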