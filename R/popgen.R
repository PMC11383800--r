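#' Per-site nucleotide diversity
#'
#' Computes the per-polymorphic-site heterozygosity
#' \eqn{\pi = c_{ref} c_{alt} / \binom{n}{2}} from called allele copies,
#' where `n` is the number of called allele copies at the site (two per
#' called diploid genotype). This is the expected pairwise difference at
#' the site among sampled chromosomes.
#'
#' @param dosages integer vector of per-sample alternative-allele dosages
#'   in {0, 1, 2, NA}.
#' @return per-site diversity in `[0, 1]`; NA if fewer than 2 allele copies
#'   are called.
#' @export
site_pi <- function(dosages) {
  called <- !is.na(dosages)
  n <- 2 * sum(called)
  if (n < 2) return(NA_real_)
  c_alt <- sum(dosages[called])
  c_ref <- n - c_alt
  c_ref * c_alt / choose(n, 2)
}

#' Matrix version of [site_pi()]
#' @param geno sites x samples dosage matrix.
#' @return numeric vector of per-site diversity values.
#' @export
site_pi_all <- function(geno) apply(geno, 1, site_pi)

#' Per-gene nucleotide-diversity summaries
#'
#' Two complementary summaries: the maximum per-site \eqn{\pi} within the
#' gene, and \eqn{\pi}/bp computed as the sum of all site \eqn{\pi} values
#' divided by the gene's genomic length (positions without a SNP are taken
#' as invariant, contributing 0 to the sum).
#'
#' @param pi_values per-site diversity of the gene's SNPs (possibly empty).
#' @param gene_length gene genomic length in bp.
#' @return list with `pi_max_site` and `pi_per_bp` (both 0 for a gene
#'   without SNPs).
#' @export
gene_pi_summary <- function(pi_values, gene_length) {
  stopifnot(gene_length >= 1)
  pi_values <- pi_values[is.finite(pi_values)]
  if (length(pi_values) == 0) return(list(pi_max_site = 0, pi_per_bp = 0))
  list(pi_max_site = max(pi_values),
       pi_per_bp = sum(pi_values) / gene_length)
}

#' Watterson's theta per base pair
#'
#' \eqn{\theta_W / bp = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i},
#' `S` segregating sites, `n` sequences (chromosomes), `L` length in bp.
#'
#' @param S number of segregating sites.
#' @param n number of sequences.
#' @param L sequence length in bp.
#' @return per-bp estimate.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, L >= 1)
  if (n < 2) stop("watterson_theta requires n >= 2 sequences")
  S / (sum(1 / seq_len(n - 1)) * L)
}

# Tajima (1989) constants for sample size n (chromosomes).
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from window summaries
#'
#' \eqn{D = (\hat{k} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} with the
#' standard constants of Tajima (1989), where \eqn{\hat{k}} is the sum of
#' per-site pairwise diversities over the window and `S` the number of
#' segregating sites.
#'
#' @param pi_sum sum of per-site \eqn{\pi} over the window.
#' @param S segregating sites in the window.
#' @param n number of sequences (chromosomes).
#' @return D, or NA when `S` = 0 or `n` < 4 (variance terms unstable).
#' @export
tajima_d <- function(pi_sum, S, n) {
  if (n < 4) {
    warning("Tajima's D undefined for n < 4 sequences")
    return(NA_real_)
  }
  if (S == 0) return(NA_real_)
  k <- .tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed Tajima's D over a variant set
#'
#' Non-overlapping windows of `window_bp` anchored at position 1 on each
#' chromosome (window `w` covers positions `[(w-1)*window_bp + 1,
#' w*window_bp]`). Within a window, `S` counts polymorphic sites (both
#' alleles observed among called genotypes) and the pairwise-diversity sum
#' uses [site_pi()]. Sample size for the constants is twice the number of
#' samples in the set. Windows containing no variant records are absent
#' from the output; windows whose sites are all monomorphic get NA.
#'
#' @param vs a [variant_set()] for a single population.
#' @param window_bp window size in bp (default 100).
#' @return data.frame `chrom`, `window`, `start`, `end` (1-based inclusive),
#'   `n_snps`, `S`, `D`.
#' @export
tajima_d_windows <- function(vs, window_bp = 100) {
  stopifnot(window_bp > 0)
  n <- 2 * ncol(vs$geno)
  pi_site <- site_pi_all(vs$geno)
  mac <- .alt_mac(vs$geno, "alleles")
  ncalled <- 2 * rowSums(!is.na(vs$geno))
  seg <- mac > 0 & mac < ncalled
  win <- (vs$sites$pos - 1L) %/% window_bp
  key <- paste(vs$sites$chrom, win)
  idx <- split(seq_len(n_sites(vs)), key)
  rows <- lapply(idx, function(ii) {
    S <- sum(seg[ii])
    D <- if (n < 4) NA_real_ else
      tajima_d(sum(pi_site[ii][seg[ii]], na.rm = TRUE), S, n)
    data.frame(chrom = vs$sites$chrom[ii[1]],
               window = win[ii[1]] + 1L,
               start = win[ii[1]] * window_bp + 1L,
               end = (win[ii[1]] + 1L) * window_bp,
               n_snps = length(ii), S = S, D = D)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$window), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean Tajima's D per gene
#'
#' Each SNP inherits the D of the window containing it; the gene value is
#' the mean over the gene's SNPs with a defined D (so windows holding more
#' of the gene's SNPs weigh more).
#'
#' @param windows output of [tajima_d_windows()].
#' @param snp_chrom,snp_pos coordinates of the gene's SNPs.
#' @param window_bp the window size used.
#' @return mean D, or NA when no SNP has a defined D.
#' @export
gene_tajima_mean <- function(windows, snp_chrom, snp_pos, window_bp = 100) {
  w <- (snp_pos - 1L) %/% window_bp + 1L
  key <- paste(snp_chrom, w)
  wkey <- paste(windows$chrom, windows$window)
  d <- windows$D[match(key, wkey)]
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

#' Weir & Cockerham (1984) per-SNP F_ST
#'
#' Computes the variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) from diploid
#' genotype counts and returns \eqn{\theta = a/(a+b+c)}. Estimates may be
#' negative and are retained as such.
#'
#' @param dosages integer vector of dosages in {0, 1, 2, NA}.
#' @param pops factor/vector of population labels, parallel to `dosages`.
#' @return per-SNP F_ST estimate; NA when `a+b+c` is 0 (e.g. monomorphic).
#' @export
wc_fst_site <- function(dosages, pops) {
  pops <- factor(pops)
  if (nlevels(pops) < 2) stop("wc_fst_site requires >= 2 populations")
  called <- !is.na(dosages)
  dosages <- dosages[called]; pops <- droplevels(pops[called])
  if (nlevels(pops) < 2) stop("need >= 2 populations with called genotypes")
  n_i <- as.numeric(table(pops))
  r <- length(n_i)
  p_i <- tapply(dosages, pops, function(d) mean(d) / 2)
  h_i <- tapply(dosages, pops, function(d) mean(d == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(NA_real_)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  if (tot == 0) return(NA_real_)
  a / tot
}

#' Per-SNP F_ST over a variant set
#'
#' @param vs a [variant_set()].
#' @param pops population labels, one per sample (NA samples excluded).
#' @return numeric vector of per-SNP Weir-Cockerham estimates.
#' @export
wc_fst <- function(vs, pops) {
  keep <- !is.na(pops)
  geno <- vs$geno[, keep, drop = FALSE]
  pops <- pops[keep]
  apply(geno, 1, wc_fst_site, pops = pops)
}

#' Mean per-gene F_ST
#'
#' The gene value is the mean of the per-SNP ratio estimates (negatives
#' retained), not a ratio of summed components.
#'
#' @param fst_site per-SNP estimates (from [wc_fst()]).
#' @param site_index indices of the gene's SNPs.
#' @return mean F_ST, NA if no SNP has a defined estimate.
#' @export
gene_fst_mean <- function(fst_site, site_index) {
  v <- fst_site[site_index]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Population assignment by k-means with silhouette-selected k
#'
#' Standardises the feature matrix (zero mean, unit variance per column),
#' runs a k-means clustering for each k in `k_range`, computes the mean
#' silhouette width, and keeps the k with the highest score; the final
#' labels come from a single k-means run at that k under `seed`. Values of
#' k not smaller than the number of samples are skipped.
#'
#' @param features numeric matrix, samples x features, complete cases only.
#' @param k_range candidate cluster counts (default 2:15).
#' @param seed RNG seed (labels are deterministic given it).
#' @return list with `labels` (named by rownames of `features`), `k`,
#'   `silhouette` (named vector of mean widths per k) and `scheme`.
#' @param scheme label recorded in the result (e.g. `"climate"`).
#' @export
kmeans_populations <- function(features, k_range = 2:15, seed = 1,
                               scheme = "climate") {
  features <- as.matrix(features)
  stopifnot(all(is.finite(features)))
  x <- scale(features)
  x[, attr(x, "scaled:scale") == 0] <- 0
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0) stop("no usable k in k_range for ", n, " samples")
  d <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    set.seed(seed + k)
    cl <- stats::kmeans(x, centers = k)$cluster
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  best_k <- k_range[which.max(sil)]
  set.seed(seed + best_k)
  labels <- stats::kmeans(x, centers = best_k)$cluster
  names(labels) <- rownames(features)
  list(labels = labels, k = best_k, silhouette = sil, scheme = scheme)
}

#' Per-gene population-genetics summary table
#'
#' Bundles SNP count, SNPs/bp, the two \eqn{\pi} summaries, \eqn{\theta_W}/bp,
#' the SNP-weighted mean windowed Tajima's D, and (optionally) mean per-gene
#' F_ST under one or more population schemes.
#'
#' @param vs a [variant_set()].
#' @param assignment SNP-to-gene assignment ([assign_snps_to_genes()]).
#' @param genes gene-model data.frame; one output row per gene.
#' @param pop_schemes named list of per-sample population label vectors;
#'   each adds a `fst_<name>` column.
#' @param window_bp Tajima window size (default 100).
#' @return data.frame of per-gene statistics.
#' @export
gene_pop_stats <- function(vs, assignment, genes, pop_schemes = list(),
                           window_bp = 100) {
  pi_site <- site_pi_all(vs$geno)
  n_seq <- 2 * ncol(vs$geno)
  wins <- tajima_d_windows(vs, window_bp)
  fst <- lapply(pop_schemes, function(p) wc_fst(vs, p))
  by_gene <- split(assignment$site, assignment$gene_id)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]; L <- genes$length[i]
    idx <- by_gene[[gid]]
    S <- length(idx)
    pis <- gene_pi_summary(pi_site[idx], L)
    row <- data.frame(
      gene_id = gid, snp_count = S, snps_per_bp = S / L,
      pi_max_site = pis$pi_max_site, pi_per_bp = pis$pi_per_bp,
      theta_w_per_bp = if (n_seq >= 2) watterson_theta(S, n_seq, L) else NA,
      tajima_d_mean = if (S > 0)
        gene_tajima_mean(wins, vs$sites$chrom[idx], vs$sites$pos[idx],
                         window_bp) else NA_real_)
    for (nm in names(fst))
      row[[paste0("fst_", nm)]] <-
        if (S > 0) gene_fst_mean(fst[[nm]], idx) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
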