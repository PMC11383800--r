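test_that("per-site pi matches combinatorial enumeration", {
  expect_equal(site_pi(c(0L, 2L)), 4 / 6)         # 2 ref + 2 alt copies
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)         # monomorphic
  expect_equal(site_pi(c(1L)), 1)                 # one het: n=2, one of each
  expect_true(is.na(site_pi(c(NA_integer_))))     # < 2 called alleles
  set.seed(3)
  for (i in 1:20) {
    d <- sample(c(0L, 1L, 2L, NA), 8, replace = TRUE)
    expect_equal(site_pi(d), oracle_site_pi(d))
  }
})

test_that("gene pi summaries: max site value and sum over gene length", {
  s <- gene_pi_summary(c(0.5, 0.1), 1000)
  expect_equal(s$pi_max_site, 0.5)
  expect_equal(s$pi_per_bp, 0.0006)
  expect_equal(gene_pi_summary(numeric(0), 500), list(pi_max_site = 0,
                                                      pi_per_bp = 0))
})

test_that("Watterson's theta follows the harmonic scaling", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(5, 2, 1000), 0.005)      # a1 = 1
  expect_equal(watterson_theta(10, 5, 100),
               10 / (sum(1 / 1:4) * 100))
  expect_error(watterson_theta(1, 1, 100), "n >= 2")
})

test_that("pi, theta and Tajima's D match brute-force oracles on random matrices", {
  set.seed(101)
  for (rep in 1:50) {
    g <- random_geno(20, 10, p_missing = 0)
    n <- 2 * ncol(g)
    pi_pkg <- site_pi_all(g)
    pi_ora <- apply(g, 1, oracle_site_pi)
    expect_equal(pi_pkg, pi_ora, tolerance = 1e-10)

    mac <- rowSums(g)
    seg <- mac > 0 & mac < n
    S <- sum(seg)
    expect_equal(watterson_theta(S, n, 20), oracle_watterson(S, n, 20),
                 tolerance = 1e-10)
    expect_equal(tajima_d(sum(pi_pkg[seg]), S, n),
                 oracle_tajima_d(sum(pi_ora[seg]), S, n),
                 tolerance = 1e-10)
  }
})

test_that("windowed Tajima's D anchors windows at position 1 and flags S=0", {
  # n = 4 haplotypes as two homozygous diploids: {0011} pattern per site
  g <- cbind(A = c(0L, 0L, 2L), B = c(2L, 2L, 0L))
  vs <- toy_vs(g, pos = c(10, 50, 150))
  w <- tajima_d_windows(vs, window_bp = 100)
  expect_equal(w$window, c(1, 2))
  expect_equal(w$start, c(1, 101))
  expect_equal(w$S, c(2, 1))
  expect_equal(w$D[1], oracle_tajima_d(2 * oracle_site_pi(c(0L, 2L)), 2, 4))

  # monomorphic window -> NA
  g2 <- cbind(A = 0L, B = 0L)
  vs2 <- toy_vs(g2, pos = 5)
  expect_true(is.na(tajima_d_windows(vs2, 100)$D))

  # n < 4 chromosomes: warning and NA
  expect_warning(d <- tajima_d(0.5, 1, 3), "n < 4")
  expect_true(is.na(d))
})

test_that("an all-singleton window yields negative D", {
  # 10 samples, every site a singleton carrier
  g <- matrix(0L, 5, 10, dimnames = list(NULL, sprintf("S%02d", 1:10)))
  for (i in 1:5) g[i, i] <- 2L
  vs <- toy_vs(g, pos = 1:5)
  w <- tajima_d_windows(vs, 100)
  expect_lt(w$D, 0)
  expect_equal(w$D, oracle_tajima_d(sum(apply(g, 1, oracle_site_pi)), 5, 20))
})

test_that("gene Tajima mean is the SNP-weighted window mean", {
  wins <- data.frame(chrom = "1", window = c(1, 2), start = c(1, 101),
                     end = c(100, 200), n_snps = c(2, 1), S = c(2, 1),
                     D = c(1, -1))
  expect_equal(gene_tajima_mean(wins, rep("1", 2), c(10, 20)), 1)
  expect_equal(gene_tajima_mean(wins, rep("1", 2), c(10, 110)), 0)
  # uneven SNP counts per window: weighted by SNPs
  expect_equal(gene_tajima_mean(wins, rep("1", 3), c(10, 20, 110)), 1 / 3)
  expect_true(is.na(gene_tajima_mean(wins, "1", 500)))
})

test_that("Weir-Cockerham F_ST matches the ANOVA oracle and its invariances", {
  # complete fixation
  d <- c(rep(0L, 5), rep(2L, 5))
  pops <- rep(c("a", "b"), each = 5)
  expect_equal(wc_fst_site(d, pops), 1)

  # one population duplicated as two: theta <= 0 (no among-pop variance)
  set.seed(5)
  d1 <- sample(c(0L, 1L, 2L), 8, replace = TRUE, prob = c(.4, .2, .4))
  expect_lte(wc_fst_site(c(d1, d1), rep(c("x", "y"), each = 8)), 1e-12)

  for (rep in 1:50) {
    d <- sample(c(0L, 1L, 2L, NA), 30, replace = TRUE,
                prob = c(.4, .15, .4, .05))
    pops <- sample(c("p1", "p2", "p3"), 30, replace = TRUE)
    pkg <- wc_fst_site(d, pops)
    ora <- oracle_wc_fst(d, pops)
    expect_equal(pkg, ora, tolerance = 1e-10)
    # relabeling invariance
    relab <- c(p1 = "z", p2 = "q", p3 = "m")[pops]
    expect_equal(wc_fst_site(d, relab), pkg, tolerance = 1e-12)
    # ref/alt swap invariance
    if (!is.na(pkg))
      expect_equal(wc_fst_site(2L - d, pops), pkg, tolerance = 1e-12)
  }

  expect_error(wc_fst_site(c(0L, 2L), c("a", "a")), "2 populations")
})

test_that("neutral-spectrum simulation gives mean D near zero", {
  # coalescent-free: draw derived-allele counts from the neutral site
  # frequency spectrum P(i) proportional to 1/i, for which the expected
  # per-site pi equals 1/a1, so E[pi_sum - S/a1] = 0
  set.seed(21)
  n <- 40; S <- 50
  spectrum <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  ds <- replicate(400, {
    i <- sample(1:(n - 1), S, replace = TRUE, prob = spectrum)
    pi_sum <- sum(i * (n - i) / choose(n, 2))
    tajima_d(pi_sum, S, n)
  })
  expect_lt(abs(mean(ds)), 3 * sd(ds) / sqrt(length(ds)))
})

test_that("k-means population construction picks k by silhouette", {
  set.seed(8)
  blobs <- rbind(matrix(rnorm(60, 0), ncol = 2),
                 matrix(rnorm(60, 8), ncol = 2))
  rownames(blobs) <- sprintf("S%02d", 1:60)
  pa <- kmeans_populations(blobs, k_range = 2:15, seed = 4)
  expect_equal(pa$k, 2)
  expect_equal(length(unique(pa$labels)), 2)
  # the two blobs separate perfectly
  expect_equal(length(unique(pa$labels[1:30])), 1)
  expect_equal(length(unique(pa$labels[31:60])), 1)

  # determinism under seed
  pa2 <- kmeans_populations(blobs, k_range = 2:15, seed = 4)
  expect_identical(pa$labels, pa2$labels)

  # k values >= sample count are skipped
  tiny <- matrix(rnorm(6), ncol = 2,
                 dimnames = list(c("a", "b", "c"), NULL))
  pa3 <- kmeans_populations(tiny, k_range = 2:15, seed = 1)
  expect_true(all(as.integer(names(pa3$silhouette)) < 3))
})

test_that("per-gene stats bundle matches direct summation", {
  set.seed(31)
  cfg <- synth_config(seed = 31, n_hist = 8, n_mod = 8, n_focus_genes = 4,
                      n_effect_genes = 2, n_increase = 1, pool_size = 12,
                      snps_per_gene = 5)
  st <- generate_study(cfg, climate = FALSE)
  vs <- st$variants
  asn <- assign_snps_to_genes(vs, st$genes)
  epoch <- st$samples$epoch[match(vs_samples(vs), st$samples$sample_id)]
  gs <- gene_pop_stats(vs, asn, st$genes,
                       pop_schemes = list(epoch = epoch))
  g1 <- st$genes$gene_id[1]
  idx <- asn$site[asn$gene_id == g1]
  L <- st$genes$length[1]
  expect_equal(gs$snp_count[1], length(idx))
  expect_equal(gs$snps_per_bp[1], length(idx) / L)
  pis <- apply(vs$geno[idx, , drop = FALSE], 1, oracle_site_pi)
  expect_equal(gs$pi_max_site[1], max(pis))
  expect_equal(gs$pi_per_bp[1], sum(pis) / L)
  fst <- sapply(idx, function(i) oracle_wc_fst(vs$geno[i, ], epoch))
  expect_equal(gs$fst_epoch[1], mean(fst, na.rm = TRUE), tolerance = 1e-10)
})
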