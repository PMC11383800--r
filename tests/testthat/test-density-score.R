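# small scored cohort: 3 genes (+1, +1, -1), hand-placed functional SNPs
scored_fixture <- function() {
  geno <- rbind(
    c(0L, 2L, 0L, 2L),  # G1 NONSYN
    c(0L, 2L, 0L, 0L),  # G1 LOF (duplicate carriage for S2)
    c(0L, 0L, 2L, NA),  # G2 NONSYN; missing for S4
    c(2L, 0L, 0L, 0L),  # G2 SYN (must never count)
    c(0L, 0L, 2L, 2L))  # G3 LOF
  colnames(geno) <- c("S1", "S2", "S3", "S4")
  vs <- toy_vs(geno)
  asn <- data.frame(site = 1:5,
                    gene_id = c("G1", "G1", "G2", "G2", "G3"),
                    class = c("NONSYN", "LOF", "NONSYN", "SYN", "LOF"))
  eff <- data.frame(gene_id = c("G1", "G2", "G3"),
                    effect = c(1L, 1L, -1L))
  list(vs = vs, asn = asn, eff = eff)
}

test_that("functional indicator counts any functional carriage once per gene", {
  f <- scored_fixture()
  ind <- functional_indicator(f$vs, f$asn, c("G1", "G2", "G3"))
  expect_equal(ind["S1", ], c(G1 = 0L, G2 = 0L, G3 = 0L))  # SYN only
  expect_equal(ind["S2", "G1"], 1L)  # two functional SNPs still 1
  expect_equal(ind["S4", "G2"], 0L)  # missing genotype is not carriage
  # S3 carries G2 (+1) and G3 (-1): they cancel; S4 carries G1 (+1) and
  # G3 (-1): cancel; S2 carries G1 twice, counted once
  sc <- density_score(f$vs, f$asn, f$eff)
  expect_equal(sc$score, c(0L, 1L, 0L, 0L))
})

test_that("scoring is invariant to SNP order and functional duplication", {
  f <- scored_fixture()
  sc <- density_score(f$vs, f$asn, f$eff)$score
  perm <- sample(1:5)
  vs2 <- vs_subset(f$vs, sites = perm)
  asn2 <- f$asn[perm, ]; asn2$site <- order(perm)[asn2$site]
  # re-map: site i of vs2 is old site perm[i]
  asn3 <- f$asn; asn3$site <- match(f$asn$site, perm)
  expect_equal(density_score(vs2, asn3, f$eff)$score, sc)
  # duplicating a functional SNP changes nothing
  vs3 <- vs_subset(f$vs, sites = c(1:5, 1L))
  asn4 <- rbind(f$asn, data.frame(site = 6, gene_id = "G1",
                                  class = "NONSYN"))
  expect_equal(density_score(vs3, asn4, f$eff)$score, sc)
})

test_that("flipping all effect labels negates scores and deltas", {
  set.seed(12)
  cfg <- synth_config(seed = 12, n_hist = 10, n_mod = 10, n_focus_genes = 8,
                      n_effect_genes = 6, n_increase = 3, pool_size = 20)
  st <- generate_study(cfg, climate = FALSE)
  asn <- assign_snps_to_genes(st$variants, st$genes)
  sc1 <- density_score(st$variants, asn, st$effects)
  eff2 <- st$effects; eff2$effect <- -eff2$effect
  sc2 <- density_score(st$variants, asn, eff2)
  expect_equal(sc2$score, -sc1$score)
})

test_that("signed-rank test matches full enumeration, drops zeros, handles ties", {
  cases <- list(c(-2, -1, -1, -1, 1),
                c(3, -1, 2, -2, 4),
                c(-1, -1, -1, 2, 2),
                c(0.5, -0.5, 1.5, 2.5, -1.5, 1),
                c(-3, -2, -2, 1, 1, 1, 4))
  for (d in cases) {
    pkg <- signed_rank_test(d)
    ora <- oracle_signed_rank(d)
    expect_equal(pkg$statistic, ora$statistic)
    expect_equal(pkg$p, ora$p, tolerance = 1e-12)
  }
  # zeros dropped
  expect_equal(signed_rank_test(c(0, -2, -1, -1, -1, 1, 0))$p,
               oracle_signed_rank(c(-2, -1, -1, -1, 1))$p)
  # all zeros: undefined
  expect_true(is.na(signed_rank_test(c(0, 0, 0))$p))
  # symmetric +/-1: p = 1
  expect_equal(signed_rank_test(rep(c(1, -1), 6))$p, 1)
  # large-n path agrees with the exact path to a few percent
  set.seed(6)
  d <- sample(c(-3:-1, 1:2), 24, replace = TRUE)
  exact <- signed_rank_test(d, exact_max = 25)$p
  approx <- signed_rank_test(d, exact_max = 10)$p
  expect_lt(abs(exact - approx) / exact, 0.2)
})

test_that("delta summary subtracts historical from modern scores", {
  pairs <- data.frame(hist_id = c("h1", "h2"), mod_id = c("m1", "m2"))
  scores <- data.frame(sample_id = c("h1", "h2", "m1", "m2"),
                       score = c(2L, -1L, 0L, 1L))
  dw <- delta_and_wilcoxon(pairs, scores)
  expect_equal(dw$deltas$delta, c(-2, 2))
  expect_equal(dw$mean_delta, 0)
  expect_error(delta_and_wilcoxon(
    pairs, scores[1:3, ]), "unscored")
})

test_that("effect-label permutations preserve composition and include identity", {
  set.seed(13)
  cfg <- synth_config(seed = 13, n_hist = 12, n_mod = 12, n_focus_genes = 10,
                      n_effect_genes = 8, n_increase = 5, pool_size = 20)
  st <- generate_study(cfg, climate = FALSE)
  asn <- assign_snps_to_genes(st$variants, st$genes)
  s <- st$samples
  pairs <- pair_samples(s[s$epoch == "historical", ], s[s$epoch == "modern", ],
                        max_km = 1e6)
  pm <- permute_effect_labels(st$variants, asn, st$effects, pairs,
                              n_perm = 50, seed = 2)
  expect_length(pm$null_means, 50)
  expect_true(pm$rank >= 0 && pm$rank <= 50)
  # reproducibility under seed
  pm2 <- permute_effect_labels(st$variants, asn, st$effects, pairs,
                               n_perm = 50, seed = 2)
  expect_identical(pm$null_means, pm2$null_means)

  # identity permutation: applying the observed labels reproduces the
  # observed mean delta through the same linear path
  sc <- density_score(st$variants, asn, st$effects)
  dw <- delta_and_wilcoxon(pairs, sc)
  expect_equal(pm$observed_mean_delta, dw$mean_delta, tolerance = 1e-12)

  # null means all arise from the same +1/-1 composition: each null mean
  # must be attainable as dind . e for some label shuffle; check parity via
  # the global-flip bound |null| <= sum |dind|
  ind <- attr(sc, "indicator")
  ih <- match(pairs$hist_id, rownames(ind))
  im <- match(pairs$mod_id, rownames(ind))
  dind <- colMeans(ind[im, , drop = FALSE]) - colMeans(ind[ih, , drop = FALSE])
  expect_true(all(abs(pm$null_means) <= sum(abs(dind)) + 1e-12))
})

test_that("permutation rank is calibrated under a null generator", {
  # labels irrelevant at generation time: the observed mean delta is
  # exchangeable with the permuted ones, so its tie-smoothed rank is
  # uniform on (0, 1)
  set.seed(14)
  u <- replicate(60, {
    cfg <- synth_config(seed = sample.int(1e6, 1), n_hist = 10, n_mod = 10,
                        n_focus_genes = 8, n_effect_genes = 6,
                        n_increase = 3, pool_size = 16, shift_delta = 0)
    st <- generate_study(cfg, climate = FALSE)
    asn <- assign_snps_to_genes(st$variants, st$genes)
    s <- st$samples
    pairs <- pair_samples(s[s$epoch == "historical", ],
                          s[s$epoch == "modern", ], max_km = 1e6)
    pm <- permute_effect_labels(st$variants, asn, st$effects, pairs,
                                n_perm = 20, seed = sample.int(1e6, 1))
    n_lt <- sum(pm$null_means < pm$observed_mean_delta - 1e-12)
    n_eq <- sum(abs(pm$null_means - pm$observed_mean_delta) <= 1e-12)
    (n_lt + runif(1) * (1 + n_eq)) / (pm$n_perm + 1)
  })
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("Fisher odds of decrease match the hypergeometric oracle", {
  # symmetric table
  f <- fisher_odds(deltas = c(-1, 1, -1, 1), in_group = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(f$p, 1)
  # zero cell -> infinite conditional MLE
  f2 <- fisher_odds(deltas = c(rep(-1, 5), rep(1, 4), rep(-1, 3)),
                    in_group = c(rep(TRUE, 5), rep(FALSE, 7)))
  expect_equal(unname(f2$table["group", ]), c(5, 0))
  expect_true(is.infinite(f2$odds_ratio))
  expect_equal(f2$p, oracle_fisher_p(f2$table), tolerance = 1e-9)
  # [[10,5],[5,10]] against the fixed-margin enumeration and stats oracle
  deltas <- c(rep(-1, 10), rep(1, 5), rep(-1, 5), rep(1, 10))
  grp <- rep(c(TRUE, FALSE), each = 15)
  f3 <- fisher_odds(deltas, grp)
  expect_equal(unname(f3$table), rbind(c(10, 5), c(5, 10)))
  expect_equal(f3$p, oracle_fisher_p(f3$table), tolerance = 1e-9)
  # zero margin: p 1, OR undefined
  f4 <- fisher_odds(c(-1, -1), c(TRUE, FALSE))
  expect_true(is.na(f4$odds_ratio))
  expect_equal(f4$p, 1)
})

test_that("latitude correlation: exact line, subsampling, degenerate inputs", {
  samples <- data.frame(
    sample_id = c(sprintf("h%d", 1:10), sprintf("m%d", 1:30)),
    epoch = rep(c("historical", "modern"), c(10, 30)),
    lat = c(seq(40, 58, 2), seq(40, 63.2, 0.8)))
  # score equal to latitude: r = 1 in both sets
  scores <- data.frame(sample_id = samples$sample_id, score = samples$lat)
  lc <- latitude_correlation(scores, samples, n_subsamples = 20, seed = 5)
  expect_equal(lc$historical$r, 1)
  expect_equal(lc$modern$mean_r, 1)
  expect_equal(lc$modern$n_per_draw, 10)
  # intercept re-expressed at the median latitude equals the median score
  expect_equal(lc$historical$intercept_at_median,
               median(samples$lat[1:10]))
  # permuted scores: mean r near zero
  set.seed(9)
  scores2 <- scores
  scores2$score <- sample(scores$score)
  lc2 <- latitude_correlation(scores2, samples, n_subsamples = 50, seed = 5)
  expect_lt(abs(lc2$modern$mean_r), 0.35)
  # constant score: undefined r
  scores3 <- scores; scores3$score <- 1
  lc3 <- latitude_correlation(scores3, samples, n_subsamples = 5, seed = 1)
  expect_true(is.na(lc3$historical$r))
})

test_that("delta-vs-climate regression recovers group means exactly", {
  cls <- rep(c("matching_increase", "matching_decrease", "unmatched"),
             each = 4)
  deltas <- c(rep(-1, 4), rep(1, 4), rnorm(4))
  # exact fits make summary.lm warn about perfect residuals; irrelevant here
  reg <- suppressWarnings(delta_vs_climate_regression(deltas, cls))
  co <- reg$coefficients
  expect_equal(unname(co[1, 1]), -1)       # increase-group mean
  expect_equal(unname(co[2, 1]), 2)        # decrease - increase contrast
  expect_lt(reg$p_model, 1e-10)
  expect_equal(reg$n_per_level, c(4L, 4L))
  # all-equal deltas: zero contrast
  reg2 <- suppressWarnings(delta_vs_climate_regression(rep(2, 8), cls[1:8]))
  expect_equal(unname(reg2$coefficients[2, 1]), 0)
  # a level with < 2 pairs errors and names the level
  expect_error(delta_vs_climate_regression(
    c(-1, -1, 1), c("matching_increase", "matching_increase",
                    "matching_decrease")), "matching_decrease")
})
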