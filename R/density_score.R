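#' Read a gene-effect table
#'
#' TSV with columns `gene_id`, `effect` (+1 / -1 / 0) and optionally
#' `note`. The packaged study fixture
#' (`system.file("extdata", "stomatal_gene_effects_synthetic.tsv",
#' package = "stomatrend")`) holds 43 stomatal-development genes of which
#' 24 have a known density effect: loss of 14 increases (+1) and loss of 10
#' decreases (-1) stomatal density.
#'
#' @param path TSV path.
#' @return data.frame `gene_id`, `effect`, `note`.
#' @export
read_gene_effects <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "effect") %in% names(tab)),
            all(tab$effect %in% c(-1L, 0L, 1L)))
  if (is.null(tab$note)) tab$note <- NA_character_
  tab
}

#' Functional-variant indicator matrix
#'
#' For every sample and gene: 1 iff the sample carries at least one
#' alternative allele (dosage >= 1) at any putatively functional SNP —
#' effect class LOF or NONSYN — assigned to that gene; otherwise 0.
#' Missing genotypes never count as carriage. Multiple functional SNPs in
#' one gene still yield a single 1.
#'
#' @param vs a [variant_set()].
#' @param assignment SNP-to-gene assignment ([assign_snps_to_genes()]).
#' @param genes character vector of gene ids (columns of the result).
#' @param functional_classes classes counted as protein-function affecting
#'   (default `c("LOF", "NONSYN")`).
#' @param dosage_weighted if TRUE, return the summed dosage over the gene's
#'   functional SNPs instead of the 0/1 indicator.
#' @return integer matrix samples x genes.
#' @export
functional_indicator <- function(vs, assignment, genes,
                                 functional_classes = c("LOF", "NONSYN"),
                                 dosage_weighted = FALSE) {
  fun <- assignment[assignment$class %in% functional_classes &
                      assignment$gene_id %in% genes, , drop = FALSE]
  out <- matrix(0L, nrow = ncol(vs$geno), ncol = length(genes),
                dimnames = list(vs_samples(vs), genes))
  for (g in unique(fun$gene_id)) {
    idx <- fun$site[fun$gene_id == g]
    sub <- vs$geno[idx, , drop = FALSE]
    out[, g] <- if (dosage_weighted) colSums(sub, na.rm = TRUE)
    else as.integer(colSums(sub >= 1, na.rm = TRUE) > 0)
  }
  out
}

#' Cumulative functional stomatal-density score
#'
#' Per sample: the sum over genes with a nonzero density effect of
#' `effect x indicator`, where the indicator marks carriage of any
#' functional (LOF or non-synonymous) variant in the gene and the effect is
#' +1 for genes whose loss increases stomatal density and -1 for genes
#' whose loss decreases it. The all-reference (Col-0-like) sample scores 0.
#'
#' @param vs a [variant_set()].
#' @param assignment SNP-to-gene assignment.
#' @param effects gene-effect data.frame (`gene_id`, `effect`).
#' @param ... passed to [functional_indicator()].
#' @return data.frame `sample_id`, `score`, plus the indicator matrix in
#'   the `"indicator"` attribute (samples x nonzero-effect genes).
#' @export
density_score <- function(vs, assignment, effects, ...) {
  eff <- effects[effects$effect != 0, , drop = FALSE]
  ind <- functional_indicator(vs, assignment, eff$gene_id, ...)
  score <- as.integer(ind %*% eff$effect)
  out <- data.frame(sample_id = vs_samples(vs), score = score)
  attr(out, "indicator") <- ind
  attr(out, "effects") <- stats::setNames(eff$effect, eff$gene_id)
  out
}

# Exact two-sided signed-rank p-value with midrank ties, via the
# characteristic-generating-function DP over 2x the (possibly half-integer)
# ranks. Zero deltas must already be removed.
.signed_rank_exact_p <- function(deltas) {
  r2 <- round(2 * rank(abs(deltas)))
  w2 <- sum(r2[deltas > 0])
  # distribution of W2 = sum of a uniformly random subset of r2
  probs <- 1
  offset <- 0
  for (r in r2) {
    probs <- c(probs, numeric(r)) / 2 + c(numeric(r), probs) / 2
  }
  # probs[k + 1] = P(W2 = k)
  lo <- sum(probs[seq_len(w2 + 1)])
  hi <- sum(probs[seq.int(w2 + 1, length(probs))])
  min(1, 2 * min(lo, hi))
}

#' Signed-rank test of a delta vector against zero
#'
#' Wilcoxon signed-rank with the conventions: zero deltas dropped, midrank
#' ties, exact null distribution (enumerated by dynamic programming over
#' sign assignments) when at most `exact_max` nonzero deltas remain, else
#' the normal approximation with tie correction and continuity correction.
#'
#' @param deltas numeric vector.
#' @param exact_max largest nonzero-delta count for the exact path
#'   (default 25).
#' @return list `statistic` (V, sum of positive ranks), `p` (NA when all
#'   deltas are zero), `n_nonzero`, `method`.
#' @export
signed_rank_test <- function(deltas, exact_max = 25) {
  nz <- deltas[deltas != 0]
  n <- length(nz)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, n_nonzero = 0L,
                method = "undefined"))
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(nz)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = v, p = p, n_nonzero = as.integer(n), method = method)
}

#' Per-pair score deltas and signed-rank inference
#'
#' delta = score(modern) - score(historical) per pair; the mean delta and a
#' two-sided signed-rank test of the deltas against zero.
#'
#' @param pairs pair data.frame (`hist_id`, `mod_id`).
#' @param scores data.frame `sample_id`, `score` covering both pair members
#'   (scored on the shared-SNP dataset).
#' @return list with `deltas` (data.frame `hist_id`, `mod_id`, `delta`),
#'   `mean_delta`, `wilcoxon_p`, `wilcoxon_v`.
#' @export
delta_and_wilcoxon <- function(pairs, scores) {
  stopifnot(nrow(pairs) > 0)
  sh <- scores$score[match(pairs$hist_id, scores$sample_id)]
  sm <- scores$score[match(pairs$mod_id, scores$sample_id)]
  if (anyNA(sh) || anyNA(sm)) stop("unscored pair member(s)")
  delta <- sm - sh
  wt <- signed_rank_test(delta)
  list(deltas = data.frame(hist_id = pairs$hist_id, mod_id = pairs$mod_id,
                           delta = delta),
       mean_delta = mean(delta), wilcoxon_p = wt$p, wilcoxon_v = wt$statistic)
}

#' Permutation null for the gene-effect assignment
#'
#' Shuffles the effect labels across the nonzero-effect genes (preserving
#' the +1/-1 composition; genotypes and zero-effect genes untouched),
#' recomputes every sample score and the per-pair mean delta for each
#' permutation. The indicator matrix is computed once, so a permutation is
#' a relabelled inner product.
#'
#' @param vs,assignment,effects as in [density_score()].
#' @param pairs pair data.frame.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param redraw if TRUE, labels are redrawn independently and uniformly
#'   from the observed label multiset instead of shuffled (composition then
#'   only preserved in expectation).
#' @return list `observed_mean_delta`, `null_means` (length `n_perm`),
#'   `rank` (number of null means <= observed), `n_perm`.
#' @export
permute_effect_labels <- function(vs, assignment, effects, pairs,
                                  n_perm = 100, seed = 1, redraw = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  eff <- effects[effects$effect != 0, , drop = FALSE]
  if (nrow(eff) < 2) stop("need >= 2 nonzero-effect genes")
  sc <- density_score(vs, assignment, effects)
  ind <- attr(sc, "indicator")
  ih <- match(pairs$hist_id, rownames(ind))
  im <- match(pairs$mod_id, rownames(ind))
  stopifnot(!anyNA(ih), !anyNA(im))
  # mean delta as a linear function of the effect vector
  dind <- colMeans(ind[im, , drop = FALSE]) - colMeans(ind[ih, , drop = FALSE])
  observed <- sum(dind * eff$effect)
  set.seed(seed)
  null_means <- vapply(seq_len(n_perm), function(i) {
    e <- if (redraw) sample(eff$effect, replace = TRUE) else sample(eff$effect)
    sum(dind * e)
  }, numeric(1))
  list(observed_mean_delta = observed, null_means = null_means,
       rank = sum(null_means <= observed), n_perm = as.integer(n_perm))
}

#' Fisher's exact odds of density decrease under a pair split
#'
#' Builds the 2x2 table rows = (in group, not in group), columns =
#' (delta < 0, delta >= 0) and applies the two-sided exact test on the
#' hypergeometric distribution (`stats::fisher.test`, conditional
#' maximum-likelihood odds ratio). An odds ratio above 1 means the named
#' group holds relatively more score decreases.
#'
#' @param deltas numeric per-pair delta vector.
#' @param in_group logical vector: pair membership in the named group.
#' @return list `table`, `odds_ratio` (NA when undefined by a zero margin),
#'   `p`.
#' @export
fisher_odds <- function(deltas, in_group) {
  stopifnot(length(deltas) == length(in_group))
  tab <- rbind(group = c(dec = sum(in_group & deltas < 0),
                         nondec = sum(in_group & deltas >= 0)),
               other = c(dec = sum(!in_group & deltas < 0),
                         nondec = sum(!in_group & deltas >= 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Latitude correlation of the density score
#'
#' One-sided Pearson test (positive alternative) of score versus latitude.
#' The historical set is used whole; the modern set is subsampled without
#' replacement to the historical size `n_subsamples` times and per-draw
#' r and P are averaged. Regression intercepts are re-expressed at each
#' set's median latitude (the slope is unchanged; the intercept then reads
#' as the expected score at the median latitude).
#'
#' @param scores data.frame `sample_id`, `score`.
#' @param samples data.frame `sample_id`, `epoch`, `lat`.
#' @param n_subsamples modern subsample draws (default 100).
#' @param seed RNG seed for the subsampling.
#' @return list with `historical` (r, p, n, slope, intercept_at_median) and
#'   `modern` (mean_r, mean_p, n_draws, n_per_draw, slope, ...).
#' @export
latitude_correlation <- function(scores, samples, n_subsamples = 100,
                                 seed = 1) {
  d <- merge(scores, samples, by = "sample_id")
  one_set <- function(dd) {
    if (nrow(dd) < 3) stop("need >= 3 samples per set")
    if (stats::sd(dd$score) == 0 || stats::sd(dd$lat) == 0)
      return(list(r = NA_real_, p = NA_real_, n = nrow(dd),
                  slope = NA_real_, intercept_at_median = NA_real_))
    ct <- stats::cor.test(dd$score, dd$lat, alternative = "greater")
    med <- stats::median(dd$lat)
    fit <- stats::lm(score ~ I(lat - med), data = dd)
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(dd),
         slope = unname(stats::coef(fit)[2]),
         intercept_at_median = unname(stats::coef(fit)[1]))
  }
  hist <- d[d$epoch == "historical", ]
  mod <- d[d$epoch == "modern", ]
  res_h <- one_set(hist)
  n_h <- nrow(hist)
  set.seed(seed)
  draws <- lapply(seq_len(n_subsamples), function(i) {
    sub <- mod[sample.int(nrow(mod), min(n_h, nrow(mod))), ]
    one_set(sub)
  })
  rs <- vapply(draws, `[[`, numeric(1), "r")
  ps <- vapply(draws, `[[`, numeric(1), "p")
  list(historical = res_h,
       modern = list(mean_r = mean(rs, na.rm = TRUE),
                     mean_p = mean(ps, na.rm = TRUE),
                     n_draws = n_subsamples,
                     n_per_draw = min(n_h, nrow(mod)),
                     r_draws = rs, p_draws = ps))
}

#' Regression of score deltas on precipitation directionality
#'
#' Restricts pairs to the `matching_increase` and `matching_decrease`
#' climate classes and fits `delta ~ direction` by least squares with
#' treatment coding (increase is the reference level). Reports the
#' coefficient table and the whole-model F-test P.
#'
#' @param deltas per-pair delta vector.
#' @param climate_class per-pair class vector
#'   ({"matching_increase", "matching_decrease", "unmatched", NA}).
#' @return list `coefficients` (matrix), `p_model`, `n_per_level`.
#' @export
delta_vs_climate_regression <- function(deltas, climate_class) {
  keep <- climate_class %in% c("matching_increase", "matching_decrease")
  d <- data.frame(delta = deltas[keep],
                  direction = factor(climate_class[keep],
                                     levels = c("matching_increase",
                                                "matching_decrease")))
  n_lev <- table(d$direction)
  if (any(n_lev < 2))
    stop("fewer than 2 pairs in level(s): ",
         paste(names(n_lev)[n_lev < 2], collapse = ", "))
  fit <- stats::lm(delta ~ direction, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_model <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(coefficients = sm$coefficients, p_model = p_model,
       n_per_level = as.integer(n_lev))
}
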