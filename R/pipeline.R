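#' Pipeline configuration
#'
#' One structured configuration for all stages, with every threshold
#' defaulting to the study's values: minor-allele carrier count 3, site
#' missingness 0.15, sample missingness 0.5, DP > 22, FS < 0.2,
#' |ReadPosRankSum| < 2, control length tolerance 2.5%, 1,000 control
#' draws, 100-bp Tajima windows, 500-km pairing radius, alpha 0.01 for
#' climate calls, 100 effect-label permutations and 100 modern subsamples.
#'
#' @param synth a [synth_config()] for the simulate stage.
#' @param filter a [filter_config()].
#' @param control_tol,control_draws control-gene matching tolerance and
#'   number of draws.
#' @param window_bp Tajima's D window size.
#' @param max_km pairing radius.
#' @param alpha climate significance level (on BH-adjusted P).
#' @param n_perm effect-label permutations.
#' @param n_subsamples modern subsample draws for latitude correlation.
#' @param order_policy historical iteration order for pairing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter = filter_config(),
                            control_tol = 0.025, control_draws = 1000,
                            window_bp = 100, max_km = 500, alpha = 0.01,
                            n_perm = 100, n_subsamples = 100,
                            order_policy = "id") {
  structure(list(synth = synth, filter = filter,
                 control_tol = control_tol, control_draws = control_draws,
                 window_bp = window_bp, max_km = max_km, alpha = alpha,
                 n_perm = n_perm, n_subsamples = n_subsamples,
                 order_policy = order_policy),
            class = "pipeline_config")
}

.stage_file <- function(state, name) {
  if (is.null(state[[name]]))
    stop("missing upstream artifact: stage '", name,
         "' has not been run", call. = FALSE)
  state[[name]]
}

#' Run one pipeline stage
#'
#' Stages, in dependency order: `simulate` (synthetic study),
#' `filter` (sample/site filters per epoch + shared-site intersection),
#' `constraint-scan` (SNP density, pi, theta_W and the group empirical
#' tests against length-matched controls), `adaptation-scan` (windowed
#' Tajima's D, epoch F_ST, per-gene decile flags), `pair` (greedy
#' geographic pairing), `climate` (per-location trends and pair
#' classification), `score` (density scores on the shared-SNP data),
#' `temporal-test` (pair deltas, signed-rank, effect-label permutations,
#' climate-split Fisher odds, latitude correlation) and `report` (summary
#' list). State is carried in an environment-free list: each stage returns
#' an updated copy.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @param state list returned by the previous stage (empty for
#'   `simulate`).
#' @return updated state list; the stage's own outputs live under
#'   `state[[name]]`.
#' @export
run_stage <- function(name, config = pipeline_config(), state = list()) {
  switch(
    name,
    simulate = {
      state$simulate <- generate_study(config$synth)
      state
    },
    filter = {
      study <- .stage_file(state, "simulate")
      vs <- study$variants
      is_hist <- study$samples$epoch[
        match(vs_samples(vs), study$samples$sample_id)] == "historical"
      f_hist <- filter_dataset(vs_subset(vs, samples = is_hist),
                               config$filter, quality = TRUE)
      f_mod <- filter_dataset(vs_subset(vs, samples = !is_hist),
                              config$filter, quality = TRUE)
      shared <- intersect_shared_sites(f_hist, f_mod)
      state$filter <- list(historical = shared$a, modern = shared$b,
                           log = list(
                             historical = attr(f_hist, "filter_log"),
                             modern = attr(f_mod, "filter_log"),
                             intersect = attr(shared, "intersect_log")))
      state
    },
    `constraint-scan` = {
      study <- .stage_file(state, "simulate")
      filt <- .stage_file(state, "filter")
      focus <- study$genes[study$genes$set == "focus", ]
      pool <- study$genes[study$genes$set == "pool", ]
      draws <- draw_length_matched_controls(
        focus, pool, tol = config$control_tol,
        n_sets = config$control_draws, seed = config$synth$seed + 10)
      per_epoch <- lapply(list(historical = filt$historical,
                               modern = filt$modern), function(vs) {
        asn <- assign_snps_to_genes(vs, study$genes)
        stats <- gene_pop_stats(vs, asn, study$genes,
                                window_bp = config$window_bp)
        tests <- lapply(c(pi_per_bp = "pi_per_bp",
                          theta_w_per_bp = "theta_w_per_bp",
                          snps_per_bp = "snps_per_bp"), function(col) {
          vals <- stats::setNames(stats[[col]], stats$gene_id)
          focus_mean <- mean(vals[focus$gene_id], na.rm = TRUE)
          ctrl_means <- tapply(vals[draws$control_gene], draws$draw_id,
                               mean, na.rm = TRUE)
          empirical_group_test(focus_mean, as.numeric(ctrl_means), "lower")
        })
        list(assignment = asn, gene_stats = stats, group_tests = tests)
      })
      state$`constraint-scan` <- c(per_epoch, list(control_draws = draws))
      state
    },
    `adaptation-scan` = {
      study <- .stage_file(state, "simulate")
      filt <- .stage_file(state, "filter")
      scan <- .stage_file(state, "constraint-scan")
      focus <- study$genes[study$genes$set == "focus", ]
      vs_all <- study$variants
      epoch <- study$samples$epoch[
        match(vs_samples(vs_all), study$samples$sample_id)]
      asn <- assign_snps_to_genes(vs_all, study$genes)
      stats_all <- gene_pop_stats(vs_all, asn, study$genes,
                                  pop_schemes = list(epoch = epoch),
                                  window_bp = config$window_bp)
      draws <- scan$control_draws
      flags <- lapply(c(tajima = "tajima_d_mean", fst = "fst_epoch"),
                      function(col) {
        vals <- stats::setNames(stats_all[[col]], stats_all$gene_id)
        vapply(focus$gene_id, function(g) {
          ctrl <- vals[draws$control_gene[draws$focus_gene == g]]
          ctrl <- ctrl[is.finite(ctrl)]
          if (!is.finite(vals[g]) || length(ctrl) == 0) return(NA_character_)
          per_gene_decile_flag(vals[g], ctrl)
        }, character(1))
      })
      state$`adaptation-scan` <- list(gene_stats = stats_all,
                                      decile_flags = flags)
      state
    },
    pair = {
      study <- .stage_file(state, "simulate")
      s <- study$samples
      state$pair <- pair_samples(s[s$epoch == "historical", ],
                                 s[s$epoch == "modern", ],
                                 max_km = config$max_km,
                                 order_policy = config$order_policy)
      state
    },
    climate = {
      study <- .stage_file(state, "simulate")
      pairs <- .stage_file(state, "pair")
      if (is.null(study$climate)) stop("simulate stage produced no climate")
      used <- unique(c(pairs$hist_id, pairs$mod_id))
      cl <- study$climate[study$climate$location_id %in% used, ]
      trends <- climate_trends(cl, alpha = config$alpha)
      state$climate <- list(trends = trends,
                            pairs = classify_pairs(pairs, trends, "ppt"))
      state
    },
    score = {
      study <- .stage_file(state, "simulate")
      filt <- .stage_file(state, "filter")
      shared <- intersect_shared_sites(filt$historical, filt$modern)
      vs <- variant_set(shared$a$sites,
                        cbind(shared$a$geno, shared$b$geno))
      asn <- assign_snps_to_genes(vs, study$genes)
      sc <- density_score(vs, asn, study$effects)
      state$score <- list(scores = sc, variants = vs, assignment = asn)
      state
    },
    `temporal-test` = {
      study <- .stage_file(state, "simulate")
      sc <- .stage_file(state, "score")
      cl <- .stage_file(state, "climate")
      pairs <- cl$pairs
      pairs <- pairs[pairs$hist_id %in% sc$scores$sample_id &
                       pairs$mod_id %in% sc$scores$sample_id, ]
      dw <- delta_and_wilcoxon(pairs, sc$scores)
      perm <- permute_effect_labels(sc$variants, sc$assignment,
                                    study$effects, pairs,
                                    n_perm = config$n_perm,
                                    seed = config$synth$seed + 20)
      cls <- pairs$climate_class
      fisher <- list(
        ppt_increase = fisher_odds(dw$deltas$delta,
                                   cls %in% "matching_increase"),
        ppt_decrease = fisher_odds(dw$deltas$delta,
                                   cls %in% "matching_decrease"))
      latcor <- latitude_correlation(sc$scores, study$samples,
                                     n_subsamples = config$n_subsamples,
                                     seed = config$synth$seed + 30)
      reg <- tryCatch(delta_vs_climate_regression(dw$deltas$delta, cls),
                      error = function(e) list(error = conditionMessage(e)))
      state$`temporal-test` <- list(pairs = pairs, delta = dw,
                                    permutation = perm, fisher = fisher,
                                    latitude = latcor, regression = reg)
      state
    },
    report = {
      tt <- .stage_file(state, "temporal-test")
      scan <- .stage_file(state, "constraint-scan")
      pairs <- tt$pairs
      state$report <- list(
        n_pairs = nrow(pairs),
        pair_distance_km = list(min = min(pairs$distance_km),
                                max = max(pairs$distance_km),
                                mean = mean(pairs$distance_km),
                                median = stats::median(pairs$distance_km)),
        mean_year_gap = mean(pairs$year_gap),
        group_empirical_p = lapply(
          scan[c("historical", "modern")],
          function(e) lapply(e$group_tests, `[[`, "p_empirical")),
        mean_delta = tt$delta$mean_delta,
        wilcoxon_p = tt$delta$wilcoxon_p,
        permutation_rank = tt$permutation$rank,
        n_perm = tt$permutation$n_perm,
        fisher_or_ppt_increase = tt$fisher$ppt_increase$odds_ratio,
        fisher_p_ppt_increase = tt$fisher$ppt_increase$p,
        fisher_or_ppt_decrease = tt$fisher$ppt_decrease$odds_ratio,
        fisher_p_ppt_decrease = tt$fisher$ppt_decrease$p,
        latitude_r_modern = tt$latitude$modern$mean_r,
        latitude_r_historical = tt$latitude$historical$r)
      state
    },
    stop("unknown stage: ", name)
  )
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns the final state; the
#' machine-readable summary sits in `$report`.
#'
#' @param config a [pipeline_config()].
#' @param stages stage names in order (default: all).
#' @return final state list.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "filter", "constraint-scan",
                                    "adaptation-scan", "pair", "climate",
                                    "score", "temporal-test", "report")) {
  state <- list()
  for (s in stages) state <- run_stage(s, config, state)
  state
}
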