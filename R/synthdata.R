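#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study design at desk scale: two cohorts of
#' homozygous (selfing) samples with collection years 1817-2002
#' (historical) and 1992-2012 (modern), coordinates across a European-like
#' latitude band, a 43-gene focus set of which 24 carry density effects
#' (14 loss-increases, 10 loss-decreases), a control pool guaranteeing
#' length-matched draws at ±2.5%, a latitudinal allele-frequency cline,
#' and an optional epoch shift in functional-allele frequency signed by
#' gene effect (positive `shift_delta` = coordinated density decrease in
#' the modern cohort). Climate series are monthly 1958-2017 with seasonal
#' cycle, linear trend and AR(1) noise.
#'
#' @param seed RNG seed controlling every draw.
#' @param n_hist,n_mod cohort sizes.
#' @param hist_years,mod_years inclusive collection-year ranges.
#' @param lat_range,lon_range coordinate bounding box (degrees).
#' @param n_focus_genes,n_effect_genes,n_increase number of focus genes,
#'   of nonzero-effect genes among them, and of +1 genes among those.
#' @param pool_size control-pool size (pool gene lengths are drawn within
#'   ±2% of focus lengths so every focus gene has eligible controls at
#'   the ±2.5% tolerance).
#' @param gene_length_range focus gene length range in bp.
#' @param snps_per_gene mean SNP count per gene (Poisson, minimum 1).
#' @param focus_snp_factor multiplier on the background SNP rate of focus
#'   genes (default 0.5), emulating the diversity depletion of a gene set
#'   under purifying selection relative to the genomic background.
#' @param class_mix named probabilities over effect classes for non-functional
#'   SNPs; `functional_snps_per_gene` functional (NONSYN/LOF) SNPs are
#'   guaranteed per effect gene.
#' @param functional_snps_per_gene functional SNPs per effect gene.
#' @param base_freq baseline alternative-allele frequency of functional SNPs.
#' @param cline_beta log-odds change in functional allele frequency per
#'   degree latitude (centred at the box midpoint).
#' @param shift_delta epoch log-odds shift of functional-allele frequency in
#'   effect genes, applied to modern samples with sign `-effect` (so a
#'   positive value lowers carriage in +1 genes and raises it in -1 genes:
#'   a coordinated stomatal-density decrease).
#' @param shift_group `NULL` (shift applies to all modern samples) or a
#'   predicate taking the sample data.frame and returning a logical vector;
#'   the epoch shift is then confined to those samples.
#' @param het_rate probability a carried genotype is heterozygous
#'   (default 0, fully selfing).
#' @param climate_years climate series year range.
#' @param ppt_mean,ppt_amp,tmax_mean,tmax_amp seasonal means/amplitudes
#'   (mm, degrees C).
#' @param trend_sd standard deviation of per-location true slopes
#'   (units/year); mean slope is 0 so increases and decreases both occur.
#' @param noise_sd,ar1 monthly noise scale and AR(1) coefficient.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_hist = 48, n_mod = 96,
                         hist_years = c(1817, 2002),
                         mod_years = c(1992, 2012),
                         lat_range = c(35, 63), lon_range = c(-10, 30),
                         n_focus_genes = 43, n_effect_genes = 24,
                         n_increase = 14,
                         pool_size = 200,
                         gene_length_range = c(800, 4000),
                         snps_per_gene = 6,
                         focus_snp_factor = 0.5,
                         class_mix = c(NONSYN = 0.18, LOF = 0.02,
                                       SYN = 0.28, UTR = 0.12,
                                       INTRON = 0.27, OTHER = 0.13),
                         functional_snps_per_gene = 3,
                         base_freq = 0.15,
                         cline_beta = 0.06,
                         shift_delta = 0.8,
                         shift_group = NULL,
                         het_rate = 0,
                         climate_years = c(1958, 2017),
                         ppt_mean = 60, ppt_amp = 30,
                         tmax_mean = 16, tmax_amp = 9,
                         trend_sd = 0.15, noise_sd = 6, ar1 = 0.2) {
  stopifnot(n_effect_genes <= n_focus_genes, n_increase <= n_effect_genes,
            n_hist > 0, n_mod > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate sample metadata for both epochs
#'
#' Coordinates uniform in the bounding box, collection years uniform within
#' each epoch's range; deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return data.frame as from [sample_records()].
#' @export
generate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_hist + cfg$n_mod
  epoch <- rep(c("historical", "modern"), c(cfg$n_hist, cfg$n_mod))
  year <- c(sample(seq(cfg$hist_years[1], cfg$hist_years[2]), cfg$n_hist,
                   replace = TRUE),
            sample(seq(cfg$mod_years[1], cfg$mod_years[2]), cfg$n_mod,
                   replace = TRUE))
  ids <- sprintf("%s%03d", ifelse(epoch == "historical", "H", "M"),
                 c(seq_len(cfg$n_hist), seq_len(cfg$n_mod)))
  sample_records(ids, epoch, year,
                 lat = stats::runif(n, cfg$lat_range[1], cfg$lat_range[2]),
                 lon = stats::runif(n, cfg$lon_range[1], cfg$lon_range[2]))
}

#' Generate focus and control-pool gene models with effects
#'
#' Focus genes `SG001..`, pool genes `CG001..`; pool lengths are sampled
#' within ±2% of focus lengths (cycled) so every focus gene has at least
#' one eligible length-matched control at the ±2.5% tolerance. Effects
#' assign +1 to the first `n_increase` effect genes, -1 to the remainder
#' of the `n_effect_genes`, 0 beyond.
#'
#' @param cfg a [synth_config()].
#' @return list `genes` (focus + pool gene models, with a `set` column),
#'   `effects` (gene-effect data.frame over the focus set).
#' @export
generate_genes <- function(cfg) {
  set.seed(cfg$seed + 1)
  nf <- cfg$n_focus_genes; np <- cfg$pool_size
  len_f <- round(stats::runif(nf, cfg$gene_length_range[1],
                              cfg$gene_length_range[2]))
  base <- len_f[rep_len(seq_len(nf), np)]
  len_p <- round(base * stats::runif(np, 0.98, 1.02))
  lens <- c(len_f, len_p)
  ids <- c(sprintf("SG%03d", seq_len(nf)), sprintf("CG%03d", seq_len(np)))
  gap <- 500L
  start <- cumsum(c(1L, utils::head(lens + gap, -1)))
  genes <- gene_models(ids, chrom = "1", start = start,
                       end = start + lens - 1L)
  genes$set <- rep(c("focus", "pool"), c(nf, np))
  effect <- c(rep(1L, cfg$n_increase),
              rep(-1L, cfg$n_effect_genes - cfg$n_increase),
              rep(0L, nf - cfg$n_effect_genes))
  effects <- data.frame(gene_id = genes$gene_id[seq_len(nf)],
                        effect = effect,
                        note = "synthetic knockout-phenotype assignment")
  list(genes = genes, effects = effects)
}

.class_term <- function(class) {
  switch(class,
         LOF = "stop_gained", NONSYN = "missense_variant",
         SYN = "synonymous_variant", UTR = "5_prime_UTR_variant",
         INTRON = "intron_variant", OTHER = "upstream_gene_variant")
}

#' Generate annotated genotypes for a cohort
#'
#' Sites are independent (no linkage). Every gene gets a Poisson number of
#' SNPs with the configured class mixture; effect genes additionally carry
#' `functional_snps_per_gene` NONSYN/LOF SNPs. The per-sample alternative
#' allele probability of a functional SNP in an effect gene is
#' `plogis(qlogis(base_freq) + cline_beta * (lat - lat0) -
#' effect * shift_delta * modern)`; non-functional SNPs follow the same
#' cline without the epoch term. Genotypes are homozygous (0/2) unless
#' `het_rate > 0`. ANN entries are written for the gene's `.1` isoform
#' (and `.2` with identical terms), and INFO metrics DP/FS/ReadPosRankSum
#' are drawn to pass the default quality filter.
#'
#' @param cfg a [synth_config()].
#' @param samples cohort data.frame ([generate_cohort()]).
#' @param genes gene table from [generate_genes()] (the `genes` element).
#' @param effects gene-effect table (the `effects` element).
#' @return a [variant_set()] with a `"truth"` attribute recording each
#'   site's gene, class and frequency parameters.
#' @export
generate_genotypes <- function(cfg, samples, genes, effects) {
  set.seed(cfg$seed + 2)
  lat0 <- mean(cfg$lat_range)
  modern <- as.numeric(samples$epoch == "modern")
  if (!is.null(cfg$shift_group)) modern <- modern * cfg$shift_group(samples)
  eff <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  eff[effects$gene_id] <- effects$effect
  n <- nrow(samples)
  site_rows <- list(); truth_rows <- list(); geno_rows <- list()
  is_focus <- genes$gene_id %in% effects$gene_id
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    rate <- cfg$snps_per_gene * if (is_focus[i]) cfg$focus_snp_factor else 1
    n_bg <- max(1L, stats::rpois(1, rate))
    cls <- sample(names(cfg$class_mix), n_bg, replace = TRUE,
                  prob = cfg$class_mix)
    if (eff[gid] != 0) {
      nf <- cfg$functional_snps_per_gene
      cls <- c(sample(c("NONSYN", "LOF"), nf, replace = TRUE,
                      prob = c(0.8, 0.2)), cls)
    }
    m <- length(cls)
    pos <- sort(sample(seq(genes$start[i], genes$end[i]), m))
    base_logit <- stats::qlogis(cfg$base_freq) +
      stats::rnorm(m, 0, 0.3)
    functional <- cls %in% c("NONSYN", "LOF")
    for (k in seq_len(m)) {
      shift <- if (functional[k] && eff[gid] != 0)
        -eff[gid] * cfg$shift_delta else 0
      p <- stats::plogis(base_logit[k] +
                           cfg$cline_beta * (samples$lat - lat0) +
                           shift * modern)
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      carrier <- stats::rbinom(n, 1, p)
      dos <- carrier * 2L
      if (cfg$het_rate > 0) {
        het <- stats::rbinom(n, 1, cfg$het_rate) == 1
        dos[carrier == 1 & het] <- 1L
      }
      geno_rows[[length(geno_rows) + 1]] <- dos
      site_rows[[length(site_rows) + 1]] <- data.frame(
        chrom = genes$chrom[i], pos = pos[k],
        ref = "A", alt = "T",
        dp = round(stats::runif(1, 25, 80)),
        fs = round(stats::runif(1, 0, 0.19), 3),
        rprs = round(stats::rnorm(1, 0, 0.6), 3))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        gene_id = gid, class = cls[k], base_logit = base_logit[k],
        epoch_shift = if (functional[k] && eff[gid] != 0)
          -eff[gid] * cfg$shift_delta else 0)
    }
  }
  sites <- do.call(rbind, site_rows)
  truth <- do.call(rbind, truth_rows)
  sites$rprs <- pmin(pmax(sites$rprs, -1.9), 1.9)
  sites$ann <- lapply(seq_len(nrow(sites)), function(k) {
    tx <- paste0(truth$gene_id[k], c(".1", ".2"))
    data.frame(transcript = tx,
               terms = I(rep(list(.class_term(truth$class[k])), 2)))
  })
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- samples$sample_id
  out <- variant_set(sites, geno)
  attr(out, "truth") <- truth
  out
}

#' Generate monthly climate series for sample locations
#'
#' Monthly value = mean + amplitude * sin(2 pi month / 12) +
#' slope * (year - first year) + AR(1) noise. One true slope per location
#' (and variable) drawn from N(0, `trend_sd`); truth is returned in the
#' `"truth"` attribute. Precipitation is floored at 0 (the default scales
#' make that a rare event).
#'
#' @param cfg a [synth_config()].
#' @param location_ids character vector of location (sample) ids.
#' @param null_trend if TRUE all true slopes are 0.
#' @return long data.frame `location_id`, `variable`, `year`, `month`,
#'   `value`.
#' @export
generate_climate <- function(cfg, location_ids, null_trend = FALSE) {
  set.seed(cfg$seed + 3)
  years <- seq(cfg$climate_years[1], cfg$climate_years[2])
  ny <- length(years)
  month <- rep(1:12, ny)
  yr <- rep(years, each = 12)
  t_rel <- yr - years[1] + (month - 1) / 12
  pars <- list(ppt = c(cfg$ppt_mean, cfg$ppt_amp),
               tmax = c(cfg$tmax_mean, cfg$tmax_amp))
  out <- list(); truth <- list()
  for (v in names(pars)) {
    noise_sd <- if (v == "ppt") cfg$noise_sd else cfg$noise_sd / 4
    slope_sd <- if (v == "ppt") cfg$trend_sd else cfg$trend_sd / 3
    for (loc in location_ids) {
      slope <- if (null_trend) 0 else stats::rnorm(1, 0, slope_sd)
      e <- stats::rnorm(length(t_rel), 0, noise_sd)
      noise <- as.numeric(stats::filter(e, cfg$ar1, method = "recursive"))
      val <- pars[[v]][1] + pars[[v]][2] * sin(2 * pi * month / 12) +
        slope * t_rel + noise
      if (v == "ppt") val <- pmax(val, 0)
      out[[length(out) + 1]] <- data.frame(
        location_id = loc, variable = v, year = yr, month = month,
        value = val)
      truth[[length(truth) + 1]] <- data.frame(
        location_id = loc, variable = v, slope = slope)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- do.call(rbind, truth)
  res
}

#' Generate a complete synthetic study in memory
#'
#' @param cfg a [synth_config()].
#' @param climate include climate series (default TRUE; generation is the
#'   most expensive step and calibration loops that do not use climate can
#'   skip it).
#' @return list `config`, `samples`, `genes`, `effects`, `variants`
#'   (a [variant_set()]), and optionally `climate`.
#' @export
generate_study <- function(cfg = synth_config(), climate = TRUE) {
  samples <- generate_cohort(cfg)
  g <- generate_genes(cfg)
  vs <- generate_genotypes(cfg, samples, g$genes, g$effects)
  out <- list(config = cfg, samples = samples, genes = g$genes,
              effects = g$effects, variants = vs)
  if (climate) out$climate <- generate_climate(cfg, samples$sample_id)
  out
}

.dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Write a synthetic study to disk
#'
#' Emits a complete runnable study directory: annotated VCF 4.2
#' (`variants.vcf`), GFF3 gene models (`genes.gff3`), gene-effect TSV
#' (`gene_effects.tsv`), sample metadata TSV (`samples.tsv`), climate long
#' TSV (`climate.tsv`, when present) and ground-truth JSON
#' (`truth.json`).
#'
#' @param study list from [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- study$variants
  truth <- attr(vs, "truth")
  ann <- vapply(seq_len(n_sites(vs)), function(k) {
    a <- vs$sites$ann[[k]]
    paste(vapply(seq_len(nrow(a)), function(j)
      paste(vs$sites$alt[k], paste(a$terms[[j]], collapse = "&"), "MODIFIER",
            sub("\\.[0-9]+$", "", a$transcript[j]), "", "transcript",
            a$transcript[j], "", "", "", "", "", "", "", "",
            sep = "|"),
      character(1)), collapse = ",")
  }, character(1))
  info <- sprintf("DP=%d;FS=%s;ReadPosRankSum=%s;ANN=%s",
                  vs$sites$dp, vs$sites$fs, vs$sites$rprs, ann)
  gts <- apply(vs$geno, 1, .dosage_to_gt)
  gts <- if (is.null(dim(gts))) matrix(gts, ncol = n_sites(vs)) else gts
  body <- paste(vs$sites$chrom, vs$sites$pos,
                paste0("s", seq_len(n_sites(vs))),
                vs$sites$ref, vs$sites$alt, ".", "PASS", info, "GT",
                apply(gts, 2, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
              "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred strand bias\">",
              "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
              "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", vs_samples(vs)), collapse = "\t"))
  writeLines(c(header, body), file.path(dir, "variants.vcf"))

  g <- study$genes
  gff <- c("##gff-version 3",
           paste(g$chrom, "stomatrend", "gene", g$start, g$end, ".",
                 g$strand, ".",
                 sprintf("ID=%s;Name=%s", g$gene_id, g$gene_id),
                 sep = "\t"),
           paste(g$chrom, "stomatrend", "mRNA", g$start, g$end, ".",
                 g$strand, ".",
                 sprintf("ID=%s.1;Parent=%s", g$gene_id, g$gene_id),
                 sep = "\t"))
  writeLines(gff, file.path(dir, "genes.gff3"))

  utils::write.table(study$effects, file.path(dir, "gene_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$climate))
    utils::write.table(study$climate, file.path(dir, "climate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth_all <- list(
    config = study$config[setdiff(names(study$config), "shift_group")],
    site_truth = truth,
    climate_truth = if (!is.null(study$climate))
      attr(study$climate, "truth") else NULL)
  jsonlite::write_json(truth_all, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
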