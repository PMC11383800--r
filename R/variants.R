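#' Effect classes recognised by the classifier, in priority order
#'
#' Most to least severe. A variant annotated with terms from several classes
#' is assigned the highest-priority (most severe) class.
#'
#' @export
EFFECT_CLASSES <- c("LOF", "NONSYN", "SYN", "UTR", "INTRON", "OTHER")

# SnpEff vocabulary, normalised (trailing "_variant" stripped).
.effect_vocab <- list(
  LOF = c("disruptive_inframe_deletion", "disruptive_inframe_insertion",
          "inframe_deletion", "inframe_insertion", "frameshift",
          "start_lost", "stop_lost", "stop_gained"),
  NONSYN = "missense",
  SYN = "synonymous",
  UTR = c("5_prime_UTR_premature_start_codon_gain", "3_prime_UTR",
          "5_prime_UTR"),
  INTRON = "intron",
  OTHER = c("none", "splice_region", "splice_donor", "splice_acceptor",
            "stop_retained", "non_coding_transcript_exon",
            "upstream_gene", "downstream_gene")
)

.normalize_term <- function(terms) sub("_variant$", "", terms)

#' Classify SnpEff annotation terms into an effect class
#'
#' Maps the annotation terms attached to one (variant, transcript) pair onto
#' one of six mutually exclusive classes: putative loss-of-function
#' (disruptive/plain inframe indels, frameshift, start/stop loss, stop gain),
#' non-synonymous (missense), synonymous, UTR, intron, or other. When terms
#' from several classes co-occur the most severe class wins
#' (LOF > NONSYN > SYN > UTR > INTRON > OTHER). Terms may carry the SnpEff
#' `_variant` suffix or not.
#'
#' @param terms character vector of annotation terms for one variant and
#'   transcript (an `&`-joined ANN effect field, already split).
#' @return a single string, one of [EFFECT_CLASSES]. Unknown terms are
#'   ignored with a warning; an empty or all-unknown set yields `"OTHER"`.
#' @examples
#' classify_effect(c("missense_variant", "synonymous_variant")) # "NONSYN"
#' classify_effect("stop_gained")                               # "LOF"
#' @export
classify_effect <- function(terms) {
  terms <- .normalize_term(as.character(terms))
  known <- unlist(.effect_vocab, use.names = FALSE)
  unknown <- setdiff(terms, known)
  if (length(unknown) > 0)
    warning("unknown annotation term(s) treated as OTHER: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  for (cls in EFFECT_CLASSES[1:5]) {
    if (any(terms %in% .effect_vocab[[cls]])) return(cls)
  }
  "OTHER"
}

#' Vectorised effect classification
#'
#' @param term_list list of character vectors, one per variant.
#' @return character vector of classes, same length as `term_list`.
#' @export
classify_effects <- function(term_list) {
  vapply(term_list, classify_effect, character(1))
}

#' Filtering thresholds for annotated variant collections
#'
#' Defaults reproduce the historical-cohort calling filters: combined site
#' depth DP > 22, Fisher strand bias FS < 0.2, |ReadPosRankSum| < 2,
#' minor-allele carrier count >= 3, site missingness <= 15%, sample
#' missingness <= 50%.
#'
#' @param min_mac minimum number of samples carrying the alternative allele
#'   (carrier count, not allele copies, unless `mac_mode = "alleles"`).
#' @param max_site_missing maximum fraction of missing genotypes per site.
#' @param max_sample_missing maximum fraction of missing genotypes per sample.
#' @param dp_min,fs_max,rprs_abs_max site-quality thresholds (all strict
#'   inequalities; ReadPosRankSum must lie in the open interval
#'   (-rprs_abs_max, rprs_abs_max)).
#' @param mac_mode `"carriers"` counts samples with dosage >= 1;
#'   `"alleles"` counts alternative allele copies.
#' @param missing_metric_pass if TRUE a site lacking one of the INFO metrics
#'   passes the quality predicate; default FALSE (conservative fail).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_mac = 3, max_site_missing = 0.15,
                          max_sample_missing = 0.5,
                          dp_min = 22, fs_max = 0.2, rprs_abs_max = 2,
                          mac_mode = c("carriers", "alleles"),
                          missing_metric_pass = FALSE) {
  stopifnot(min_mac >= 0, max_site_missing >= 0, max_site_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            dp_min > 0, fs_max > 0, rprs_abs_max > 0)
  structure(list(min_mac = min_mac, max_site_missing = max_site_missing,
                 max_sample_missing = max_sample_missing, dp_min = dp_min,
                 fs_max = fs_max, rprs_abs_max = rprs_abs_max,
                 mac_mode = match.arg(mac_mode),
                 missing_metric_pass = missing_metric_pass),
            class = "filter_config")
}

#' Construct a variant set
#'
#' The central in-memory container: a site table plus a sites x samples
#' dosage matrix. Dosages are alternative-allele counts in {0, 1, 2} with
#' NA for missing calls; half-missing diploid calls are treated as missing
#' and phased and unphased genotypes are read identically.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, the
#'   INFO metrics `dp`, `fs`, `rprs` (NA allowed) and a list-column `ann`
#'   (per site, a data.frame with columns `transcript`, `terms` where
#'   `terms` is a list of character vectors).
#' @param geno integer matrix, `nrow(sites)` rows, one column per sample
#'   (named), values in {0, 1, 2, NA}.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(sites, geno) {
  stopifnot(is.data.frame(sites), is.matrix(geno),
            nrow(sites) == nrow(geno))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  stopifnot(all(sites$pos >= 1))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("dosages must be in {0, 1, 2, NA}")
  if (is.null(colnames(geno))) stop("geno must have sample names")
  for (col in c("dp", "fs", "rprs"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  if (is.null(sites$ann)) sites$ann <- replicate(nrow(sites), NULL, simplify = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", ncol(x$geno), "samples\n")
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a `variant_set`.
#' @export
n_sites <- function(vs) nrow(vs$sites)

#' Sample names of a variant set
#' @param vs a `variant_set`.
#' @export
vs_samples <- function(vs) colnames(vs$geno)

#' Subset a variant set by site and/or sample
#' @param vs a `variant_set`.
#' @param sites,samples index vectors (logical or integer/character).
#' @export
vs_subset <- function(vs, sites = NULL, samples = NULL) {
  s <- vs$sites; g <- vs$geno
  if (!is.null(sites)) {
    s <- s[sites, , drop = FALSE]
    rownames(s) <- NULL
    g <- g[sites, , drop = FALSE]
  }
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  variant_set(s, g)
}

# Parse one VCF GT string vector into dosages.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

# Parse a SnpEff ANN INFO value into a per-site annotation data.frame.
.parse_ann <- function(ann_string) {
  if (is.na(ann_string) || !nzchar(ann_string)) return(NULL)
  entries <- strsplit(ann_string, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  terms <- lapply(fields, function(f)
    if (length(f) >= 2) strsplit(f[2], "&", fixed = TRUE)[[1]] else character(0))
  transcript <- vapply(fields, function(f)
    if (length(f) >= 7 && nzchar(f[7])) f[7] else NA_character_, character(1))
  data.frame(transcript = transcript, terms = I(terms))
}

.info_str <- function(info, key) {
  out <- rep(NA_character_, length(info))
  pat <- paste0("(^|;)", key, "=([^;]+)")
  m <- regexpr(pat, info)
  hit <- m > 0
  out[hit] <- sub(pat, "\\2", regmatches(info, m))
  out
}

.info_num <- function(info, key) suppressWarnings(as.numeric(.info_str(info, key)))

#' Read an effect-annotated VCF into a variant set
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) carrying SnpEff-style `ANN` INFO
#' entries. Multi-allelic records and indels are dropped (the pipeline keeps
#' biallelic SNPs only); the drop counts are recorded in the
#' `"read_log"` attribute.
#'
#' @param path path to a VCF (optionally gzipped).
#' @return a [variant_set()].
#' @export
read_annotated_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt, fixed = TRUE)
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & alt != "*"
  keep <- biallelic & snp
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  geno <- apply(gt[keep, , drop = FALSE], 2, .gt_to_dosage)
  if (is.null(dim(geno)))
    geno <- matrix(geno, nrow = sum(keep), dimnames = list(NULL, colnames(gt)))
  info_k <- info[keep]
  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    dp = .info_num(info_k, "DP"),
    fs = .info_num(info_k, "FS"),
    rprs = .info_num(info_k, "ReadPosRankSum"))
  sites$ann <- lapply(.info_str(info_k, "ANN"), .parse_ann)
  out <- variant_set(sites, geno)
  attr(out, "read_log") <- list(
    n_records = length(alt),
    dropped_multiallelic = sum(!biallelic),
    dropped_indel = sum(biallelic & !snp))
  out
}

#' Site-quality predicate
#'
#' A site passes iff DP > `dp_min`, FS < `fs_max` and ReadPosRankSum lies
#' strictly inside (-`rprs_abs_max`, `rprs_abs_max`). All inequalities are
#' strict, so boundary values fail. A missing metric fails the predicate
#' unless `cfg$missing_metric_pass` is TRUE.
#'
#' @param dp,fs,rprs numeric vectors of site INFO metrics (NA allowed).
#' @param cfg a [filter_config()].
#' @return logical vector.
#' @export
site_quality_pass <- function(dp, fs, rprs, cfg = filter_config()) {
  res <- dp > cfg$dp_min & fs < cfg$fs_max &
    rprs > -cfg$rprs_abs_max & rprs < cfg$rprs_abs_max
  res[is.na(res)] <- cfg$missing_metric_pass
  res
}

# Carrier / allele count of the alternative allele at each site.
.alt_mac <- function(geno, mode = "carriers") {
  if (mode == "carriers") rowSums(geno >= 1, na.rm = TRUE)
  else rowSums(geno, na.rm = TRUE)
}

#' Apply sample- and site-level filters to a variant set
#'
#' Filter order: (1) drop samples whose missing-genotype fraction exceeds
#' `max_sample_missing`; (2) on the reduced matrix, drop sites whose missing
#' fraction exceeds `max_site_missing`, whose alternative-allele carrier
#' count falls below `min_mac`, or (if `quality = TRUE`) that fail
#' [site_quality_pass()]. The steps and counts removed at each are recorded
#' in the `"filter_log"` attribute. The operation is idempotent.
#'
#' @param vs a [variant_set()].
#' @param cfg a [filter_config()].
#' @param quality also apply the INFO-metric site-quality predicate.
#' @return filtered `variant_set` (possibly with zero sites; never an error).
#' @export
filter_dataset <- function(vs, cfg = filter_config(), quality = FALSE) {
  log <- list(config = unclass(cfg))
  samp_miss <- colMeans(is.na(vs$geno))
  keep_samp <- samp_miss <= cfg$max_sample_missing
  log$samples_removed <- sum(!keep_samp)
  vs <- vs_subset(vs, samples = keep_samp)

  site_miss <- rowMeans(is.na(vs$geno))
  if (ncol(vs$geno) == 0) site_miss <- rep(1, n_sites(vs))
  mac <- .alt_mac(vs$geno, cfg$mac_mode)
  keep <- site_miss <= cfg$max_site_missing & mac >= cfg$min_mac
  log$sites_removed_missing <- sum(site_miss > cfg$max_site_missing)
  log$sites_removed_mac <- sum(site_miss <= cfg$max_site_missing &
                                 mac < cfg$min_mac)
  if (quality) {
    q <- site_quality_pass(vs$sites$dp, vs$sites$fs, vs$sites$rprs, cfg)
    log$sites_removed_quality <- sum(keep & !q)
    keep <- keep & q
  }
  out <- vs_subset(vs, sites = keep)
  log$sites_retained <- n_sites(out)
  log$samples_retained <- ncol(out$geno)
  if (n_sites(out) == 0)
    message("filter_dataset: no sites retained")
  attr(out, "filter_log") <- log
  out
}

.site_key <- function(sites) paste(sites$chrom, sites$pos, sites$ref, sites$alt)

#' Intersect two variant collections to their shared sites
#'
#' Sites are matched on the strict key (chrom, pos, ref, alt). Sites present
#' at the same position but with ref/alt exchanged between the two datasets
#' are excluded from both and counted in the `"intersect_log"` attribute.
#' Input order is preserved; the two outputs carry identical site keys.
#'
#' @param a,b two [variant_set()] objects (already biallelic-filtered).
#' @return list with elements `a` and `b`, the reduced variant sets.
#' @export
intersect_shared_sites <- function(a, b) {
  ka <- .site_key(a$sites); kb <- .site_key(b$sites)
  shared <- intersect(ka, kb)
  swap_a <- paste(a$sites$chrom, a$sites$pos, a$sites$alt, a$sites$ref)
  n_swapped <- length(intersect(swap_a, setdiff(kb, shared)))
  out <- list(a = vs_subset(a, sites = ka %in% shared),
              b = vs_subset(b, sites = kb %in% shared))
  attr(out, "intersect_log") <- list(
    n_shared = length(shared),
    n_only_a = sum(!ka %in% shared), n_only_b = sum(!kb %in% shared),
    n_allele_swapped = n_swapped)
  out
}

#' Per-gene and per-set effect-class counts
#'
#' Counts SNPs of each effect class within each gene of an assignment (see
#' [assign_snps_to_genes()]) and totals over the set, with proportions.
#'
#' @param assignment data.frame with columns `gene_id`, `class` (one row per
#'   assigned SNP), as returned by [assign_snps_to_genes()].
#' @param genes optional character vector of gene ids to report (genes with
#'   zero SNPs appear with zero counts and are flagged).
#' @return list with `per_gene` (gene_id x class count matrix),
#'   `set_counts`, `set_proportions` and `empty_genes`.
#' @export
class_counts <- function(assignment, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(assignment$gene_id))
  cls <- factor(assignment$class, levels = EFFECT_CLASSES)
  gid <- factor(assignment$gene_id, levels = genes)
  keep <- !is.na(gid)
  per_gene <- table(gene_id = gid[keep], class = cls[keep])
  set_counts <- colSums(per_gene)
  total <- sum(set_counts)
  props <- if (total > 0) set_counts / total else set_counts * NA_real_
  list(per_gene = unclass(per_gene),
       set_counts = set_counts,
       set_proportions = props,
       empty_genes = genes[rowSums(per_gene) == 0])
}
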