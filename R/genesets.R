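#' Build a gene-model table
#'
#' @param gene_id,chrom,start,end,strand parallel vectors describing gene
#'   spans (1-based inclusive coordinates).
#' @return data.frame with a `length` column (`end - start + 1`). Gene length
#'   here is the genomic span of the gene feature, the same span used for
#'   SNP assignment and per-bp statistics.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+") {
  stopifnot(all(start <= end), all(start >= 1))
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, length(gene_id)),
             length = as.integer(end - start + 1L))
}

#' Read gene models from a GFF3 file
#'
#' Uses \pkg{rtracklayer} to parse GFF3 and keeps features of type `gene`.
#'
#' @param path GFF3 file path.
#' @return gene-model data.frame as from [gene_models()].
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 files")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  gene_models(gene_id = ids,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)))
}

# "AT1G01010.1" -> gene "AT1G01010", isoform 1L
.split_transcript <- function(tx) {
  gene <- sub("\\.[0-9]+$", "", tx)
  iso <- suppressWarnings(as.integer(sub("^.*\\.", "", tx)))
  iso[gene == tx] <- NA_integer_
  list(gene = gene, isoform = iso)
}

#' Assign SNPs to genes via annotated isoforms
#'
#' A SNP belongs to a gene iff one of its ANN entries names that gene's
#' first or second splice isoform (transcript suffix `.1` or `.2`). The
#' SNP's effect class within the gene is taken from the first-isoform
#' annotation (falling back to the second isoform only when no `.1` entry
#' exists for that gene).
#'
#' @param vs a [variant_set()] whose sites carry parsed `ann` entries.
#' @param genes gene-model data.frame ([gene_models()]); ANN entries naming
#'   genes absent from it are left unassigned and counted in the
#'   `"assign_log"` attribute.
#' @param isoforms integer vector of admissible isoform numbers
#'   (default `c(1, 2)`).
#' @return data.frame with one row per (SNP, gene) assignment: `site`
#'   (row index into `vs$sites`), `gene_id`, `class`, `isoform` (the isoform
#'   the class was read from).
#' @export
assign_snps_to_genes <- function(vs, genes, isoforms = c(1L, 2L)) {
  rows <- vector("list", n_sites(vs))
  n_unknown <- 0L
  known <- genes$gene_id
  for (i in seq_len(n_sites(vs))) {
    ann <- vs$sites$ann[[i]]
    if (is.null(ann) || nrow(ann) == 0) next
    tx <- .split_transcript(ann$transcript)
    ok <- !is.na(tx$isoform) & tx$isoform %in% isoforms
    if (!any(ok)) next
    g <- tx$gene[ok]; iso <- tx$isoform[ok]; terms <- ann$terms[ok]
    unknown <- !g %in% known
    n_unknown <- n_unknown + sum(unknown & !duplicated(g))
    g <- g[!unknown]; iso <- iso[!unknown]; terms <- terms[!unknown]
    if (length(g) == 0) next
    out <- lapply(unique(g), function(gid) {
      sel <- which(g == gid)
      use <- sel[which.min(iso[sel])]  # class from the first isoform present
      data.frame(site = i, gene_id = gid,
                 class = classify_effect(terms[[use]]),
                 isoform = iso[use])
    })
    rows[[i]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(site = integer(0), gene_id = character(0),
                      class = character(0), isoform = integer(0))
  attr(res, "assign_log") <- list(n_unassigned_unknown_gene = n_unknown)
  res
}

#' Draw length-matched control gene sets
#'
#' For each focus gene, the eligible pool consists of pool genes whose
#' genomic length lies within `± tol` (fractional) of the focus gene's
#' length, excluding the focus gene itself and (by default) every focus
#' gene. Within a draw one control gene is picked uniformly and
#' independently per focus gene; across focus genes the same control may
#' recur unless `no_duplicates = TRUE`.
#'
#' @param focus,pool gene-model data.frames ([gene_models()]).
#' @param tol fractional length tolerance (default 0.025, i.e. ±2.5%).
#' @param n_sets number of control sets to draw (default 1000).
#' @param seed RNG seed; draws are reproducible given the seed.
#' @param exclude_all_focus exclude every focus gene from all eligibility
#'   pools (default TRUE), not just each gene's own.
#' @param no_duplicates forbid the same control gene appearing twice within
#'   one draw (resampled per draw; a draw that cannot be completed errors).
#' @return data.frame with columns `draw_id`, `focus_gene`, `control_gene`.
#' @export
draw_length_matched_controls <- function(focus, pool, tol = 0.025,
                                         n_sets = 1000, seed = NULL,
                                         exclude_all_focus = TRUE,
                                         no_duplicates = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  banned <- if (exclude_all_focus) focus$gene_id else character(0)
  eligible <- lapply(seq_len(nrow(focus)), function(i) {
    L <- focus$length[i]
    ok <- abs(pool$length - L) <= tol * L &
      !pool$gene_id %in% c(banned, focus$gene_id[i])
    pool$gene_id[ok]
  })
  empty <- lengths(eligible) == 0
  if (any(empty))
    stop("no eligible control gene within ±", tol * 100, "% for: ",
         paste(focus$gene_id[empty], collapse = ", "))
  nf <- nrow(focus)
  draws <- lapply(seq_len(n_sets), function(d) {
    if (!no_duplicates) {
      picks <- vapply(eligible, function(e) e[sample.int(length(e), 1)],
                      character(1))
    } else {
      picks <- character(nf); taken <- character(0)
      for (i in order(lengths(eligible))) {
        avail <- setdiff(eligible[[i]], taken)
        if (length(avail) == 0)
          stop("draw ", d, ": no duplicate-free control for ",
               focus$gene_id[i])
        picks[i] <- avail[sample.int(length(avail), 1)]
        taken <- c(taken, picks[i])
      }
    }
    data.frame(draw_id = d, focus_gene = focus$gene_id, control_gene = picks)
  })
  do.call(rbind, draws)
}

#' Empirical group outlier test against control-set means
#'
#' Compares the focus-group statistic with the distribution of control-group
#' means: `p = (# control means at least as extreme as the focus value) /
#' (# draws)`. Ties count as "as extreme"; no +1 continuity term is added,
#' so a focus value beyond every control yields an exact 0.
#'
#' @param focus_stat focus-group statistic (scalar).
#' @param control_stats vector of control-group means, one per draw.
#' @param tail `"lower"`, `"upper"`, or `"two"` (twice the smaller one-sided
#'   fraction, capped at 1).
#' @return list with `focus_stat`, `control_stats`, `p_empirical`, `tail`.
#' @export
empirical_group_test <- function(focus_stat, control_stats,
                                 tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  stopifnot(length(control_stats) >= 1, is.finite(focus_stat))
  lo <- mean(control_stats <= focus_stat)
  hi <- mean(control_stats >= focus_stat)
  p <- switch(tail, lower = lo, upper = hi, two = min(1, 2 * min(lo, hi)))
  list(focus_stat = focus_stat, control_stats = control_stats,
       p_empirical = p, tail = tail)
}

#' Per-gene decile outlier flag
#'
#' Flags a gene statistic against its own length-matched control
#' distribution: `"low"` if at or below the 10th percentile, `"high"` if at
#' or above the 90th, else `"none"`. Percentiles use linear interpolation
#' between order statistics (`quantile` type 7).
#'
#' @param gene_stat the gene's statistic (scalar).
#' @param control_stats statistics of that gene's length-matched controls.
#' @return `"low"`, `"high"`, or `"none"`.
#' @export
per_gene_decile_flag <- function(gene_stat, control_stats) {
  control_stats <- control_stats[is.finite(control_stats)]
  if (length(control_stats) < 10)
    warning("fewer than 10 control values; decile flag unstable")
  q <- stats::quantile(control_stats, c(0.1, 0.9), names = FALSE, type = 7)
  if (gene_stat <= q[1]) "low" else if (gene_stat >= q[2]) "high" else "none"
}
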