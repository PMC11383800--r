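#' Ellipsoidal geodesic distance in kilometres
#'
#' Vincenty inverse solution on the WGS84 ellipsoid
#' (\code{geosphere::distVincentyEllipsoid}). For near-antipodal point pairs
#' where Vincenty's iteration fails to converge, falls back to Karney's
#' always-convergent geodesic (\code{geosphere::distGeo}); fallback use is
#' flagged in the `"fallback"` attribute.
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree coordinates (vectors recycle).
#' @return distance(s) in km, symmetric in the two points and zero iff they
#'   coincide.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  p1 <- cbind(lon1, lat1); p2 <- cbind(lon2, lat2)
  d <- suppressWarnings(geosphere::distVincentyEllipsoid(p1, p2))
  bad <- !is.finite(d)
  if (any(bad)) {
    p1 <- p1[rep_len(seq_len(nrow(p1)), length(d)), , drop = FALSE]
    p2 <- p2[rep_len(seq_len(nrow(p2)), length(d)), , drop = FALSE]
    d[bad] <- geosphere::distGeo(p1[bad, , drop = FALSE],
                                 p2[bad, , drop = FALSE])
  }
  out <- d / 1000
  attr(out, "fallback") <- bad
  out
}

#' Build a sample-metadata table
#'
#' @param sample_id,epoch,year,lat,lon parallel vectors; `epoch` in
#'   {"historical", "modern"}; coordinates WGS84 decimal degrees.
#' @param region_tags optional character vector of comma-free exclusion
#'   tags (e.g. landmass identifiers); used by pairing exclusion rules.
#' @return data.frame of sample records.
#' @export
sample_records <- function(sample_id, epoch, year, lat, lon,
                           region_tags = NA_character_) {
  stopifnot(all(epoch %in% c("historical", "modern")),
            all(lat >= -90 & lat <= 90), all(lon >= -180 & lon <= 180),
            all(year >= 1500 & year <= 2100))
  data.frame(sample_id = as.character(sample_id), epoch = epoch,
             year = as.integer(year), lat = lat, lon = lon,
             region_tags = rep_len(as.character(region_tags),
                                   length(sample_id)))
}

#' Greedy geographic pairing of historical and modern samples
#'
#' Iterates over historical samples under the chosen order policy; each
#' picks the geodesically nearest modern sample still in the pool, which is
#' then removed from further consideration (each modern sample is used at
#' most once). A formed pair is discarded — with its reason recorded — when
#' the distance exceeds `max_km`, when the modern collection year does not
#' postdate the historical one, or when an exclusion rule fires (the two
#' members carry different `region_tags`, e.g. island vs mainland).
#'
#' @param historical,modern data.frames as from [sample_records()].
#' @param max_km maximum pair distance in km (default 500).
#' @param order_policy `"id"` (ascending sample_id; the default,
#'   deterministic), `"year"` (ascending collection year, ties by id) or
#'   `"random"` (under `seed`).
#' @param seed RNG seed, used only by the `"random"` policy.
#' @param exclude_tag_mismatch drop pairs whose members carry differing
#'   non-NA `region_tags` (default TRUE).
#' @return data.frame of pairs (`hist_id`, `mod_id`, `distance_km`,
#'   `year_gap`); dropped candidate pairs, with `excluded_reason`, are in
#'   the `"dropped"` attribute, unpaired historical samples in
#'   `"unpaired"`.
#' @export
pair_samples <- function(historical, modern, max_km = 500,
                         order_policy = c("id", "year", "random"),
                         seed = 1, exclude_tag_mismatch = TRUE) {
  order_policy <- match.arg(order_policy)
  stopifnot(nrow(historical) > 0, nrow(modern) > 0)
  ord <- switch(order_policy,
    id = order(historical$sample_id),
    year = order(historical$year, historical$sample_id),
    random = { set.seed(seed); sample.int(nrow(historical)) })
  pool <- rep(TRUE, nrow(modern))
  pairs <- list(); dropped <- list(); unpaired <- character(0)
  for (i in ord) {
    if (!any(pool)) {
      unpaired <- c(unpaired, historical$sample_id[i])
      next
    }
    cand <- which(pool)
    d <- geodesic_km(historical$lat[i], historical$lon[i],
                     modern$lat[cand], modern$lon[cand])
    j <- cand[which.min(d)]
    dist_km <- min(d)
    pool[j] <- FALSE
    gap <- modern$year[j] - historical$year[i]
    reason <- NULL
    if (dist_km > max_km) reason <- "distance_gt_max_km"
    else if (gap <= 0) reason <- "year_gap_not_positive"
    else if (exclude_tag_mismatch &&
             !is.na(historical$region_tags[i]) &&
             !is.na(modern$region_tags[j]) &&
             historical$region_tags[i] != modern$region_tags[j])
      reason <- "region_tag_mismatch"
    rec <- data.frame(hist_id = historical$sample_id[i],
                      mod_id = modern$sample_id[j],
                      distance_km = dist_km, year_gap = gap)
    if (is.null(reason)) pairs[[length(pairs) + 1]] <- rec
    else {
      rec$excluded_reason <- reason
      dropped[[length(dropped) + 1]] <- rec
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(hist_id = character(0), mod_id = character(0),
               distance_km = numeric(0), year_gap = integer(0))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  attr(out, "unpaired") <- unpaired
  attr(out, "order_policy") <- order_policy
  out
}
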