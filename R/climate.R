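#' Annual maximum of monthly maximum temperatures
#'
#' Reduces a monthly tmax series to one value per year: the month with the
#' highest recorded temperature.
#'
#' @param series data.frame with columns `year`, `month`, `value`
#'   (degrees C) for one location.
#' @return data.frame `year`, `value`, sorted by year.
#' @export
annual_tmax <- function(series) {
  stopifnot(all(series$month %in% 1:12),
            !anyDuplicated(series[c("year", "month")]))
  agg <- tapply(series$value, series$year, max)
  data.frame(year = as.integer(names(agg)), value = as.numeric(agg))
}

#' Deseasonalised annual trend of a monthly precipitation series
#'
#' Additive seasonal decomposition with period 12 (`stats::decompose`): the
#' trend component is the centred 12-month moving average (first and last
#' half-window undefined and dropped, not padded); the annual value is the
#' mean of the defined trend values within each calendar year.
#'
#' @param series data.frame `year`, `month`, `value` (mm) for one location;
#'   months must be consecutive and cover at least two full periods
#'   (24 months).
#' @return data.frame `year`, `value` (annualised trend component).
#' @export
decompose_trend <- function(series) {
  series <- series[order(series$year, series$month), ]
  stopifnot(all(series$month %in% 1:12),
            !anyDuplicated(series[c("year", "month")]))
  if (nrow(series) < 24)
    stop("decompose_trend needs >= 24 consecutive months")
  mi <- series$year * 12 + series$month
  if (!all(diff(mi) == 1)) stop("monthly series must be consecutive")
  x <- stats::ts(series$value, frequency = 12,
                 start = c(series$year[1], series$month[1]))
  tr <- stats::decompose(x, type = "additive")$trend
  ok <- !is.na(tr)
  agg <- tapply(as.numeric(tr)[ok], series$year[ok], mean)
  data.frame(year = as.integer(names(agg)), value = as.numeric(agg))
}

#' Slope and Spearman significance of an annual climate series
#'
#' The directionality of change is the sign of the ordinary least-squares
#' slope of value on year; the raw P value comes from a two-sided Spearman
#' rank correlation of value versus year.
#'
#' @param annual data.frame `year`, `value` (>= 3 rows).
#' @return list with `slope` (units/year), `rho`, `p_raw` (`rho`/`p_raw`
#'   NA for constant series).
#' @export
trend_test <- function(annual) {
  stopifnot(nrow(annual) >= 3)
  slope <- unname(stats::coef(stats::lm(value ~ year, data = annual))[2])
  if (stats::sd(annual$value) == 0)
    return(list(slope = slope, rho = NA_real_, p_raw = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(annual$value, annual$year, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(slope = slope, rho = unname(ct$estimate), p_raw = ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, order-preserving wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order (empty in, empty out).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-location climate trends with significance calls
#'
#' For every (location, variable) series: annualise (month-of-maximum for
#' tmax, deseasonalised trend for ppt), fit the OLS slope, compute the
#' Spearman P, adjust within each variable by Benjamini-Hochberg, and call
#' a direction: `"increase"`/`"decrease"` by slope sign when
#' `p_adj < alpha`, else `"none"`.
#'
#' @param climate long data.frame: `location_id`, `variable` (`"ppt"` or
#'   `"tmax"`), `year`, `month`, `value`.
#' @param alpha significance level on adjusted P (default 0.01).
#' @return data.frame `location_id`, `variable`, `slope`, `rho`, `p_raw`,
#'   `p_adj`, `direction`.
#' @export
climate_trends <- function(climate, alpha = 0.01) {
  stopifnot(all(climate$variable %in% c("ppt", "tmax")))
  groups <- split(climate, list(climate$location_id, climate$variable),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    annual <- if (g$variable[1] == "tmax") annual_tmax(g) else
      decompose_trend(g)
    tt <- trend_test(annual)
    data.frame(location_id = g$location_id[1], variable = g$variable[1],
               slope = tt$slope, rho = tt$rho, p_raw = tt$p_raw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (v in unique(out$variable)) {
    sel <- out$variable == v & !is.na(out$p_raw)
    out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
  }
  sig <- !is.na(out$p_adj) & out$p_adj < alpha
  out$direction <- ifelse(sig, ifelse(out$slope > 0, "increase", "decrease"),
                          "none")
  out
}

#' Classify a sample pair by matching climate-change direction
#'
#' `"matching_increase"`/`"matching_decrease"` iff both locations show a
#' significant trend in the same direction; every other combination —
#' neither significant, only one significant, or opposing directions — is
#' `"unmatched"`. Symmetric in its two arguments.
#'
#' @param trend_hist,trend_mod single rows of a [climate_trends()] table
#'   (or lists with `variable` and `direction`), same variable.
#' @return classification string.
#' @export
classify_pair <- function(trend_hist, trend_mod) {
  if (trend_hist$variable != trend_mod$variable)
    stop("classify_pair: variable mismatch (", trend_hist$variable,
         " vs ", trend_mod$variable, ")")
  d1 <- trend_hist$direction; d2 <- trend_mod$direction
  if (d1 == d2 && d1 == "increase") return("matching_increase")
  if (d1 == d2 && d1 == "decrease") return("matching_decrease")
  "unmatched"
}

#' Climate classification for a pair table
#'
#' @param pairs pair data.frame ([pair_samples()]).
#' @param trends a [climate_trends()] table whose `location_id` values are
#'   sample ids (one location per sample).
#' @param variable which variable to classify on (default `"ppt"`).
#' @return `pairs` with an added `climate_class` column (NA when either
#'   member lacks a trend row).
#' @export
classify_pairs <- function(pairs, trends, variable = "ppt") {
  tr <- trends[trends$variable == variable, ]
  ih <- match(pairs$hist_id, tr$location_id)
  im <- match(pairs$mod_id, tr$location_id)
  cls <- rep(NA_character_, nrow(pairs))
  ok <- !is.na(ih) & !is.na(im)
  cls[ok] <- mapply(function(a, b)
    classify_pair(tr[a, ], tr[b, ]), ih[ok], im[ok])
  pairs$climate_class <- cls
  pairs
}
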