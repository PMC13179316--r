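#' Map a zone index to the normalized lobular position
#'
#' The lobular position `x` is normalized from 0 (portal field) to 1
#' (central vein), which makes fitted gradients comparable independent of
#' the number of zones. Zone *centers* are used: `x = 1 - (zone - 0.5) /
#' n_zones`. Zone 1 (pericentral) maps near 1, zone `n_zones` (periportal)
#' near 0 — the position axis runs opposite to portality.
#'
#' @param zone_index integer zone in `1..n_zones` (vectorized).
#' @param n_zones number of zones (default 12).
#' @return position(s) in `[0, 1]`.
#' @export
zone_to_position <- function(zone_index, n_zones = 12L) {
  if (any(zone_index < 1L | zone_index > n_zones)) {
    stop("zone index out of range 1..", n_zones, call. = FALSE)
  }
  1 - (zone_index - 0.5) / n_zones
}

# closed-form OLS; exact on collinear points
ols <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(NULL)
  slope <- stats::cov(x, y) / vx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Fit per-lobule linear zonal trends
#'
#' For every lobule, the response (steatosis fraction or a marker's positive
#' ratio) is modeled as a linear function of the lobular position,
#' `p(x) = m*x + p0`, by minimizing the squared error. Zones in
#' `cfg$excluded_zones` and zones with absent response are dropped before
#' fitting; lobules with fewer than 2 usable zones yield an absent fit with
#' a flag rather than an error.
#'
#' @param table joint quantification table (from [join_records()] or a
#'   single-stain record table).
#' @param response name of the response column (e.g. `"steatosis"`).
#' @param cfg a [quant_config()].
#' @return tibble with one row per lobule: `lobule_id`, `response`,
#'   `predictor` (`"position"`), `slope`, `intercept`, `n_points`, `flag`.
#' @export
fit_zonal_trends <- function(table, response, cfg = quant_config()) {
  stopifnot(response %in% names(table))
  tab <- table[!table$zone %in% cfg$excluded_zones, ]
  fit_by_lobule(tab, x = zone_to_position(tab$zone, cfg$n_zones),
                y = tab[[response]], response = response,
                predictor = "position")
}

#' Fit per-lobule marker-versus-steatosis relations
#'
#' Models a marker's positive ratio as a linear function of the steatosis
#' fraction, `p(s) = m_s*s + p_s0`, per lobule, over the zones where both
#' values are present. If all steatosis values in a lobule are identical the
#' predictor is degenerate and the fit is absent with flag
#' `"degenerate_predictor"` (returning infinite slopes would poison the
#' summaries, as a steatosis-free control does).
#'
#' @param table joint quantification table containing `steatosis` and the
#'   marker column.
#' @param marker marker column name.
#' @param cfg a [quant_config()].
#' @return tibble as in [fit_zonal_trends()] with `predictor = "steatosis"`.
#' @export
fit_marker_vs_steatosis <- function(table, marker, cfg = quant_config()) {
  stopifnot(all(c("steatosis", marker) %in% names(table)))
  tab <- table[!table$zone %in% cfg$excluded_zones, ]
  fit_by_lobule(tab, x = tab$steatosis, y = tab[[marker]],
                response = marker, predictor = "steatosis")
}

fit_by_lobule <- function(tab, x, y, response, predictor) {
  ids <- unique(tab$lobule_id)
  res <- lapply(ids, function(id) {
    sel <- tab$lobule_id == id & !is.na(x) & !is.na(y)
    n <- sum(sel)
    if (n < 2L) {
      return(tibble::tibble(lobule_id = id, response = response,
                            predictor = predictor, slope = NA_real_,
                            intercept = NA_real_, n_points = n,
                            flag = "insufficient_points"))
    }
    f <- ols(x[sel], y[sel])
    if (is.null(f)) {
      return(tibble::tibble(lobule_id = id, response = response,
                            predictor = predictor, slope = NA_real_,
                            intercept = NA_real_, n_points = n,
                            flag = "degenerate_predictor"))
    }
    tibble::tibble(lobule_id = id, response = response, predictor = predictor,
                   slope = f$slope, intercept = f$intercept, n_points = n,
                   flag = "")
  })
  dplyr::bind_rows(res)
}

#' Summarize per-lobule fits across a slide
#'
#' Median, mean, standard deviation, quartiles and 1.5*IQR whiskers
#' (Tukey convention: whiskers reach the most extreme value within 1.5 times
#' the interquartile range beyond the quartiles) of the slopes and
#' intercepts over all lobules with a present fit; absent fits are excluded
#' and counted.
#'
#' @param fits tibble from [fit_zonal_trends()] /
#'   [fit_marker_vs_steatosis()] (may mix responses/predictors; summaries
#'   are grouped).
#' @return tibble with one row per (response, predictor): statistics of
#'   `slope` and `intercept` (`*_median`, `*_mean`, `*_sd`, `*_q1`, `*_q3`,
#'   `*_whisker_lo`, `*_whisker_hi`), `n_lobules`, `n_absent`.
#' @export
summarize_fits <- function(fits) {
  if (nrow(fits) == 0L) stop("no fits to summarize", call. = FALSE)
  grp <- unique(fits[c("response", "predictor")])
  res <- lapply(seq_len(nrow(grp)), function(i) {
    sub <- fits[fits$response == grp$response[i] &
                  fits$predictor == grp$predictor[i], ]
    ok <- sub[!is.na(sub$slope), ]
    stats_of <- function(v) {
      if (length(v) == 0L) {
        return(stats::setNames(rep(NA_real_, 7),
                               c("median", "mean", "sd", "q1", "q3",
                                 "whisker_lo", "whisker_hi")))
      }
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      c(median = stats::median(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        q1 = q[1], q3 = q[2],
        whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
        whisker_hi = max(v[v <= q[2] + 1.5 * iqr]))
    }
    s <- stats_of(ok$slope); p <- stats_of(ok$intercept)
    tibble::tibble(response = grp$response[i], predictor = grp$predictor[i],
                   !!!stats::setNames(as.list(s), paste0("slope_", names(s))),
                   !!!stats::setNames(as.list(p), paste0("intercept_", names(p))),
                   n_lobules = nrow(ok), n_absent = nrow(sub) - nrow(ok))
  })
  dplyr::bind_rows(res)
}
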