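#' Dual-channel color map of joint zonated results
#'
#' Projects the joint table back onto the lobular geometry: blue intensity
#' encodes steatosis, red the marker's positive ratio, so magenta marks
#' joint presence and black the absence of both signals; the green channel
#' is identically zero. Values are scaled by the configurable channel
#' maxima, absent marker cells render as red 0, background stays black, and
#' the raster is downsampled by nearest neighbor.
#'
#' @param table joint quantification table.
#' @param lobules,zones label maps in the table's frame.
#' @param marker marker column name.
#' @param scaling named vector `c(steatosis_max=, marker_max=)`; channel
#'   values are `255 * min(value/max, 1)`.
#' @param downsample integer nearest-neighbor downsampling factor
#'   (default 4).
#' @return a `zq_dualchannel` object: list with `rgb` array (0..255),
#'   `channel_scaling`, `downsample_factor`.
#' @export
render_dual_channel <- function(table, lobules, zones, marker,
                                scaling = c(steatosis_max = 0.5, marker_max = 1),
                                downsample = 4L) {
  if (any(scaling <= 0)) stop("channel scaling maxima must be positive", call. = FALSE)
  nz <- zones$n_zones
  nkeys <- max(lobules$labels) * nz
  sval <- rep(0, nkeys); mval <- rep(0, nkeys)
  key_tab <- (table$lobule_label - 1L) * nz + table$zone
  if ("steatosis" %in% names(table)) {
    sval[key_tab] <- ifelse(is.na(table$steatosis), 0, table$steatosis)
  }
  mval[key_tab] <- ifelse(is.na(table[[marker]]), 0, table[[marker]])

  lab <- subsample_nn(lobules$labels, downsample)
  zon <- subsample_nn(zones$zones, downsample)
  nr <- nrow(lab); nc <- ncol(lab)
  rch <- base::matrix(0, nr, nc); bch <- base::matrix(0, nr, nc)
  fg <- lab > 0L
  key <- (lab[fg] - 1L) * nz + zon[fg]
  bch[fg] <- 255 * pmin(sval[key] / scaling[["steatosis_max"]], 1)
  rch[fg] <- 255 * pmin(mval[key] / scaling[["marker_max"]], 1)
  rgb <- array(0, dim = c(nr, nc, 3))
  rgb[, , 1] <- rch; rgb[, , 3] <- bch
  structure(list(rgb = rgb, channel_scaling = scaling,
                 downsample_factor = as.integer(downsample)),
            class = "zq_dualchannel")
}

#' Write an RGB array (0..255) as PNG
#'
#' @param rgb array `[rows, cols, 3]`.
#' @param path output path.
#' @export
write_image_png <- function(rgb, path) {
  if (inherits(rgb, "zq_dualchannel")) rgb <- rgb$rgb
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Per-zone mean and covariance ellipses
#'
#' For every analyzed zone, the mean vector and sample covariance of
#' `(steatosis, marker)` across all lobules with both values present. Zones
#' with fewer than 2 complete observations are skipped with a message. The
#' ellipse drawn from these is the mean plus/minus the principal axes scaled
#' by one standard deviation.
#'
#' @param table joint quantification table.
#' @param marker marker column name.
#' @param cfg a [quant_config()]; its `excluded_zones` are dropped.
#' @return tibble: `zone`, `n_lobules`, `mean_steatosis`, `mean_marker`,
#'   `cov_ss`, `cov_sm`, `cov_mm`.
#' @export
zone_ellipses <- function(table, marker, cfg = quant_config()) {
  stopifnot(all(c("steatosis", marker) %in% names(table)))
  tab <- table[!table$zone %in% cfg$excluded_zones, ]
  zs <- sort(unique(tab$zone))
  res <- lapply(zs, function(z) {
    sub <- tab[tab$zone == z, ]
    ok <- !is.na(sub$steatosis) & !is.na(sub[[marker]])
    if (sum(ok) < 2L) {
      message("zone ", z, ": fewer than 2 complete observations, skipped")
      return(NULL)
    }
    s <- sub$steatosis[ok]; p <- sub[[marker]][ok]
    cv <- stats::cov(cbind(s, p))
    tibble::tibble(zone = z, n_lobules = sum(ok),
                   mean_steatosis = mean(s), mean_marker = mean(p),
                   cov_ss = cv[1, 1], cov_sm = cv[1, 2], cov_mm = cv[2, 2])
  })
  dplyr::bind_rows(res)
}

# polygon points of the 1-sd ellipse of a 2x2 covariance
ellipse_points <- function(mx, my, cov_ss, cov_sm, cov_mm, n = 72L) {
  e <- eigen(base::matrix(c(cov_ss, cov_sm, cov_sm, cov_mm), 2, 2),
             symmetric = TRUE)
  lam <- sqrt(pmax(e$values, 0))
  t <- seq(0, 2 * pi, length.out = n)
  pts <- e$vectors %*% rbind(lam[1] * cos(t), lam[2] * sin(t))
  tibble::tibble(x = mx + pts[1, ], y = my + pts[2, ])
}

#' Scatter plot of marker versus steatosis with per-zone ellipses
#'
#' One dot per (lobule, zone) — steatosis fraction on the horizontal axis,
#' positive-ratio on the vertical axis — colored by zone on the viridis
#' colormap with yellow periportal and dark blue pericentral, overlaid with
#' the per-zone mean/standard-deviation ellipses.
#'
#' @param table joint quantification table.
#' @param marker marker column name.
#' @param cfg a [quant_config()].
#' @param path optional PNG output path; a CSV sidecar with the plotted
#'   numbers (dots and ellipse parameters) is written next to it.
#' @return the ggplot object (invisibly when `path` given).
#' @export
scatter_plot <- function(table, marker, cfg = quant_config(), path = NULL) {
  tab <- table[!table$zone %in% cfg$excluded_zones, ]
  dots <- tibble::tibble(steatosis = tab$steatosis, marker = tab[[marker]],
                         zone = tab$zone, lobule_id = tab$lobule_id)
  dots <- dots[!is.na(dots$steatosis) & !is.na(dots$marker), ]
  if (nrow(dots) == 0L) warning("no complete (steatosis, ", marker, ") pairs to plot")
  ell <- zone_ellipses(table, marker, cfg)
  gg <- ggplot2::ggplot(dots, ggplot2::aes(x = .data$steatosis, y = .data$marker,
                                           color = .data$zone)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_viridis_c(limits = c(1, cfg$n_zones), name = "zone") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "steatosis (fat droplet area fraction)",
                  y = paste0(marker, " (positive ratio)")) +
    ggplot2::theme_minimal()
  if (nrow(ell)) {
    paths <- dplyr::bind_rows(lapply(seq_len(nrow(ell)), function(i) {
      p <- ellipse_points(ell$mean_steatosis[i], ell$mean_marker[i],
                          ell$cov_ss[i], ell$cov_sm[i], ell$cov_mm[i])
      p$zone <- ell$zone[i]
      p
    }))
    gg <- gg + ggplot2::geom_path(data = paths,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               group = .data$zone,
                                               color = .data$zone),
                                  linewidth = 0.7, inherit.aes = FALSE)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = 6, height = 5, dpi = 150)
    utils::write.csv(dots, sub("\\.png$", "_dots.csv", path), row.names = FALSE)
    utils::write.csv(ell, sub("\\.png$", "_ellipses.csv", path), row.names = FALSE)
    return(invisible(gg))
  }
  gg
}

#' Box-and-whisker plot
#'
#' Tukey convention: median line, first/third-quartile box, whiskers
#' extending to the most extreme point within 1.5 times the interquartile
#' range, and values beyond the whiskers drawn as circles.
#'
#' @param data tibble with the plotted values.
#' @param value name of the value column.
#' @param group name of the grouping column (e.g. `"zone"`).
#' @param path optional PNG output path; writes a CSV sidecar with the
#'   per-group box statistics.
#' @return the ggplot object (invisibly when `path` given).
#' @export
box_whisker <- function(data, value, group, path = NULL) {
  stopifnot(all(c(value, group) %in% names(data)))
  d <- data[!is.na(data[[value]]), ]
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[group]]),
                                        y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = group, y = value) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    stats_tab <- dplyr::bind_rows(lapply(split(d[[value]], d[[group]]), function(v) {
      b <- grDevices::boxplot.stats(v)
      tibble::tibble(whisker_lo = b$stats[1], q1 = b$stats[2],
                     median = b$stats[3], q3 = b$stats[4],
                     whisker_hi = b$stats[5], n = b$n,
                     n_outliers = length(b$out))
    }), .id = group)
    ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 150)
    utils::write.csv(stats_tab, sub("\\.png$", "_stats.csv", path),
                     row.names = FALSE)
    return(invisible(gg))
  }
  gg
}
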