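#' Compute the portality field
#'
#' Portality encodes the relative position of every pixel along the
#' porto-central axis:
#' `portality(x) = 1 - dist(x, closest PF) / (dist(x, closest PF) + dist(x, closest CV))`,
#' i.e. 1 at the nearest portal field, 0 at the nearest central vein, and 0.5
#' on the PF/CV equidistant locus. Distances are Euclidean in pixel units and
#' assume isotropic spacing.
#'
#' Pixel `[row r, col c]` (1-based R indexing) sits at position
#' `(x, y) = (c-1, r-1)`.
#'
#' @param shape integer vector `c(rows, cols)` of the output raster.
#' @param pf_centers,cv_centers n x 2 matrices (or tibbles with `x`, `y`
#'   columns) of vessel center points.
#' @param resolution_um_per_px pixel size carried as metadata (default 1).
#' @return a `zq_portality` object: list with `values` (matrix `[row, col]`
#'   in `[0, 1]`) and `resolution_um_per_px`.
#' @export
compute_portality <- function(shape, pf_centers, cv_centers,
                              resolution_um_per_px = 1) {
  pf <- as_points(pf_centers)
  cv <- as_points(cv_centers)
  if (nrow(pf) == 0L || nrow(cv) == 0L) {
    stop("portality is undefined without at least one PF and one CV center",
         call. = FALSE)
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  oob <- function(p) any(p[, 1] < 0 | p[, 1] > nc - 1 | p[, 2] < 0 | p[, 2] > nr - 1)
  if (oob(pf) || oob(cv)) {
    warning("vessel center(s) outside the raster bounds; portality computed anyway")
  }
  dpf <- min_dist2_field(nr, nc, pf)
  dcv <- min_dist2_field(nr, nc, cv)
  dpf <- sqrt(dpf); dcv <- sqrt(dcv)
  denom <- dpf + dcv
  p <- ifelse(denom == 0, 0.5, 1 - dpf / denom)
  structure(list(values = p, resolution_um_per_px = resolution_um_per_px),
            class = "zq_portality")
}

# squared distance to the nearest of a set of centers, on the pixel grid
min_dist2_field <- function(nr, nc, centers) {
  .min_dist2_field_cpp(as.integer(nr), as.integer(nc),
                       base::matrix(as.numeric(centers), ncol = 2))
}

as_points <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  if (is.null(p) || length(p) == 0L) return(matrix(numeric(0), 0, 2))
  m <- base::matrix(as.numeric(p), ncol = 2)
  if (anyNA(m)) stop("center points must be finite", call. = FALSE)
  m
}

#' @export
print.zq_portality <- function(x, ...) {
  cat(sprintf("<zq_portality> %dx%d, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Segment lobules as watershed catchment basins
#'
#' Lobules are the catchment basins of a pre-flooded watershed transform of
#' the portality surface: one basin per central vein (a minimum of the
#' portality), with minima shallower than `preflood_height` merged into their
#' neighbours before flooding. Basins are relabeled `1..n` in ascending
#' `(y, x)` order of their seed CV center, and each label is linked to the
#' CV's UUID. Two CVs falling into one merged basin share a label and are
#' reported with a warning; basins that contain no CV (spurious discrete
#' minima that survived pre-flooding) are merged into the basin of the
#' nearest CV.
#'
#' @param p a [compute_portality()] result.
#' @param cv_centers tibble with `id`, `x`, `y` columns (e.g. from
#'   [vessel_centers()]), or an n x 2 matrix (UUIDs then generated).
#' @param preflood_height pre-flooding height in portality units
#'   (default 0.05).
#' @return a `zq_lobules` object: list with `labels` (integer matrix,
#'   0 = none), `cv_index` (tibble `label`, `id`, `x`, `y`) and `merged`
#'   (tibble of CVs sharing a basin, possibly empty).
#' @export
segment_lobules <- function(p, cv_centers, preflood_height = 0.05) {
  stopifnot(inherits(p, "zq_portality"))
  if (preflood_height < 0 || preflood_height >= 1) {
    stop("preflood_height must lie in [0, 1)", call. = FALSE)
  }
  if (is.matrix(cv_centers)) {
    cv_centers <- tibble::tibble(id = zq_uuid4(nrow(cv_centers)),
                                 x = cv_centers[, 1], y = cv_centers[, 2])
  }
  nr <- nrow(p$values); nc <- ncol(p$values)
  ri <- pmin(pmax(round(cv_centers$y) + 1L, 1L), nr)
  ci <- pmin(pmax(round(cv_centers$x) + 1L, 1L), nc)
  if (any(round(cv_centers$y) + 1 != ri) || any(round(cv_centers$x) + 1 != ci)) {
    stop("every CV center must lie inside the raster", call. = FALSE)
  }

  w <- pmax(1 - p$values, 1e-9)  # invert so CVs are peaks; keep all pixels > 0
  raw <- from_ebimage(EBImage::watershed(as_ebimage(w),
                                         tolerance = preflood_height, ext = 1))
  raw <- base::matrix(as.integer(raw), nr, nc)

  # deterministic relabeling in ascending (y, x) order of the seed CV
  ord <- order(cv_centers$y, cv_centers$x)
  cv_ord <- cv_centers[ord, , drop = FALSE]
  basin_at_cv <- raw[cbind(ri[ord], ci[ord])]

  new_of_basin <- integer(max(raw))
  label_of_cv <- integer(nrow(cv_ord))
  nxt <- 0L
  for (k in seq_along(basin_at_cv)) {
    b <- basin_at_cv[k]
    if (b == 0L) { # CV on a ridge pixel: adopt the dominant neighbour basin
      nb <- raw[pmax(ri[ord][k] - 1, 1):pmin(ri[ord][k] + 1, nr),
                pmax(ci[ord][k] - 1, 1):pmin(ci[ord][k] + 1, nc)]
      nb <- nb[nb > 0]
      b <- if (length(nb)) as.integer(names(which.max(table(nb)))) else 0L
    }
    if (b > 0L && new_of_basin[b] == 0L) {
      nxt <- nxt + 1L
      new_of_basin[b] <- nxt
    }
    label_of_cv[k] <- if (b > 0L) new_of_basin[b] else NA_integer_
  }

  merged <- cv_ord[duplicated(label_of_cv) | duplicated(label_of_cv, fromLast = TRUE), ]
  if (nrow(merged) > 0) {
    warning(sprintf("%d CV center(s) share a pre-flooded basin (merged lobule)",
                    nrow(merged)))
  }

  # basins without a seed: merge into the basin of the nearest CV center
  unseeded <- which(new_of_basin == 0L)
  if (length(unseeded)) {
    for (b in unseeded) {
      px <- which(raw == b)
      cy <- mean((px - 1L) %% nr)       # 0-based row -> y
      cx <- mean((px - 1L) %/% nr)      # 0-based col -> x
      nearest <- which.min((cv_ord$x - cx)^2 + (cv_ord$y - cy)^2)
      new_of_basin[b] <- label_of_cv[nearest]
    }
  }

  labels <- base::matrix(0L, nr, nc)
  pos <- raw > 0L
  labels[pos] <- new_of_basin[raw[pos]]

  keep <- !duplicated(label_of_cv)
  structure(
    list(labels = labels,
         cv_index = tibble::tibble(label = label_of_cv[keep], id = cv_ord$id[keep],
                                   x = cv_ord$x[keep], y = cv_ord$y[keep]),
         merged = tibble::as_tibble(merged)),
    class = "zq_lobules"
  )
}

#' @export
print.zq_lobules <- function(x, ...) {
  cat(sprintf("<zq_lobules> %dx%d, %d lobule(s)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$cv_index)))
  invisible(x)
}

#' Quantize portality into zones
#'
#' Each lobule is divided into `n_zones` (default 12) portality-quantile
#' zones using half-open intervals `[(i-1)/n, i/n)` with the top edge closed:
#' `zone = clamp(floor(portality * n_zones) + 1, 1, n_zones)`. Zone 1 is the
#' most pericentral band (portality near 0), zone `n_zones` the most
#' periportal (portality near 1). Background (no lobule) is zone 0.
#'
#' @param p a [compute_portality()] result.
#' @param lobules a [segment_lobules()] result.
#' @param n_zones number of zones (default 12).
#' @return a `zq_zones` object: list with `zones` (integer matrix) and
#'   `n_zones`.
#' @export
quantize_zones <- function(p, lobules, n_zones = 12L) {
  stopifnot(inherits(p, "zq_portality"), inherits(lobules, "zq_lobules"))
  if (n_zones < 2L) stop("n_zones must be >= 2", call. = FALSE)
  if (!all(dim(p$values) == dim(lobules$labels))) {
    stop("portality and lobule map shapes differ", call. = FALSE)
  }
  z <- pmin(pmax(floor(p$values * n_zones) + 1L, 1L), as.integer(n_zones))
  z <- base::matrix(as.integer(z), nrow(z), ncol(z))
  z[lobules$labels == 0L] <- 0L
  structure(list(zones = z, n_zones = as.integer(n_zones)), class = "zq_zones")
}

#' Write / read label maps and portality as TIFF
#'
#' Rasters are stored as single-channel 32-bit float TIFF. The writer clamps
#' samples to `[0, 1]`, so label maps are scaled by `1/scale` on write and
#' back on read; with the default power-of-two scale this is exact for
#' integer labels below 2^24. For lobule maps a JSON sidecar carries the
#' label-to-CV-UUID index.
#'
#' @param m numeric or integer matrix. Portality fits `[0, 1]` natively
#'   (use `scale = 1`); label maps need `scale = 2^15` (the default of
#'   [write_label_tiff()]).
#' @param path output `.tif` path.
#' @param scale values are divided by `scale` on write and multiplied back on
#'   read.
#' @export
write_raster_tiff <- function(m, path, scale = 1) {
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @param integer round the values read back to integers (label maps).
#' @export
read_raster_tiff <- function(path, scale = 1, integer = FALSE) {
  m <- tiff::readTIFF(path, as.is = FALSE) * scale
  if (integer) {
    m <- base::matrix(as.integer(round(m)), nrow(m), ncol(m))
  }
  m
}

#' @rdname write_raster_tiff
#' @export
write_label_tiff <- function(m, path, scale = 2^15) {
  write_raster_tiff(m, path, scale = scale)
}

#' @rdname write_raster_tiff
#' @export
read_label_tiff <- function(path, scale = 2^15) {
  read_raster_tiff(path, scale = scale, integer = TRUE)
}
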