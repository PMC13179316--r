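#' Tissue mask from a brightfield RGB image
#'
#' Stained tissue absorbs light against a bright background, so tissue is
#' taken as the pixels *darker* than Otsu's threshold on the luminance image.
#' Optional cleanup: morphological closing with a 3-px-radius disk, filling
#' of enclosed holes (vessel lumina, lipid vacuoles — areas the downstream
#' color classes must see), and removal of connected components below
#' `min_component_px`.
#'
#' @param rgb RGB array `[rows, cols, 3]` with 8-bit values (0..255).
#' @param cleanup apply morphological cleanup (default TRUE).
#' @param fill_holes fill enclosed bright holes (default TRUE).
#' @param min_component_px drop components smaller than this (default 64).
#' @return a `zq_tissue_mask` object: list with logical `mask` and the Otsu
#'   `threshold` on the 0..255 luminance scale.
#' @export
compute_tissue_mask <- function(rgb, cleanup = TRUE, fill_holes = TRUE,
                                min_component_px = 64L) {
  stopifnot_rgb(rgb)
  g <- zq_gray(rgb)
  if (length(unique(round(as.vector(g)))) < 2L) {
    stop("degenerate single-valued image: Otsu threshold undefined", call. = FALSE)
  }
  thr <- EBImage::otsu(as_ebimage(g / 255), range = c(0, 1), levels = 256) * 255
  mask <- g < thr
  if (cleanup) {
    img <- as_ebimage(mask * 1)
    img <- EBImage::closing(img, EBImage::makeBrush(7L, "disc"))
    if (fill_holes) img <- EBImage::fillHull(img)
    lab <- EBImage::bwlabel(img)
    m <- from_ebimage(lab)
    if (max(m) > 0) {
      sizes <- tabulate(m[m > 0], nbins = max(m))
      keep <- which(sizes >= min_component_px)
      mask <- base::matrix(m %in% keep, nrow(m), ncol(m))
    } else {
      mask <- m > 0
    }
  }
  structure(list(mask = mask, threshold = thr), class = "zq_tissue_mask")
}

#' Fit the three-class color model by expectation maximization
#'
#' A 3-component Gaussian mixture is fitted to the tissue-masked RGB
#' distribution. Following standard practice for whole-slide images, EM runs
#' on the *binned* 3D RGB histogram rather than on raw pixels: each occupied
#' bin contributes its mean color weighted by its pixel count, which is
#' orders of magnitude faster and numerically equivalent for practical bin
#' widths. Initialization is seeded k-means++ on the weighted bin colors;
#' the fit is deterministic given `seed`.
#'
#' @param rgb RGB array (0..255).
#' @param tissue a [compute_tissue_mask()] result (or logical matrix).
#' @param seed integer RNG seed for the k-means++ initialization.
#' @param bins histogram bins per channel (default 64).
#' @param max_iter EM iteration cap (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-5).
#' @return a `zq_color_model`: list with `means` (3x3 matrix, one RGB row per
#'   class), `weights`, `covariances` (list of 3x3), `semantics` (NULL until
#'   [assign_semantics()]), `seed`, `loglik` trace.
#' @export
fit_color_classes <- function(rgb, tissue, seed = 1L, bins = 64L,
                              max_iter = 200L, tol = 1e-5) {
  stopifnot_rgb(rgb)
  mask <- tissue_mask_of(tissue)
  idx <- which(mask)
  if (length(idx) == 0L) stop("tissue mask is empty", call. = FALSE)
  px <- cbind(rgb[, , 1][idx], rgb[, , 2][idx], rgb[, , 3][idx])
  if (nrow(unique(px)) < 3L) {
    stop("fewer than 3 distinct colors under the tissue mask", call. = FALSE)
  }

  # aggregate to the binned histogram: per-bin mean color + count
  bw <- 256 / bins
  key <- floor(px[, 1] / bw) + bins * floor(px[, 2] / bw) +
    bins^2 * floor(px[, 3] / bw) + 1
  cnt <- tabulate(key, nbins = bins^3)
  occ <- which(cnt > 0)
  sums <- rowsum(px, key, reorder = TRUE)  # sorted by key = occ order
  pts <- sums / cnt[occ]
  w <- cnt[occ]

  fit <- withr::with_seed(as.integer(seed), weighted_gmm_em(pts, w, k = 3L,
                                                            max_iter = max_iter,
                                                            tol = tol))
  structure(list(means = fit$means, weights = fit$weights,
                 covariances = fit$covariances, semantics = NULL,
                 seed = as.integer(seed), loglik = fit$loglik,
                 converged = fit$converged),
            class = "zq_color_model")
}

tissue_mask_of <- function(tissue) {
  if (inherits(tissue, "zq_tissue_mask")) tissue$mask else tissue
}

# Weighted EM for a k-component full-covariance Gaussian mixture.
# pts: n x d, w: n weights (counts). Deterministic under the current RNG.
weighted_gmm_em <- function(pts, w, k = 3L, max_iter = 200L, tol = 1e-5,
                            ridge = 0.1) {
  n <- nrow(pts); d <- ncol(pts)
  W <- sum(w)

  # k-means++ seeding on weighted points
  centers <- base::matrix(0, k, d)
  centers[1, ] <- pts[sample.int(n, 1, prob = w), ]
  d2 <- rowSums((pts - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1) + 1) {
    pr <- w * d2
    centers[j, ] <- pts[if (sum(pr) > 0) sample.int(n, 1, prob = pr) else sample.int(n, 1), ]
    d2 <- pmin(d2, rowSums((pts - rep(centers[j, ], each = n))^2))
  }
  # a few weighted Lloyd iterations to stabilize the seeds
  for (it in 1:10) {
    D <- dist2_to_centers(pts, centers)
    a <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      sel <- a == j
      if (any(sel)) centers[j, ] <- colSums(pts[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    }
  }

  means <- centers
  covs <- replicate(k, diag(ridge + stats::var(as.vector(pts)), d), simplify = FALSE)
  wgt <- rep(1 / k, k)
  ll_trace <- numeric(0)
  converged <- FALSE
  logw <- log(w)

  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j) {
      log(wgt[j]) + dmvnorm_log(pts, means[j, ], covs[[j]])
    }, numeric(n))
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(w * lse)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <= tol * abs(ll_trace[it - 1])) {
      converged <- TRUE
      break
    }
    r <- exp(logp - lse)           # n x k responsibilities
    rw <- r * w
    nk <- colSums(rw)
    wgt <- nk / W
    for (j in seq_len(k)) {
      mu <- colSums(pts * rw[, j]) / nk[j]
      cen <- pts - rep(mu, each = n)
      covj <- crossprod(cen * rw[, j], cen) / nk[j]
      covs[[j]] <- covj + diag(ridge, d)
      means[j, ] <- mu
    }
  }
  if (!converged && max_iter > 1) {
    stop("EM did not converge after ", max_iter, " iterations; log-likelihood trace: ",
         paste(sprintf("%.6g", utils::tail(ll_trace, 5)), collapse = ", "),
         call. = FALSE)
  }
  list(means = means, weights = wgt, covariances = covs,
       loglik = ll_trace, converged = converged)
}

dist2_to_centers <- function(pts, centers) {
  n <- nrow(pts)
  d <- vapply(seq_len(nrow(centers)), function(j) {
    rowSums((pts - rep(centers[j, ], each = n))^2)
  }, numeric(n))
  base::matrix(d, nrow = n)
}

dmvnorm_log <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi)
}

#' Assign class semantics to a fitted color model
#'
#' The three mixture components are mapped to `unstained`, `positive`,
#' `negative`: the component with the highest luminance mean is `unstained`
#' (lipid vacuoles, vessel lumina, void); of the remaining two, the one
#' nearer (Euclidean RGB) to `positive_reference_rgb` (default a DAB brown)
#' is `positive`, the other `negative`. An exact tie is broken toward the
#' lower-luminance component with a warning.
#'
#' @param model a [fit_color_classes()] result.
#' @param positive_reference_rgb RGB triple of the positive chromogen
#'   (default DAB brown `c(140, 110, 80)`).
#' @param unstained_reference_rgb retained for config symmetry; unstained is
#'   selected by luminance.
#' @return the model with `semantics` set: named integer vector mapping
#'   `unstained`/`positive`/`negative` to component indices.
#' @export
assign_semantics <- function(model, positive_reference_rgb = c(140, 110, 80),
                             unstained_reference_rgb = c(245, 245, 245)) {
  stopifnot(inherits(model, "zq_color_model"))
  lum <- apply(model$means, 1, zq_luminance)
  unst <- which.max(lum)
  rest <- setdiff(1:3, unst)
  dref <- sqrt(rowSums((model$means[rest, , drop = FALSE] -
                          rep(positive_reference_rgb, each = 2))^2))
  if (abs(dref[1] - dref[2]) < 1e-9) {
    warning("two classes equally near the positive reference; tie broken toward lower luminance")
    pos <- rest[which.min(lum[rest])]
  } else {
    pos <- rest[which.min(dref)]
  }
  neg <- setdiff(rest, pos)
  model$semantics <- c(unstained = unst, positive = pos, negative = neg)
  model
}

#' @export
print.zq_color_model <- function(x, ...) {
  cat("<zq_color_model> 3-class RGB Gaussian mixture\n")
  sem <- x$semantics
  for (j in 1:3) {
    nm <- if (!is.null(sem)) names(sem)[match(j, sem)] else sprintf("class %d", j)
    cat(sprintf("  %-9s mean (%5.1f, %5.1f, %5.1f)  weight %.3f\n",
                nm, x$means[j, 1], x$means[j, 2], x$means[j, 3], x$weights[j]))
  }
  invisible(x)
}

#' Classify each tissue pixel into the ternary stain mask
#'
#' Every tissue pixel is labeled by the *nearest class mean* in Euclidean RGB
#' distance (not by mixture posterior): 1 = unstained, 2 = positive,
#' 3 = negative; pixels outside the tissue mask get 0. Ties go to the lower
#' class index.
#'
#' @param rgb RGB array (0..255).
#' @param model a [fit_color_classes()] model with semantics assigned.
#' @param tissue a [compute_tissue_mask()] result (or logical matrix).
#' @return a `zq_ternary` object: list with integer matrix `labels`
#'   (values 0..3) and the `model`.
#' @export
classify_ternary <- function(rgb, model, tissue) {
  stopifnot_rgb(rgb)
  stopifnot(inherits(model, "zq_color_model"))
  if (is.null(model$semantics)) {
    stop("model semantics not assigned; call assign_semantics() first", call. = FALSE)
  }
  mask <- tissue_mask_of(tissue)
  if (!all(dim(mask) == dim(rgb)[1:2])) stop("tissue mask shape mismatch", call. = FALSE)
  idx <- which(mask)
  labels <- base::matrix(0L, nrow(mask), ncol(mask))
  if (length(idx)) {
    px <- cbind(rgb[, , 1][idx], rgb[, , 2][idx], rgb[, , 3][idx])
    means_sem <- model$means[model$semantics, , drop = FALSE]  # rows: unst, pos, neg
    D <- dist2_to_centers(px, means_sem)
    labels[idx] <- max.col(-D, ties.method = "first")
  }
  structure(list(labels = labels, model = model), class = "zq_ternary")
}

#' Fat detection parameters
#'
#' Macrovesicular fat droplets appear as bright, round vacuoles enclosed by
#' tissue. Candidates are pixels whose every channel exceeds the
#' `brightness_quantile` of the tissue-masked luminance; connected components
#' are then filtered by physical area and circularity `4*pi*A/P^2`. The
#' defaults approximate published fat-detection practice and are deliberately
#' config-exposed.
#'
#' @param brightness_quantile quantile of tissue luminance defining "bright"
#'   (default 0.90).
#' @param min_brightness absolute near-white floor on the candidate
#'   threshold (default 200 of 255). Lipid vacuoles are unstained glass near
#'   the illumination white point; the floor keeps the relative quantile
#'   from sliding into stained-tissue brightness on slides without any
#'   bright population.
#' @param min_area_um2,max_area_um2 droplet area window in square micrometers
#'   (defaults 40 and 5000).
#' @param min_circularity minimum `4*pi*A/P^2` (default 0.5).
#' @param fill_holes fill holes in the candidate mask before labeling.
#' @return a `zq_fat_params` list.
#' @export
fat_params <- function(brightness_quantile = 0.90, min_brightness = 200,
                       min_area_um2 = 40, max_area_um2 = 5000,
                       min_circularity = 0.5, fill_holes = TRUE) {
  stopifnot(min_area_um2 < max_area_um2, min_circularity > 0, min_circularity <= 1.5)
  structure(list(brightness_quantile = brightness_quantile,
                 min_brightness = min_brightness,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_circularity = min_circularity, fill_holes = fill_holes),
            class = "zq_fat_params")
}

#' Detect macrovesicular fat droplets
#'
#' @param rgb RGB array (0..255).
#' @param tissue a [compute_tissue_mask()] result (or logical matrix); the
#'   mask must include enclosed vacuoles (see `fill_holes` of
#'   [compute_tissue_mask()]).
#' @param params a [fat_params()] list.
#' @param resolution_um_per_px pixel size (areas are filtered in um^2).
#' @return a `zq_fat` object: list with logical `mask`, `droplet_count`, and
#'   `droplet_areas` (pixel counts of retained droplets).
#' @export
detect_fat <- function(rgb, tissue, params = fat_params(),
                       resolution_um_per_px = 1) {
  stopifnot_rgb(rgb)
  mask <- tissue_mask_of(tissue)
  empty <- structure(list(mask = base::matrix(FALSE, nrow(mask), ncol(mask)),
                          droplet_count = 0L, droplet_areas = integer(0)),
                     class = "zq_fat")
  if (!any(mask)) return(empty)
  g <- zq_gray(rgb)
  # reference population = stained tissue: pixels under the mask darker than
  # Otsu's threshold. The mask itself includes enclosed vacuoles, which can
  # be a sizeable area fraction; including them would drag the brightness
  # threshold into the vacuole population itself.
  ot <- EBImage::otsu(as_ebimage(g / 255), range = c(0, 1), levels = 256) * 255
  ref <- g[mask & g < ot]
  if (length(ref) < 100L) ref <- g[mask]
  thr <- max(stats::quantile(ref, params$brightness_quantile, names = FALSE),
             params$min_brightness)
  cand <- mask & rgb[, , 1] > thr & rgb[, , 2] > thr & rgb[, , 3] > thr
  if (!any(cand)) return(empty)
  img <- as_ebimage(cand * 1)
  if (params$fill_holes) img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  if (max(lab) == 0) return(empty)
  feats <- EBImage::computeFeatures.shape(lab)
  area_px <- feats[, "s.area"]
  per <- feats[, "s.perimeter"]
  circ <- ifelse(per > 0, 4 * pi * area_px / per^2, 1)
  area_um2 <- area_px * resolution_um_per_px^2
  keep <- which(area_um2 >= params$min_area_um2 &
                  area_um2 <= params$max_area_um2 &
                  circ >= params$min_circularity)
  m <- from_ebimage(lab)
  structure(list(mask = base::matrix(m %in% keep, nrow(m), ncol(m)),
                 droplet_count = length(keep),
                 droplet_areas = as.integer(area_px[keep])),
            class = "zq_fat")
}

#' Serialize / restore a color model as JSON
#'
#' @param model a `zq_color_model`.
#' @param path JSON file path.
#' @export
write_color_model <- function(model, path) {
  stopifnot(inherits(model, "zq_color_model"))
  j <- list(means = model$means, weights = model$weights,
            covariances = model$covariances,
            semantics = as.list(model$semantics), seed = model$seed)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_color_model
#' @export
read_color_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sem <- unlist(j$semantics)
  structure(list(means = base::matrix(j$means, 3, 3),
                 weights = as.numeric(j$weights),
                 covariances = lapply(seq_len(3), function(k) j$covariances[k, , ]),
                 semantics = if (length(sem)) sem else NULL,
                 seed = j$seed),
            class = "zq_color_model")
}
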