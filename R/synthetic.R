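#' Specification for a synthetic lobular slide
#'
#' The generator emulates the statistical structure the pipeline is built
#' for: central veins on a hexagonal lattice with portal fields at the cell
#' vertices, monotone linear stain gradients along the porto-central
#' position `x` (0 = portal field, 1 = central vein), periportal
#' macrovesicular fat droplets, three color populations (unstained vacuoles,
#' positively and negatively stained tissue) and additive Gaussian color
#' noise. Positivity is sampled per pixel (Bernoulli), so a zone's true
#' positive-pixel fraction equals the programmed gradient value by
#' construction — exactly the quantity the ratio-of-areas quantification
#' estimates.
#'
#' Default conditions: 8-bit colors, noise sigma 8 gray levels, a
#' periportal steatosis gradient `s(x) = 0.25 - 0.2*x`, and a three-marker
#' panel with slopes +0.8 (pericentral marker), 0 (uniform), -0.8
#' (periportal marker).
#'
#' @param image_size `c(rows, cols)` in pixels (default 1024 x 1024).
#' @param resolution_um_per_px pixel size (default 0.909, a typical
#'   quarter-resolution WSI scale).
#' @param lattice_pitch_px center-to-center CV distance (default 224).
#' @param jitter_px max uniform jitter applied to each vessel center
#'   (default 0).
#' @param markers named list of `c(slope, intercept)` gradients of the
#'   positive-stain probability versus position `x`.
#' @param steatosis_gradient `c(slope, intercept)` of the fat area fraction
#'   versus `x`, clipped to `[0, 1]`.
#' @param droplet_radius_px integer `c(min, max)` droplet radii
#'   (default 4..8).
#' @param palette named list of RGB triples: `unstained`, `positive`,
#'   `negative`, `background`; triples must be pairwise at least 40 gray
#'   levels apart (Euclidean).
#' @param noise_sigma additive Gaussian noise sd in gray levels (default 8).
#' @param margin_px background border around the tissue rectangle
#'   (default 24).
#' @param seed RNG seed governing layout, Bernoulli draws, droplet placement
#'   and noise.
#' @return a `zq_synthetic_spec` list.
#' @export
synthetic_slide_spec <- function(image_size = c(1024L, 1024L),
                                 resolution_um_per_px = 0.909,
                                 lattice_pitch_px = 224,
                                 jitter_px = 0,
                                 markers = list(
                                   pericentral = c(slope = 0.8, intercept = 0.1),
                                   uniform = c(slope = 0, intercept = 0.5),
                                   periportal = c(slope = -0.8, intercept = 0.9)
                                 ),
                                 steatosis_gradient = c(slope = -0.2, intercept = 0.25),
                                 droplet_radius_px = c(4L, 8L),
                                 palette = list(
                                   unstained = c(245, 243, 240),
                                   positive = c(135, 100, 70),
                                   negative = c(170, 150, 200),
                                   background = c(255, 255, 255)
                                 ),
                                 noise_sigma = 8,
                                 margin_px = 24L,
                                 seed = 1L) {
  if (lattice_pitch_px <= 4 * max(droplet_radius_px)) {
    stop("lattice pitch must exceed 4x the maximum droplet radius", call. = FALSE)
  }
  pal <- rbind(palette$unstained, palette$positive, palette$negative)
  dmat <- as.matrix(stats::dist(pal))
  if (any(dmat[upper.tri(dmat)] < 40)) {
    stop("the unstained/positive/negative palette triples must be pairwise >= 40 gray levels apart",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 resolution_um_per_px = resolution_um_per_px,
                 lattice_pitch_px = lattice_pitch_px, jitter_px = jitter_px,
                 markers = markers, steatosis_gradient = steatosis_gradient,
                 droplet_radius_px = as.integer(droplet_radius_px),
                 palette = palette, noise_sigma = noise_sigma,
                 margin_px = as.integer(margin_px), seed = as.integer(seed)),
            class = "zq_synthetic_spec")
}

#' Generate the vessel layout of a synthetic slide
#'
#' Central veins sit on a hexagonal lattice, portal fields at the hexagon
#' vertices (CV-to-PF distance `pitch/sqrt(3)`). Only CVs whose six PFs fall
#' inside the tissue rectangle are kept, so every generated lobule has its
#' full portal ring. Shared vertices are deduplicated before jitter, fresh
#' v4 UUIDs are drawn, and everything is deterministic given the spec seed.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return a `zq_layout` list: `pf`, `cv` (tibbles `id`, `x`, `y`) and the
#'   `spec`.
#' @export
generate_layout <- function(spec) {
  stopifnot(inherits(spec, "zq_synthetic_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  a <- spec$lattice_pitch_px
  rv <- a / sqrt(3)
  dy <- a * sqrt(3) / 2
  pad <- spec$margin_px + 2
  lo_x <- pad; hi_x <- nc - 1 - pad
  lo_y <- pad; hi_y <- nr - 1 - pad

  jmax <- ceiling((nr + 2 * a) / dy)
  imax <- ceiling((nc + 2 * a) / a)
  cvs <- NULL
  pfs <- NULL
  ang <- pi / 6 + (0:5) * pi / 3
  for (j in 0:jmax) {
    y <- lo_y + rv + j * dy
    for (i in 0:imax) {
      x <- lo_x + rv + i * a + (j %% 2) * a / 2
      vx <- x + rv * cos(ang); vy <- y + rv * sin(ang)
      if (x >= lo_x && x <= hi_x && y >= lo_y && y <= hi_y &&
          all(vx >= lo_x & vx <= hi_x) && all(vy >= lo_y & vy <= hi_y)) {
        cvs <- rbind(cvs, c(x, y))
        pfs <- rbind(pfs, cbind(vx, vy))
      }
    }
  }
  if (is.null(cvs)) {
    stop("lattice pitch too large for the image: no complete lobule fits",
         call. = FALSE)
  }
  pfs <- unique(round(pfs, 3))

  withr::with_seed(spec$seed, {
    if (spec$jitter_px > 0) {
      jit <- function(m) {
        m + base::matrix(stats::runif(length(m), -spec$jitter_px, spec$jitter_px),
                         nrow(m), ncol(m))
      }
      cvs <- jit(cvs); pfs <- jit(pfs)
    }
    cv_ids <- zq_uuid4(nrow(cvs))
    pf_ids <- zq_uuid4(nrow(pfs))
  })
  structure(list(
    cv = tibble::tibble(id = cv_ids, x = cvs[, 1], y = cvs[, 2]),
    pf = tibble::tibble(id = pf_ids, x = pfs[, 1], y = pfs[, 2]),
    spec = spec
  ), class = "zq_layout")
}

#' Annotation set for a synthetic layout
#'
#' Wraps the layout's center points into axis-aligned rectangle annotations
#' (half-width 8 px) so the synthetic bundle feeds the same interface as
#' real annotation files.
#'
#' @param layout a [generate_layout()] result.
#' @param slide_id slide identifier (default `"synthetic"`).
#' @return a `zq_annotations` object.
#' @export
layout_annotations <- function(layout, slide_id = "synthetic") {
  stopifnot(inherits(layout, "zq_layout"))
  mk <- function(tb, kind, half = 8) {
    lapply(seq_len(nrow(tb)), function(i) {
      x <- tb$x[i]; y <- tb$y[i]
      vessel_annotation(tb$id[i], kind,
                        rbind(c(x - half, y - half), c(x + half, y - half),
                              c(x + half, y + half), c(x - half, y + half)))
    })
  }
  annotation_set(slide_id, layout$spec$resolution_um_per_px,
                 c(mk(layout$cv, "CV"), mk(layout$pf, "PF")))
}

#' True geometry of a synthetic layout
#'
#' Portality, lobule and zone maps computed from the true vessel centers
#' with the package's geometry operations, plus the tissue-rectangle mask.
#' Computing this once and passing it to [render_slide()] /
#' [expected_zone_table()] avoids repeating the distance transforms.
#'
#' @param spec,layout synthetic spec and layout.
#' @param n_zones zones per lobule (default 12).
#' @return list with `portality`, `lobules`, `zones`, `tissue`.
#' @export
synthetic_geometry <- function(spec, layout, n_zones = 12L) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  p <- compute_portality(c(nr, nc), layout$pf, layout$cv,
                         resolution_um_per_px = spec$resolution_um_per_px)
  lob <- segment_lobules(p, layout$cv)
  zon <- quantize_zones(p, lob, n_zones)
  tissue <- base::matrix(FALSE, nr, nc)
  m <- spec$margin_px
  tissue[(m + 1):(nr - m), (m + 1):(nc - m)] <- TRUE
  list(portality = p, lobules = lob, zones = zon, tissue = tissue)
}

clip01 <- function(v) pmin(pmax(v, 0), 1)

grad_at <- function(grad, x) clip01(grad[["slope"]] * x + grad[["intercept"]])

#' Expected per-zone quantification table of a synthetic slide
#'
#' The ground-truth oracle: for each (lobule, zone), the expected marker
#' ratio and steatosis fraction implied by the programmed linear gradients.
#' By default the gradient is evaluated at the zone's *mean* position
#' (averaged over the zone's tissue pixels from the true geometry), which is
#' what the per-zone pixel averages of an ideal render converge to;
#' `x_at = "zone_center"` evaluates at the nominal zone-center position
#' instead.
#'
#' @param spec,layout synthetic spec and layout.
#' @param geometry optional precomputed [synthetic_geometry()].
#' @param x_at `"zone_mean"` (default) or `"zone_center"`.
#' @return tibble: `lobule_id`, `lobule_label`, `zone`, `zone_area_px`, `x`,
#'   `steatosis`, then one column per marker.
#' @export
expected_zone_table <- function(spec, layout, geometry = NULL,
                                x_at = c("zone_mean", "zone_center")) {
  x_at <- match.arg(x_at)
  g <- geometry %||% synthetic_geometry(spec, layout)
  kk <- zone_keys_tissue(g)
  tab <- kk$tab
  x <- if (x_at == "zone_mean") kk$xbar else 1 - (tab$zone - 0.5) / g$zones$n_zones
  tab$x <- x
  tab$steatosis <- grad_at(spec$steatosis_gradient, x)
  for (nm in names(spec$markers)) {
    tab[[nm]] <- grad_at(spec$markers[[nm]], x)
  }
  tab
}

# (lobule, zone) table over tissue pixels with mean position x per zone
zone_keys_tissue <- function(g) {
  nz <- g$zones$n_zones
  sel <- g$lobules$labels > 0L & g$tissue
  key <- (g$lobules$labels[sel] - 1L) * nz + g$zones$zones[sel]
  nk <- max(g$lobules$labels) * nz
  counts <- tabulate(key, nbins = nk)
  xsum <- rowsum((1 - g$portality$values[sel]), key, reorder = TRUE)
  present <- which(counts > 0L)
  lab <- (present - 1L) %/% nz + 1L
  tab <- tibble::tibble(
    lobule_id = g$lobules$cv_index$id[match(lab, g$lobules$cv_index$label)],
    lobule_label = lab,
    zone = (present - 1L) %% nz + 1L,
    zone_area_px = counts[present]
  )
  list(tab = tab, xbar = as.vector(xsum) / counts[present],
       key = key, sel = sel, present = present, nk = nk)
}

#' Render a synthetic stained slide
#'
#' Per tissue pixel, the positive-stain probability is the marker gradient
#' evaluated at the pixel's true position `x = 1 - portality`; a Bernoulli
#' draw picks the positive or negative palette color. Fat droplets are
#' placed as non-overlapping disks, budgeted per (lobule, zone) so the
#' realized per-zone fat area fraction matches the programmed steatosis
#' gradient; droplets are rendered in the unstained (lipid-vacuole) color.
#' Pixels outside the tissue rectangle take the background color. Finally
#' i.i.d. Gaussian noise is added per channel and clipped to `[0, 255]`.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param layout a [generate_layout()] result.
#' @param marker name of the marker gradient to render.
#' @param geometry optional precomputed [synthetic_geometry()].
#' @return list with `rgb` (array `[rows, cols, 3]`, 0..255) and `truth`:
#'   `tissue`, `ternary` (0 none, 1 unstained/fat, 2 positive, 3 negative),
#'   `fat`, `geometry`, `expected` (the [expected_zone_table()]), and the
#'   marker's `gradient`.
#' @export
render_slide <- function(spec, layout, marker, geometry = NULL) {
  stopifnot(inherits(spec, "zq_synthetic_spec"))
  if (!marker %in% names(spec$markers)) {
    stop("unknown marker '", marker, "'", call. = FALSE)
  }
  g <- geometry %||% synthetic_geometry(spec, layout)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  xpos <- 1 - g$portality$values
  pmark <- grad_at(spec$markers[[marker]], xpos)

  kk <- zone_keys_tissue(g)
  sfrac <- grad_at(spec$steatosis_gradient, kk$xbar)
  if (any(sfrac > 0.6)) {
    stop("programmed fat fraction exceeds 0.6 in some zone; non-overlapping placement infeasible",
         call. = FALSE)
  }

  seed_r <- spec$seed + 7919L * match(marker, names(spec$markers))
  withr::with_seed(seed_r, {
    tsel <- which(g$tissue)
    upos <- stats::runif(length(tsel)) < pmark[tsel]

    ternary <- base::matrix(0L, nr, nc)
    ternary[tsel] <- ifelse(upos, 2L, 3L)

    fat <- place_droplets(g, kk, sfrac, spec)
    ternary[fat] <- 1L

    img <- array(0, dim = c(nr, nc, 3))
    pal <- spec$palette
    for (ch in 1:3) {
      plane <- base::matrix(pal$background[ch], nr, nc)
      plane[tsel] <- ifelse(upos, pal$positive[ch], pal$negative[ch])
      plane[fat] <- pal$unstained[ch]
      if (spec$noise_sigma > 0) {
        plane <- plane + stats::rnorm(length(plane), 0, spec$noise_sigma)
      }
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
  })

  expected <- expected_zone_table(spec, layout, geometry = g)
  list(rgb = img,
       truth = list(tissue = g$tissue, ternary = ternary, fat = fat,
                    geometry = g, expected = expected,
                    gradient = spec$markers[[marker]]))
}

# Dart-throwing droplet placement with per-(lobule, zone) area budgeting.
# Darts are thrown at shuffled tissue pixels; a disk is accepted only when at
# least half of its area lands in zones that still have budget left, which
# bounds the per-zone overshoot to roughly one droplet even where a zone band
# is narrower than a droplet diameter. The droplet radius adapts to the
# remaining budget of the center zone. Returns a logical fat mask; uses the
# current RNG stream.
place_droplets <- function(g, kk, sfrac, spec) {
  nr <- nrow(g$tissue); nc <- ncol(g$tissue)
  fat <- base::matrix(FALSE, nr, nc)
  rmin <- spec$droplet_radius_px[1]; rmax <- spec$droplet_radius_px[2]
  radii <- rmin:rmax
  offs <- lapply(radii, function(r) {
    d <- expand.grid(dr = -r:r, dc = -r:r)
    as.matrix(d[d$dr^2 + d$dc^2 <= r^2, ])
  })
  areas <- vapply(offs, nrow, integer(1))
  min_area <- areas[1]

  nz <- g$zones$n_zones
  keymap <- base::matrix(0L, nr, nc)
  sel <- g$lobules$labels > 0L & g$tissue
  keymap[sel] <- (g$lobules$labels[sel] - 1L) * nz + g$zones$zones[sel]

  rem <- numeric(kk$nk)
  rem[kk$present] <- sfrac * kk$tab$zone_area_px
  if (sum(rem) == 0) return(fat)

  # three passes with descending acceptance strictness and radius caps:
  # early passes fill wide zones with little overshoot, late passes squeeze
  # small droplets into zone bands narrower than a droplet diameter.
  # Candidate darts come from per-zone pixel pools so satisfied zones cost
  # nothing to skip.
  pools <- split(which(sel), keymap[sel])
  passes <- list(list(th = 0.85, rcap = rmax),
                 list(th = 0.60, rcap = max(rmin + 1L, rmin)),
                 list(th = 0.45, rcap = rmin))
  for (ps in passes) {
    needy <- intersect(names(pools), as.character(which(rem >= min_area / 2)))
    if (!length(needy)) break
    for (knm in sample(needy)) {
      k0 <- as.integer(knm)
      cand <- pools[[knm]]
      cand <- sample(cand[!fat[cand]])
      for (cen in cand) {
        if (rem[k0] < min_area / 2) break
        # adapt the radius to the center zone's remaining budget
        rtarget <- floor(sqrt(rem[k0] / pi))
        r <- min(max(rtarget, rmin), ps$rcap)
        o <- offs[[match(r, radii)]]
        ri <- (cen - 1L) %% nr + 1L
        ci <- (cen - 1L) %/% nr + 1L
        rr <- ri + o[, 1]; cc <- ci + o[, 2]
        if (any(rr < 1L | rr > nr | cc < 1L | cc > nc)) next
        lin <- rr + (cc - 1L) * nr
        if (any(!g$tissue[lin]) || any(fat[lin])) next
        hit <- keymap[lin]
        cnt <- table(hit[hit > 0L])
        ks <- as.integer(names(cnt))
        covered <- sum(pmin(as.integer(cnt), pmax(rem[ks], 0)))
        if (covered < ps$th * length(lin)) next
        fat[lin] <- TRUE
        rem[ks] <- rem[ks] - as.integer(cnt)
      }
    }
  }
  fat
}
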