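#' Coordinate transforms between slide frames
#'
#' Registration of serial sections yields coordinate transforms between slide
#' frames. This package only *consumes* such transforms: an affine 3x3 matrix
#' in homogeneous coordinates acting on column vectors `(x, y, 1)`, or a dense
#' displacement field `(dx, dy)` sampled on a regular grid. The JSON file
#' declares its mapping direction explicitly and [apply_transform()] trusts
#' that declaration, so no silent double inversion can occur.
#'
#' @param matrix invertible 3x3 numeric matrix.
#' @param direction free-text direction label, e.g. `"HE_to_GS"`.
#' @return a `zq_transform` object of variant `"affine"`.
#' @seealso [displacement_transform()], [invert_transform()],
#'   [transform_points()]
#' @export
affine_transform <- function(matrix, direction = "A_to_B") {
  m <- base::matrix(as.numeric(matrix), 3, 3)
  if (anyNA(m) || any(!is.finite(m))) stop("affine matrix must be finite", call. = FALSE)
  structure(list(variant = "affine", matrix = m, direction = direction),
            class = "zq_transform")
}

#' Dense displacement-field transform
#'
#' The forward map is `f(p) = p + d(p)` with `d` interpolated bilinearly from
#' the grid. Grid node `[row i, col j]` (1-based in R) sits at position
#' `((j-1)*spacing, (i-1)*spacing)` in pixels.
#'
#' @param dx,dy matrices `[row, col]` of displacements in pixels.
#' @param spacing grid spacing in pixels (default 1).
#' @param direction free-text direction label.
#' @return a `zq_transform` object of variant `"displacement_field"`.
#' @export
displacement_transform <- function(dx, dy, spacing = 1, direction = "A_to_B") {
  stopifnot(is.matrix(dx), is.matrix(dy), all(dim(dx) == dim(dy)))
  if (anyNA(dx) || anyNA(dy) || any(!is.finite(dx)) || any(!is.finite(dy))) {
    stop("displacement field must be finite everywhere", call. = FALSE)
  }
  structure(list(variant = "displacement_field", dx = dx, dy = dy,
                 spacing = as.numeric(spacing), direction = direction),
            class = "zq_transform")
}

#' @export
print.zq_transform <- function(x, ...) {
  if (x$variant == "affine") {
    cat("<zq_transform> affine,", x$direction, "\n")
  } else {
    cat(sprintf("<zq_transform> displacement field %dx%d @ spacing %g, %s\n",
                nrow(x$dx), ncol(x$dx), x$spacing, x$direction))
  }
  invisible(x)
}

# Bilinear interpolation of matrix m at real positions (x, y) in pixel units
# (0-based grid scaled by `spacing`). Positions are clamped to the grid.
interp_bilinear <- function(m, x, y, spacing = 1) {
  gx <- x / spacing
  gy <- y / spacing
  gx <- pmin(pmax(gx, 0), ncol(m) - 1)
  gy <- pmin(pmax(gy, 0), nrow(m) - 1)
  x0 <- pmin(floor(gx), ncol(m) - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(gy), nrow(m) - 2); y0 <- pmax(y0, 0)
  fx <- gx - x0
  fy <- gy - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Apply a transform to points
#'
#' @param t a `zq_transform`.
#' @param pts n x 2 matrix of `(x, y)` points.
#' @param check_domain for displacement fields, error when a point falls
#'   outside the field extent (default TRUE).
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(t, pts, check_domain = TRUE) {
  stopifnot(inherits(t, "zq_transform"))
  pts <- base::matrix(as.numeric(pts), ncol = 2)
  if (t$variant == "affine") {
    h <- t$matrix %*% rbind(t(pts), 1)
    return(cbind(h[1, ] / h[3, ], h[2, ] / h[3, ]))
  }
  xmax <- (ncol(t$dx) - 1) * t$spacing
  ymax <- (nrow(t$dx) - 1) * t$spacing
  if (check_domain &&
      any(pts[, 1] < 0 | pts[, 1] > xmax | pts[, 2] < 0 | pts[, 2] > ymax)) {
    bad <- which(pts[, 1] < 0 | pts[, 1] > xmax | pts[, 2] < 0 | pts[, 2] > ymax)
    stop("point(s) outside displacement-field extent at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cbind(pts[, 1] + interp_bilinear(t$dx, pts[, 1], pts[, 2], t$spacing),
        pts[, 2] + interp_bilinear(t$dy, pts[, 1], pts[, 2], t$spacing))
}

#' Invert a coordinate transform
#'
#' Affine transforms are inverted exactly. Displacement fields are inverted
#' numerically on their own grid by damped fixed-point iteration
#' `x_{n+1} = y - d(x_n)` (max `max_iter` iterations); the residual
#' `max |f(f_inv(y)) - y|` must fall below `tolerance`.
#'
#' @param t a `zq_transform`.
#' @param tolerance maximum permitted inversion residual in pixels
#'   (default 0.5).
#' @param max_iter iteration cap for the fixed-point scheme (default 50).
#' @return the inverse `zq_transform` (same variant).
#' @export
invert_transform <- function(t, tolerance = 0.5, max_iter = 50L) {
  stopifnot(inherits(t, "zq_transform"))
  dir_inv <- paste0("inverse(", t$direction, ")")
  if (t$variant == "affine") {
    if (abs(det(t$matrix)) < 1e-12) stop("affine transform is singular", call. = FALSE)
    return(affine_transform(solve(t$matrix), dir_inv))
  }
  nr <- nrow(t$dx); nc <- ncol(t$dx)
  yx <- rep((seq_len(nc) - 1) * t$spacing, each = nr)   # target x, column-major
  yy <- rep((seq_len(nr) - 1) * t$spacing, times = nc)  # target y
  x <- yx; y <- yy
  for (i in seq_len(max_iter)) {
    nx <- yx - interp_bilinear(t$dx, x, y, t$spacing)
    ny <- yy - interp_bilinear(t$dy, x, y, t$spacing)
    if (max(abs(nx - x), abs(ny - y)) < tolerance / 10) {
      x <- nx; y <- ny
      break
    }
    x <- nx; y <- ny
  }
  res <- max(abs(x + interp_bilinear(t$dx, x, y, t$spacing) - yx),
             abs(y + interp_bilinear(t$dy, x, y, t$spacing) - yy))
  if (res > tolerance) {
    stop(sprintf("displacement-field inversion did not converge: residual %.3g px > tolerance %.3g px",
                 res, tolerance), call. = FALSE)
  }
  displacement_transform(base::matrix(x - yx, nr, nc),
                         base::matrix(y - yy, nr, nc),
                         spacing = t$spacing, direction = dir_inv)
}

#' Read / write transforms as JSON
#'
#' Affine: `{"variant": "affine", "direction": str, "matrix": [[..] x3]}`.
#' Displacement: `{"variant": "displacement_field", "direction": str,
#' "spacing": num, "dx": [[..]], "dy": [[..]]}` with row-major nested arrays.
#'
#' @param path JSON file path.
#' @return a `zq_transform` object.
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$variant, "affine")) {
    affine_transform(j$matrix, j$direction %||% "A_to_B")
  } else if (identical(j$variant, "displacement_field")) {
    displacement_transform(j$dx, j$dy, j$spacing %||% 1, j$direction %||% "A_to_B")
  } else {
    stop("unknown transform variant: ", j$variant, call. = FALSE)
  }
}

#' @rdname read_transform
#' @param t a `zq_transform` to serialize.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "zq_transform"))
  j <- if (t$variant == "affine") {
    list(variant = "affine", direction = t$direction, matrix = t$matrix)
  } else {
    list(variant = "displacement_field", direction = t$direction,
         spacing = t$spacing, dx = t$dx, dy = t$dy)
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
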