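#' Vessel annotations
#'
#' Portal fields (PF) and central veins (CV) are annotated as axis-aligned
#' rectangles, each carrying a v4 UUID so that the same vessel can be tracked
#' across co-registered slides. Only the rectangle *center points* feed the
#' downstream lobule geometry.
#'
#' Coordinate convention used throughout the package: `(x, y)` =
#' `(column, row)`, 0-based, pixel centers at integer coordinates; all rasters
#' are R matrices indexed `[row, column]`.
#'
#' @param id UUID string (RFC 4122 v4).
#' @param kind `"PF"` or `"CV"`.
#' @param vertices 4x2 numeric matrix of `(x, y)` rectangle corners,
#'   axis-aligned (exactly two distinct x and two distinct y values).
#' @return A `zq_vessel` object: list with `id`, `kind`, `vertices`, `center`
#'   (arithmetic mean of the vertices) and `bbox_approx` (TRUE when the
#'   rectangle is the bounding box of a non-rigidly mapped original).
#' @seealso [annotation_set()], [read_annotations()], [apply_transform()]
#' @export
vessel_annotation <- function(id, kind, vertices, bbox_approx = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) != 4L || anyNA(vertices) || any(!is.finite(vertices))) {
    stop("annotation '", id, "': vertices must be 4 finite (x, y) points",
         call. = FALSE)
  }
  if (!kind %in% c("PF", "CV")) {
    stop("annotation '", id, "': kind must be 'PF' or 'CV'", call. = FALSE)
  }
  if (!is_uuid4(id)) {
    stop("annotation id '", id, "' is not a v4 UUID", call. = FALSE)
  }
  if (!bbox_approx && !is_axis_aligned(vertices)) {
    stop("annotation '", id, "': rectangle is not axis-aligned", call. = FALSE)
  }
  structure(
    list(id = tolower(id), kind = kind, vertices = vertices,
         center = colMeans(vertices), bbox_approx = isTRUE(bbox_approx)),
    class = "zq_vessel"
  )
}

is_axis_aligned <- function(v, tol = 1e-9) {
  xs <- sort(unique(round(v[, 1] / tol) * tol))
  ys <- sort(unique(round(v[, 2] / tol) * tol))
  length(unique(round(v[, 1], 9))) == 2L && length(unique(round(v[, 2], 9))) == 2L
}

#' Create a set of vessel annotations for one slide
#'
#' @param slide_id character identifier of the slide/frame the coordinates
#'   live in.
#' @param resolution_um_per_px isotropic pixel size in micrometers.
#' @param annotations list of [vessel_annotation()] objects.
#' @return A `zq_annotations` object.
#' @export
annotation_set <- function(slide_id, resolution_um_per_px, annotations = list()) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!is.numeric(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("resolution_um_per_px must be a positive real", call. = FALSE)
  }
  ids <- vapply(annotations, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate annotation UUID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(slide_id = slide_id,
         resolution_um_per_px = as.numeric(resolution_um_per_px),
         annotations = annotations),
    class = "zq_annotations"
  )
}

#' @export
print.zq_annotations <- function(x, ...) {
  k <- vapply(x$annotations, `[[`, character(1), "kind")
  cat(sprintf("<zq_annotations> slide '%s' @ %.4g um/px: %d PF, %d CV\n",
              x$slide_id, x$resolution_um_per_px, sum(k == "PF"), sum(k == "CV")))
  invisible(x)
}

#' Extract vessel center points
#'
#' @param set a `zq_annotations` object.
#' @param kind optional filter, `"PF"` or `"CV"`.
#' @return tibble with columns `id`, `kind`, `x`, `y`.
#' @export
vessel_centers <- function(set, kind = NULL) {
  stopifnot(inherits(set, "zq_annotations"))
  ann <- set$annotations
  if (!is.null(kind)) {
    ann <- Filter(function(a) a$kind == kind, ann)
  }
  tibble::tibble(
    id = vapply(ann, `[[`, character(1), "id"),
    kind = vapply(ann, `[[`, character(1), "kind"),
    x = vapply(ann, function(a) a$center[1], numeric(1)),
    y = vapply(ann, function(a) a$center[2], numeric(1))
  )
}

#' Read vessel annotations from JSON
#'
#' Schema: `{"slide_id": str, "resolution_um_per_px": num,
#' "annotations": [{"id": uuid4, "kind": "PF"|"CV", "vertices": [[x,y] x4]}]}`.
#'
#' @param path JSON file path.
#' @return a `zq_annotations` object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("malformed annotation JSON in '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  for (field in c("slide_id", "resolution_um_per_px")) {
    if (is.null(j[[field]])) stop("annotation JSON missing '", field, "'", call. = FALSE)
  }
  anns <- lapply(j$annotations %||% list(), function(a) {
    if (is.null(a$id) || is.null(a$kind) || is.null(a$vertices)) {
      stop("malformed annotation record: ",
           jsonlite::toJSON(a, auto_unbox = TRUE), call. = FALSE)
    }
    v <- do.call(rbind, lapply(a$vertices, unlist))
    vessel_annotation(a$id, a$kind, v, bbox_approx = isTRUE(a$bbox_approx))
  })
  annotation_set(j$slide_id, j$resolution_um_per_px, anns)
}

#' Write vessel annotations to JSON
#'
#' Lossless counterpart of [read_annotations()].
#'
#' @param set a `zq_annotations` object.
#' @param path output file path.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "zq_annotations"))
  j <- list(
    slide_id = set$slide_id,
    resolution_um_per_px = set$resolution_um_per_px,
    annotations = lapply(set$annotations, function(a) {
      rec <- list(
        id = a$id, kind = a$kind,
        vertices = lapply(seq_len(4), function(i) as.numeric(a$vertices[i, ]))
      )
      if (isTRUE(a$bbox_approx)) rec$bbox_approx <- TRUE
      rec
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Transfer annotations to another slide frame
#'
#' Applies a coordinate transform point-wise to every rectangle vertex and
#' recomputes the centers, preserving UUIDs and vessel kinds. When the mapped
#' rectangle is no longer axis-aligned (non-rigid or rotational transforms),
#' the axis-aligned bounding box of the mapped vertices is stored and the
#' annotation is flagged with `bbox_approx = TRUE`; only the center point is
#' consumed by the lobule geometry, so this approximation is lossless for the
#' downstream analysis.
#'
#' @param set a `zq_annotations` object.
#' @param t a [affine_transform()] or [displacement_transform()].
#' @param slide_id optional new slide id for the output frame.
#' @return transformed `zq_annotations` object.
#' @export
apply_transform <- function(set, t, slide_id = NULL) {
  stopifnot(inherits(set, "zq_annotations"), inherits(t, "zq_transform"))
  anns <- lapply(set$annotations, function(a) {
    v <- tryCatch(transform_points(t, a$vertices),
                  error = function(e) stop("annotation '", a$id, "': ",
                                           conditionMessage(e), call. = FALSE))
    if (is_axis_aligned(v)) {
      vessel_annotation(a$id, a$kind, v)
    } else {
      bb <- rbind(c(min(v[, 1]), min(v[, 2])), c(max(v[, 1]), min(v[, 2])),
                  c(max(v[, 1]), max(v[, 2])), c(min(v[, 1]), max(v[, 2])))
      vessel_annotation(a$id, a$kind, bb, bbox_approx = TRUE)
    }
  })
  annotation_set(slide_id %||% set$slide_id, set$resolution_um_per_px, anns)
}

#' Match lobules across slides via central-vein UUIDs
#'
#' Lobules are defined one-per-CV, so the 1:1 lobule correspondence between
#' two co-registered slides is the identity on CV UUIDs. Given the two
#' annotation sets (and optionally the label-to-UUID index of each slide's
#' lobule map), returns the paired labels and reports unmatched UUIDs.
#'
#' @param set_a,set_b `zq_annotations` objects sharing CV UUIDs.
#' @param cv_index_a,cv_index_b optional tibbles `(label, id)` as found in
#'   the `cv_index` field of [segment_lobules()] output.
#' @return list with `matched` (tibble `id`, `label_a`, `label_b`) and
#'   `unmatched_a`, `unmatched_b` (character vectors of UUIDs).
#' @export
match_lobules_by_cv <- function(set_a, set_b, cv_index_a = NULL, cv_index_b = NULL) {
  ids_a <- vessel_centers(set_a, "CV")$id
  ids_b <- vessel_centers(set_b, "CV")$id
  common <- intersect(ids_a, ids_b)
  lab <- function(ids, idx) {
    if (is.null(idx)) return(match(ids, sort(ids)))
    idx$label[match(ids, idx$id)]
  }
  list(
    matched = tibble::tibble(
      id = common,
      label_a = lab(common, cv_index_a),
      label_b = lab(common, cv_index_b)
    ),
    unmatched_a = setdiff(ids_a, ids_b),
    unmatched_b = setdiff(ids_b, ids_a)
  )
}
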