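test_that("rectangle parsing computes centers and validates invariants", {
  id <- zq_uuid4_test(1)
  v <- rbind(c(10, 10), c(30, 10), c(30, 20), c(10, 20))
  a <- vessel_annotation(id, "CV", v)
  expect_equal(a$center, c(20, 15))

  expect_error(vessel_annotation("not-a-uuid", "CV", v), "v4 UUID")
  expect_error(vessel_annotation(id, "XX", v), "PF.*CV")
  expect_error(
    vessel_annotation(id, "CV", rbind(c(0, 0), c(10, 1), c(11, 10), c(1, 9))),
    "axis-aligned"
  )
  expect_error(
    annotation_set("s", 1, list(a, vessel_annotation(id, "PF", v))),
    "duplicate"
  )
  expect_error(annotation_set("s", -1, list(a)), "positive")
})

test_that("annotation JSON round-trips losslessly", {
  ids <- zq_uuid4_test(3)
  anns <- lapply(1:3, function(i) {
    vessel_annotation(ids[i], c("CV", "PF", "PF")[i],
                      rbind(c(i, i), c(i + 10, i), c(i + 10, i + 4.25), c(i, i + 4.25)))
  })
  set <- annotation_set("slide-A", 0.909, anns)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(set, f)
  back <- read_annotations(f)
  expect_equal(back$slide_id, "slide-A")
  expect_equal(back$resolution_um_per_px, 0.909)
  expect_equal(back$annotations, set$annotations)

  # empty list is a valid file
  f2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(annotation_set("empty", 1), f2)
  expect_length(read_annotations(f2)$annotations, 0)

  expect_error(read_annotations(withr::local_tempfile()), "not found")
})

test_that("affine transforms map vertices point-wise and preserve identity", {
  id <- zq_uuid4_test(1)
  set <- annotation_set("s", 1, list(
    vessel_annotation(id, "CV", rbind(c(10, 10), c(30, 10), c(30, 20), c(10, 20)))
  ))

  ident <- affine_transform(diag(3))
  same <- apply_transform(set, ident)
  expect_equal(same$annotations[[1]]$center, c(20, 15))
  expect_equal(same$annotations[[1]]$vertices, set$annotations[[1]]$vertices)

  shift <- affine_transform(rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1)))
  moved <- apply_transform(set, shift)
  expect_equal(moved$annotations[[1]]$center, c(25, 12))
  expect_equal(moved$annotations[[1]]$id, id)

  # rotation: rectangle becomes a bounding box, center follows the rotation
  th <- 10 * pi / 180
  rot <- affine_transform(rbind(c(cos(th), -sin(th), 0),
                                c(sin(th), cos(th), 0), c(0, 0, 1)))
  rotated <- apply_transform(set, rot)
  expect_true(rotated$annotations[[1]]$bbox_approx)
  # oracle: rotate the original center directly
  ctr <- transform_points(rot, matrix(c(20, 15), 1, 2))
  expect_lt(max(abs(rotated$annotations[[1]]$center - ctr)), 1)
})

test_that("affine inversion is exact and UUIDs survive any transform", {
  sc <- affine_transform(diag(c(2, 2, 1)))
  inv <- invert_transform(sc)
  expect_equal(inv$matrix, diag(c(0.5, 0.5, 1)))
  expect_error(invert_transform(affine_transform(matrix(0, 3, 3) + diag(c(1, 0, 1)))),
               "singular")

  withr::with_seed(5, {
    pts <- cbind(runif(100, 0, 50), runif(100, 0, 50))
  })
  aff <- affine_transform(rbind(c(1.2, 0.1, 3), c(-0.05, 0.9, -7), c(0, 0, 1)))
  round_trip <- transform_points(invert_transform(aff), transform_points(aff, pts))
  expect_lt(max(abs(round_trip - pts)), 1e-9)

  ids <- zq_uuid4_test(4)
  set <- annotation_set("s", 1, lapply(1:4, function(i) {
    vessel_annotation(ids[i], ifelse(i < 3, "CV", "PF"),
                      rbind(c(i, i), c(i + 2, i), c(i + 2, i + 2), c(i, i + 2)))
  }))
  out <- apply_transform(set, aff)
  expect_setequal(vapply(out$annotations, `[[`, character(1), "id"), ids)
})

test_that("displacement fields invert below tolerance on smooth deformations", {
  # smooth sinusoidal field on a 64x64 grid
  gx <- outer(rep(1, 64), 0:63); gy <- outer(0:63, rep(1, 64))
  dx <- 2 * sin(2 * pi * gy / 63); dy <- 1.5 * cos(2 * pi * gx / 63)
  t <- displacement_transform(dx, dy)
  inv <- invert_transform(t, tolerance = 0.1)

  withr::with_seed(9, {
    pts <- cbind(runif(200, 5, 58), runif(200, 5, 58))
  })
  fwd <- transform_points(t, pts)
  back <- transform_points(inv, fwd, check_domain = FALSE)
  expect_lt(max(abs(back - pts)), 0.25)

  expect_error(
    transform_points(t, matrix(c(100, 5), 1, 2)),
    "outside displacement-field extent"
  )
})

test_that("transform JSON round-trips both variants", {
  f <- withr::local_tempfile(fileext = ".json")
  aff <- affine_transform(rbind(c(1, 0, 2.5), c(0, 1, -1), c(0, 0, 1)), "HE_to_GS")
  write_transform(aff, f)
  expect_equal(read_transform(f)$matrix, aff$matrix)
  expect_equal(read_transform(f)$direction, "HE_to_GS")

  d <- displacement_transform(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4),
                              spacing = 8)
  write_transform(d, f)
  back <- read_transform(f)
  expect_equal(back$dx, d$dx)
  expect_equal(back$spacing, 8)
})

test_that("lobule correspondence pairs CV UUIDs and reports unmatched ones", {
  ids <- zq_uuid4_test(3)
  mk <- function(keep) {
    annotation_set("s", 1, lapply(keep, function(i) {
      vessel_annotation(ids[i], "CV",
                        rbind(c(i, i), c(i + 2, i), c(i + 2, i + 2), c(i, i + 2)))
    }))
  }
  full <- mk(1:3)
  m <- match_lobules_by_cv(full, full)
  expect_setequal(m$matched$id, ids)
  expect_length(m$unmatched_a, 0)

  partial <- match_lobules_by_cv(full, mk(1:2))
  expect_setequal(partial$matched$id, ids[1:2])
  expect_equal(partial$unmatched_a, ids[3])

  # translation does not affect the pairing (UUIDs are transform-invariant)
  shifted <- apply_transform(mk(1:3), affine_transform(rbind(c(1, 0, 40), c(0, 1, 9), c(0, 0, 1))))
  expect_setequal(match_lobules_by_cv(full, shifted)$matched$id, ids)
})
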