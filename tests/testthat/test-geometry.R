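test_that("portality matches the defining distance ratio", {
  p <- compute_portality(c(21, 21), pf_centers = cbind(0, 0),
                         cv_centers = cbind(10, 0))
  # [row, col] = (y+1, x+1)
  expect_equal(p$values[1, 6], 0.5)    # (5,0): equidistant
  expect_equal(p$values[1, 1], 1.0)    # at the PF
  expect_equal(p$values[1, 11], 0.0)   # at the CV
  expect_equal(p$values[1, 3], 0.8)    # (2,0): 1 - 2/(2+8)

  # nearest PF governs: two PFs, symmetric about the CV
  p2 <- compute_portality(c(5, 21), pf_centers = rbind(c(0, 0), c(20, 0)),
                          cv_centers = cbind(10, 0))
  expect_equal(p2$values[1, 5], 0.6)   # (4,0): 1 - 4/(4+6)
  expect_equal(p2$values[1, 5], p2$values[1, 17])  # symmetry about x=10

  expect_error(compute_portality(c(5, 5), cbind(0, 0), matrix(numeric(0), 0, 2)),
               "at least one PF and one CV")
  expect_warning(compute_portality(c(5, 5), cbind(99, 99), cbind(1, 1)),
                 "outside the raster")
})

test_that("portality agrees with a brute-force oracle on random layouts", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      pf <- cbind(runif(4, 0, 31), runif(4, 0, 31))
      cv <- cbind(runif(3, 0, 31), runif(3, 0, 31))
      p <- compute_portality(c(32, 32), pf, cv)
      expect_true(all(p$values >= 0 & p$values <= 1))
      probe <- cbind(sample(0:31, 10), sample(0:31, 10))
      expected <- vapply(1:10, function(i) {
        portality_point(probe[i, 1], probe[i, 2], pf, cv)
      }, numeric(1))
      expect_equal(p$values[cbind(probe[, 2] + 1, probe[, 1] + 1)], expected)
    }
  })
})

test_that("a single CV yields one lobule covering every pixel", {
  p <- compute_portality(c(64, 64), cbind(0, 0), cbind(40, 40))
  cv <- tibble::tibble(id = zq_uuid4_test(1), x = 40, y = 40)
  lob <- segment_lobules(p, cv)
  expect_equal(sort(unique(as.vector(lob$labels))), 1L)
  expect_equal(lob$cv_index$id, cv$id)
  expect_error(segment_lobules(p, cv, preflood_height = 1), "\\[0, 1\\)")
  expect_error(segment_lobules(p, tibble::tibble(id = "x", x = 99, y = 99)),
               "inside the raster")
})

test_that("watershed basins agree with the steepest-descent oracle", {
  # two CVs with PFs at the corners and edge midpoints
  pf <- rbind(c(0, 0), c(63, 0), c(0, 63), c(63, 63), c(32, 0), c(32, 63))
  cv_pts <- rbind(c(16, 32), c(48, 32))
  p <- compute_portality(c(64, 64), pf, cv_pts)
  cv <- tibble::tibble(id = zq_uuid4_test(2), x = cv_pts[, 1], y = cv_pts[, 2])
  lob <- segment_lobules(p, cv)
  expect_equal(nrow(lob$cv_index), 2L)
  # each basin contains its own CV
  expect_equal(lob$labels[33, 17], lob$cv_index$label[lob$cv_index$x == 16])
  expect_equal(lob$labels[33, 49], lob$cv_index$label[lob$cv_index$x == 48])
  expect_gte(descent_agreement(p, lob, cv), 0.99)

  # labels ascend in (y, x) order of the seed CVs
  expect_equal(lob$cv_index$label[order(lob$cv_index$y, lob$cv_index$x)], 1:2)
})

test_that("hexagonal layouts give one lobule per CV", {
  b <- small_bundle()
  g <- b$geometry
  expect_equal(nrow(g$lobules$cv_index), nrow(b$layout$cv))
  expect_setequal(unique(as.vector(g$lobules$labels)),
                  seq_len(nrow(b$layout$cv)))
})

test_that("zone quantization uses half-open bins with a closed top edge", {
  mkp <- function(v) structure(list(values = base::matrix(v, 1, length(v)),
                                    resolution_um_per_px = 1),
                               class = "zq_portality")
  lob <- structure(list(labels = base::matrix(1L, 1, 5),
                        cv_index = tibble::tibble(label = 1L, id = "a", x = 0, y = 0)),
                   class = "zq_lobules")
  z <- quantize_zones(mkp(c(0, 0.5, 0.999, 1, 1 / 12)), lob)
  expect_equal(as.vector(z$zones), c(1L, 7L, 12L, 12L, 2L))
  expect_error(quantize_zones(mkp(0.5), lob, n_zones = 1), ">= 2")

  # a uniform gradient across one lobule exposes all 12 zones
  zz <- quantize_zones(mkp(seq(0, 1, length.out = 60)),
                       structure(list(labels = base::matrix(1L, 1, 60),
                                      cv_index = tibble::tibble(label = 1L, id = "a",
                                                                x = 0, y = 0)),
                                 class = "zq_lobules"))
  expect_setequal(unique(as.vector(zz$zones)), 1:12)
})

test_that("zones partition every lobule and conserve area", {
  g <- small_bundle()$geometry
  inlob <- g$lobules$labels > 0L
  expect_true(all(g$zones$zones[inlob] %in% 1:12))
  expect_true(all(g$zones$zones[!inlob] == 0L))
  per_lob <- tapply(rep(1L, sum(inlob)), g$lobules$labels[inlob], sum)
  kk <- table(g$lobules$labels[inlob], g$zones$zones[inlob])
  expect_equal(unname(rowSums(kk)), as.vector(per_lob))
})

test_that("segmentation is deterministic and CV merging is reported", {
  p <- compute_portality(c(64, 64), rbind(c(0, 0), c(63, 63)), cbind(32, 32))
  cv <- tibble::tibble(id = zq_uuid4_test(2), x = c(32, 33), y = c(32, 32))
  expect_warning(lob <- segment_lobules(p, cv), "share a pre-flooded basin")
  expect_equal(nrow(lob$merged), 2L)

  b <- small_bundle()
  l1 <- segment_lobules(b$geometry$portality, b$layout$cv)
  l2 <- segment_lobules(b$geometry$portality, b$layout$cv)
  expect_identical(l1$labels, l2$labels)
})

test_that("label and portality rasters round-trip through TIFF", {
  g <- small_bundle()$geometry
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(g$lobules$labels, f1)
  expect_identical(read_label_tiff(f1), g$lobules$labels)
  write_raster_tiff(g$portality$values, f2)
  expect_lt(max(abs(read_raster_tiff(f2) - g$portality$values)), 1e-6)
})
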