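rgb_of <- function(labmat, colors) {
  # build an RGB array from an integer matrix and a list of color triples
  arr <- array(0, dim = c(dim(labmat), 3))
  for (ch in 1:3) {
    plane <- labmat
    for (k in seq_along(colors)) plane[labmat == k] <- colors[[k]][ch]
    arr[, , ch] <- plane
  }
  arr
}

test_that("Otsu tissue mask separates dark tissue from bright background", {
  half <- base::matrix(rep(c(1L, 2L), each = 50), 10, 10)
  img <- rgb_of(half, list(c(0, 0, 0), c(255, 255, 255)))
  tm <- compute_tissue_mask(img, cleanup = FALSE)
  expect_equal(tm$mask, half == 1L)

  expect_error(compute_tissue_mask(rgb_of(base::matrix(1L, 8, 8),
                                          list(c(255, 255, 255)))),
               "degenerate")
})

test_that("tissue mask covers the generated tissue region", {
  b <- small_bundle()
  tm <- compute_tissue_mask(b$render$rgb)
  expect_gte(mean(tm$mask[b$render$truth$tissue]), 0.99)
})

test_that("EM recovers exactly three constant colors", {
  lab <- base::matrix(rep(1:3, each = 300), 30, 30)
  cols <- list(c(240, 240, 240), c(150, 110, 70), c(80, 80, 160))
  img <- rgb_of(lab, cols)
  model <- fit_color_classes(img, base::matrix(TRUE, 30, 30), seed = 1)
  ord <- order(model$means[, 1], decreasing = TRUE)
  truth <- do.call(rbind, cols)[order(sapply(cols, `[[`, 1), decreasing = TRUE), ]
  expect_lt(max(abs(model$means[ord, ] - truth)), 1)
  expect_equal(model$weights[ord], rep(1 / 3, 3), tolerance = 1e-6)

  expect_error(fit_color_classes(rgb_of(lab * 0 + 1, list(c(9, 9, 9))),
                                 base::matrix(TRUE, 30, 30)),
               "fewer than 3 distinct colors")
})

test_that("EM recovers noisy Gaussian color blobs within 3 gray levels", {
  n <- 1e5
  truth <- rbind(c(245, 243, 240), c(135, 100, 70), c(170, 150, 200))
  withr::with_seed(21, {
    cls <- sample(1:3, n, replace = TRUE)
    px <- truth[cls, ] + base::matrix(rnorm(3 * n, 0, 8), n, 3)
  })
  px <- pmin(pmax(round(px), 0), 255)
  img <- array(0, dim = c(200, 500, 3))
  for (ch in 1:3) img[, , ch] <- base::matrix(px[, ch], 200, 500)
  model <- fit_color_classes(img, base::matrix(TRUE, 200, 500), seed = 4)
  model <- assign_semantics(model)
  sem <- model$semantics
  for (i in 1:3) {
    expect_lt(max(abs(model$means[sem[i], ] - truth[i, ])), 3)
  }
  # same input, same seed -> identical model
  again <- fit_color_classes(img, base::matrix(TRUE, 200, 500), seed = 4)
  expect_identical(model$means[order(model$means[, 1]), ],
                   again$means[order(again$means[, 1]), ])
})

test_that("semantics assignment uses luminance and the chromogen reference", {
  model <- structure(list(
    means = rbind(c(240, 240, 240), c(150, 110, 70), c(80, 80, 160)),
    weights = rep(1 / 3, 3),
    covariances = replicate(3, diag(3), simplify = FALSE),
    semantics = NULL, seed = 1L
  ), class = "zq_color_model")
  m <- assign_semantics(model)
  expect_equal(unname(m$semantics), c(1L, 2L, 3L))

  tied <- model
  tied$means <- rbind(c(10, 10, 10), c(10, 10, 10), c(200, 200, 200))
  expect_warning(assign_semantics(tied), "tie")
})

test_that("ternary classification picks the nearest mean with fixed ties", {
  model <- structure(list(
    means = rbind(c(240, 240, 240), c(150, 110, 70), c(80, 80, 160)),
    weights = rep(1 / 3, 3),
    covariances = replicate(3, diag(3), simplify = FALSE),
    semantics = NULL, seed = 1L
  ), class = "zq_color_model")
  m <- assign_semantics(model)
  img <- rgb_of(base::matrix(1:3, 1, 3),
                list(c(240, 240, 240), c(150, 110, 70), c(80, 80, 160)))
  tern <- classify_ternary(img, m, base::matrix(TRUE, 1, 3))
  expect_equal(as.vector(tern$labels), c(1L, 2L, 3L))  # exactly at the means

  # mask partition: outside tissue is 0, inside 1..3
  mask <- base::matrix(c(TRUE, TRUE, FALSE), 1, 3)
  tern2 <- classify_ternary(img, m, mask)
  expect_equal(as.vector(tern2$labels), c(1L, 2L, 0L))
  expect_error(classify_ternary(img, model, mask), "semantics not assigned")

  # pixel equidistant between two means: lower semantic class index wins
  m2 <- m
  m2$means <- rbind(c(100, 100, 100), c(120, 100, 100), c(250, 250, 250))
  m2$semantics <- c(unstained = 3L, positive = 1L, negative = 2L)
  eq <- rgb_of(base::matrix(1L, 1, 1), list(c(110, 100, 100)))
  tern3 <- classify_ternary(eq, m2, base::matrix(TRUE, 1, 1))
  expect_equal(as.vector(tern3$labels), 2L)  # positive (class 2) before negative (3)
})

test_that("ternary classification matches generator truth at noise sigma 8", {
  b <- small_bundle()
  r <- b$render
  tm <- compute_tissue_mask(r$rgb)
  model <- assign_semantics(fit_color_classes(r$rgb, tm, seed = 2))
  tern <- classify_ternary(r$rgb, model, tm)
  both <- tern$labels > 0L & r$truth$ternary > 0L
  expect_gte(mean(tern$labels[both] == r$truth$ternary[both]), 0.95)

  # permutation invariance: shuffling the mixture components changes nothing
  perm <- c(2L, 3L, 1L)
  shuffled <- model
  shuffled$means <- model$means[perm, ]
  shuffled$weights <- model$weights[perm]
  shuffled$covariances <- model$covariances[perm]
  shuffled$semantics <- NULL
  shuffled <- assign_semantics(shuffled)
  tern2 <- classify_ternary(r$rgb, shuffled, tm)
  expect_identical(tern$labels, tern2$labels)
})

test_that("fat detection keeps round bright droplets and drops cracks", {
  # dark tissue with one white disk (r = 10) and a long thin white crack
  lab <- base::matrix(1L, 100, 200)
  xs <- outer(rep(1, 100), 1:200); ys <- outer(1:100, rep(1, 200))
  disk <- (xs - 50)^2 + (ys - 50)^2 <= 10^2
  crack <- xs >= 120 & xs <= 180 & ys >= 48 & ys <= 50
  lab[disk | crack] <- 2L
  img <- rgb_of(lab, list(c(120, 100, 90), c(255, 255, 255)))
  tissue <- base::matrix(TRUE, 100, 200)

  fat <- detect_fat(img, tissue, fat_params(), resolution_um_per_px = 1)
  expect_equal(fat$droplet_count, 1L)
  expect_lt(abs(sum(fat$mask) - pi * 100) / (pi * 100), 0.10)
  expect_true(all(fat$mask[disk & !crack] | !disk[disk & !crack]))

  # no bright regions -> empty result
  none <- detect_fat(rgb_of(lab * 0 + 1, list(c(120, 100, 90))), tissue,
                     fat_params(), 1)
  expect_equal(none$droplet_count, 0L)
  expect_false(any(none$mask))

  # monotonicity: stricter circularity or narrower area window never adds droplets
  loose <- detect_fat(img, tissue, fat_params(min_circularity = 0.2), 1)
  strict <- detect_fat(img, tissue, fat_params(min_circularity = 0.9), 1)
  expect_lte(strict$droplet_count, loose$droplet_count)
  narrow <- detect_fat(img, tissue, fat_params(min_area_um2 = 400, max_area_um2 = 500), 1)
  expect_lte(narrow$droplet_count, loose$droplet_count)
})

test_that("color model JSON round-trips", {
  b <- small_bundle()
  tm <- compute_tissue_mask(b$render$rgb)
  model <- assign_semantics(fit_color_classes(b$render$rgb, tm, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_color_model(model, f)
  back <- read_color_model(f)
  expect_equal(back$means, model$means)
  expect_equal(back$weights, model$weights)
  expect_equal(unname(back$semantics), unname(model$semantics))
  expect_equal(back$covariances[[2]], model$covariances[[2]])
})
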