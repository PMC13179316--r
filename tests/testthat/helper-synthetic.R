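# Shared fixtures, built in code and memoized for the test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small slide: 512^2, 6 full lobules, default gradients and noise
small_spec <- function(seed = 42, ...) {
  synthetic_slide_spec(image_size = c(512L, 512L), lattice_pitch_px = 160,
                       margin_px = 16, seed = seed, ...)
}

small_bundle <- function() {
  memo("small_bundle", {
    spec <- small_spec()
    lay <- generate_layout(spec)
    g <- synthetic_geometry(spec, lay)
    r <- render_slide(spec, lay, "pericentral", geometry = g)
    list(spec = spec, layout = lay, geometry = g, render = r,
         ann = layout_annotations(lay))
  })
}

small_run <- function() {
  memo("small_run", {
    b <- small_bundle()
    cfg <- zq_config(analysis_downsample = 1L, seed = 7L)
    res <- run_quantify(list(HE = b$render$rgb, CYP = b$render$rgb),
                        b$ann, config = cfg)
    list(res = res, cfg = cfg, trends = run_trends(res$table, cfg))
  })
}

# hand-built tiny label maps for arithmetic checks: one lobule, n zones of
# `zone_px` pixels each, laid out as vertical bands
tiny_maps <- function(n_zones = 2L, zone_px = 100L, nrows = 10L) {
  cols_per_zone <- zone_px %/% nrows
  ncols <- n_zones * cols_per_zone
  labels <- base::matrix(1L, nrows, ncols)
  zones <- base::matrix(rep(seq_len(n_zones), each = cols_per_zone * nrows),
                        nrows, ncols)
  lob <- structure(list(labels = labels,
                        cv_index = tibble::tibble(label = 1L, id = zq_uuid4_test(1),
                                                  x = 0, y = 0),
                        merged = tibble::tibble()),
                   class = "zq_lobules")
  zon <- structure(list(zones = zones, n_zones = as.integer(n_zones)),
                   class = "zq_zones")
  list(lobules = lob, zones = zon)
}

# deterministic uuid-v4-shaped strings for fixtures
zq_uuid4_test <- function(n, salt = 0L) {
  vapply(seq_len(n), function(i) {
    paste0(sprintf("%08d", i + salt), "-abcd-4abc-8abc-abcdefabcdef")
  }, character(1))
}
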