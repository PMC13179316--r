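#' Pipeline configuration
#'
#' All tunable parameters of the zonated-quantification workflow, with the
#' defaults used throughout: geometry at a downsampling of the input
#' (quarter resolution for real whole-slide material), twelve zones,
#' pre-flood height 0.05 portality units, 5% minimum stained fraction,
#' zones 1 and 12 excluded from analysis, and a fixed seed for the EM
#' initialization. The configuration is serializable and is logged verbatim
#' into every output sidecar.
#'
#' @param analysis_downsample integer downsampling factor applied to images
#'   and annotation coordinates before analysis (default 4).
#' @param n_zones zones per lobule (default 12).
#' @param preflood_height watershed pre-flood height (default 0.05).
#' @param min_stained_fraction marker-ratio inclusion threshold
#'   (default 0.05).
#' @param excluded_zones zones excluded from trends/plots (default 1 and 12).
#' @param seed RNG seed for the color-model EM (default 1).
#' @param steatosis_stain name of the stain used for fat detection (default:
#'   a stain named like H&E if present, else the first image).
#' @param positive_reference_rgb reference chromogen color for
#'   [assign_semantics()].
#' @param fat a [fat_params()] list.
#' @param denominator stained-fraction denominator, `"zone"` or `"tissue"`.
#' @return a `zq_config` list.
#' @export
zq_config <- function(analysis_downsample = 4L, n_zones = 12L,
                      preflood_height = 0.05, min_stained_fraction = 0.05,
                      excluded_zones = c(1L, 12L), seed = 1L,
                      steatosis_stain = NULL,
                      positive_reference_rgb = c(140, 110, 80),
                      fat = fat_params(), denominator = "zone") {
  structure(list(analysis_downsample = as.integer(analysis_downsample),
                 n_zones = as.integer(n_zones),
                 preflood_height = preflood_height,
                 min_stained_fraction = min_stained_fraction,
                 excluded_zones = as.integer(excluded_zones),
                 seed = as.integer(seed), steatosis_stain = steatosis_stain,
                 positive_reference_rgb = positive_reference_rgb,
                 fat = fat, denominator = denominator),
            class = "zq_config")
}

#' @rdname zq_config
#' @param config a `zq_config` to serialize.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

config_as_list <- function(config) {
  l <- unclass(config)
  l$fat <- unclass(l$fat)
  l
}

#' @rdname zq_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- zq_config()
  for (nm in setdiff(names(j), "fat")) cfg[[nm]] <- j[[nm]]
  if (!is.null(j$fat)) cfg$fat <- do.call(fat_params, as.list(j$fat))
  cfg$analysis_downsample <- as.integer(cfg$analysis_downsample)
  cfg$n_zones <- as.integer(cfg$n_zones)
  cfg$excluded_zones <- as.integer(cfg$excluded_zones)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

quant_config_of <- function(config) {
  quant_config(min_stained_fraction = config$min_stained_fraction,
               excluded_zones = config$excluded_zones,
               n_zones = config$n_zones, denominator = config$denominator)
}

read_rgb_image <- function(x) {
  if (is.character(x)) {
    a <- if (grepl("\\.tiff?$", x, ignore.case = TRUE)) {
      tiff::readTIFF(x)
    } else {
      png::readPNG(x)
    }
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
    x <- a[, , 1:3, drop = FALSE] * 255
  }
  stopifnot_rgb(x)
  x
}

#' Run the joint zonated quantification
#'
#' Orchestrates the full workflow for one stack of co-registered stains:
#' per stain, annotations are transferred into the stain's frame (when a
#' transform is given), portality / lobule / zone maps are computed from the
#' transferred vessel centers *in that frame*, signals are detected (fat
#' droplets on the steatosis stain, EM ternary classification on marker
#' stains) and aggregated per (lobule, zone); the per-stain records are then
#' joined into one table via the CV UUIDs.
#'
#' @param images named list of RGB arrays (0..255) or image file paths
#'   (PNG/TIFF), one per stain.
#' @param annotations a [annotation_set()] shared by all stains, or a named
#'   list with one set per stain.
#' @param transforms optional named list of [affine_transform()] /
#'   [displacement_transform()] mapping the shared annotation frame into
#'   each stain's frame; stains without an entry use the annotations as-is.
#' @param config a [zq_config()].
#' @param out_dir optional output directory: writes the joint table CSV,
#'   per-stain label-map TIFFs and portality, the fitted color models, and
#'   a provenance sidecar (config + input checksums).
#' @return list with `table` (joint tibble), `per_stain` (geometry, masks,
#'   records, model per stain), `config`, `log` (per-stage timings/counts).
#' @export
run_quantify <- function(images, annotations, transforms = NULL,
                         config = zq_config(), out_dir = NULL) {
  stopifnot(is.list(images), length(images) >= 1L, !is.null(names(images)))
  qc <- quant_config_of(config)
  ds <- config$analysis_downsample
  steat <- config$steatosis_stain %||%
    (grep("^h&?e$", names(images), ignore.case = TRUE, value = TRUE)[1])
  if (is.na(steat) || is.null(steat)) steat <- names(images)[1]

  log <- list()
  per_stain <- list()
  tables <- list()
  geom_cache <- list()

  for (s in names(images)) {
    t0 <- Sys.time()
    ann <- if (inherits(annotations, "zq_annotations")) annotations else annotations[[s]]
    if (is.null(ann)) stop("no annotations for stain '", s, "'", call. = FALSE)
    if (!is.null(transforms[[s]])) {
      ann <- apply_transform(ann, transforms[[s]], slide_id = s)
    }
    img <- read_rgb_image(images[[s]])
    if (ds > 1L) img <- downsample_rgb(img, ds)

    cvc <- vessel_centers(ann, "CV")
    pfc <- vessel_centers(ann, "PF")
    if (nrow(cvc) == 0L) {
      stop("stain '", s, "': no CV annotations; portality undefined", call. = FALSE)
    }
    cvc$x <- cvc$x / ds; cvc$y <- cvc$y / ds
    pfc$x <- pfc$x / ds; pfc$y <- pfc$y / ds

    gkey <- zq_md5(list(dim(img)[1:2], pfc[c("x", "y")], cvc[c("id", "x", "y")],
                        config$preflood_height, config$n_zones))
    if (is.null(geom_cache[[gkey]])) {
      p <- compute_portality(dim(img)[1:2], pfc, cvc,
                             resolution_um_per_px = ann$resolution_um_per_px * ds)
      lob <- segment_lobules(p, cvc, config$preflood_height)
      zon <- quantize_zones(p, lob, config$n_zones)
      geom_cache[[gkey]] <- list(portality = p, lobules = lob, zones = zon)
    }
    g <- geom_cache[[gkey]]

    tissue <- compute_tissue_mask(img)
    entry <- list(annotations = ann, geometry = g, tissue = tissue)

    if (s == steat) {
      fat <- detect_fat(img, tissue, config$fat,
                        resolution_um_per_px = ann$resolution_um_per_px * ds)
      tables[["steatosis"]] <- quantify_steatosis(fat, g$lobules, g$zones,
                                                  tissue = tissue)
      entry$fat <- fat
      log[[s]] <- list(stage = "steatosis", lobules = nrow(g$lobules$cv_index),
                       droplets = fat$droplet_count,
                       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    } else {
      model <- fit_color_classes(img, tissue, seed = config$seed)
      model <- assign_semantics(model, config$positive_reference_rgb)
      tern <- classify_ternary(img, model, tissue)
      rec <- quantify_marker(tern, g$lobules, g$zones, qc, name = s)
      tables[[s]] <- rec
      entry$model <- model
      entry$ternary <- tern
      log[[s]] <- list(stage = "marker", lobules = nrow(g$lobules$cv_index),
                       zones_suppressed = sum(is.na(rec[[s]])),
                       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
    per_stain[[s]] <- entry
  }

  table <- join_records(tables)
  out <- list(table = table, per_stain = per_stain, config = config, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_zone_table(table, file.path(out_dir, "zone_table.csv"))
    for (s in names(per_stain)) {
      g <- per_stain[[s]]$geometry
      write_raster_tiff(g$portality$values, file.path(out_dir, paste0(s, "_portality.tif")))
      write_label_tiff(g$lobules$labels, file.path(out_dir, paste0(s, "_lobules.tif")))
      write_label_tiff(g$zones$zones, file.path(out_dir, paste0(s, "_zones.tif")))
      jsonlite::write_json(g$lobules$cv_index,
                           file.path(out_dir, paste0(s, "_lobule_index.json")),
                           dataframe = "rows", digits = NA)
      if (!is.null(per_stain[[s]]$model)) {
        write_color_model(per_stain[[s]]$model,
                          file.path(out_dir, paste0(s, "_color_model.json")))
      }
    }
    sidecar <- list(config = config_as_list(config),
                    config_md5 = zq_md5(config_as_list(config)),
                    input_md5 = lapply(images, function(x) {
                      if (is.character(x)) unname(tools::md5sum(x)) else zq_md5(x)
                    }),
                    log = log)
    jsonlite::write_json(sidecar, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Fit and summarize all zonation trends of a joint table
#'
#' Zonal (versus lobular position) linear fits for steatosis and every
#' marker column, marker-versus-steatosis fits, and per-slide summaries of
#' the slopes and intercepts.
#'
#' @param table joint quantification table.
#' @param config a [zq_config()].
#' @param out_dir optional directory for `fits.csv` and `summaries.csv`.
#' @return list with `fits` and `summaries` tibbles.
#' @export
run_trends <- function(table, config = zq_config(), out_dir = NULL) {
  if (nrow(table) == 0L) stop("empty quantification table", call. = FALSE)
  qc <- quant_config_of(config)
  value_cols <- setdiff(names(table),
                        c("lobule_id", "lobule_label", "zone", "zone_area_px",
                          grep("^stained_fraction_", names(table), value = TRUE)))
  fits <- dplyr::bind_rows(lapply(value_cols, function(v) {
    fit_zonal_trends(table, v, qc)
  }))
  markers <- setdiff(value_cols, "steatosis")
  if ("steatosis" %in% value_cols && length(markers)) {
    fits <- dplyr::bind_rows(fits, dplyr::bind_rows(lapply(markers, function(m) {
      fit_marker_vs_steatosis(table, m, qc)
    })))
  }
  summaries <- summarize_fits(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
  }
  list(fits = fits, summaries = summaries)
}
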