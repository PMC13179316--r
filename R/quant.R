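#' Quantification configuration
#'
#' @param min_stained_fraction zones whose stained fraction (positive +
#'   negative pixels over zone area) falls below this threshold get no marker
#'   ratio — suppresses noisy data in void and unstained areas. Boundary
#'   inclusive: a zone exactly at the threshold is kept. Default 0.05.
#' @param excluded_zones zones dropped at *analysis* time (trend fits,
#'   plots); the quantification table keeps all zones. Zones 1 and 12 are
#'   excluded by default because vessel area dominates them.
#' @param n_zones number of zones (default 12).
#' @param denominator `"zone"` (default): stained fraction is relative to the
#'   full zone pixel count, so void/non-tissue areas depress it, which is
#'   what the threshold must catch. `"tissue"`: relative to tissue pixels
#'   only.
#' @return a `zq_quant_config` list.
#' @export
quant_config <- function(min_stained_fraction = 0.05, excluded_zones = c(1L, 12L),
                         n_zones = 12L, denominator = c("zone", "tissue")) {
  stopifnot(min_stained_fraction >= 0, min_stained_fraction < 1)
  structure(list(min_stained_fraction = min_stained_fraction,
                 excluded_zones = as.integer(excluded_zones),
                 n_zones = as.integer(n_zones),
                 denominator = match.arg(denominator)),
            class = "zq_quant_config")
}

# per-(lobule, zone) pixel keys; returns list(key vector, n_keys, decode fn)
zone_keys <- function(lobules, zones, tissue = NULL) {
  stopifnot(inherits(lobules, "zq_lobules"), inherits(zones, "zq_zones"))
  if (!all(dim(lobules$labels) == dim(zones$zones))) {
    stop("lobule and zone map shapes differ", call. = FALSE)
  }
  nz <- zones$n_zones
  sel <- lobules$labels > 0L
  if (!is.null(tissue)) sel <- sel & tissue_mask_of(tissue)
  key <- (lobules$labels[sel] - 1L) * nz + zones$zones[sel]
  list(sel = sel, key = key, nz = nz,
       nkeys = max(lobules$labels) * nz)
}

key_table <- function(kk, lobules) {
  counts <- tabulate(kk$key, nbins = kk$nkeys)
  present <- which(counts > 0L)
  lab <- (present - 1L) %/% kk$nz + 1L
  tibble::tibble(
    lobule_id = lobules$cv_index$id[match(lab, lobules$cv_index$label)],
    lobule_label = lab,
    zone = (present - 1L) %% kk$nz + 1L,
    zone_area_px = counts[present],
    .key = present
  )
}

#' Quantify steatosis per lobule and zone
#'
#' Steatosis is the fat droplet area fraction of each zone in each lobule:
#' `|fat & zone & lobule & tissue| / |zone & lobule & tissue|`. When no
#' tissue mask is given the denominator is the full zone pixel count; with a
#' mask, the fraction is relative to tissue area, so void regions at the
#' slide border do not dilute it.
#'
#' @param fat a [detect_fat()] result (or logical matrix).
#' @param lobules a [segment_lobules()] result.
#' @param zones a [quantize_zones()] result.
#' @param tissue optional [compute_tissue_mask()] result (or logical
#'   matrix) restricting the denominator to tissue pixels.
#' @return tibble with `lobule_id`, `lobule_label`, `zone`, `zone_area_px`
#'   (the denominator used), `steatosis`.
#' @export
quantify_steatosis <- function(fat, lobules, zones, tissue = NULL) {
  fmask <- if (inherits(fat, "zq_fat")) fat$mask else fat
  if (!all(dim(fmask) == dim(lobules$labels))) {
    stop("fat mask shape mismatch", call. = FALSE)
  }
  if (!is.null(tissue)) {
    tm <- tissue_mask_of(tissue)
    fmask <- fmask & tm
  }
  kk <- zone_keys(lobules, zones, tissue)
  tab <- key_table(kk, lobules)
  fcount <- tabulate(kk$key[fmask[kk$sel]], nbins = kk$nkeys)
  tab$steatosis <- fcount[tab$.key] / tab$zone_area_px
  tab$.key <- NULL
  tab
}

#' Quantify marker positivity per lobule and zone
#'
#' For each zone the stained fraction is `(positive + negative) / area`; if
#' it reaches `cfg$min_stained_fraction` the marker ratio
#' `positive / (positive + negative)` is reported, otherwise the ratio is
#' absent (`NA`), never zero.
#'
#' @param ternary a [classify_ternary()] result (or integer matrix 0..3).
#' @param lobules,zones label maps.
#' @param cfg a [quant_config()].
#' @param name marker name used for the ratio column (default `"marker"`).
#' @return tibble with `lobule_id`, `lobule_label`, `zone`, `zone_area_px`,
#'   `stained_fraction_<name>` and `<name>` (the positive ratio).
#' @export
quantify_marker <- function(ternary, lobules, zones, cfg = quant_config(),
                            name = "marker") {
  tlab <- if (inherits(ternary, "zq_ternary")) ternary$labels else ternary
  if (!all(dim(tlab) == dim(lobules$labels))) {
    stop("ternary mask shape mismatch", call. = FALSE)
  }
  kk <- zone_keys(lobules, zones)
  tab <- key_table(kk, lobules)
  tern <- tlab[kk$sel]
  npos <- tabulate(kk$key[tern == 2L], nbins = kk$nkeys)[tab$.key]
  nneg <- tabulate(kk$key[tern == 3L], nbins = kk$nkeys)[tab$.key]
  denom <- if (cfg$denominator == "zone") {
    tab$zone_area_px
  } else {
    tabulate(kk$key[tern != 0L], nbins = kk$nkeys)[tab$.key]
  }
  sf <- ifelse(denom > 0, (npos + nneg) / denom, 0)
  ratio <- ifelse(sf >= cfg$min_stained_fraction & (npos + nneg) > 0,
                  npos / (npos + nneg), NA_real_)
  tab[[paste0("stained_fraction_", name)]] <- sf
  tab[[name]] <- ratio
  tab$.key <- NULL
  tab
}

#' Join per-stain records into the joint quantification table
#'
#' Records from different stains are matched to the same lobule and zone via
#' the UUID of the corresponding central vein (an outer join on
#' `(lobule_id, zone)`); cells missing in one stain stay absent. Rows are
#' sorted by `(lobule_label, zone)`.
#'
#' @param tables named list of record tibbles (each keyed by `lobule_id`,
#'   `zone`), e.g. one [quantify_steatosis()] and several
#'   [quantify_marker()] outputs.
#' @param correspondence optional result of [match_lobules_by_cv()]; used
#'   only to report unmatched CVs, the join itself runs on shared UUIDs.
#' @return the joint tibble: `lobule_id`, `lobule_label`, `zone`,
#'   `zone_area_px`, then the value columns in input order.
#' @export
join_records <- function(tables, correspondence = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    if (anyDuplicated(t[c("lobule_id", "zone")])) {
      stop("duplicate (lobule_id, zone) keys in table '", nm, "'", call. = FALSE)
    }
  }
  strip <- function(t) t[setdiff(names(t), c("lobule_label", "zone_area_px"))]
  joined <- Reduce(function(a, b) dplyr::full_join(a, strip(b),
                                                   by = c("lobule_id", "zone")),
                   tables[-1], init = tables[[1]])
  # lobule_label/area from the first table that has them for the key
  for (t in tables[-1]) {
    miss <- is.na(joined$lobule_label)
    if (!any(miss)) break
    m <- match(paste(joined$lobule_id, joined$zone),
               paste(t$lobule_id, t$zone))
    joined$lobule_label[miss] <- t$lobule_label[m[miss]]
    joined$zone_area_px[miss] <- t$zone_area_px[m[miss]]
  }
  dplyr::arrange(joined, .data$lobule_label, .data$zone)
}

#' Write / read the joint quantification table as CSV
#'
#' Numeric fractions are written with four decimal places; absent cells are
#' empty fields (never zero). Round-trips are lossless at that precision.
#'
#' @param table joint tibble from [join_records()].
#' @param path CSV file path.
#' @export
write_zone_table <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), "", sprintf("%.4f", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_zone_table
#' @export
read_zone_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(t)
}
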