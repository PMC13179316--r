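# Internal helpers shared across modules.

# RFC 4122 v4 UUIDs from the current RNG stream (seedable for reproducible
# synthetic layouts).
zq_uuid4 <- function(n = 1L) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    h <- sample(hex, 32L, replace = TRUE)
    h[13] <- "4"                              # version nibble
    h[17] <- sample(c("8", "9", "a", "b"), 1) # variant nibble
    paste0(
      paste(h[1:8], collapse = ""), "-", paste(h[9:12], collapse = ""), "-",
      paste(h[13:16], collapse = ""), "-", paste(h[17:20], collapse = ""), "-",
      paste(h[21:32], collapse = "")
    )
  }, character(1))
}

is_uuid4 <- function(x) {
  grepl(
    "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
    tolower(x)
  )
}

# Rec. 601 luma of an RGB triple / array on the 0..255 scale.
zq_luminance <- function(r, g = NULL, b = NULL) {
  if (is.null(g)) {
    stopifnot(length(r) == 3L)
    return(0.299 * r[1] + 0.587 * r[2] + 0.114 * r[3])
  }
  0.299 * r + 0.587 * g + 0.114 * b
}

# Grayscale [row, col] matrix from an RGB array [row, col, 3] (0..255).
zq_gray <- function(rgb) {
  zq_luminance(rgb[, , 1], rgb[, , 2], rgb[, , 3])
}

stopifnot_rgb <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    stop("expected an RGB array with dimensions [rows, cols, 3]", call. = FALSE)
  }
}

# Block-mean downsampling of a matrix by an integer factor (area averaging).
# Trailing rows/cols that do not fill a block are dropped.
block_mean <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # average over row blocks, then column blocks
  rm <- rowsum(m, gl(nr / f, f), reorder = FALSE) / f
  t(rowsum(t(rm), gl(nc / f, f), reorder = FALSE) / f)
}

downsample_rgb <- function(rgb, f) {
  stopifnot_rgb(rgb)
  if (f == 1L) return(rgb)
  out <- lapply(1:3, function(k) block_mean(rgb[, , k], f))
  array(unlist(out), dim = c(dim(out[[1]]), 3L))
}

# Nearest-neighbour subsampling for label-like matrices.
subsample_nn <- function(m, f) {
  if (f == 1L) return(m)
  m[seq(1L, nrow(m), by = f), seq(1L, ncol(m), by = f), drop = FALSE]
}

# EBImage stores images [x, y]; package rasters are R matrices [row, col].
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

# md5 of an arbitrary R object (provenance sidecars).
zq_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
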