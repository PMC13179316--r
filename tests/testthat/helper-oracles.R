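# Independent oracles, kept free of the implementation paths they check.

# Brute-force portality at a single point from the defining distance ratio.
portality_point <- function(x, y, pf, cv) {
  dp <- min(sqrt((pf[, 1] - x)^2 + (pf[, 2] - y)^2))
  dc <- min(sqrt((cv[, 1] - x)^2 + (cv[, 2] - y)^2))
  if (dp + dc == 0) return(0.5)
  1 - dp / (dp + dc)
}

# Steepest-descent basin assignment on a scalar surface (8-neighborhood):
# pixels are processed in ascending surface order; each pixel joins the basin
# of its lowest neighbor, pixels without a lower neighbor found a new basin.
steepest_descent_basins <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  basin <- base::matrix(0L, nr, nc)
  ord <- order(p)
  nxt <- 0L
  for (lin in ord) {
    r <- (lin - 1L) %% nr + 1L
    c <- (lin - 1L) %/% nr + 1L
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    nb <- as.matrix(expand.grid(rs, cs))
    vals <- p[nb]
    best <- which.min(vals)
    if (vals[best] < p[r, c]) {
      basin[r, c] <- basin[nb[best, 1], nb[best, 2]]
    } else {
      # plateau: adopt an already-assigned neighbor at equal height if any
      eq <- which(vals == p[r, c] & basin[nb] > 0L)
      if (length(eq)) {
        basin[r, c] <- basin[nb[eq[1], 1], nb[eq[1], 2]]
      } else {
        nxt <- nxt + 1L
        basin[r, c] <- nxt
      }
    }
  }
  basin
}

# ridge pixels = pixels with an 8-neighbor in a different oracle basin
ridge_mask <- function(basin) {
  nr <- nrow(basin); nc <- ncol(basin)
  ridge <- base::matrix(FALSE, nr, nc)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    r0 <- max(1, 1 - s[1]):min(nr, nr - s[1])
    c0 <- max(1, 1 - s[2]):min(nc, nc - s[2])
    ridge[r0, c0] <- ridge[r0, c0] |
      (basin[r0, c0, drop = FALSE] != basin[r0 + s[1], c0 + s[2], drop = FALSE])
  }
  ridge
}

# agreement of watershed lobule labels with the steepest-descent oracle,
# measured off-ridge after matching basins via the CV seed pixels
descent_agreement <- function(port, lobules, cv_centers) {
  oracle <- steepest_descent_basins(port$values)
  ridge <- ridge_mask(oracle)
  # relabel oracle basins by the lobule label of each CV's basin
  map <- rep(NA_integer_, max(oracle))
  for (i in seq_len(nrow(cv_centers))) {
    r <- round(cv_centers$y[i]) + 1L
    c <- round(cv_centers$x[i]) + 1L
    lb <- lobules$labels[r, c]
    map[oracle[r, c]] <- lb
  }
  mapped <- base::matrix(map[oracle], nrow(oracle), ncol(oracle))
  sel <- !ridge & !is.na(mapped)
  mean(mapped[sel] == lobules$labels[sel])
}
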