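# Small raster helpers shared by the segmentation and simulation code.
# All filters use edge replication and are deterministic.

# Pad a matrix by r rows/cols of replicated edges.
pad_replicate <- function(m, r) {
  if (r < 1) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Sliding-window sums over a (2r+1)^2 neighbourhood with edge replication,
# via a summed-area table. Returns a matrix the size of m.
box_sum <- function(m, r) {
  p <- pad_replicate(m, r)
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  nr <- nrow(m); nc <- ncol(m); w <- 2L * r + 1L
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  sat[i1 + w, j1 + w, drop = FALSE] - sat[i1, j1 + w, drop = FALSE] -
    sat[i1 + w, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
}

# Local mean and population SD over a (2r+1)^2 window, edge-replicated.
local_mean_sd <- function(m, r) {
  n <- (2 * r + 1)^2
  s1 <- box_sum(m, r)
  s2 <- box_sum(m * m, r)
  mu <- s1 / n
  va <- pmax(s2 / n - mu^2, 0)
  list(mean = mu, sd = sqrt(va))
}

# Separable Gaussian blur, kernel truncated at 3 sigma, edge replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  # rows then columns; stats::filter works column-wise on matrices
  p <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  p <- t(apply(p, 1, function(row) stats::filter(row, k, sides = 2)))
  p[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

# Binary dilation by a Euclidean disk of radius r_px (0 = identity).
dilate_mask <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  r <- ceiling(r_px)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, ]
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | mask[si, sj]
  }
  out
}

#' Multi-channel image stack
#'
#' Container for named, shape-matched intensity channels with a physical
#' pixel size. Input to the colocalization pipeline and the fluorescence
#' summaries.
#'
#' @param channels Named list of numeric matrices (2-D) or 3-D arrays
#'   (z-stacks), all the same shape, intensities >= 0.
#' @param pixel_size Pixel size, um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size = 1) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a named list", call. = FALSE)
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1)
    stop("all channels must share the same shape", call. = FALSE)
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("intensities must be >= 0", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image stack: %s [%s], %.3f um/px\n",
              paste(names(x$channels), collapse = ", "),
              paste(d, collapse = " x "), x$pixel_size))
  invisible(x)
}
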