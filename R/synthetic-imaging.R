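# Synthetic ground-truth generators for the imaging pipeline: vesicle
# colocalization stacks, traction fields, vesicle-compartment movies.

# Rejection-sample `n` centres with border margin and minimum distances to
# previously accepted points (`avoid`, distance `avoid_dist`) and within the
# new set (`self_dist`). Deterministic given the RNG state.
place_centers <- function(n, shape, margin, self_dist, avoid = NULL,
                          avoid_dist = 0, max_tries = 20000L,
                          restarts = 5L) {
  for (attempt in seq_len(restarts)) {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n && tries < max_tries) {
      tries <- tries + 1L
      p <- c(stats::runif(1, 1 + margin, shape[1] - margin),
             stats::runif(1, 1 + margin, shape[2] - margin))
      ok <- TRUE
      if (nrow(pts) && min(sqrt(colSums((t(pts) - p)^2))) < self_dist)
        ok <- FALSE
      if (ok && !is.null(avoid) && nrow(avoid) &&
          min(sqrt(colSums((t(avoid) - p)^2))) < avoid_dist) ok <- FALSE
      if (ok) pts <- rbind(pts, p)
    }
    # an early accepted point can block the remainder; restart from scratch
    if (nrow(pts) == n) return(pts)
  }
  stop("placement error: could not place vesicles without violating ",
       "separation constraints", call. = FALSE)
}

# Paint unit disks of radius r at centres (rows of `centers`) into a matrix.
paint_disks <- function(shape, centers, radius, value) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(centers)) return(img)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
    img[d2 <= radius^2] <- value
  }
  img
}

#' Simulate a multi-channel vesicle stack with controlled true overlap
#'
#' Generates two or three channels of blurred, noisy vesicle images in which
#' a stated fraction of channel-2 (and channel-3) vesicles share their centre
#' with a channel-1 vesicle; the remaining vesicles are placed at least
#' `4 * vesicle_radius` away from every channel-1 vesicle, so they cannot
#' overlap even after point-spread-function blur. The ground truth records
#' the per-pair overlap fraction actually constructed (requested fraction
#' rounded to a whole number of vesicles).
#'
#' @param shape `c(nrow, ncol)` image size, px.
#' @param n_vesicles_per_channel Vesicles per channel.
#' @param overlap_fraction Fraction in [0, 1] of channel-2/3 vesicles sharing
#'   channel-1 centres.
#' @param vesicle_radius Disk radius, px.
#' @param psf_sigma Gaussian point-spread blur SD, px.
#' @param intensity Peak vesicle intensity, counts.
#' @param noise_sd Additive Gaussian noise SD, counts (images are rounded to
#'   integer counts and clamped at 0, like a camera).
#' @param n_channels 2 or 3.
#' @param seed Integer seed.
#' @param pixel_size Pixel size, um.
#' @return List with `stack` (an [image_stack()], channels `ch1..chN`) and
#'   `truth` (`synthetic_truth` of kind `"coloc_stack"`, payload holding the
#'   per-pair true overlap fractions, shared counts and all centres).
#' @export
simulate_coloc_stack <- function(shape = c(160, 160),
                                 n_vesicles_per_channel = 40,
                                 overlap_fraction = 0.5, vesicle_radius = 4,
                                 psf_sigma = 1, intensity = 100,
                                 noise_sd = 20, n_channels = 2, seed = 1L,
                                 pixel_size = 0.1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("'overlap_fraction' must be in [0, 1]", call. = FALSE)
  if (!n_channels %in% 2:3) stop("'n_channels' must be 2 or 3", call. = FALSE)
  n <- n_vesicles_per_channel
  n_shared <- round(overlap_fraction * n)
  margin <- vesicle_radius + 3 * psf_sigma + 1
  with_seed(seed, {
    c1 <- place_centers(n, shape, margin,
                        self_dist = 2 * vesicle_radius + 2)
    make_secondary <- function() {
      shared_idx <- sample.int(n, n_shared)
      extra <- place_centers(n - n_shared, shape, margin,
                             self_dist = 2 * vesicle_radius + 2,
                             avoid = c1, avoid_dist = 4 * vesicle_radius)
      list(centers = rbind(c1[shared_idx, , drop = FALSE], extra),
           shared_idx = shared_idx)
    }
    sec <- lapply(seq_len(n_channels - 1), function(i) make_secondary())
    centers <- c(list(c1), lapply(sec, `[[`, "centers"))
    channels <- lapply(centers, function(ct) {
      img <- gaussian_blur(paint_disks(shape, ct, vesicle_radius, intensity),
                           psf_sigma)
      if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
      matrix(pmax(round(img), 0), shape[1], shape[2])
    })
    names(channels) <- paste0("ch", seq_len(n_channels))
    overlap <- stats::setNames(
      rep(n_shared / n, n_channels - 1),
      paste0("ch1_ch", 2:n_channels))
    truth <- structure(
      list(kind = "coloc_stack",
           payload = list(overlap_fraction = overlap, n_shared = n_shared,
                          n_per_channel = n, centers = centers,
                          shared_idx = lapply(sec, `[[`, "shared_idx")),
           seed = as.integer(seed)),
      class = "synthetic_truth")
    list(stack = image_stack(channels, pixel_size), truth = truth)
  })
}

# Inward Euclidean-ish distance (in px) from the mask boundary, by iterative
# erosion; good enough for a smooth edge-decay pattern.
inward_distance <- function(mask) {
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  cur <- mask
  level <- 0
  while (any(cur)) {
    shrunk <- cur
    shrunk[1, ] <- FALSE; shrunk[nrow(cur), ] <- FALSE
    shrunk[, 1] <- FALSE; shrunk[, ncol(cur)] <- FALSE
    inner <- cur
    inner[2:nrow(cur), ] <- inner[2:nrow(cur), ] & cur[1:(nrow(cur) - 1), ]
    inner[1:(nrow(cur) - 1), ] <- inner[1:(nrow(cur) - 1), ] & cur[2:nrow(cur), ]
    inner[, 2:ncol(cur)] <- inner[, 2:ncol(cur)] & cur[, 1:(ncol(cur) - 1)]
    inner[, 1:(ncol(cur) - 1)] <- inner[, 1:(ncol(cur) - 1)] & cur[, 2:ncol(cur)]
    inner <- inner & shrunk
    d[cur & !inner] <- level
    cur <- inner
    level <- level + 1
  }
  d
}

#' Simulate a cell traction field with known summary truth
#'
#' Places planar traction vectors under a cell mask, either with uniform
#' magnitude (`"uniform"`) or concentrated at the mask boundary and decaying
#' inward with a 2 um length scale (`"edge_concentrated"`), with random
#' in-plane directions and optional Gaussian component noise. The ground
#' truth stores the exact noise-free mean stress and total force, which the
#' summary operation must reproduce.
#'
#' @param cell_mask Logical matrix (non-empty).
#' @param peak_stress Peak traction magnitude, Pa.
#' @param pattern `"uniform"` or `"edge_concentrated"`.
#' @param grid_spacing Vector grid spacing, um.
#' @param noise_sd Component noise SD, Pa.
#' @param seed Integer seed.
#' @param decay_um Decay length of the edge-concentrated pattern, um.
#' @return List with `field` (class `traction_field`: `tx`, `ty` in Pa,
#'   `grid_spacing`, `mask`) and `truth` (kind `"traction"`, payload with
#'   `mean_stress_pa`, `total_force_nn`, `area_um2`).
#' @export
simulate_traction_field <- function(cell_mask, peak_stress = 100,
                                    pattern = c("uniform", "edge_concentrated"),
                                    grid_spacing = 1, noise_sd = 0, seed = 1L,
                                    decay_um = 2) {
  pattern <- match.arg(pattern)
  if (!any(cell_mask)) stop("'cell_mask' must be non-empty", call. = FALSE)
  mag <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  if (pattern == "uniform") {
    mag[cell_mask] <- peak_stress
  } else {
    d <- inward_distance(cell_mask) * grid_spacing
    mag[cell_mask] <- peak_stress * exp(-d[cell_mask] / decay_um)
  }
  with_seed(seed, {
    theta <- matrix(stats::runif(length(mag), 0, 2 * pi), nrow(mag))
    tx <- mag * cos(theta); ty <- mag * sin(theta)
    if (noise_sd > 0) {
      tx <- tx + stats::rnorm(length(tx), 0, noise_sd)
      ty <- ty + stats::rnorm(length(ty), 0, noise_sd)
    }
    area <- sum(cell_mask) * grid_spacing^2
    truth <- structure(
      list(kind = "traction",
           payload = list(mean_stress_pa = mean(mag[cell_mask]),
                          # Pa * um^2 = pN; /1e3 -> nN
                          total_force_nn = sum(mag[cell_mask]) *
                            grid_spacing^2 / 1e3,
                          area_um2 = area),
           seed = as.integer(seed)),
      class = "synthetic_truth")
    field <- structure(list(tx = tx, ty = ty, grid_spacing = grid_spacing,
                            mask = cell_mask),
                       class = "traction_field")
    list(field = field, truth = truth)
  })
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("traction field: %d x %d vectors, %.2f um spacing, %d mask px\n",
              nrow(x$tx), ncol(x$tx), x$grid_spacing, sum(x$mask)))
  invisible(x)
}

# Snap a continuous (row, col) position to the nearest pixel of `pool`
# (a 2-col matrix of allowed pixel coordinates).
snap_to <- function(pos, pool) {
  d2 <- (pool[, 1] - pos[1])^2 + (pool[, 2] - pos[2])^2
  pool[which.min(d2), ]
}

#' Simulate vesicle trajectories with prescribed compartment contacts
#'
#' Vesicles perform a seeded random walk; during each prescribed contact
#' interval the (nearest-pixel-rounded) centroid lies inside the compartment
#' mask, and outside those intervals it stays at least 2 px away from it, so
#' the contact state is unambiguous. Frames are 0-based and intervals are
#' inclusive at both ends: a contact over frames 3-7 at 1 s per frame lasts
#' 5 s.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @param compartment_mask Logical matrix (static compartment).
#' @param contact_intervals Either a list of `c(enter, exit)` 0-based frame
#'   pairs (one vesicle), or a list of such lists (one element per vesicle).
#'   Intervals must lie in `[0, n_frames)` and must not overlap per vesicle.
#' @param step_sd Random-walk step SD, px.
#' @param seed Integer seed.
#' @param render Also render one-channel frames with Gaussian spots.
#' @param psf_sigma,intensity Rendering parameters.
#' @return List with `detections` (data frame: `frame`, `label`, `row`,
#'   `col`), `frames` (array `nrow x ncol x n_frames` or NULL), `masks`
#'   (per-frame list of the compartment mask), and `truth` (kind
#'   `"vesicle_movie"`; payload with per-vesicle intervals and durations in
#'   seconds).
#' @export
simulate_vesicle_movie <- function(n_frames, frame_interval = 1,
                                   compartment_mask, contact_intervals,
                                   step_sd = 1, seed = 1L, render = FALSE,
                                   psf_sigma = 1, intensity = 100) {
  if (length(contact_intervals) && is.numeric(contact_intervals[[1]]))
    contact_intervals <- list(contact_intervals)
  n_ves <- max(length(contact_intervals), 1L)
  if (!length(contact_intervals)) contact_intervals <- list(list())
  for (iv in contact_intervals) {
    if (!length(iv)) next
    m <- do.call(rbind, iv)
    if (any(m[, 1] > m[, 2]) || any(m < 0) || any(m >= n_frames))
      stop("contact interval out of range [0, n_frames)", call. = FALSE)
    if (nrow(m) > 1) {
      o <- order(m[, 1])
      if (any(m[o[-1], 1] <= m[o[-nrow(m)], 2]))
        stop("contact intervals overlap within a vesicle", call. = FALSE)
    }
  }
  inside_pool <- arrayInd(which(compartment_mask), dim(compartment_mask))
  # between contacts the vesicle hovers in a ring 2-5 px outside the
  # compartment, so enter/exit steps stay small enough to track
  ring <- dilate_mask(compartment_mask, 5) & !dilate_mask(compartment_mask, 2)
  if (!any(ring)) ring <- !dilate_mask(compartment_mask, 2)
  outside_pool <- arrayInd(which(ring), dim(compartment_mask))
  if (!nrow(inside_pool) || !nrow(outside_pool))
    stop("compartment mask must leave both inside and outside pixels",
         call. = FALSE)
  det <- vector("list", n_ves)
  with_seed(seed, {
    for (v in seq_len(n_ves)) {
      in_contact <- rep(FALSE, n_frames)
      for (iv in contact_intervals[[v]])
        in_contact[(iv[1]:iv[2]) + 1] <- TRUE
      pos <- matrix(NA_real_, n_frames, 2)
      cur <- outside_pool[sample.int(nrow(outside_pool), 1), ] +
        stats::runif(2, -0.4, 0.4)
      for (fr in seq_len(n_frames)) {
        cur <- cur + stats::rnorm(2, 0, step_sd)
        pool <- if (in_contact[fr]) inside_pool else outside_pool
        snapped <- snap_to(round(cur), pool)
        # keep sub-pixel jitter but never enough to change the rounded pixel
        cur <- snapped + stats::runif(2, -0.4, 0.4)
        pos[fr, ] <- cur
      }
      det[[v]] <- data.frame(frame = 0:(n_frames - 1), label = v,
                             row = pos[, 1], col = pos[, 2])
    }
    detections <- do.call(rbind, det)
    frames <- NULL
    if (render) {
      frames <- array(0, c(dim(compartment_mask), n_frames))
      for (fr in seq_len(n_frames)) {
        sub <- detections[detections$frame == fr - 1, , drop = FALSE]
        img <- paint_disks(dim(compartment_mask),
                           as.matrix(sub[, c("row", "col")]), 1, intensity)
        frames[, , fr] <- pmax(round(gaussian_blur(img, psf_sigma)), 0)
      }
    }
    durations <- lapply(contact_intervals, function(ivs)
      vapply(ivs, function(iv) (iv[2] - iv[1] + 1) * frame_interval,
             numeric(1)))
    truth <- structure(
      list(kind = "vesicle_movie",
           payload = list(intervals = contact_intervals,
                          durations_s = durations,
                          frame_interval = frame_interval),
           seed = as.integer(seed)),
      class = "synthetic_truth")
    list(detections = detections, frames = frames,
         masks = rep(list(compartment_mask), n_frames), truth = truth)
  })
}
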