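# Mechano-morphometric summaries: traction statistics, FRET ratio, corrected
# total cell fluorescence, shape metrics, track metrics, nearest-neighbour
# linking and vesicle-compartment residence times.

#' Traction-field summary statistics
#'
#' Total force exerted on the substrate, computed by summing the magnitudes
#' of the traction vectors under (and, by a configurable margin, near) the
#' cell and multiplying by the area each vector covers. The region is the
#' cell mask dilated by `margin_um`.
#'
#' @param field A `traction_field` (see [simulate_traction_field()] or
#'   [read_traction_field()]).
#' @param margin_um Dilation margin defining "near the cell", um.
#' @return List with `mean_stress_pa`, `total_force_nn` (nN), `area_um2` and
#'   `n_vectors`.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' f <- simulate_traction_field(m, 100, "uniform", grid_spacing = 1)$field
#' traction_summary(f, margin_um = 0)$total_force_nn  # 2.5 nN
#' @export
traction_summary <- function(field, margin_um = 2) {
  stopifnot(inherits(field, "traction_field"))
  region <- dilate_mask(field$mask, margin_um / field$grid_spacing)
  if (!any(region)) stop("empty traction region", call. = FALSE)
  mag <- sqrt(field$tx^2 + field$ty^2)
  a <- field$grid_spacing^2                       # um^2 per vector
  list(mean_stress_pa = mean(mag[region]),
       total_force_nn = sum(mag[region]) * a / 1e3,  # Pa um^2 = pN -> nN
       area_um2 = sum(region) * a,
       n_vectors = sum(region))
}

#' FRET ratio of a biosensor
#'
#' Ratio between the summed YFP (acceptor) and CFP (donor) signal over the
#' cell mask; reports the conformational state of a ratiometric biosensor.
#' Also returns the per-pixel ratio image with donor-zero pixels set to NA.
#'
#' @param yfp,cfp Intensity matrices.
#' @param mask Logical matrix; defaults to all pixels.
#' @return List with `ratio` (scalar `sum(YFP)/sum(CFP)` over the mask),
#'   `ratio_image` and `n_cfp_zero` (flagged donor-zero pixels in the mask).
#' @export
fret_ratio <- function(yfp, cfp, mask = NULL) {
  stopifnot(identical(dim(yfp), dim(cfp)))
  if (is.null(mask)) mask <- array(TRUE, dim(yfp))
  stopifnot(identical(dim(yfp), dim(mask)))
  denom <- sum(cfp[mask])
  if (denom <= 0) stop("CFP signal over the mask is zero", call. = FALSE)
  ratio_image <- yfp / cfp
  ratio_image[cfp == 0] <- NA_real_
  list(ratio = sum(yfp[mask]) / denom, ratio_image = ratio_image,
       n_cfp_zero = sum(mask & cfp == 0))
}

#' Corrected total cell fluorescence (CTCF)
#'
#' Integrated intensity over the cell mask minus the cell area (in px) times
#' the mean intensity of a user-supplied background region:
#' `CTCF = sum(I[cell]) - n_cell * mean(I[background])`.
#'
#' @param image Intensity matrix.
#' @param cell_mask,background_mask Disjoint, non-empty logical matrices.
#' @return CTCF value (intensity units).
#' @export
corrected_total_fluorescence <- function(image, cell_mask, background_mask) {
  stopifnot(identical(dim(image), dim(cell_mask)),
            identical(dim(image), dim(background_mask)))
  if (!any(cell_mask) || !any(background_mask))
    stop("cell and background masks must be non-empty", call. = FALSE)
  if (any(cell_mask & background_mask))
    stop("cell and background masks must be disjoint", call. = FALSE)
  sum(image[cell_mask]) - sum(cell_mask) * mean(image[background_mask])
}

#' Cell-shape metrics from binary masks
#'
#' Aspect ratio of the best-fit ellipse of the cell mask (second-moment
#' method: square root of the ratio of the principal eigenvalues of the
#' pixel-coordinate covariance) and the Euclidean distance between the cell
#' centroid and the nucleus centroid. An elongated, polarized cell has a
#' large aspect ratio and an off-centre nucleus.
#'
#' @param cell_mask,nucleus_mask Logical matrices.
#' @param pixel_size Pixel size, um.
#' @param method `"ellipse"` (second moments) or `"feret"` (max/min caliper
#'   of the pixel centres).
#' @return List with `aspect_ratio` (>= 1), `cell_centroid`,
#'   `nucleus_centroid` (um, `c(row, col)` from the image origin) and
#'   `nucleus_centroid_distance` (um).
#' @export
shape_metrics <- function(cell_mask, nucleus_mask, pixel_size = 1,
                          method = c("ellipse", "feret")) {
  method <- match.arg(method)
  if (sum(cell_mask) < 2 || sum(nucleus_mask) < 1)
    stop("degenerate mask", call. = FALSE)
  pts <- arrayInd(which(cell_mask), dim(cell_mask))
  if (method == "ellipse") {
    cv <- stats::cov(pts)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= 0) stop("degenerate (collinear) cell mask", call. = FALSE)
    ar <- sqrt(ev[1] / ev[2])
  } else {
    # caliper extents along the principal axes
    pr <- stats::prcomp(pts)$x
    ar <- diff(range(pr[, 1])) / max(diff(range(pr[, 2])), 1e-12)
  }
  cc <- colMeans(pts) * pixel_size
  nc <- colMeans(arrayInd(which(nucleus_mask), dim(nucleus_mask))) * pixel_size
  list(aspect_ratio = ar, cell_centroid = cc, nucleus_centroid = nc,
       nucleus_centroid_distance = sqrt(sum((cc - nc)^2)))
}

#' Track kinematics
#'
#' @param track Data frame with strictly increasing `t_s` (s) and positions
#'   `x_um`, `y_um`.
#' @return List with `path_length_um` (sum of step norms),
#'   `net_displacement_um` (start-to-end distance) and `mean_speed_um_min`
#'   (path length over elapsed time).
#' @export
track_metrics <- function(track) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2) stop("track needs >= 2 samples", call. = FALSE)
  if (any(diff(track$t_s) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  path <- sum(steps)
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                (track$y_um[nrow(track)] - track$y_um[1])^2)
  elapsed_min <- (track$t_s[nrow(track)] - track$t_s[1]) / 60
  list(path_length_um = path, net_displacement_um = net,
       mean_speed_um_min = if (elapsed_min > 0) path / elapsed_min else 0)
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame linking: a detection in
#' frame t+1 is appended to a live track iff each is the other's nearest
#' neighbour and the step is at most `max_step`. Unmatched detections start
#' new tracks. Ties break deterministically toward the lowest index.
#'
#' @param detections Data frame with `frame` (integer), `row`, `col` (px)
#'   and optionally `label` (ignored by the linker).
#' @param max_step Largest allowed frame-to-frame step, px.
#' @return Data frame `track_id`, `frame`, `row`, `col`, ordered by track
#'   then frame.
#' @export
link_detections <- function(detections, max_step = 5) {
  stopifnot(all(c("frame", "row", "col") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  next_id <- 1L
  live <- list()    # track_id -> last position
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    sub <- detections[detections$frame == frames[fi], , drop = FALSE]
    sub <- sub[order(sub$row, sub$col), , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(sub))
    if (length(live) && nrow(sub)) {
      prev <- do.call(rbind, live)
      ids <- as.integer(names(live))
      d <- outer(seq_len(nrow(prev)), seq_len(nrow(sub)),
                 function(a, b) sqrt((prev[a, 1] - sub$row[b])^2 +
                                       (prev[a, 2] - sub$col[b])^2))
      for (a in seq_len(nrow(prev))) {
        b <- which.min(d[a, ])
        if (d[a, b] <= max_step && which.min(d[, b]) == a &&
            is.na(assigned[b]))
          assigned[b] <- ids[a]
      }
    }
    new_live <- list()
    for (b in seq_len(nrow(sub))) {
      if (is.na(assigned[b])) {
        assigned[b] <- next_id
        next_id <- next_id + 1L
      }
      new_live[[as.character(assigned[b])]] <- c(sub$row[b], sub$col[b])
    }
    live <- new_live
    if (nrow(sub))
      out[[fi]] <- data.frame(track_id = assigned, frame = frames[fi],
                              row = sub$row, col = sub$col)
  }
  res <- do.call(rbind, out)
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Residence times of tracked vesicles in a compartment
#'
#' For each track, finds maximal runs of consecutive frames whose
#' nearest-pixel position lies on a foreground compartment pixel; each run's
#' duration is its (inclusive) frame count times `frame_interval`. A vesicle
#' seen inside over frames 3-7 of a 1-s series therefore resided 5 s.
#'
#' @param tracks Data frame from [link_detections()] (`track_id`, `frame`,
#'   `row`, `col`) or the generator's detection table (with `label`).
#' @param compartment_masks List of logical matrices, one per frame (indexed
#'   by `frame + 1`), or a single matrix recycled over frames.
#' @param frame_interval Seconds per frame.
#' @return Data frame `track_id`, `enter_frame`, `exit_frame`, `duration_s`;
#'   zero rows when no contacts occur.
#' @export
residence_times <- function(tracks, compartment_masks, frame_interval = 1) {
  if (!"track_id" %in% names(tracks) && "label" %in% names(tracks))
    tracks$track_id <- tracks$label
  stopifnot(all(c("track_id", "frame", "row", "col") %in% names(tracks)))
  if (is.matrix(compartment_masks))
    compartment_masks <- list(compartment_masks)
  get_mask <- function(fr)
    compartment_masks[[min(fr + 1, length(compartment_masks))]]
  recs <- list()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    inside <- vapply(seq_len(nrow(tr)), function(i) {
      m <- get_mask(tr$frame[i])
      r <- round(tr$row[i]); c <- round(tr$col[i])
      if (r < 1 || c < 1 || r > nrow(m) || c > ncol(m))
        stop("track position outside the compartment raster", call. = FALSE)
      m[r, c]
    }, logical(1))
    # maximal runs of frames that are both inside and consecutive
    if (!any(inside)) next
    enter <- NULL; last_in <- NULL
    for (i in seq_len(nrow(tr))) {
      if (inside[i]) {
        if (is.null(enter)) {
          enter <- tr$frame[i]
        } else if (tr$frame[i] != last_in + 1) {
          recs[[length(recs) + 1]] <- c(id, enter, last_in)
          enter <- tr$frame[i]
        }
        last_in <- tr$frame[i]
      } else if (!is.null(enter)) {
        recs[[length(recs) + 1]] <- c(id, enter, last_in)
        enter <- NULL
      }
    }
    if (!is.null(enter)) recs[[length(recs) + 1]] <- c(id, enter, last_in)
  }
  if (!length(recs))
    return(data.frame(track_id = numeric(0), enter_frame = numeric(0),
                      exit_frame = numeric(0), duration_s = numeric(0)))
  m <- do.call(rbind, recs)
  data.frame(track_id = m[, 1], enter_frame = m[, 2], exit_frame = m[, 3],
             duration_s = (m[, 3] - m[, 2] + 1) * frame_interval)
}
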