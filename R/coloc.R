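# Object-based colocalization: Phansalkar local thresholding, binary median
# filtering, Manders split coefficients, conjunction (triple) colocalization.

#' Min-max normalize a channel to [0, 1]
#'
#' Local-threshold parameters assume unit-range intensities, so each channel
#' is rescaled to \eqn{(I - \min)/(\max - \min)} first. A constant image maps
#' to all zeros.
#'
#' @param image Numeric matrix or array.
#' @return Same shape, values in [0, 1].
#' @export
normalize_channel <- function(image) {
  rng <- range(image)
  if (rng[2] == rng[1]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Phansalkar local threshold parameters
#'
#' Defaults follow the original published method as implemented in standard
#' auto-local-threshold tools (k = 0.25, r = 0.5, p = 2, q = 10, 15 px
#' window), designed for low-contrast fluorescence images.
#'
#' @param window Odd window side, px.
#' @param k_p,r_p,p_p,q_p Dimensionless method parameters.
#' @return Named list of class `threshold_params`.
#' @export
threshold_params <- function(window = 15, k_p = 0.25, r_p = 0.5,
                             p_p = 2, q_p = 10) {
  if (window < 3 || window %% 2 == 0)
    stop("'window' must be odd and >= 3", call. = FALSE)
  if (r_p <= 0) stop("'r_p' must be positive", call. = FALSE)
  structure(list(window = as.integer(window), k_p = k_p, r_p = r_p,
                 p_p = p_p, q_p = q_p),
            class = "threshold_params")
}

#' Segment a channel by Phansalkar local thresholding
#'
#' For each pixel, the mean m and population SD s of the normalized
#' intensities in a square `window` neighbourhood (edge-replicated) set the
#' local threshold
#' \deqn{t = m\,(1 + p\,e^{-q m} + k\,(s/r - 1)),}
#' and the pixel is foreground iff its intensity strictly exceeds t. The
#' exponential term lifts the threshold in dim regions, which makes the
#' method robust for low-contrast fluorescence.
#'
#' @param image Normalized matrix in [0, 1] (see [normalize_channel()]).
#' @param params A [threshold_params()] object.
#' @return Logical matrix, `TRUE` = foreground.
#' @examples
#' img <- matrix(0.5, 32, 32)
#' all(phansalkar_threshold(img))  # uniform 0.5 exceeds its own threshold
#' @export
phansalkar_threshold <- function(image, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  if (min(image) < 0 || max(image) > 1 + 1e-9)
    stop("'image' must be normalized to [0, 1]", call. = FALSE)
  r <- (params$window - 1L) %/% 2L
  st <- local_mean_sd(image, r)
  t <- st$mean * (1 + params$p_p * exp(-params$q_p * st$mean) +
                    params$k_p * (st$sd / params$r_p - 1))
  image > t
}

#' Majority median filter on a binary mask
#'
#' Sliding-window median (= majority vote) over a square neighbourhood with
#' edge replication; removes speckle noise from segmentation masks while
#' preserving objects larger than about half the window. The `neighborhood`
#' number is interpreted, by default, as the pixel AREA of the window (the
#' `medfilt2([m n])` convention), so 16 gives a window of side
#' `round(sqrt(16)) = 4`, bumped to the nearest odd size (5) for a
#' well-defined centre. Alternative readings (side length, radius) are
#' selectable.
#'
#' @param mask Logical matrix.
#' @param neighborhood Neighbourhood size (>= 1); meaning set by
#'   `interpretation`.
#' @param interpretation One of `"area"` (window area in px, default),
#'   `"side"` (window side in px) or `"radius"` (window side = 2r+1).
#' @return Filtered logical matrix.
#' @export
median_filter_mask <- function(mask, neighborhood = 16,
                               interpretation = c("area", "side", "radius")) {
  interpretation <- match.arg(interpretation)
  if (neighborhood < 1) stop("'neighborhood' must be >= 1", call. = FALSE)
  side <- switch(interpretation,
                 area = round(sqrt(neighborhood)),
                 side = neighborhood,
                 radius = 2 * neighborhood + 1)
  if (side %% 2 == 0) side <- side + 1
  if (side < 3) return(mask)
  r <- (side - 1L) %/% 2L
  n <- side^2
  2 * box_sum(mask * 1, r) > n
}

#' Manders split colocalization coefficients
#'
#' Intensity-weighted overlap of two segmented channels:
#' \deqn{M1 = \frac{\sum_i S1_{i,coloc}}{\sum_i S1_i}, \qquad
#'       M2 = \frac{\sum_j S2_{j,coloc}}{\sum_j S2_j},}
#' where \eqn{S1_{i,coloc} = S1_i} on pixels where both channels are present
#' and 0 elsewhere. "Present" is realized through the segmentation masks:
#' channel-1 signal is summed over `mask1`, and counted as colocalized where
#' `mask1 & mask2`.
#'
#' @param s1,s2 Intensity matrices/arrays of the two channels.
#' @param mask1,mask2 Logical foreground masks of the two channels.
#' @param labels Length-2 character vector naming the ordered pair.
#' @return An object of class `coloc_result` with `m1`, `m2`, labels and
#'   pixel counts. A channel with an empty mask (zero denominator) yields
#'   `NaN` and sets `empty_denominator`.
#' @examples
#' s1 <- c(2, 3, 0); s2 <- c(1, 0, 4)
#' r <- manders_split(s1, s2, s1 > 0, s2 > 0)
#' c(r$m1, r$m2)  # 0.4, 0.2
#' @export
manders_split <- function(s1, s2, mask1, mask2,
                          labels = c("ch1", "ch2")) {
  if (!all(length(s1) == c(length(s2), length(mask1), length(mask2))))
    stop("images and masks must have identical shapes", call. = FALSE)
  both <- mask1 & mask2
  d1 <- sum(s1[mask1]); d2 <- sum(s2[mask2])
  m1 <- if (d1 > 0) sum(s1[both]) / d1 else NaN
  m2 <- if (d2 > 0) sum(s2[both]) / d2 else NaN
  structure(
    list(m1 = m1, m2 = m2, labels = labels,
         n_total = length(s1), n_mask1 = sum(mask1), n_mask2 = sum(mask2),
         n_coloc = sum(both),
         empty_denominator = (d1 <= 0) || (d2 <= 0)),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 4, ...) {
  cat(sprintf("Manders split coefficients (%s vs %s):\n",
              x$labels[1], x$labels[2]))
  cat(sprintf("  M1 = %s  M2 = %s  (coloc px %d; fg px %d / %d)\n",
              format(x$m1, digits = digits), format(x$m2, digits = digits),
              x$n_coloc, x$n_mask1, x$n_mask2))
  if (x$empty_denominator) cat("  warning: empty channel mask\n")
  invisible(x)
}

#' Conjunction mask for triple colocalization
#'
#' Logical AND of two channel masks. The conjunction's intensity image, used
#' when the conjunction enters a Manders computation against a third channel,
#' is taken from the first-listed channel by default (`"first"`), or the
#' pixel-wise minimum of the two (`"min"`).
#'
#' @param mask_a,mask_b Logical masks.
#' @return Logical matrix `mask_a & mask_b`.
#' @export
conjunction_mask <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  mask_a & mask_b
}

# Segment one channel: normalize -> threshold -> median filter, slice-wise
# for 3-D stacks.
segment_channel <- function(img, params, neighborhood, interpretation) {
  seg2d <- function(m) median_filter_mask(
    phansalkar_threshold(normalize_channel(m), params),
    neighborhood, interpretation)
  if (length(dim(img)) == 3) {
    out <- array(FALSE, dim(img))
    for (z in seq_len(dim(img)[3])) out[, , z] <- seg2d(img[, , z])
    out
  } else seg2d(img)
}

#' Full colocalization pipeline
#'
#' Normalizes, thresholds (Phansalkar) and median-filters each requested
#' channel, optionally forms a conjunction (AND) of two masks, and computes
#' the Manders split coefficients for the requested ordered pair. Z-stacks
#' are segmented slice-wise; coefficients are computed from pooled sums over
#' all slices, giving one number per stack (per cell).
#'
#' @param stack An [image_stack()].
#' @param pair Character vector of two channel names, e.g. `c("ahph",
#'   "rab35")`. For triple colocalization, the first element may be a
#'   conjunction written `"a+b"`.
#' @param params [threshold_params()].
#' @param neighborhood,interpretation Passed to [median_filter_mask()].
#' @param conjunction_intensity `"first"` or `"min"`: how the conjunction's
#'   intensity image is formed.
#' @return A `coloc_result`.
#' @export
coloc_pipeline <- function(stack, pair, params = threshold_params(),
                           neighborhood = 16,
                           interpretation = "area",
                           conjunction_intensity = c("first", "min")) {
  stopifnot(inherits(stack, "image_stack"), length(pair) == 2)
  conjunction_intensity <- match.arg(conjunction_intensity)
  get_side <- function(name) {
    parts <- strsplit(name, "+", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(stack$channels))
    if (length(missing))
      stop("unknown channel(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    masks <- lapply(stack$channels[parts], segment_channel, params,
                    neighborhood, interpretation)
    mask <- Reduce(conjunction_mask, masks)
    img <- if (length(parts) == 1 || conjunction_intensity == "first")
      stack$channels[[parts[1]]]
    else pmin(stack$channels[[parts[1]]], stack$channels[[parts[2]]])
    list(img = img, mask = mask)
  }
  a <- get_side(pair[1]); b <- get_side(pair[2])
  manders_split(a$img, b$img, a$mask, b$mask, labels = pair)
}
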