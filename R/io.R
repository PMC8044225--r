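# Readers/writers for the package's portable formats. CSV dialect is fixed
# (UTF-8, comma, "." decimal, header row) and numbers are written with 17
# significant digits so write -> read round-trips are lossless.

fmt_num <- function(x) sprintf("%.17g", x)

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a force-volume map to the portable JSON + CSV container
#'
#' The container is a JSON header (probe parameters, grid shape, pixel size,
#' units) plus one long-format CSV with columns `pixel_row`, `pixel_col`,
#' `z_nm`, `force_pN` (0-based pixel indices).
#'
#' @param map A `force_volume`.
#' @param path Path of the header JSON; the CSV is written next to it with
#'   the extension replaced by `.csv`.
#' @return `path`, invisibly.
#' @export
write_force_volume <- function(map, path) {
  stopifnot(inherits(map, "force_volume"))
  csv_path <- sub("\\.json$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  d <- dim(map$curves)
  header <- list(
    format = "cellmech-force-volume", version = 1L,
    grid = list(nrow = d[1], ncol = d[2]),
    pixel_size_um = map$pixel_size,
    units = list(z = "nm", force = "pN"),
    probe = unclass(map$probe),
    data_file = basename(csv_path))
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rows <- vector("list", prod(d))
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    cur <- map$curves[[i, j]]
    n <- n + 1L
    rows[[n]] <- data.frame(pixel_row = i - 1L, pixel_col = j - 1L,
                            z_nm = cur$z, force_pN = cur$force)
  }
  write_csv_exact(do.call(rbind, rows), csv_path)
  invisible(path)
}

#' Read a force-volume map from the portable container
#'
#' @param path Path of the header JSON written by [write_force_volume()].
#' @return A `force_volume`.
#' @export
read_force_volume <- function(path) {
  header <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(header$format, "cellmech-force-volume"))
    stop("not a force-volume container: ", path, call. = FALSE)
  if (!identical(header$units$z, "nm") ||
      !identical(header$units$force, "pN"))
    stop("unit mismatch: container must carry z in nm and force in pN, got ",
         header$units$z, "/", header$units$force, call. = FALSE)
  csv_path <- file.path(dirname(path), header$data_file)
  df <- utils::read.csv(csv_path)
  nr <- header$grid$nrow; nc <- header$grid$ncol
  probe <- probe_params(header$probe$tip_radius, header$probe$spring_constant,
                        header$probe$poisson_ratio, header$probe$trigger_force,
                        header$probe$velocity)
  curves <- vector("list", nr * nc); dim(curves) <- c(nr, nc)
  key <- paste(df$pixel_row, df$pixel_col)
  split_idx <- split(seq_len(nrow(df)), key)
  expected <- as.vector(outer(0:(nr - 1), 0:(nc - 1), paste))
  missing <- setdiff(expected, names(split_idx))
  if (length(missing))
    stop("missing pixel(s) in container: ",
         paste(utils::head(missing, 5), collapse = "; "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  for (k in expected) {
    idx <- split_idx[[k]]
    z <- df$z_nm[idx]; f <- df$force_pN[idx]
    if (any(diff(z) <= 0))
      stop("non-monotone z for pixel (", k, ")", call. = FALSE)
    rc <- as.integer(strsplit(k, " ")[[1]])
    curves[[rc[1] + 1, rc[2] + 1]] <- structure(
      list(z = z, force = f, probe = probe, pixel = rc + 1L, truth = NULL),
      class = "force_curve")
  }
  structure(list(curves = curves, pixel_size = header$pixel_size_um,
                 probe = probe),
            class = "force_volume")
}

#' Write an image stack as multi-page TIFF plus a channel-name sidecar
#'
#' Intensities are stored as 16-bit pages; the sidecar JSON records channel
#' names, pixel size and the intensity scale, so integer count images
#' round-trip exactly.
#'
#' @param stack An [image_stack()] of 2-D channels (counts in
#'   `[0, 65535]`).
#' @param path TIFF path; sidecar written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$channels, function(ch) {
    if (length(dim(ch)) != 2)
      stop("TIFF writer supports 2-D channels only", call. = FALSE)
    if (max(ch) > 65535) stop("intensities exceed 16-bit range", call. = FALSE)
    ch / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(format = "cellmech-image-stack", version = 1L,
                  channels = names(stack$channels),
                  pixel_size_um = stack$pixel_size, scale = 65535,
                  integer_counts = TRUE)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path. When the `<path>.json` sidecar is missing the
#'   channels are auto-named `ch0..chN` with a warning and pixel size 1 um.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("non-uniform page shapes in ", path, call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (length(sc$channels) != length(pages))
      stop("sidecar names ", length(sc$channels), " channels but TIFF has ",
           length(pages), " pages", call. = FALSE)
    chans <- lapply(pages, function(p) {
      v <- p * sc$scale
      if (isTRUE(sc$integer_counts)) v <- round(v)
      v
    })
    names(chans) <- sc$channels
    image_stack(chans, sc$pixel_size_um)
  } else {
    warning("missing sidecar ", sidecar_path,
            "; auto-naming channels ch0..ch", length(pages) - 1, call. = FALSE)
    chans <- lapply(pages, function(p) round(p * 65535))
    names(chans) <- paste0("ch", seq_along(pages) - 1)
    image_stack(chans, 1)
  }
}

#' Write / read a traction field (CSV grid + JSON sidecar)
#'
#' CSV columns: `row`, `col` (0-based), `tx_pa`, `ty_pa`, `mask` (0/1); the
#' sidecar records the grid shape and spacing.
#'
#' @param field A `traction_field`.
#' @param path CSV path; sidecar at `<path>.json`.
#' @return `path` invisibly (writer); a `traction_field` (reader).
#' @export
write_traction_field <- function(field, path) {
  stopifnot(inherits(field, "traction_field"))
  idx <- arrayInd(seq_along(field$tx), dim(field$tx))
  df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   tx_pa = as.vector(field$tx), ty_pa = as.vector(field$ty),
                   mask = as.integer(as.vector(field$mask)))
  write_csv_exact(df, path)
  jsonlite::write_json(
    list(format = "cellmech-traction", version = 1L,
         nrow = nrow(field$tx), ncol = ncol(field$tx),
         grid_spacing_um = field$grid_spacing),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_traction_field
#' @export
read_traction_field <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  tx <- ty <- matrix(NA_real_, sc$nrow, sc$ncol)
  mask <- matrix(FALSE, sc$nrow, sc$ncol)
  idx <- cbind(df$row + 1L, df$col + 1L)
  tx[idx] <- df$tx_pa; ty[idx] <- df$ty_pa; mask[idx] <- df$mask == 1
  if (any(is.na(tx)))
    stop("incomplete traction grid in ", path, call. = FALSE)
  structure(list(tx = tx, ty = ty, grid_spacing = sc$grid_spacing_um,
                 mask = mask),
            class = "traction_field")
}

#' Write / read track tables (CSV: label, t_s, x_um, y_um)
#'
#' @param tracks Data frame with columns `label`, `t_s`, `x_um`, `y_um`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("label", "t_s", "x_um", "y_um") %in% names(tracks)))
  write_csv_exact(tracks[, c("label", "t_s", "x_um", "y_um")], path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) utils::read.csv(path)
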