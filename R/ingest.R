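# Ingestion: locate and decode the barcode label, crop the growth zone by
# hue segmentation, calibrate the mm-per-pixel scale from the known paper
# width, and file images into the hierarchical
# species/population/genotype/replicate database.

#' Locate the barcode label in a plate photograph
#'
#' Implements the locator sequence: (1) 8-bit grayscale; (2) local variance
#' filter (window `variance_window`), normalised to 0..255 so it is
#' comparable with the grayscale; (3) pixel-wise minimum of the normalised
#' variance image and the grayscale, leaving bright only the regions that
#' are both locally heterogeneous and bright; (4) fixed threshold at
#' `threshold_frac` of the maximum of that image; (5) connected components;
#' (6) bounding box of the largest component.  The threshold is relative, so
#' the locator is invariant to uniform brightness scaling (up to
#' saturation).
#'
#' @param img A [plate_image()].
#' @param variance_window Odd window size in px for the variance filter; it
#'   should exceed the barcode module pitch so the symbol region is
#'   uniformly high-variance.
#' @param threshold_frac Fraction of the maximum intensity (default 0.8).
#' @return The label bounding box as a [px_rect()].
#' @export
locate_qr <- function(img, variance_window = 15, threshold_frac = 0.8) {
  stopifnot(inherits(img, "plate_image"),
            threshold_frac > 0, threshold_frac < 1)
  gray <- luma(img$pixels)
  w <- as.integer(variance_window)
  if (w %% 2L == 0L) w <- w + 1L
  box <- matrix(1 / w^2, w, w)
  m1 <- from_ebi(EBImage::filter2(as_ebi(gray), box, boundary = "replicate"))
  m2 <- from_ebi(EBImage::filter2(as_ebi(gray^2), box, boundary = "replicate"))
  v <- pmax(m2 - m1^2, 0)
  # normalise variance to the grayscale's own range so the two are
  # comparable and the pixel-wise minimum scales with image brightness
  if (max(v) > 0) v <- v * (max(gray) / max(v))
  minimg <- pmin(v, gray)
  mx <- max(minimg)
  if (mx <= 0) rr_abort("rr_qr_not_found", "no bright heterogeneous region")
  mask <- minimg >= threshold_frac * mx
  lc <- largest_component(mask)
  if (is.null(lc)) rr_abort("rr_qr_not_found", "no component above threshold")
  lc$bbox
}

#' Decode the barcode label
#'
#' Crops to the located rectangle (expanded by `margin`) and decodes the
#' matrix symbol, then parses the payload with the
#' `species|population|genotype|replicate` grammar.
#'
#' @param img A [plate_image()].
#' @param qr_rect Label rectangle from [locate_qr()].
#' @param margin Fractional margin added around the rectangle before
#'   decoding (default 0.75: the located box is approximate and tends to
#'   under-cover the symbol, and a generous margin costs nothing because the
#'   decoder re-locates the label inside the crop).
#' @return A [plate_label()].  Signals `rr_qr_unreadable` for an
#'   undecodable symbol and `rr_label_parse_error` for a payload that does
#'   not match the grammar.
#' @export
decode_qr <- function(img, qr_rect, margin = 0.75) {
  stopifnot(inherits(img, "plate_image"))
  d <- dim(img$pixels)
  gray_full <- luma(img$pixels)
  mr <- ceiling(margin * rect_height(qr_rect))
  mc <- ceiling(margin * rect_width(qr_rect))
  r0 <- max(1L, qr_rect$r0 - mr); r1 <- min(d[1], qr_rect$r1 + mr)
  c0 <- max(1L, qr_rect$c0 - mc); c1 <- min(d[2], qr_rect$c1 + mc)
  # the located box may cover only a fragment of the symbol; on failure grow
  # the decoding window (the decoder re-locates the label inside it)
  last_err <- NULL
  for (k in 1:5) {
    gray <- gray_full[r0:r1, c0:c1, drop = FALSE]
    payload <- tryCatch(decode_matrix_code(gray), error = function(e) e)
    if (!inherits(payload, "error")) return(parse_label_payload(payload))
    last_err <- payload
    if (r0 == 1L && c0 == 1L && r1 == d[1] && c1 == d[2]) break
    gr <- ceiling(0.5 * (r1 - r0 + 1L)); gc <- ceiling(0.5 * (c1 - c0 + 1L))
    r0 <- max(1L, r0 - gr); r1 <- min(d[1], r1 + gr)
    c0 <- max(1L, c0 - gc); c1 <- min(d[2], c1 + gc)
  }
  if (inherits(last_err, "rr_qr_unreadable")) stop(last_err)
  rr_abort("rr_qr_unreadable", conditionMessage(last_err))
}

#' Crop the growth zone by hue segmentation
#'
#' Implements the growth-zone sequence: (1) hue channel of the HSV
#' transform, mapped to 0..255 (the blue paper sits far from the 0/255 hue
#' discontinuity; red-dominant papers would need a hue rotation upstream);
#' (2) Otsu auto-threshold; (3) largest connected component (holes filled);
#' (4) exterior filled with black and image cropped to the component
#' bounding box.
#'
#' @param img A [plate_image()].
#' @param calibrate If `TRUE` (default), attach the mm-per-pixel scale from
#'   [calibrate_scale()] to the cropped image.
#' @param paper_width_mm Physical paper width used for calibration.
#' @return A `crop_result`: `cropped` ([plate_image()], exterior black),
#'   `paper_rect` ([px_rect()] in the original frame), `mask` (logical
#'   matrix, same dimensions as the crop).
#' @export
crop_growth_zone <- function(img, calibrate = TRUE, paper_width_mm = 99) {
  stopifnot(inherits(img, "plate_image"))
  hue <- hue255(img$pixels)
  if (diff(range(hue)) < 1)
    rr_abort("rr_no_paper_region", "degenerate hue channel (constant colour)")
  t <- 255 * EBImage::otsu(as_ebi(hue / 255), range = c(0, 1))
  lc <- largest_component(hue > t)
  if (is.null(lc)) rr_abort("rr_no_paper_region", "no component above Otsu threshold")
  mask <- from_ebi(EBImage::fillHull(as_ebi(lc$mask * 1))) > 0
  w <- which(mask, arr.ind = TRUE)
  bb <- px_rect(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
  sub <- img$pixels[bb$r0:bb$r1, bb$c0:bb$c1, , drop = FALSE]
  msub <- mask[bb$r0:bb$r1, bb$c0:bb$c1]
  for (ch in 1:3) sub[, , ch][!msub] <- 0
  cropped <- plate_image(sub, source_path = img$source_path, scale = img$scale)
  out <- structure(list(cropped = cropped, paper_rect = bb, mask = msub),
                   class = "crop_result")
  if (calibrate) out$cropped$scale <- calibrate_scale(out, paper_width_mm)
  out
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result %d x %d px at rows %d..%d cols %d..%d>\n",
              rect_height(x$paper_rect), rect_width(x$paper_rect),
              x$paper_rect$r0, x$paper_rect$r1, x$paper_rect$c0, x$paper_rect$c1))
  invisible(x)
}

#' Calibrate the mm-per-pixel scale from the paper width
#'
#' @param crop A `crop_result` (or a [px_rect()] of the paper region).
#' @param paper_width_mm Physical width of the germination paper (default
#'   99 mm).
#' @return Scale in mm per pixel.
#' @export
calibrate_scale <- function(crop, paper_width_mm = 99) {
  if (paper_width_mm <= 0)
    rr_abort("rr_bad_params", "paper_width_mm must be > 0")
  rect <- if (inherits(crop, "crop_result")) crop$paper_rect else crop
  w <- rect_width(rect)
  if (!is.finite(w) || w < 1)
    rr_abort("rr_bad_params", "paper rectangle has no width")
  paper_width_mm / w
}

#' File a plate into the hierarchical image database
#'
#' Writes the raw image, the cropped growth zone and the barcode sub-image
#' under `root_dir/species/population/genotype/replicate_k/`.
#'
#' @param img A [plate_image()] (raw frame).
#' @param label A [plate_label()].
#' @param crop A `crop_result` from [crop_growth_zone()].
#' @param root_dir Database root directory.
#' @param qr_rect Label rectangle; located automatically when `NULL`.
#' @param overwrite If `FALSE` (default), an existing target signals
#'   `rr_exists`.
#' @return Named character vector of the written paths (`raw`, `cropped`,
#'   `qr`).
#' @export
file_into_database <- function(img, label, crop, root_dir, qr_rect = NULL,
                               overwrite = FALSE) {
  stopifnot(inherits(img, "plate_image"), inherits(label, "plate_label"))
  if (is.null(qr_rect)) qr_rect <- locate_qr(img)
  dir <- file.path(root_dir, label$species, label$population, label$genotype,
                   sprintf("replicate_%d", label$replicate))
  paths <- c(raw = file.path(dir, "raw.png"),
             cropped = file.path(dir, "cropped.png"),
             qr = file.path(dir, "qr.png"))
  if (!overwrite && any(file.exists(paths)))
    rr_abort("rr_exists", sprintf("database entry already exists: %s", dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plate(img, paths[["raw"]])
  write_plate(crop$cropped, paths[["cropped"]])
  qr_img <- plate_image(img$pixels[qr_rect$r0:qr_rect$r1,
                                   qr_rect$c0:qr_rect$c1, , drop = FALSE])
  write_plate(qr_img, paths[["qr"]])
  paths
}

#' Ingest one plate photograph end to end
#'
#' Locate + decode the label, crop the growth zone, calibrate the scale and
#' file the images into the database.
#'
#' @param img A [plate_image()] or a path to a PNG file.
#' @param root_dir Database root directory.
#' @param variance_window,threshold_frac Passed to [locate_qr()].
#' @param paper_width_mm Passed to [calibrate_scale()].
#' @param overwrite Passed to [file_into_database()].
#' @return List with `label`, `crop`, `qr_rect`, `scale` and `paths`.
#' @export
ingest_plate <- function(img, root_dir, variance_window = 15,
                         threshold_frac = 0.8, paper_width_mm = 99,
                         overwrite = FALSE) {
  if (is.character(img)) img <- read_plate(img)
  qr_rect <- locate_qr(img, variance_window, threshold_frac)
  label <- decode_qr(img, qr_rect)
  crop <- crop_growth_zone(img, calibrate = TRUE,
                           paper_width_mm = paper_width_mm)
  paths <- file_into_database(img, label, crop, root_dir, qr_rect = qr_rect,
                              overwrite = overwrite)
  list(label = label, crop = crop, qr_rect = qr_rect,
       scale = crop$cropped$scale, paths = paths)
}
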