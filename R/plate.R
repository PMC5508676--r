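# Core value types: plate images and plate labels.

#' Plate image
#'
#' A calibrated RGB raster of one petri-dish photograph.  Pixels are stored as
#' a numeric array `[rows, cols, 3]` on a 0..255 scale.
#'
#' @param pixels Numeric array `[rows, cols, 3]`, values in 0..255.
#' @param source_path Optional origin file path.
#' @param scale Optional mm-per-pixel calibration (set by [calibrate_scale()]).
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, source_path = NA_character_, scale = NA_real_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L ||
      dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    rr_abort("rr_bad_image", "pixels must be a non-empty [rows, cols, 3] array")
  structure(list(pixels = pixels, source_path = source_path, scale = scale),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image %d x %d px, scale %s mm/px>\n", d[1], d[2],
              ifelse(is.na(x$scale), "uncalibrated", format(x$scale, digits = 4))))
  invisible(x)
}

#' Read a plate photograph from a PNG file
#'
#' @param path Path to an 8-bit PNG (RGB, RGBA or grayscale; alpha is dropped
#'   and grayscale replicated to three channels).
#' @return A [plate_image()].
#' @export
read_plate <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  plate_image(px * 255, source_path = path)
}

#' Write a plate image to PNG
#'
#' @param img A [plate_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(img, path) {
  png::writePNG(clamp(img$pixels, 0, 255) / 255, path)
  invisible(path)
}

#' Plate label
#'
#' The decoded content of the barcode on a petri-dish lid: plant species,
#' mapping population, genotype and replicate number.  The fields become
#' folder names in the image database, so path separators are rejected.
#'
#' @param species,population,genotype Non-empty strings without `/` or `\`.
#' @param replicate Integer replicate number, `>= 1`.
#' @return An object of class `plate_label`.
#' @export
plate_label <- function(species, population, genotype, replicate) {
  fields <- c(species = species, population = population, genotype = genotype)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!is.character(f) || length(f) != 1L || is.na(f) || !nzchar(f) ||
        grepl("[/\\\\|]", f))
      rr_abort("rr_label_parse_error",
               sprintf("label field '%s' must be non-empty text without / \\ |", nm))
  }
  rep_num <- suppressWarnings(as.integer(replicate))
  if (is.na(rep_num) || rep_num < 1L || rep_num != as.numeric(replicate))
    rr_abort("rr_label_parse_error", "replicate must be an integer >= 1")
  structure(list(species = species, population = population,
                 genotype = genotype, replicate = rep_num),
            class = "plate_label")
}

#' @export
print.plate_label <- function(x, ...) {
  cat(sprintf("<plate_label %s>\n", label_payload(x)))
  invisible(x)
}

#' @export
format.plate_label <- function(x, ...) label_payload(x)

#' Barcode payload grammar
#'
#' Labels are encoded as `species|population|genotype|replicate`
#' (pipe-separated, replicate a decimal integer).
#'
#' @param label A [plate_label()].
#' @return The payload string.
#' @export
label_payload <- function(label) {
  paste(label$species, label$population, label$genotype, label$replicate,
        sep = "|")
}

#' @rdname label_payload
#' @param payload A payload string.
#' @export
parse_label_payload <- function(payload) {
  parts <- strsplit(payload, "|", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    rr_abort("rr_label_parse_error",
             sprintf("payload must have 4 '|'-separated fields, got %d",
                     length(parts)))
  plate_label(parts[1], parts[2], parts[3], parts[4])
}
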