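# Shared low-level helpers: classed conditions, pixel rectangles, raster
# conversions.  All public coordinates are 1-based (row, col); rectangles are
# inclusive on both ends.

rr_abort <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "rootrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

rr_warn <- function(msg) warning(msg, call. = FALSE)

#' Pixel rectangle
#'
#' A rectangle in image coordinates: 1-based rows `r0..r1` and columns
#' `c0..c1`, inclusive on both ends.
#'
#' @param r0,r1,c0,c1 Integer bounds, `r0 <= r1`, `c0 <= c1`.
#' @return An object of class `px_rect`.
#' @export
px_rect <- function(r0, r1, c0, c1) {
  r0 <- as.integer(r0); r1 <- as.integer(r1)
  c0 <- as.integer(c0); c1 <- as.integer(c1)
  if (anyNA(c(r0, r1, c0, c1)) || r0 > r1 || c0 > c1)
    rr_abort("rr_bad_rect", "invalid rectangle bounds")
  structure(list(r0 = r0, r1 = r1, c0 = c0, c1 = c1), class = "px_rect")
}

#' @export
print.px_rect <- function(x, ...) {
  cat(sprintf("<px_rect rows %d..%d cols %d..%d>\n", x$r0, x$r1, x$c0, x$c1))
  invisible(x)
}

rect_height <- function(r) r$r1 - r$r0 + 1L
rect_width  <- function(r) r$c1 - r$c0 + 1L
rect_area   <- function(r) as.numeric(rect_height(r)) * rect_width(r)

rect_contains_point <- function(r, row, col) {
  row >= r$r0 & row <= r$r1 & col >= r$c0 & col <= r$c1
}

rect_inside <- function(inner, outer) {
  inner$r0 >= outer$r0 && inner$r1 <= outer$r1 &&
    inner$c0 >= outer$c0 && inner$c1 <= outer$c1
}

rects_overlap <- function(a, b) {
  a$r0 <= b$r1 && b$r0 <= a$r1 && a$c0 <= b$c1 && b$c0 <= a$c1
}

#' Intersection-over-union of two pixel rectangles
#'
#' @param a,b `px_rect` objects.
#' @return IoU in `[0, 1]`.
#' @export
rect_iou <- function(a, b) {
  ir <- max(0L, min(a$r1, b$r1) - max(a$r0, b$r0) + 1L)
  ic <- max(0L, min(a$c1, b$c1) - max(a$c0, b$c0) + 1L)
  inter <- as.numeric(ir) * ic
  inter / (rect_area(a) + rect_area(b) - inter)
}

# IoU between a binary mask (matrix, full-image coords) and a rectangle.
mask_rect_iou <- function(mask, rect) {
  rmask <- matrix(FALSE, nrow(mask), ncol(mask))
  rmask[rect$r0:rect$r1, rect$c0:rect$c1] <- TRUE
  sum(mask & rmask) / sum(mask | rmask)
}

# ---- raster helpers ---------------------------------------------------------

# Luma grayscale (0..255 matrix) from an RGB array in 0..255.
luma <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Hue channel mapped to 0..255 (undefined hue, i.e. gray pixels, maps to 0).
hue255 <- function(rgb) {
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r
  h[i] <- ((g - b)[i] / d[i]) %% 6
  i <- d > 0 & mx == g
  h[i] <- (b - r)[i] / d[i] + 2
  i <- d > 0 & mx == b
  h[i] <- (r - g)[i] / d[i] + 4
  h * 255 / 6
}

# Bridge between matrix[row, col] and EBImage's Image[x = col, y = row].
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

# Largest connected component of a logical matrix (8-connectivity).
# Ties broken by the lowest (row, col) of the component bounding box.
# Returns NULL when the mask is empty, else list(mask =, bbox = px_rect).
largest_component <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- from_ebi(EBImage::bwlabel(as_ebi(mask * 1)))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    key <- vapply(best, function(k) {
      w <- which(lab == k, arr.ind = TRUE)
      min(w[, 1]) * (ncol(mask) + 1) + min(w[, 2])
    }, numeric(1))
    best <- best[which.min(key)]
  }
  cmask <- lab == best
  w <- which(cmask, arr.ind = TRUE)
  list(mask = cmask,
       bbox = px_rect(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2])))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
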