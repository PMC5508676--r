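# Marker refinement.
#
# Operators place approximate seed and root-tip markers on each cropped
# image.  Positions are refined by multiplying the working grayscale with a
# sum of Gaussian kernels centred on the markers, extracting local maxima of
# the product as candidate positions, and keeping the candidate whose
# original-image intensity is brightest.  The recorded accuracy of a marker
# is the Euclidean distance between its initial and refined positions.

#' Marker set for one image
#'
#' @param image_id Identifier of the cropped image the markers belong to.
#' @param markers `data.frame` with columns `kind` (`"seed"` or `"tip"`),
#'   `row`, `col`; optionally `corrected_row`, `corrected_col`,
#'   `accuracy_px`.
#' @param sigma Gaussian kernel scale in pixels (default 5).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(image_id, markers, sigma = 5) {
  markers <- as.data.frame(markers)
  for (col in c("corrected_row", "corrected_col", "accuracy_px"))
    if (is.null(markers[[col]])) markers[[col]] <- rep(NA_real_, nrow(markers))
  if (nrow(markers) > 0) {
    bad <- !markers$kind %in% c("seed", "tip")
    if (any(bad))
      rr_abort("rr_schema_error",
               sprintf("invalid marker kind in row(s) %s",
                       paste(which(bad), collapse = ", ")))
    if (any(markers$kind == "tip") && !any(markers$kind == "seed"))
      rr_abort("rr_schema_error", "tip markers require at least one seed marker")
  }
  if (sigma <= 0) rr_abort("rr_schema_error", "sigma must be > 0")
  structure(list(image_id = image_id, markers = markers, sigma = sigma),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set '%s': %d seeds, %d tips, sigma %.3g px>\n",
              x$image_id, sum(x$markers$kind == "seed"),
              sum(x$markers$kind == "tip"), x$sigma))
  invisible(x)
}

marker_positions <- function(ms, corrected = TRUE) {
  m <- ms$markers
  r <- if (corrected) ifelse(is.na(m$corrected_row), m$row, m$corrected_row) else m$row
  c <- if (corrected) ifelse(is.na(m$corrected_col), m$col, m$corrected_col) else m$col
  cbind(row = r, col = c)
}

#' Gaussian kernel reweighting of an image around markers
#'
#' Multiplies the working grayscale `I` by a sum of isotropic 2-D Gaussians
#' (peak value 1, unnormalised -- only the argmax structure matters) centred
#' on the marker positions, producing an image that is near zero away from
#' every marker.  Linear in `I`.
#'
#' @param I Grayscale matrix (roots bright), 0..255.
#' @param markers A [marker_set()] (its `sigma` is used), or a `[n, 2]`
#'   matrix of `(row, col)` centres together with `sigma`.
#' @param sigma Kernel scale in px; defaults to the marker set's.
#' @return The reweighted matrix `J`, same shape as `I`.
#' @export
kernel_reweight <- function(I, markers, sigma = NULL) {
  if (inherits(markers, "marker_set")) {
    if (is.null(sigma)) sigma <- markers$sigma
    pos <- marker_positions(markers, corrected = FALSE)
  } else pos <- matrix(markers, ncol = 2)
  if (nrow(pos) == 0L) rr_abort("rr_schema_error", "no markers to reweight around")
  if (is.null(sigma)) sigma <- 5
  nr <- nrow(I); nc <- ncol(I)
  w <- matrix(0, nr, nc)
  rows <- seq_len(nr); cols <- seq_len(nc)
  for (i in seq_len(nrow(pos))) {
    gr <- exp(-(rows - pos[i, 1])^2 / (2 * sigma^2))
    gc <- exp(-(cols - pos[i, 2])^2 / (2 * sigma^2))
    w <- w + outer(gr, gc)
  }
  I * w
}

#' Candidate marker positions: local maxima of the reweighted image
#'
#' Scans the disc of radius `search_radius` around a marker for strict 3x3
#' local maxima of `J` whose value clears a prominence floor (a fraction of
#' the local maximum of `J` in the search window, screening out noise bumps).
#'
#' @param J Reweighted grayscale from [kernel_reweight()].
#' @param pos Marker position `c(row, col)` (or a `Marker`-like list with
#'   `$row`, `$col`).
#' @param search_radius Search radius in px (default `3 * sigma` upstream).
#' @param prominence Floor as a fraction of `max(J)` in the window
#'   (default 0.05).
#' @return `[k, 2]` matrix of candidate `(row, col)` positions (possibly
#'   zero rows).
#' @export
candidate_positions <- function(J, pos, search_radius = 15, prominence = 0.05) {
  if (is.list(pos)) pos <- c(pos$row, pos$col)
  stopifnot(search_radius >= 1)
  nr <- nrow(J); nc <- ncol(J)
  r0 <- max(1L, floor(pos[1] - search_radius))
  r1 <- min(nr, ceiling(pos[1] + search_radius))
  c0 <- max(1L, floor(pos[2] - search_radius))
  c1 <- min(nc, ceiling(pos[2] + search_radius))
  win <- J[r0:r1, c0:c1, drop = FALSE]
  floor_val <- prominence * max(win)
  out <- NULL
  for (r in r0:r1) for (c in c0:c1) {
    if ((r - pos[1])^2 + (c - pos[2])^2 > search_radius^2) next
    v <- J[r, c]
    if (v < floor_val || v <= 0) next
    nbr <- J[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    if (v >= max(nbr) && sum(nbr == v) == 1L) out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

#' Refine one marker from its candidate positions
#'
#' Selects the candidate with the brightest original-image intensity; ties
#' are broken by smallest displacement from the initial position, then by
#' `(row, col)` order.  With no candidates the marker is left unchanged
#' (accuracy 0).
#'
#' @param I Original working grayscale (roots bright).
#' @param marker One-row `data.frame` (or list) with `kind`, `row`, `col`.
#' @param candidates Matrix from [candidate_positions()].
#' @return The marker with `corrected_row`, `corrected_col` and
#'   `accuracy_px` filled in.
#' @export
correct_marker <- function(I, marker, candidates) {
  marker <- as.list(marker)
  if (nrow(candidates) == 0L) {
    marker$corrected_row <- marker$row
    marker$corrected_col <- marker$col
    marker$accuracy_px <- 0
    return(marker)
  }
  val <- I[candidates]
  disp <- sqrt((candidates[, 1] - marker$row)^2 + (candidates[, 2] - marker$col)^2)
  o <- order(-val, disp, candidates[, 1], candidates[, 2])[1]
  marker$corrected_row <- candidates[o, 1]
  marker$corrected_col <- candidates[o, 2]
  marker$accuracy_px <- disp[o]
  marker
}

#' Refine every marker in a set
#'
#' Runs the full refinement (kernel reweighting, local-maxima candidates,
#' brightest-candidate selection) for each marker of a set against the
#' working grayscale of an image.  Seed and tip markers are treated alike.
#'
#' @param I Working grayscale matrix (roots bright, 0..255), e.g.
#'   `luma(img$pixels)` of a cropped plate.
#' @param ms A [marker_set()].
#' @param search_radius Search radius in px; default `3 * sigma`.
#' @param prominence Passed to [candidate_positions()].
#' @return The marker set with corrected positions and accuracies filled in.
#' @export
correct_markers <- function(I, ms, search_radius = 3 * ms$sigma,
                            prominence = 0.05) {
  stopifnot(inherits(ms, "marker_set"))
  J <- kernel_reweight(I, ms)
  m <- ms$markers
  for (i in seq_len(nrow(m))) {
    cand <- candidate_positions(J, c(m$row[i], m$col[i]), search_radius,
                                prominence)
    res <- correct_marker(I, m[i, ], cand)
    m$corrected_row[i] <- res$corrected_row
    m$corrected_col[i] <- res$corrected_col
    m$accuracy_px[i] <- res$accuracy_px
  }
  ms$markers <- m
  ms
}

MARKER_COLS <- c("image_id", "kind", "row", "col",
                 "corrected_row", "corrected_col", "accuracy_px")

#' Read / write marker CSV files
#'
#' Schema: `image_id, kind, row, col, corrected_row, corrected_col,
#' accuracy_px` (the last three optional on input).  The round trip is
#' lossless.  Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @param sigma Kernel scale attached to the returned set.
#' @return A [marker_set()] (read) or `path` invisibly (write).
#' @export
read_markers <- function(path, sigma = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(marker_set(image_id = character(0),
                      markers = data.frame(kind = character(0), row = numeric(0),
                                           col = numeric(0)), sigma = sigma))
  missing_cols <- setdiff(c("image_id", "kind", "row", "col"), names(df))
  if (length(missing_cols))
    rr_abort("rr_schema_error",
             sprintf("marker file missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  bad_kind <- which(!df$kind %in% c("seed", "tip"))
  bad_pos <- which(!is.finite(df$row) | !is.finite(df$col) | df$row < 1 | df$col < 1)
  bad <- sort(union(bad_kind, bad_pos))
  if (length(bad))
    rr_abort("rr_schema_error",
             sprintf("malformed marker row(s) at line(s) %s of %s",
                     paste(bad + 1L, collapse = ", "), path)) # +1: header line
  marker_set(image_id = df$image_id[1],
             markers = df[setdiff(names(df), "image_id")], sigma = sigma)
}

#' @rdname read_markers
#' @param ms A [marker_set()].
#' @export
write_markers <- function(ms, path) {
  df <- ms$markers
  df$image_id <- if (nrow(df) > 0) ms$image_id else character(0)
  write.csv(df[, intersect(MARKER_COLS, names(df))], path, row.names = FALSE)
  invisible(path)
}
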