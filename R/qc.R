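# Quality control: a four-class typology of tracing errors scored against
# ground truth, histogram-style outlier flags on trait batches, and a
# segmentation + skeletonisation baseline length measurement.
#
# The error typology was originally established by human inspection of
# traced images; the tolerance-based geometric rules used here are an
# operationalisation of those descriptions, not a reimplementation of a
# published classifier.

ERROR_CLASSES <- c("ok", "shortcut", "convergence", "wrong_association",
                   "misplacement", "not_on_root", "not_on_tip")

# mark a disc of radius `tol` around each point (rounded) in an nr x nc mask
points_disc_mask <- function(points, nr, nc, tol) {
  mask <- matrix(FALSE, nr, nc)
  if (nrow(points) == 0L) return(mask)
  pr <- round(points[, 1]); pc <- round(points[, 2])
  t <- ceiling(tol)
  for (dr in -t:t) for (dc in -t:t) {
    if (dr^2 + dc^2 > tol^2) next
    rr <- pr + dr; cc <- pc + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (any(ok)) mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Convert ground-truth skeletons into traced form
#'
#' Re-expresses the generator's true polylines as `root_skeleton` objects
#' (pixels rounded, consecutive duplicates removed), e.g. to feed
#' [classify_errors()] a perfect tracing.
#'
#' @param truth A `ground_truth` from [render_plate()].
#' @return List of `root_skeleton` objects.
#' @export
truth_as_traced <- function(truth) {
  lapply(truth$skeletons, function(sk) {
    paths <- lapply(sk$paths, function(p) {
      px <- round(p)
      keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
      px <- px[keep, , drop = FALSE]
      colnames(px) <- c("row", "col")
      structure(list(seed = as.integer(round(sk$seed)),
                     tip = as.integer(px[nrow(px), ]),
                     pixels = px, total_cost = NA_real_),
                class = "root_path")
    })
    structure(list(seed = as.integer(round(sk$seed)), paths = paths),
              class = "root_skeleton")
  })
}

#' Classify tracing errors against ground truth
#'
#' Assigns each traced path one class, in priority order:
#' `wrong_association` (the traced tip's true seed differs from the seed
#' the path was assigned to); the `misadjustment` subtypes judged from the
#' traced tip position -- `not_on_root` (farther than `tol` from every true
#' polyline), `misplacement` (on a true root, but not the one its nearest
#' true tip belongs to), `not_on_tip` (on its own root but farther than
#' `tol` from the true tip); `convergence` (more than half of the path's
#' pixels lie within `tol` of another traced path of the same image);
#' `shortcut` (more than 10% of its pixels lie farther than `tol` from
#' every true polyline); else `ok`.  Classes are mutually exclusive per
#' path and counts sum to the number of paths.
#'
#' @param traced List of `root_skeleton` objects (from [trace_image()]).
#' @param truth The matching `ground_truth`.
#' @param tol Geometric tolerance in px (default 3).
#' @param convergence_frac,shortcut_frac Fraction thresholds for the
#'   convergence (default 0.5) and shortcut (default 0.1) rules.
#' @param traced_image_id Optional id of the traced image; must equal
#'   `truth$image_id` when given.
#' @return An `error_report`: `image_id`, per-path classes, class counts,
#'   `n_paths`, `any_error`.
#' @export
classify_errors <- function(traced, truth, tol = 3, convergence_frac = 0.5,
                            shortcut_frac = 0.1, traced_image_id = NULL) {
  if (!is.null(traced_image_id) && !identical(traced_image_id, truth$image_id))
    rr_abort("rr_bad_params",
             sprintf("image id mismatch: traced '%s' vs truth '%s'",
                     traced_image_id, truth$image_id))
  all_px <- do.call(rbind, c(
    lapply(traced, function(sk) do.call(rbind, lapply(sk$paths, path_pixels))),
    lapply(truth$skeletons, function(sk) do.call(rbind, sk$paths))))
  nr <- max(all_px[, 1]) + ceiling(tol) + 1L
  nc <- max(all_px[, 2]) + ceiling(tol) + 1L
  if (!is.null(truth$root_mask)) {
    nr <- max(nr, nrow(truth$root_mask)); nc <- max(nc, ncol(truth$root_mask))
  }

  # true polylines, their tips and owning seeds
  true_polys <- list(); tip_seed <- integer(0); tip_pos <- NULL
  for (s in seq_along(truth$skeletons)) {
    for (p in truth$skeletons[[s]]$paths) {
      true_polys[[length(true_polys) + 1L]] <- p
      tip_seed <- c(tip_seed, s)
      tip_pos <- rbind(tip_pos, round(p[nrow(p), ]))
    }
  }
  poly_masks <- lapply(true_polys, points_disc_mask, nr = nr, nc = nc, tol = tol)
  any_mask <- Reduce(`|`, poly_masks, matrix(FALSE, nr, nc))
  true_seeds <- do.call(rbind, lapply(truth$skeletons, function(sk) round(sk$seed)))

  # dilated coverage count over traced paths (for the convergence rule)
  cov_count <- matrix(0L, nr, nc)
  for (sk in traced) for (p in sk$paths)
    cov_count <- cov_count + points_disc_mask(path_pixels(p), nr, nc, tol)

  rows <- list()
  for (s in seq_along(traced)) {
    sk <- traced[[s]]
    assigned_true_seed <- which.min(
      (true_seeds[, 1] - sk$seed[1])^2 + (true_seeds[, 2] - sk$seed[2])^2)
    for (j in seq_along(sk$paths)) {
      px <- path_pixels(sk$paths[[j]])
      tip <- px[nrow(px), ]
      d2tips <- (tip_pos[, 1] - tip[1])^2 + (tip_pos[, 2] - tip[2])^2
      k <- which.min(d2tips)
      own_mask <- poly_masks[[k]]
      tip_idx <- cbind(clamp(round(tip[1]), 1L, nr), clamp(round(tip[2]), 1L, nc))
      pix_idx <- cbind(clamp(round(px[, 1]), 1L, nr), clamp(round(px[, 2]), 1L, nc))
      cls <- if (tip_seed[k] != assigned_true_seed) "wrong_association"
      else if (!any_mask[tip_idx]) "not_on_root"
      else if (!own_mask[tip_idx]) "misplacement"
      else if (sqrt(d2tips[k]) > tol) "not_on_tip"
      else if (mean(cov_count[pix_idx] >= 2L) > convergence_frac) "convergence"
      else if (mean(!any_mask[pix_idx]) > shortcut_frac) "shortcut"
      else "ok"
      rows[[length(rows) + 1L]] <- data.frame(seed_idx = s, path_idx = j,
                                              class = cls)
    }
  }
  paths_df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(seed_idx = integer(0), path_idx = integer(0),
                    class = character(0))
  counts <- setNames(integer(length(ERROR_CLASSES)), ERROR_CLASSES)
  tab <- table(paths_df$class)
  counts[names(tab)] <- as.integer(tab)
  structure(list(image_id = truth$image_id, paths = paths_df, counts = counts,
                 n_paths = nrow(paths_df),
                 any_error = any(paths_df$class != "ok")),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report '%s': %d path(s)>\n", x$image_id, x$n_paths))
  print(x$counts)
  invisible(x)
}

#' Fraction of images with at least one tracing error
#'
#' @param reports List of `error_report`s.
#' @return Fraction in `[0, 1]`.
#' @export
error_fraction <- function(reports) {
  mean(vapply(reports, `[[`, logical(1), "any_error"))
}

#' Flag outlier plants by robust batch statistics
#'
#' Screens a batch of per-seed records with three histogram-style rules:
#' root count, total root length, and tortuosity (path length divided by
#' the straight seed-to-tip chord; exactly 1 for a straight root, the
#' per-seed statistic being the maximum over its paths).  A value outside
#' `median +/- k * MAD` within the batch is flagged.
#'
#' @param records List of `trait_record`s.
#' @param skeletons Optional list of `root_skeleton` (or skeleton lists)
#'   aligned with `records`, needed for the tortuosity rule.
#' @param k Robust threshold multiplier (default 3.5).
#' @return A `flag_set`: data frame of flags, each naming its rule, value
#'   and threshold.  Fewer than 5 records yields an empty set with a
#'   warning.
#' @export
flag_outliers <- function(records, skeletons = NULL, k = 3.5) {
  empty <- data.frame(record_idx = integer(0), image_id = character(0),
                      seed_idx = integer(0), rule = character(0),
                      value = numeric(0), center = numeric(0),
                      threshold = numeric(0))
  if (length(records) < 5L) {
    rr_warn("fewer than 5 records: outlier statistics unreliable, no flags")
    return(structure(list(flags = empty, n_records = length(records), k = k),
                     class = "flag_set"))
  }
  tortuosity <- function(sk) {
    if (is.null(sk) || length(sk$paths) == 0L) return(NA_real_)
    max(vapply(sk$paths, function(p) {
      px <- path_pixels(p)
      chord <- sqrt(sum((px[nrow(px), ] - px[1, ])^2))
      if (chord <= 0) return(NA_real_)
      path_length(px) / chord
    }, numeric(1)), na.rm = TRUE)
  }
  stats <- data.frame(
    record_idx = seq_along(records),
    image_id = vapply(records, function(r) as.character(r$image_id), character(1)),
    seed_idx = vapply(records, function(r) as.integer(r$seed_idx), integer(1)),
    n_roots = vapply(records, function(r) as.numeric(r$n_roots), numeric(1)),
    total_length = vapply(records, function(r) as.numeric(r$total_length), numeric(1)),
    tortuosity = if (is.null(skeletons)) NA_real_
                 else vapply(skeletons, tortuosity, numeric(1)))
  flags <- empty
  for (rule in c("n_roots", "total_length", "tortuosity")) {
    x <- stats[[rule]]
    use <- is.finite(x)
    if (sum(use) < 5L) next
    med <- median(x[use]); m <- mad(x[use])
    hit <- use & abs(x - med) > k * m
    if (any(hit))
      flags <- rbind(flags, data.frame(
        record_idx = stats$record_idx[hit], image_id = stats$image_id[hit],
        seed_idx = stats$seed_idx[hit], rule = rule, value = x[hit],
        center = med, threshold = k * m))
  }
  structure(list(flags = flags, n_records = length(records), k = k),
            class = "flag_set")
}

#' @export
print.flag_set <- function(x, ...) {
  cat(sprintf("<flag_set: %d flag(s) over %d record(s), k = %.2f>\n",
              nrow(x$flags), x$n_records, x$k))
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}

#' Maximum-entropy (Kapur) intensity threshold
#'
#' Picks the threshold maximising the sum of the Shannon entropies of the
#' foreground and background intensity histograms.
#'
#' @param gray Numeric matrix, values in 0..255.
#' @return Threshold value `t`; foreground is `gray > t`.
#' @export
max_entropy_threshold <- function(gray) {
  h <- tabulate(pmin(pmax(floor(gray), 0), 255) + 1L, 256L)
  p <- h / sum(h)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Stot <- S[256]
  best <- -Inf; best_t <- 127
  for (t in 1:255) {
    P0 <- P[t]
    if (P0 <= 0 || P0 >= 1) next
    hb <- log(P0) - S[t] / P0
    hw <- log(1 - P0) - (Stot - S[t]) / (1 - P0)
    if (hb + hw > best) { best <- hb + hw; best_t <- t - 1L }
  }
  best_t
}

#' Baseline total root length by segmentation and skeletonisation
#'
#' The fully automatic benchmark measurement: red channel only; short-range
#' variation smoothed with a median then Gaussian filter of radius 0.16 mm;
#' long-range variation removed by subtracting a background obtained with a
#' median filter of diameter 2.6 mm; maximum-entropy threshold; morphological
#' thinning to a 1-px skeleton; total length as the skeleton step length
#' (axial steps 1 px, diagonal steps sqrt(2)) times the scale.
#'
#' @param img A [plate_image()] (cropped growth zone).
#' @param scale mm per pixel (filter radii are specified in mm).
#' @return Total root length in mm (0, with a warning, when nothing is
#'   segmented).
#' @export
baseline_total_length <- function(img, scale = img$scale) {
  stopifnot(inherits(img, "plate_image"))
  if (is.na(scale) || scale <= 0)
    rr_abort("rr_bad_params", "a positive mm-per-pixel scale is required")
  red <- img$pixels[, , 1]
  r_short <- max(1L, round(0.16 / scale))
  r_long <- max(2L, round(1.3 / scale)) # 2.6 mm diameter
  ebi <- as_ebi(red / 255)
  smoothed <- EBImage::gblur(EBImage::medianFilter(ebi, r_short),
                             sigma = r_short)
  bg <- EBImage::medianFilter(ebi, r_long)
  resid <- pmax(from_ebi(smoothed) - from_ebi(bg), 0) * 255
  # the paper/exterior rim leaves a bright residual ring; blank the frame
  b <- max(2L, r_long)
  nr <- nrow(resid); nc <- ncol(resid)
  resid[c(seq_len(min(b, nr)), seq(max(1L, nr - b + 1L), nr)), ] <- 0
  resid[, c(seq_len(min(b, nc)), seq(max(1L, nc - b + 1L), nc))] <- 0
  resid[resid < 1] <- 0 # below one 8-bit level: numerical residue, not signal
  if (max(resid) < 8) {
    rr_warn("no foreground after background subtraction; length 0")
    return(0)
  }
  # threshold from the positive residuals: the subtraction clips most of the
  # background to exact zero, which would dominate the entropy balance
  t <- max_entropy_threshold(resid[resid > 0])
  fg <- resid > t
  if (!any(fg)) {
    rr_warn("empty foreground after thresholding; length 0")
    return(0)
  }
  skel <- cpp_thin(fg)
  skeleton_length_px(skel) * scale
}

# total step length of a 1-px skeleton: axial adjacencies count 1, diagonal
# adjacencies sqrt(2) unless an axial pixel already bridges the pair
skeleton_length_px <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  if (nr < 2L || nc < 2L) return(0)
  n_h <- sum(S[, -nc] & S[, -1])
  n_v <- sum(S[-nr, ] & S[-1, ])
  d1 <- S[-nr, -nc] & S[-1, -1] & !(S[-1, -nc] | S[-nr, -1])   # "\" diagonal
  d2 <- S[-nr, -1] & S[-1, -nc] & !(S[-1, -1] | S[-nr, -nc])   # "/" diagonal
  (n_h + n_v) + sqrt(2) * (sum(d1) + sum(d2))
}
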