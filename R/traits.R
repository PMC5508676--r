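# Root architectural traits computed from traced skeletons.
#
# Lengths are sums of Euclidean distances between consecutive path pixels,
# converted to mm by the image scale.  Angles are measured from the downward
# image vertical (the gravity direction for upright dishes), positive
# clockwise (towards the right of the image), in (-180, 180].

path_pixels <- function(p) {
  if (inherits(p, "root_path")) p$pixels
  else if (is.matrix(p)) p
  else stop("not a path")
}

#' Length of a root path
#'
#' @param path A `root_path` or a `[k, 2]` matrix of path points.
#' @param scale mm per pixel (default 1: length in px).
#' @return Length in mm (or px when `scale = 1`).
#' @export
path_length <- function(path, scale = 1) {
  px <- path_pixels(path)
  if (nrow(px) < 2L) return(0)
  sum(sqrt(rowSums(diff(px)^2))) * scale
}

#' Point at a fraction of a path's arc length
#'
#' Walks `f` of the total arc length along the path from the seed end,
#' interpolating linearly between path points and rounding to the nearest
#' pixel.
#'
#' @param path A `root_path` or point matrix (seed first).
#' @param f Fraction in `(0, 1]`.
#' @return Pixel `c(row, col)`.
#' @export
point_at_fraction <- function(path, f) {
  stopifnot(f > 0, f <= 1)
  px <- path_pixels(path)
  seg <- if (nrow(px) < 2L) numeric(0) else sqrt(rowSums(diff(px)^2))
  total <- sum(seg)
  if (total <= 0) rr_abort("rr_bad_params", "zero-length path")
  arc <- c(0, cumsum(seg))
  target <- f * total
  i <- findInterval(target, arc, rightmost.closed = TRUE)
  i <- min(i, nrow(px) - 1L)
  t <- (target - arc[i]) / (arc[i + 1] - arc[i])
  round(px[i, ] + t * (px[i + 1, ] - px[i, ]))
}

#' Signed angle of a seed-to-point segment from the vertical
#'
#' @param seed,pt Pixels `c(row, col)`, distinct.
#' @return Angle in degrees in `(-180, 180]`: 0 straight down, positive
#'   clockwise (to the right).
#' @export
segment_angle <- function(seed, pt) {
  dr <- pt[1] - seed[1]; dc <- pt[2] - seed[2]
  if (dr == 0 && dc == 0)
    rr_abort("rr_bad_params", "coincident seed and point")
  ang <- atan2(dc, dr) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Basal and apical spread angles of a root system
#'
#' The basal spread is the difference between the angles of the outermost
#' right and left roots, measured on the segments connecting the seed to the
#' point at fraction `f` (default 10%) of each root's length.  The apical
#' spread uses the seed-to-tip segments.  Spread angles are planar (images
#' are 2-D); the assay literature calls them "solid angles" and the output
#' headers keep that name.
#'
#' @param skel A `root_skeleton` (or a list with `seed` and `paths`).
#' @param f Arc-length fraction for the basal measurement.
#' @return `c(basal = degrees, apical = degrees)`; both 0 for a single
#'   root.
#' @export
spread_angles <- function(skel, f = 0.1) {
  stopifnot(length(skel$paths) >= 1L)
  seed <- skel$seed
  basal_ang <- vapply(skel$paths, function(p)
    segment_angle(seed, point_at_fraction(p, f)), numeric(1))
  apical_ang <- vapply(skel$paths, function(p) {
    px <- path_pixels(p)
    segment_angle(seed, px[nrow(px), ])
  }, numeric(1))
  c(basal = max(basal_ang) - min(basal_ang),
    apical = max(apical_ang) - min(apical_ang))
}

new_trait_record <- function(image_id, label, seed_idx, n_roots,
                             root_lengths) {
  germinated <- n_roots >= 1L
  structure(list(
    image_id = image_id, label = label, seed_idx = seed_idx,
    germinated = germinated, n_roots = n_roots,
    root_lengths = root_lengths,
    longest_root = if (germinated) max(root_lengths) else NA_real_,
    total_length = if (germinated) sum(root_lengths) else NA_real_,
    mean_root_length = if (germinated) mean(root_lengths) else NA_real_,
    basal_angle = NA_real_, apical_angle = NA_real_,
    primary_length = NA_real_, primary_angle_seed = NA_real_,
    primary_angle_tip = NA_real_), class = "trait_record")
}

#' Per-seed trait vectors (barley and oilseed-rape conventions)
#'
#' `barley_traits()` fills the cereal convention: root count, individual and
#' total lengths, longest root, mean root length, and the basal/apical
#' spread angles.  `brassica_traits()` fills the oilseed-rape convention:
#' the primary root is the longest path; its length and its angles from the
#' vertical at the seed (segment to the 10% arc-length point) and at the tip
#' (seed-to-tip segment) are reported.  An ungerminated seed (no tips)
#' yields `germinated = FALSE` with counts 0 and unset lengths/angles.
#'
#' @param skel A `root_skeleton`.
#' @param scale mm per pixel.
#' @param image_id,label,seed_idx Provenance fields copied into the record.
#' @param angle_fraction Arc-length fraction for angles near the seed
#'   (default 0.1, i.e. 10% of each root's own length).
#' @return A `trait_record`.
#' @export
barley_traits <- function(skel, scale, image_id = NA_character_, label = NULL,
                          seed_idx = NA_integer_, angle_fraction = 0.1) {
  lens <- vapply(skel$paths, path_length, numeric(1), scale = scale)
  rec <- new_trait_record(image_id, label, seed_idx, length(skel$paths), lens)
  if (rec$germinated) {
    sp <- spread_angles(skel, angle_fraction)
    rec$basal_angle <- sp[["basal"]]
    rec$apical_angle <- sp[["apical"]]
  }
  rec
}

#' @rdname barley_traits
#' @export
brassica_traits <- function(skel, scale, image_id = NA_character_,
                            label = NULL, seed_idx = NA_integer_,
                            angle_fraction = 0.1) {
  lens <- vapply(skel$paths, path_length, numeric(1), scale = scale)
  rec <- new_trait_record(image_id, label, seed_idx, length(skel$paths), lens)
  if (rec$germinated) {
    primary <- skel$paths[[which.max(lens)]]
    px <- path_pixels(primary)
    rec$primary_length <- max(lens)
    rec$primary_angle_seed <-
      segment_angle(skel$seed, point_at_fraction(primary, angle_fraction))
    rec$primary_angle_tip <- segment_angle(skel$seed, px[nrow(px), ])
  }
  rec
}

TRAIT_NUMERIC <- c("n_roots", "total_length", "mean_root_length",
                   "longest_root", "basal_angle", "apical_angle",
                   "primary_length", "primary_angle_seed", "primary_angle_tip")

#' Flatten trait records to a data frame
#'
#' One row per seed; `root_lengths` collapsed to a `;`-separated string.
#' Spread angles keep the assay's "solid angle" headers.
#'
#' @param records List of `trait_record`s.
#' @return `data.frame`.
#' @export
trait_table <- function(records) {
  rows <- lapply(records, function(r) {
    lab <- r$label
    data.frame(
      image_id = r$image_id,
      species = if (is.null(lab)) NA_character_ else lab$species,
      population = if (is.null(lab)) NA_character_ else lab$population,
      genotype = if (is.null(lab)) NA_character_ else lab$genotype,
      replicate = if (is.null(lab)) NA_integer_ else lab$replicate,
      seed_idx = r$seed_idx, germinated = r$germinated, n_roots = r$n_roots,
      root_lengths_mm = paste(signif(r$root_lengths, 8), collapse = ";"),
      total_length_mm = r$total_length, mean_root_length_mm = r$mean_root_length,
      longest_root_mm = r$longest_root,
      basal_solid_angle_deg = r$basal_angle,
      apical_solid_angle_deg = r$apical_angle,
      primary_length_mm = r$primary_length,
      primary_angle_seed_deg = r$primary_angle_seed,
      primary_angle_tip_deg = r$primary_angle_tip)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-genotype mean and standard error of each trait
#'
#' All records must share one genotype.  For each trait the mean and the
#' standard error of the mean (sample SD / sqrt(n)) are computed over
#' germinated seeds; `n` is reported per trait.  Germination itself is
#' summarised as the count of germinated seeds over all records.
#'
#' @param records List of `trait_record`s sharing a genotype.
#' @return Long `data.frame`: `genotype, trait, mean, se, n`.
#' @export
summarise_genotype <- function(records) {
  stopifnot(length(records) >= 1L)
  geno <- unique(vapply(records, function(r)
    if (is.null(r$label)) NA_character_ else r$label$genotype, character(1)))
  if (length(geno) != 1L)
    rr_abort("rr_bad_params", "records must share a single genotype")
  germ <- vapply(records, `[[`, logical(1), "germinated")
  rows <- lapply(TRAIT_NUMERIC, function(tr) {
    vals <- vapply(records, function(r) as.numeric(r[[tr]]), numeric(1))
    vals <- vals[germ & is.finite(vals)]
    n <- length(vals)
    if (n == 0L) return(NULL)
    se <- if (n >= 2L) sd(vals) / sqrt(n) else {
      rr_warn(sprintf("genotype %s, trait %s: n = 1, SE unset", geno, tr))
      NA_real_
    }
    data.frame(genotype = geno, trait = tr, mean = mean(vals), se = se, n = n)
  })
  germ_row <- data.frame(genotype = geno, trait = "n_germinated",
                         mean = sum(germ), se = NA_real_, n = length(records))
  do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))], list(germ_row),
                   list(make.row.names = FALSE)))
}

#' Summarise every genotype in a batch of trait records
#'
#' @param records List of `trait_record`s (any mix of genotypes).
#' @return Long `data.frame` as in [summarise_genotype()], all genotypes
#'   stacked.
#' @export
summarise_genotypes <- function(records) {
  genos <- vapply(records, function(r)
    if (is.null(r$label)) NA_character_ else r$label$genotype, character(1))
  out <- lapply(split(records, genos), summarise_genotype)
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}
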