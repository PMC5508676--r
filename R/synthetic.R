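# Synthetic plate-image generator.
#
# Emulates the imaging setup the pipeline consumes: a bright, low-hue-contrast
# germination-paper region on a darker background, a decodable 2-D barcode
# label, 1-3 seeds each bearing 1-7 curvilinear roots of known polyline
# geometry, with controllable contrast, noise, curvature and crossings.
# Every plate comes with exact ground truth (label, rects, markers, true
# skeletons and lengths) so downstream stages can be scored without real data.

# A warm, low-brightness bench background: its hue (~25/255) sits far from
# the paper's blue (~157/255), and its chroma is large enough that additive
# channel noise cannot flip it across the hue threshold.
BACKGROUND_RGB <- c(80, 55, 30)
PAPER_RGB <- c(60, 90, 160) # blue germination paper, hue ~157/255

#' Scene specification for a synthetic plate
#'
#' Describes one plate to be rendered by [render_plate()].  Defaults mirror
#' the physical assay: a 99 mm x 99 mm paper square, three seeds per dish,
#' and a barcode label beside the paper.
#'
#' @param image_size `c(rows, cols)` of the full frame.
#' @param paper_rect [px_rect()] of the simulated germination paper.
#' @param qr_rect [px_rect()] reserved for the barcode label; must not
#'   overlap `paper_rect`.
#' @param label A [plate_label()].
#' @param seeds Integer matrix `[n, 2]` of seed `(row, col)` positions (1-3
#'   seeds), all inside `paper_rect`; `NULL` places them evenly near the top
#'   of the paper.
#' @param n_seeds Number of auto-placed seeds when `seeds` is `NULL`.
#' @param roots_per_seed Roots per seed, 1-7.
#' @param curvature Dimensionless bend amplitude `>= 0` (0 = straight roots).
#' @param crossing_prob Probability in `[0, 1]` that a seed's roots are made
#'   to cross each other.
#' @param contrast Root-vs-paper intensity gap in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD in `[0, 1]` intensity units
#'   (multiplied by 255 on the 8-bit scale).
#' @param root_width Rendered root width in px (2-4).
#' @param roots Optional explicit root geometry: a list with one element per
#'   seed, each a list of polylines (`[k, 2]` matrices of `(row, col)`
#'   vertices starting at the seed).  Overrides random generation.
#' @param rng_seed Integer seed making the render deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(480L, 640L),
                       paper_rect = px_rect(41, 440, 41, 440),
                       qr_rect = px_rect(121, 300, 466, 625),
                       label = plate_label("barley", "POP1", "G001", 1),
                       seeds = NULL, n_seeds = 3L, roots_per_seed = 3L,
                       curvature = 0.15, crossing_prob = 0, contrast = 0.6,
                       noise_sd = 0.05, root_width = 3, roots = NULL,
                       rng_seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 32L))
  frame <- px_rect(1, image_size[1], 1, image_size[2])
  if (!rect_inside(paper_rect, frame) || !rect_inside(qr_rect, frame))
    rr_abort("rr_bad_scene", "paper_rect and qr_rect must lie inside the image")
  if (rects_overlap(paper_rect, qr_rect))
    rr_abort("rr_bad_scene", "paper_rect and qr_rect must not overlap")
  if (is.null(seeds)) {
    n_seeds <- as.integer(n_seeds)
    if (n_seeds < 1L || n_seeds > 3L)
      rr_abort("rr_bad_scene", "n_seeds must be 1-3")
    row <- round(paper_rect$r0 + 0.12 * rect_height(paper_rect))
    cols <- round(paper_rect$c0 +
                    seq_len(n_seeds) / (n_seeds + 1) * rect_width(paper_rect))
    seeds <- cbind(rep(row, n_seeds), cols)
  }
  seeds <- matrix(as.integer(round(seeds)), ncol = 2)
  seeds <- seeds[order(seeds[, 2], seeds[, 1]), , drop = FALSE] # left to right
  if (nrow(seeds) < 1L || nrow(seeds) > 3L)
    rr_abort("rr_bad_scene", "1-3 seeds required")
  if (!all(rect_contains_point(paper_rect, seeds[, 1], seeds[, 2])))
    rr_abort("rr_bad_scene", "every seed must lie inside paper_rect")
  roots_per_seed <- as.integer(roots_per_seed)
  if (roots_per_seed < 1L || roots_per_seed > 7L)
    rr_abort("rr_bad_scene", "roots_per_seed must be 1-7")
  stopifnot(curvature >= 0, crossing_prob >= 0, crossing_prob <= 1,
            contrast >= 0, contrast <= 1, noise_sd >= 0,
            root_width >= 2, root_width <= 4)
  structure(list(image_size = image_size, paper_rect = paper_rect,
                 qr_rect = qr_rect, label = label, seeds = seeds,
                 roots_per_seed = roots_per_seed, curvature = curvature,
                 crossing_prob = crossing_prob, contrast = contrast,
                 noise_sd = noise_sd, root_width = root_width, roots = roots,
                 scale = 99 / rect_width(paper_rect),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# quadratic Bezier resampled to ~1 px arc-length steps; [k, 2] float matrix
bezier_polyline <- function(p0, p1, p2) {
  chord <- sqrt(sum((p2 - p0)^2))
  t <- seq(0, 1, length.out = max(24L, ceiling(4 * chord)))
  pts <- cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
               (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- unique(c(seq(0, total, by = 1), total))
  cbind(approx(arc, pts[, 1], xout = s)$y, approx(arc, pts[, 2], xout = s)$y)
}

polyline_length <- function(p) if (nrow(p) < 2L) 0 else sum(sqrt(rowSums(diff(p)^2)))

# round a ~1 px-step float polyline to an 8-connected integer pixel chain.
# Axial L-corners (two unit axial steps whose net move is diagonal) are
# collapsed into single diagonal steps, so the chain length sits on the same
# octile metric as a minimal 8-connected pixel path traced on the raster.
as_pixel_chain <- function(p) {
  px <- matrix(as.integer(round(p)), ncol = 2)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  # repair rare rounding jumps of 2 by inserting an intermediate pixel
  steps <- if (nrow(px) < 2L) NULL else abs(diff(px))
  if (!is.null(steps) && any(steps > 1L)) {
    out <- list(px[1, ])
    for (i in 2:nrow(px)) {
      if (max(abs(px[i, ] - px[i - 1, ])) > 1L)
        out[[length(out) + 1L]] <- round((px[i, ] + px[i - 1, ]) / 2)
      out[[length(out) + 1L]] <- px[i, ]
    }
    px <- do.call(rbind, out)
  }
  for (pass in 1:5) {
    n <- nrow(px)
    if (n < 3L) break
    drop <- logical(n)
    i <- 2L
    while (i < n) {
      d1 <- px[i, ] - px[i - 1L, ]
      d2 <- px[i + 1L, ] - px[i, ]
      if (sum(abs(d1)) == 1L && sum(abs(d2)) == 1L &&
          all(abs(px[i + 1L, ] - px[i - 1L, ]) == 1L)) {
        drop[i] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
    if (!any(drop)) break
    px <- px[!drop, , drop = FALSE]
  }
  px
}

polyline_inside <- function(p, rect, margin) {
  all(p[, 1] >= rect$r0 + margin & p[, 1] <= rect$r1 - margin &
      p[, 2] >= rect$c0 + margin & p[, 2] <= rect$c1 - margin)
}

# one random root from `seed_pos` at `angle_deg` from the downward vertical
gen_root_geometry <- function(seed_pos, angle_deg, paper, curvature, margin = 3) {
  a <- angle_deg * pi / 180
  dirv <- c(cos(a), sin(a)) # (d_row, d_col), row grows downward
  lim <- function(d, lo, hi, x) {
    if (abs(d) < 1e-12) return(Inf)
    t <- if (d > 0) (hi - x) / d else (lo - x) / d
    max(t, 0)
  }
  max_l <- min(lim(dirv[1], paper$r0 + margin, paper$r1 - margin, seed_pos[1]),
               lim(dirv[2], paper$c0 + margin, paper$c1 - margin, seed_pos[2]))
  len <- runif(1, 0.5, 0.85) * max_l
  len <- max(len, min(25, max_l))
  p2 <- seed_pos + len * dirv
  perp <- c(-dirv[2], dirv[1])
  off <- curvature * len * runif(1, 0.6, 1) * sample(c(-1, 1), 1)
  for (k in 1:9) {
    p1 <- seed_pos + 0.5 * len * dirv + off * perp
    poly <- bezier_polyline(seed_pos, p1, p2)
    if (polyline_inside(poly, paper, margin - 1)) return(list(p1 = p1, p2 = p2, poly = poly))
    off <- off * 0.6
    if (k == 9) off <- 0
  }
  list(p1 = seed_pos + 0.5 * len * dirv, p2 = p2,
       poly = bezier_polyline(seed_pos, seed_pos + 0.5 * len * dirv, p2))
}

# truncate `poly` just before it first comes within `minsep` of an accepted
# sibling root; NULL when too little would remain
trim_to_separation <- function(poly, geoms, minsep, skip = 15L, min_keep = 25L) {
  if (!length(geoms)) return(poly)
  b <- do.call(rbind, lapply(geoms, function(g)
    g$poly[-seq_len(min(skip, nrow(g$poly) - 1L)), , drop = FALSE]))
  b <- b[seq(1, nrow(b), by = 2), , drop = FALSE]
  for (i in seq(skip + 1L, nrow(poly))) {
    d2 <- min((b[, 1] - poly[i, 1])^2 + (b[, 2] - poly[i, 2])^2)
    if (d2 < minsep^2) {
      keep <- i - 6L
      if (keep < min_keep) return(NULL)
      return(poly[seq_len(keep), , drop = FALSE])
    }
  }
  poly
}

# TRUE when `poly` comes within `minsep` px of an already accepted root of
# the same seed (ignoring the shared stretch near the seed)
roots_too_close <- function(poly, geoms, minsep, skip = 15L) {
  if (!length(geoms)) return(FALSE)
  a <- poly[-seq_len(min(skip, nrow(poly) - 1L)), , drop = FALSE]
  a <- a[seq(1, nrow(a), by = 2), , drop = FALSE]
  for (g in geoms) {
    b <- g$poly[-seq_len(min(skip, nrow(g$poly) - 1L)), , drop = FALSE]
    b <- b[seq(1, nrow(b), by = 2), , drop = FALSE]
    d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
    if (min(d2) < minsep^2) return(TRUE)
  }
  FALSE
}

# stamp an anti-aliased polyline of width `w` onto min-distance field `dmin`
stamp_polyline <- function(dmin, poly, w) {
  nr <- nrow(dmin); nc <- ncol(dmin)
  rad <- ceiling(w / 2) + 1L
  pr <- poly[, 1]; pc <- poly[, 2]
  for (dr in -rad:rad) for (dc in -rad:rad) {
    rr <- round(pr) + dr; cc <- round(pc) + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) next
    d <- sqrt((rr[ok] - pr[ok])^2 + (cc[ok] - pc[ok])^2)
    idx <- cbind(rr[ok], cc[ok])
    cur <- dmin[idx]
    newv <- pmin(cur, d)
    o <- order(newv, decreasing = TRUE) # smallest written last wins on ties
    dmin[idx[o, , drop = FALSE]] <- newv[o]
  }
  dmin
}

#' Render a synthetic plate with exact ground truth
#'
#' Draws the paper region, the roots (as quadratic Bezier chains sampled at
#' ~1 px arc-length steps, rendered brighter than the paper by `contrast`),
#' the barcode label, and additive noise.  Bit-identical output for the same
#' `rng_seed`.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (a [plate_image()]) and `truth`, the ground
#'   truth: `label`, `paper_rect`, `qr_rect` (bounding box of the rendered symbol), `label_rect` (the white label reservation), `scale`,
#'   `markers` (exact seed/tip [marker_set()]), `skeletons` (per seed: true
#'   polylines and lengths in px and mm) and `root_mask` (logical raster of
#'   rendered root pixels).
#' @export
render_plate <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$rng_seed, render_plate_impl(spec))
}

render_plate_impl <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  paper <- spec$paper_rect
  rgb <- array(rep(BACKGROUND_RGB, each = nr * nc), c(nr, nc, 3))
  for (ch in 1:3)
    rgb[paper$r0:paper$r1, paper$c0:paper$c1, ch] <- PAPER_RGB[ch]

  # --- root geometry ---------------------------------------------------------
  n_seeds <- nrow(spec$seeds)
  skeletons <- vector("list", n_seeds)
  if (!is.null(spec$roots)) {
    if (length(spec$roots) != n_seeds)
      rr_abort("rr_bad_scene", "roots must have one element per seed")
    for (s in seq_len(n_seeds)) {
      polys <- lapply(spec$roots[[s]], function(p) matrix(as.numeric(p), ncol = 2))
      for (p in polys)
        if (!polyline_inside(p, paper, 0))
          rr_abort("rr_roots_outside_paper", "root polyline leaves paper_rect")
      skeletons[[s]] <- list(seed = spec$seeds[s, ], paths = polys)
    }
  } else {
    # each seed's roots are confined to its own lateral band (midway to the
    # neighbouring seeds), so roots of different seeds never meet; crossings
    # are produced only on request, within a seed
    cuts <- if (n_seeds > 1L)
      round((spec$seeds[-n_seeds, 2] + spec$seeds[-1, 2]) / 2) else integer(0)
    lo <- c(paper$c0, cuts + 3L)
    hi <- c(cuts - 3L, paper$c1)
    if (any(hi - lo < 12L))
      rr_abort("rr_bad_scene", "seeds too close together to lay out roots")
    geoms_by_seed <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      band <- px_rect(paper$r0, paper$r1, lo[s], hi[s])
      m <- spec$roots_per_seed
      base <- if (m == 1) runif(1, -15, 15) else seq(-40, 40, length.out = m)
      angles <- base + runif(m, -5, 5)
      geoms <- list()
      minsep <- spec$root_width + 2
      for (j in seq_len(m)) {
        g <- gen_root_geometry(spec$seeds[s, ], angles[j], band, spec$curvature)
        for (try in 1:4) {
          if (!roots_too_close(g$poly, geoms, minsep)) break
          g <- gen_root_geometry(spec$seeds[s, ], angles[j], band,
                                 spec$curvature * 0.5^try)
        }
        if (roots_too_close(g$poly, geoms, minsep)) {
          trimmed <- trim_to_separation(g$poly, geoms, minsep)
          if (is.null(trimmed)) next # unplaceable without touching a sibling
          g$poly <- trimmed
          g$p2 <- trimmed[nrow(trimmed), ]
        }
        geoms[[length(geoms) + 1L]] <- g
      }
      m <- length(geoms)
      if (m >= 2 && runif(1) < spec$crossing_prob) {
        i <- if (m == 2) 1L else sample(m - 1L, 1L)
        # swap endpoints of an adjacent pair: the two curves then cross
        e1 <- geoms[[i]]$p2; e2 <- geoms[[i + 1]]$p2
        geoms[[i]]$p2 <- e2; geoms[[i + 1]]$p2 <- e1
        geoms[[i]]$poly <- bezier_polyline(spec$seeds[s, ], geoms[[i]]$p1, e2)
        geoms[[i + 1]]$poly <- bezier_polyline(spec$seeds[s, ], geoms[[i + 1]]$p1, e1)
      }
      skeletons[[s]] <- list(seed = spec$seeds[s, ],
                             paths = lapply(geoms, `[[`, "poly"))
      geoms_by_seed[[s]] <- geoms
    }
    # inter-seed crossings: swap the endpoints of the facing roots of an
    # adjacent seed pair, so each curve ends in the neighbour's territory
    for (s in seq_len(max(0L, n_seeds - 1L))) {
      if (runif(1) >= spec$crossing_prob) next
      ga <- geoms_by_seed[[s]]; gb <- geoms_by_seed[[s + 1L]]
      ia <- length(ga); ib <- 1L # rightmost of s, leftmost of s+1
      ea <- ga[[ia]]$p2; eb <- gb[[ib]]$p2
      pa <- bezier_polyline(spec$seeds[s, ], ga[[ia]]$p1, eb)
      pb <- bezier_polyline(spec$seeds[s + 1L, ], gb[[ib]]$p1, ea)
      if (polyline_inside(pa, paper, 2) && polyline_inside(pb, paper, 2)) {
        skeletons[[s]]$paths[[ia]] <- pa
        skeletons[[s + 1L]]$paths[[ib]] <- pb
        geoms_by_seed[[s]][[ia]]$p2 <- eb
        geoms_by_seed[[s + 1L]][[ib]]$p2 <- ea
      }
    }
  }

  # distinct tip pixels: trim a path end while its rounded tip collides
  all_tips <- function() {
    do.call(rbind, lapply(skeletons, function(sk)
      do.call(rbind, lapply(sk$paths, function(p) round(p[nrow(p), ])))))
  }
  for (pass in 1:5) {
    tips <- all_tips()
    dup <- duplicated(tips)
    if (!any(dup)) break
    k <- 0L
    for (s in seq_along(skeletons)) for (j in seq_along(skeletons[[s]]$paths)) {
      k <- k + 1L
      if (dup[k]) {
        p <- skeletons[[s]]$paths[[j]]
        if (nrow(p) > 8L) skeletons[[s]]$paths[[j]] <- p[1:(nrow(p) - 3L), ]
      }
    }
  }

  # Rendering uses the smooth float polylines; the recorded ground truth is
  # the rounded 1-px pixel chain, so true lengths live on the same discrete
  # metric as traced pixel paths.
  float_paths <- lapply(skeletons, `[[`, "paths")
  for (s in seq_along(skeletons)) {
    skeletons[[s]]$paths <- lapply(skeletons[[s]]$paths, as_pixel_chain)
    lp <- vapply(skeletons[[s]]$paths, polyline_length, numeric(1))
    skeletons[[s]]$lengths_px <- lp
    skeletons[[s]]$lengths_mm <- lp * spec$scale
  }

  # --- raster ----------------------------------------------------------------
  dmin <- matrix(Inf, nr, nc)
  for (fp in float_paths) for (p in fp)
    dmin <- stamp_polyline(dmin, p, spec$root_width)
  cov <- clamp(spec$root_width / 2 + 0.5 - dmin, 0, 1)
  for (ch in 1:3)
    rgb[, , ch] <- rgb[, , ch] + cov * spec$contrast * (255 - rgb[, , ch])

  code <- render_code_into(rgb, spec$qr_rect, label_payload(spec$label))
  rgb <- code$rgb

  if (spec$noise_sd > 0)
    rgb <- clamp(rgb + array(rnorm(length(rgb), 0, spec$noise_sd * 255), dim(rgb)),
                 0, 255)

  # --- ground truth ----------------------------------------------------------
  image_id <- gsub("[^A-Za-z0-9_.-]", "_", label_payload(spec$label))
  mk <- do.call(rbind, c(
    lapply(seq_len(n_seeds), function(s)
      data.frame(kind = "seed", row = spec$seeds[s, 1], col = spec$seeds[s, 2])),
    lapply(skeletons, function(sk)
      do.call(rbind, lapply(sk$paths, function(p) {
        tp <- round(p[nrow(p), ])
        data.frame(kind = "tip", row = tp[1], col = tp[2])
      })))
  ))
  truth <- structure(
    list(label = spec$label, image_id = image_id, paper_rect = paper,
         qr_rect = code$symbol_rect, label_rect = spec$qr_rect,
         scale = spec$scale, markers = marker_set(image_id, mk),
         skeletons = skeletons, root_mask = cov >= 0.5),
    class = "ground_truth")
  list(image = plate_image(rgb, scale = spec$scale), truth = truth)
}

#' Write / read plate ground truth as JSON
#'
#' Serialises everything except the `root_mask` raster (which is
#' reconstructible by re-rendering the scene).
#'
#' @param truth A `ground_truth` object from [render_plate()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  rect_l <- function(r) list(r0 = r$r0, r1 = r$r1, c0 = r$c0, c1 = r$c1)
  out <- list(
    label = unclass(truth$label), image_id = truth$image_id,
    paper_rect = rect_l(truth$paper_rect), qr_rect = rect_l(truth$qr_rect),
    label_rect = rect_l(truth$label_rect), scale = truth$scale,
    markers = truth$markers$markers[, c("kind", "row", "col")],
    skeletons = lapply(truth$skeletons, function(sk)
      list(seed = as.integer(sk$seed),
           paths = lapply(sk$paths, function(p) unname(p)),
           lengths_px = sk$lengths_px, lengths_mm = sk$lengths_mm))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rect_o <- function(l) px_rect(l$r0, l$r1, l$c0, l$c1)
  lab <- plate_label(x$label$species, x$label$population, x$label$genotype,
                     x$label$replicate)
  skels <- lapply(seq_len(if (is.data.frame(x$skeletons)) nrow(x$skeletons)
                          else length(x$skeletons)), function(i) {
    sk <- if (is.data.frame(x$skeletons)) lapply(x$skeletons, `[[`, i)
          else x$skeletons[[i]]
    paths <- lapply(sk$paths, function(p)
      if (is.matrix(p)) p else matrix(unlist(p), ncol = 2, byrow = TRUE))
    list(seed = as.integer(unlist(sk$seed)), paths = paths,
         lengths_px = as.numeric(unlist(sk$lengths_px)),
         lengths_mm = as.numeric(unlist(sk$lengths_mm)))
  })
  structure(list(label = lab, image_id = x$image_id,
                 paper_rect = rect_o(x$paper_rect), qr_rect = rect_o(x$qr_rect),
                 label_rect = rect_o(x$label_rect), scale = x$scale,
                 markers = marker_set(x$image_id, as.data.frame(x$markers)),
                 skeletons = skels, root_mask = NULL),
            class = "ground_truth")
}

#' Render a batch of scenes to disk
#'
#' Renders each scene to a PNG plus a ground-truth JSON.  A failing scene is
#' recorded in the manifest and does not abort the batch.
#'
#' @param specs List of [scene_spec()] objects.
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame` (also written to `manifest.csv` in
#'   `out_dir`): scene index, file paths, label fields, status and message.
#' @export
render_batch <- function(specs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(specs), function(i) {
    img_path <- file.path(out_dir, sprintf("scene_%03d.png", i))
    json_path <- file.path(out_dir, sprintf("scene_%03d.json", i))
    lab <- specs[[i]]$label
    res <- tryCatch({
      r <- render_plate(specs[[i]])
      write_plate(r$image, img_path)
      write_ground_truth(r$truth, json_path)
      list(status = "ok", message = "")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    data.frame(scene = i,
               image_path = if (res$status == "ok") img_path else NA_character_,
               truth_path = if (res$status == "ok") json_path else NA_character_,
               species = lab$species, population = lab$population,
               genotype = lab$genotype, replicate = lab$replicate,
               status = res$status, message = res$message)
  })
  manifest <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(scene = integer(), image_path = character(),
               truth_path = character(), species = character(),
               population = character(), genotype = character(),
               replicate = integer(), status = character(),
               message = character())
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Sample a suite of random scene specifications
#'
#' Convenience generator for test/benchmark suites: random labels (genotypes
#' in replicate groups of 5), random seed counts and root counts, shared
#' rendering conditions.
#'
#' @param n Number of scenes.
#' @param rng_seed Master seed; each scene gets a derived deterministic seed.
#' @param seeds_range,roots_range Inclusive ranges to sample the number of
#'   seeds (1-3) and roots per seed (1-7) from.
#' @param species,population Label fields shared by the suite.
#' @inheritParams scene_spec
#' @return List of [scene_spec()] objects.
#' @export
sample_scene_specs <- function(n, rng_seed = 1L, noise_sd = 0.05,
                               crossing_prob = 0, curvature = 0.15,
                               contrast = 0.6, seeds_range = c(1L, 3L),
                               roots_range = c(1L, 5L), species = "barley",
                               population = "POP1") {
  withr::with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      scene_spec(
        label = plate_label(species, population,
                            sprintf("G%03d", (i - 1L) %/% 5L + 1L),
                            (i - 1L) %% 5L + 1L),
        n_seeds = sample(seeds_range[1]:seeds_range[2], 1L),
        roots_per_seed = sample(roots_range[1]:roots_range[2], 1L),
        curvature = curvature, crossing_prob = crossing_prob,
        contrast = contrast, noise_sd = noise_sd,
        rng_seed = (rng_seed %% 100000L) * 10000L + i)
    })
  })
}
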