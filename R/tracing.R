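# Root tracing.
#
# Each root is recovered as the minimal-cost path between its tip marker and
# a seed marker on a cost map built by Dijkstra front propagation.  The cost
# of entering a pixel is a piece-wise linear function of its cost-intensity:
# cheap (slope a) below a threshold B, steeply penalised (slope A) above it.
#
# Polarity convention: the package keeps ONE working grayscale in which roots
# are BRIGHT (used for marker refinement, where the brightest candidate
# wins); tracing converts it to a cost-intensity raster I = 255 - R so that
# roots have LOW cost-intensity and the piece-wise linear cost applies with
# roots cheap.  Both conventions are thereby honoured simultaneously.

#' Cost-function parameters
#'
#' The per-pixel travel cost is `a * I` for cost-intensity `I <= B` and
#' `A * (I - B) + a * B` for `I > B` (continuous at `B`, strictly
#' increasing).  The slopes are not canonical values; they were chosen to
#' keep on-root travel cheap and off-root travel strongly penalised, and are
#' fully configurable.
#'
#' @param a Shallow slope (cost per intensity unit), `0 < a < A`.
#' @param A Steep slope above the threshold.
#' @param B Intensity threshold in 0..255; `NA` means "auto": derived from
#'   the Otsu threshold of the working raster by [trace_image()].
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(a = 1, A = 10, B = NA_real_) {
  if (!is.na(B) && (B < 0 || B > 255))
    rr_abort("rr_bad_params", "B must lie in [0, 255]")
  if (!(a > 0 && A > a))
    rr_abort("rr_bad_params", "need 0 < a < A")
  structure(list(a = a, A = A, B = B), class = "cost_params")
}

#' Piece-wise linear cost of a pixel intensity
#'
#' @param I Cost-intensity value(s) in 0..255 (roots low).
#' @param p A [cost_params()] with a concrete `B`.
#' @return Non-negative cost, vectorised over `I`.
#' @export
cost_of_intensity <- function(I, p) {
  if (is.na(p$B)) rr_abort("rr_bad_params", "B is unset; resolve 'auto' first")
  ifelse(I <= p$B, p$a * I, p$A * (I - p$B) + p$a * p$B)
}

#' Build the Dijkstra cost map from one seed
#'
#' Propagates a front outward from the seed over the entire raster.  The
#' accumulated cost of a pixel is the minimum over all 8-connected paths
#' from the seed of the sum of step costs, a step into pixel `q` costing
#' `cost_of_intensity(raster[q], p) * step_length` (1 axial, sqrt(2)
#' diagonal).
#'
#' @param raster Cost-intensity matrix (0..255, roots low).
#' @param seed Seed pixel `c(row, col)`.
#' @param p A [cost_params()] with concrete `B`.
#' @param connectivity 8 (default) or 4.
#' @param min_step_cost Floor on the per-pixel step cost (default `1e-8`).
#'   Saturated pixels have cost-intensity 0; a strictly positive floor keeps
#'   the accumulated cost strictly increasing along every path so the
#'   gradient-descent backtrace cannot stall on a zero-cost plateau.  The
#'   floor is orders of magnitude below any real intensity cost.
#' @return An object of class `cost_map`: `seed`, `cost` matrix, `reached`
#'   logical matrix.
#' @export
build_cost_map <- function(raster, seed, p, connectivity = 8,
                           min_step_cost = 1e-8) {
  seed <- as.integer(round(seed))
  if (seed[1] < 1 || seed[1] > nrow(raster) || seed[2] < 1 || seed[2] > ncol(raster))
    rr_abort("rr_bad_params", "seed outside raster")
  stopifnot(connectivity %in% c(4, 8))
  node_cost <- matrix(pmax(cost_of_intensity(raster, p), min_step_cost),
                      nrow(raster), ncol(raster))
  cost <- cpp_dijkstra(node_cost, seed[1], seed[2], connectivity == 8)
  structure(list(seed = seed, cost = cost, reached = is.finite(cost)),
            class = "cost_map")
}

#' @export
print.cost_map <- function(x, ...) {
  cat(sprintf("<cost_map %d x %d from seed (%d, %d); %.1f%% reached>\n",
              nrow(x$cost), ncol(x$cost), x$seed[1], x$seed[2],
              100 * mean(x$reached)))
  invisible(x)
}

#' Backtrace a tip to the seed by cost-gradient descent
#'
#' From the tip, repeatedly steps to the neighbour of strictly smallest cost
#' until the seed (cost 0) is reached.  Ties are broken by preferring the
#' neighbour nearest (Euclidean) to the seed, then by `(row, col)` order.
#' On a valid Dijkstra map every non-seed pixel has a strictly cheaper
#' neighbour, so the descent cannot stall (asserted).
#'
#' @param cm A [build_cost_map()] result.
#' @param tip Tip pixel `c(row, col)`.
#' @return A `root_path`: `seed`, `tip`, `pixels` (ordered `[k, 2]` matrix
#'   from seed to tip, consecutive pixels 8-adjacent), `total_cost`.
#' @export
backtrace <- function(cm, tip) {
  tip <- as.integer(round(tip))
  nr <- nrow(cm$cost); nc <- ncol(cm$cost)
  if (tip[1] < 1 || tip[1] > nr || tip[2] < 1 || tip[2] > nc ||
      !cm$reached[tip[1], tip[2]])
    rr_abort("rr_unreachable_tip", "tip not reached in the cost map")
  cur <- tip
  rev_path <- list(cur)
  maxlen <- nr * nc + 1L
  while (!(cur[1] == cm$seed[1] && cur[2] == cm$seed[2])) {
    rs <- max(1L, cur[1] - 1L):min(nr, cur[1] + 1L)
    cs <- max(1L, cur[2] - 1L):min(nc, cur[2] + 1L)
    nbr <- as.matrix(expand.grid(r = rs, c = cs))
    nbr <- nbr[!(nbr[, 1] == cur[1] & nbr[, 2] == cur[2]), , drop = FALSE]
    v <- cm$cost[nbr]
    here <- cm$cost[cur[1], cur[2]]
    lower <- v < here
    if (!any(lower))
      stop("internal error: cost-gradient descent stalled off-seed")
    nbr <- nbr[lower, , drop = FALSE]; v <- v[lower]
    dseed <- sqrt((nbr[, 1] - cm$seed[1])^2 + (nbr[, 2] - cm$seed[2])^2)
    o <- order(v, dseed, nbr[, 1], nbr[, 2])[1]
    cur <- c(nbr[o, 1], nbr[o, 2])
    rev_path[[length(rev_path) + 1L]] <- cur
    if (length(rev_path) > maxlen)
      stop("internal error: backtrace exceeded raster size")
  }
  pixels <- do.call(rbind, rev(rev_path))
  colnames(pixels) <- c("row", "col")
  structure(list(seed = cm$seed, tip = tip, pixels = pixels,
                 total_cost = cm$cost[tip[1], tip[2]]),
            class = "root_path")
}

#' Associate every root tip with its minimal-cost seed
#'
#' For each tip, the accumulated cost to every seed is read off the seeds'
#' cost maps; the tip is assigned to the seed of minimal total cost (ties:
#' nearest seed by Euclidean distance, then lowest seed index) and its path
#' to that seed is backtraced.  Works for any number of seeds `>= 1`.
#'
#' @param cost_maps List of [build_cost_map()] results, one per seed.
#' @param tips `[k, 2]` matrix of tip pixels.
#' @return List of `root_skeleton` objects, one per seed (`seed`, `paths`);
#'   a seed without tips gets zero paths.  Tips unreachable from every seed
#'   are excluded and reported in the `"unassigned"` attribute.
#' @export
associate_tips <- function(cost_maps, tips) {
  stopifnot(length(cost_maps) >= 1L)
  tips <- matrix(as.integer(round(tips)), ncol = 2)
  skels <- lapply(cost_maps, function(cm)
    structure(list(seed = cm$seed, paths = list()), class = "root_skeleton"))
  unassigned <- integer(0)
  for (i in seq_len(nrow(tips))) {
    tc <- vapply(cost_maps, function(cm) {
      if (cm$reached[tips[i, 1], tips[i, 2]]) cm$cost[tips[i, 1], tips[i, 2]]
      else Inf
    }, numeric(1))
    if (!any(is.finite(tc))) {
      unassigned <- c(unassigned, i)
      next
    }
    best <- which(tc == min(tc))
    if (length(best) > 1L) {
      dseed <- vapply(cost_maps[best], function(cm)
        sqrt(sum((cm$seed - tips[i, ])^2)), numeric(1))
      best <- best[order(dseed, best)][1]
    } else best <- best[1]
    path <- backtrace(cost_maps[[best]], tips[i, ])
    skels[[best]]$paths <- c(skels[[best]]$paths, list(path))
  }
  if (length(unassigned)) {
    rr_warn(sprintf("%d tip(s) unreachable from every seed were excluded",
                    length(unassigned)))
    attr(skels, "unassigned") <- unassigned
  }
  skels
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat(sprintf("<root_skeleton seed (%d, %d), %d path(s)>\n",
              x$seed[1], x$seed[2], length(x$paths)))
  invisible(x)
}

#' Trace all root systems in one image
#'
#' Composition of the tracing stage: builds the working root-bright
#' grayscale, converts it to cost-intensity `I = 255 - R`, resolves
#' `B = "auto"` to `255 - Otsu(R)`, builds one cost map per seed marker,
#' and associates every tip marker with its minimal-cost seed.
#'
#' @param img A [plate_image()] (typically the cropped growth zone).
#' @param ms A [marker_set()]; corrected positions are used when present.
#' @param p A [cost_params()].
#' @param connectivity 8 (default) or 4.
#' @return List of `root_skeleton` objects, one per seed marker.
#' @export
trace_image <- function(img, ms, p = cost_params(), connectivity = 8) {
  stopifnot(inherits(img, "plate_image"), inherits(ms, "marker_set"))
  R <- luma(img$pixels)
  raster <- 255 - R
  if (is.na(p$B)) p$B <- 255 - root_threshold(R)
  pos <- marker_positions(ms)
  seeds <- pos[ms$markers$kind == "seed", , drop = FALSE]
  tips <- pos[ms$markers$kind == "tip", , drop = FALSE]
  if (nrow(seeds) == 0L) rr_abort("rr_schema_error", "no seed markers")
  maps <- lapply(seq_len(nrow(seeds)), function(i)
    build_cost_map(raster, seeds[i, ], p, connectivity))
  associate_tips(maps, tips)
}

#' Working grayscale of a plate image
#'
#' The single grayscale raster (standard luma weights, roots bright) shared
#' by marker refinement and tracing; tracing converts it to cost-intensity
#' `255 - R` internally.
#'
#' @param img A [plate_image()].
#' @return Numeric matrix, 0..255.
#' @export
working_raster <- function(img) {
  stopifnot(inherits(img, "plate_image"))
  luma(img$pixels)
}

#' Root-brightness threshold of a working raster
#'
#' Two-stage Otsu: cropped plates hold three intensity classes (black
#' exterior, paper, bright roots), so a single Otsu threshold tends to split
#' exterior from paper.  A first Otsu pass discards the dark class; a second
#' pass on the remaining pixels separates roots from paper.  The second pass
#' is skipped when the first already isolates a small bright class.
#'
#' @param R Working grayscale matrix (roots bright), 0..255.
#' @return Threshold `t`; root pixels are `R > t`.
#' @export
root_threshold <- function(R) {
  ot <- function(x) 255 * EBImage::otsu(as_ebi(matrix(x / 255)), range = c(0, 1))
  t1 <- ot(R)
  upper <- R[R > t1]
  if (length(upper) < 100 || mean(R > t1) < 0.05) return(t1)
  ot(upper)
}

#' Write traced skeletons to a JSON output file
#'
#' One record per seed: seed pixel and, per path, the tip, the ordered pixel
#' list and the total cost.
#'
#' @param skels List of `root_skeleton` objects.
#' @param path Output JSON path.
#' @param image_id Optional image identifier stored in the file.
#' @return `path`, invisibly.
#' @export
write_skeletons <- function(skels, path, image_id = NA_character_) {
  out <- list(
    image_id = image_id,
    skeletons = lapply(skels, function(sk)
      list(seed = as.integer(sk$seed),
           paths = lapply(sk$paths, function(pt)
             list(tip = as.integer(pt$tip), total_cost = pt$total_cost,
                  pixels = unname(pt$pixels)))))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flatten traced skeletons to a data frame
#'
#' @param skels List of `root_skeleton` objects.
#' @param image_id Image identifier column value.
#' @return `data.frame` with `image_id, seed_idx, path_idx, point_idx, row,
#'   col`.
#' @export
skeletons_to_df <- function(skels, image_id = NA_character_) {
  rows <- list()
  for (s in seq_along(skels)) for (j in seq_along(skels[[s]]$paths)) {
    px <- skels[[s]]$paths[[j]]$pixels
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = image_id, seed_idx = s, path_idx = j,
      point_idx = seq_len(nrow(px)), row = px[, 1], col = px[, 2])
  }
  if (!length(rows))
    return(data.frame(image_id = character(0), seed_idx = integer(0),
                      path_idx = integer(0), point_idx = integer(0),
                      row = integer(0), col = integer(0)))
  do.call(rbind, rows)
}
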