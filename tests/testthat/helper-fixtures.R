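# Shared fixtures and independent oracles.  Rendered plates are cached per
# session so test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a standard 3-seed plate, configurable noise
fixture_plate <- function(noise = 0, rng_seed = 7, contrast = 0.6, ...) {
  key <- paste("plate", noise, rng_seed, contrast, ...)
  cached(key, render_plate(scene_spec(noise_sd = noise, rng_seed = rng_seed,
                                      contrast = contrast, ...)))
}

# ground-truth markers shifted into the cropped frame
markers_in_crop <- function(truth, crop) {
  mk <- truth$markers$markers
  mk$row <- mk$row - (crop$paper_rect$r0 - 1L)
  mk$col <- mk$col - (crop$paper_rect$c0 - 1L)
  marker_set(truth$image_id, mk)
}

# render -> crop -> trace with exact markers; returns everything downstream
# tests need
traced_plate <- function(noise = 0, rng_seed = 7, contrast = 0.6, ...) {
  key <- paste("traced", noise, rng_seed, contrast, ...)
  cached(key, {
    r <- fixture_plate(noise, rng_seed, contrast, ...)
    crop <- crop_growth_zone(r$image)
    skels <- trace_image(crop$cropped, markers_in_crop(r$truth, crop))
    list(image = r$image, truth = r$truth, crop = crop, skels = skels)
  })
}

# pair every traced path with its true root via the nearest true tip;
# returns data.frame(true_len, traced_len) in px (crop frame)
paired_lengths <- function(truth, crop, skels) {
  off <- c(crop$paper_rect$r0 - 1L, crop$paper_rect$c0 - 1L)
  tt <- NULL
  for (s in seq_along(truth$skeletons)) for (p in truth$skeletons[[s]]$paths)
    tt <- rbind(tt, c(p[nrow(p), ] - off, polyline_len(p), s))
  out <- NULL
  for (s in seq_along(skels)) for (pt in skels[[s]]$paths) {
    k <- which.min((tt[, 1] - pt$tip[1])^2 + (tt[, 2] - pt$tip[2])^2)
    out <- rbind(out, data.frame(true_len = tt[k, 3],
                                 traced_len = path_length(pt),
                                 true_seed = tt[k, 4], assigned_seed = s))
  }
  out
}

polyline_len <- function(p) if (nrow(p) < 2) 0 else sum(sqrt(rowSums(diff(p)^2)))

# fraction of traced paths assigned to their true seed (seed indices are
# matched by position, ground truth seeds in crop frame)
association_accuracy <- function(truth, crop, skels) {
  off <- c(crop$paper_rect$r0 - 1L, crop$paper_rect$c0 - 1L)
  seeds <- do.call(rbind, lapply(truth$skeletons, `[[`, "seed"))
  pl <- paired_lengths(truth, crop, skels)
  if (nrow(pl) == 0) return(NA_real_)
  ok <- 0
  for (i in seq_len(nrow(pl))) {
    sk_seed <- skels[[pl$assigned_seed[i]]]$seed
    true_idx <- which.min((seeds[, 1] - off[1] - sk_seed[1])^2 +
                          (seeds[, 2] - off[2] - sk_seed[2])^2)
    ok <- ok + (true_idx == pl$true_seed[i])
  }
  ok / nrow(pl)
}

# --- independent oracles -----------------------------------------------------

# Bellman-Ford fixed point by repeated sweep relaxation over the 8-connected
# grid; step into q costs node_cost(q) * step_length
bellman_ford_cost <- function(node_cost, seed) {
  nr <- nrow(node_cost); nc <- ncol(node_cost)
  cost <- matrix(Inf, nr, nc)
  cost[seed[1], seed[2]] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(moves))) {
      dr <- moves$dr[k]; dc <- moves$dc[k]
      len <- sqrt(dr^2 + dc^2)
      # relax: cost[r, c] vs cost[r - dr, c - dc] + node_cost[r, c] * len
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      src <- cost[rs - dr, cs - dc, drop = FALSE]
      cand <- src + node_cost[rs, cs, drop = FALSE] * len
      cur <- cost[rs, cs, drop = FALSE]
      better <- cand < cur
      if (any(better)) {
        cur[better] <- cand[better]
        cost[rs, cs] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cost
}

# octile distance between pixels
octile <- function(a, b) {
  d <- abs(a - b)
  max(d) - min(d) + min(d) * sqrt(2)
}

# brute-force 8-connected components of a logical matrix (flood fill)
bf_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# brute-force segment-pair intersection test for two polylines
polylines_intersect <- function(a, b, skip_a = 0, skip_b = 0) {
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t >= 0 && t <= 1 && u >= 0 && u <= 1
  }
  a <- a[(skip_a + 1):nrow(a), , drop = FALSE]
  b <- b[(skip_b + 1):nrow(b), , drop = FALSE]
  ia <- seq(1, nrow(a) - 1, by = 3)
  ib <- seq(1, nrow(b) - 1, by = 3)
  for (i in ia) for (j in ib) {
    i2 <- min(i + 3, nrow(a)); j2 <- min(j + 3, nrow(b))
    if (seg_int(a[i, ], a[i2, ], b[j, ], b[j2, ])) return(TRUE)
  }
  FALSE
}
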