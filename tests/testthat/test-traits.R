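# Trait geometry: lengths, angles, species conventions, genotype summaries.

straight_path <- function(from, to, n) {
  cbind(round(seq(from[1], to[1], length.out = n)),
        round(seq(from[2], to[2], length.out = n)))
}

test_that("path_length sums Euclidean steps and scales to mm", {
  expect_equal(path_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(path_length(rbind(c(5, 5))), 0)
  expect_equal(path_length(cbind(0:10, 0), scale = 0.1), 1.0)
})

test_that("path_length is reversal-invariant and additive", {
  withr::local_seed(2)
  for (i in 1:5) {
    p <- cbind(cumsum(sample(-1:1, 30, TRUE)), cumsum(sample(-1:1, 30, TRUE)))
    expect_equal(path_length(p), path_length(p[nrow(p):1, ]))
    q <- sweep(rbind(c(0, 0), cbind(cumsum(sample(-1:1, 20, TRUE)),
                                    cumsum(sample(-1:1, 20, TRUE)))),
               2, p[nrow(p), ], `+`)
    expect_equal(path_length(rbind(p, q[-1, ])),
                 path_length(p) + path_length(q))
  }
})

test_that("point_at_fraction walks the arc length", {
  p <- cbind(0:100, 0)
  expect_equal(point_at_fraction(p, 0.1), c(10, 0))
  expect_equal(point_at_fraction(p, 1), c(100, 0))
  # L-shaped path: 50 down then 50 right; 60% of 100 is 10 px along the arm
  L <- rbind(cbind(0:50, 0), cbind(50, 1:50))
  expect_equal(point_at_fraction(L, 0.6), c(50, 10))
  expect_error(point_at_fraction(rbind(c(1, 1), c(1, 1)), 0.5),
               class = "rr_bad_params")
})

test_that("segment_angle measures from the downward vertical, clockwise", {
  expect_equal(segment_angle(c(0, 0), c(10, 0)), 0)
  expect_equal(segment_angle(c(0, 0), c(10, 10)), 45)
  expect_equal(segment_angle(c(0, 0), c(0, -5)), -90)
  expect_equal(segment_angle(c(0, 0), c(-4, 0)), 180)
  expect_error(segment_angle(c(1, 1), c(1, 1)), class = "rr_bad_params")
})

test_that("spread_angles implements the outermost-root difference", {
  seed <- c(0, 0)
  mk <- function(...) list(seed = seed, paths = list(...))
  one <- mk(straight_path(seed, c(100, 20), 101))
  expect_equal(unname(spread_angles(one)), c(0, 0))
  # symmetric +/-30 degree straight roots -> 60 degrees basal and apical
  two <- mk(straight_path(seed, round(100 * c(cos(pi / 6), -sin(pi / 6))), 101),
            straight_path(seed, round(100 * c(cos(pi / 6), sin(pi / 6))), 101))
  sp <- spread_angles(two)
  expect_equal(unname(sp["basal"]), 60, tolerance = 0.04)
  expect_equal(unname(sp["apical"]), 60, tolerance = 0.04)
  # three roots at -40, 0, +20 degrees -> spread = max - min = 60
  three <- mk(
    straight_path(seed, round(120 * c(cos(40 * pi / 180), -sin(40 * pi / 180))), 121),
    straight_path(seed, c(120, 0), 121),
    straight_path(seed, round(120 * c(cos(20 * pi / 180), sin(20 * pi / 180))), 121))
  expect_equal(unname(spread_angles(three)["basal"]), 60, tolerance = 0.2)
  # order-free
  expect_equal(spread_angles(mk(three$paths[[3]], three$paths[[1]],
                                three$paths[[2]])),
               spread_angles(three))
})

test_that("species trait conventions fill the right fields", {
  seed <- c(10, 50)
  skel <- list(seed = seed, paths = list(
    straight_path(seed, seed + c(200, 0), 201),    # 20 mm at scale 0.1
    straight_path(seed, seed + c(318, 318), 319))) # 45 mm
  rec <- barley_traits(skel, scale = 0.1)
  expect_true(rec$germinated)
  expect_equal(rec$n_roots, 2L)
  expect_equal(rec$longest_root, 45, tolerance = 1e-3)
  expect_equal(rec$total_length, 65, tolerance = 1e-3)
  expect_equal(rec$mean_root_length, 32.5, tolerance = 1e-3)
  expect_true(is.na(rec$primary_length))

  # brassica: longest path is primary; straight root -> equal angles
  ten <- 10 * pi / 180
  skel2 <- list(seed = seed, paths = list(
    straight_path(seed, seed + round(250 * c(cos(ten), sin(ten))), 251),
    straight_path(seed, seed + c(60, 0), 61)))
  rec2 <- brassica_traits(skel2, scale = 0.1)
  manual_len <- sum(sqrt(rowSums(diff(skel2$paths[[1]])^2))) * 0.1
  expect_equal(rec2$primary_length, manual_len)
  expect_gt(rec2$primary_length, path_length(skel2$paths[[2]], 0.1))
  expect_equal(rec2$primary_angle_seed, rec2$primary_angle_tip,
               tolerance = 0.6)
  expect_equal(rec2$primary_angle_tip, 10, tolerance = 0.3)

  empty <- barley_traits(list(seed = seed, paths = list()), scale = 0.1)
  expect_false(empty$germinated)
  expect_equal(empty$n_roots, 0L)
  expect_true(is.na(empty$total_length))
})

test_that("summarise_genotype reports mean and SE over germinated seeds", {
  lab <- plate_label("barley", "P", "G001", 1)
  mk_rec <- function(total) {
    skel <- list(seed = c(0, 0), paths = list(cbind(0:round(total * 10), 0)))
    barley_traits(skel, scale = 0.1, label = lab)
  }
  recs <- lapply(c(1, 2, 3), mk_rec)
  s <- summarise_genotype(recs)
  row <- s[s$trait == "total_length", ]
  expect_equal(row$mean, 2)
  expect_equal(row$se, 0.5774, tolerance = 1e-3) # sample SD / sqrt(3)
  expect_equal(row$n, 3L)
  # identical replicates -> SE 0
  s2 <- summarise_genotype(lapply(c(2, 2, 2), mk_rec))
  expect_equal(s2$se[s2$trait == "total_length"], 0)
  # ungerminated seeds drop out of length traits but count in germination
  empty <- barley_traits(list(seed = c(0, 0), paths = list()),
                         scale = 0.1, label = lab)
  s3 <- summarise_genotype(c(recs, list(empty)))
  expect_equal(s3$n[s3$trait == "total_length"], 3L)
  expect_equal(s3$mean[s3$trait == "n_germinated"], 3)
  expect_equal(s3$n[s3$trait == "n_germinated"], 4L)
  w <- testthat::capture_warnings(summarise_genotype(recs[1]))
  expect_true(any(grepl("n = 1", w)))
  tab <- trait_table(recs)
  expect_equal(nrow(tab), 3L)
  expect_true("basal_solid_angle_deg" %in% names(tab))
})
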