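# Barcode location/decoding, growth-zone cropping, calibration, database
# filing.

test_that("locate_qr finds the symbol on rendered plates", {
  for (noise in c(0, 0.1)) {
    r <- fixture_plate(noise = noise)
    rect <- locate_qr(r$image)
    expect_gte(rect_iou(rect, r$truth$qr_rect), 0.5)
  }
})

test_that("locate_qr is invariant to uniform brightness scaling", {
  r <- fixture_plate(noise = 0.02)
  rect1 <- locate_qr(r$image)
  dim_img <- plate_image(r$image$pixels * 0.5)
  rect2 <- locate_qr(dim_img)
  expect_gte(rect_iou(rect1, rect2), 0.9)
})

test_that("locate_qr rejects images without a bright homogeneous region", {
  black <- plate_image(array(0, c(60, 60, 3)))
  expect_error(locate_qr(black), class = "rr_qr_not_found")
})

test_that("a solid bright block is located at its bounding box (oracle)", {
  px <- array(0, c(80, 80, 3))
  px[21:50, 31:70, ] <- 255
  img <- plate_image(px)
  rect <- locate_qr(img, variance_window = 9)
  # oracle: same printed sequence with brute-force flood-fill components
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  w <- 9; box <- matrix(1 / w^2, w, w)
  m1 <- matrix(0, 80, 80); m2 <- matrix(0, 80, 80)
  half <- 4L
  for (r in 1:80) for (c in 1:80) {
    rs <- max(1, r - half):min(80, r + half)
    cs <- max(1, c - half):min(80, c + half)
    m1[r, c] <- mean(gray[rs, cs]); m2[r, c] <- mean(gray[rs, cs]^2)
  }
  v <- pmax(m2 - m1^2, 0); v <- v * 255 / max(v)
  minimg <- pmin(v, gray)
  lab <- bf_components(minimg >= 0.8 * max(minimg))
  big <- which(lab == which.max(tabulate(lab[lab > 0])), arr.ind = TRUE)
  expect_equal(c(rect$r0, rect$r1, rect$c0, rect$c1),
               c(min(big[, 1]), max(big[, 1]), min(big[, 2]), max(big[, 2])))
  # and the oracle's box is the block's own bounding box
  expect_equal(c(rect$r0, rect$r1, rect$c0, rect$c1), c(21, 50, 31, 70),
               tolerance = 0.15)
})

test_that("decode_qr round-trips labels and signals failure modes", {
  lab <- plate_label("barley", "AGOUEB", "G017", 3)
  r <- cached("decode_plate",
              render_plate(scene_spec(label = lab, noise_sd = 0.05,
                                      rng_seed = 11)))
  decoded <- decode_qr(r$image, locate_qr(r$image))
  expect_equal(format(decoded), "barley|AGOUEB|G017|3")
  expect_equal(decoded$replicate, 3L)

  noise_img <- plate_image(array(runif(90 * 90 * 3, 0, 255), c(90, 90, 3)))
  expect_error(decode_qr(noise_img, px_rect(10, 80, 10, 80)),
               class = "rr_qr_unreadable")
  expect_error(parse_label_payload("barley|AGOUEB|G017"),
               class = "rr_label_parse_error")
  expect_error(plate_label("bar/ley", "P", "G", 1),
               class = "rr_label_parse_error")
  expect_error(plate_label("barley", "P", "G", 0),
               class = "rr_label_parse_error")
})

test_that("crop_growth_zone recovers the paper region", {
  r <- fixture_plate(noise = 0.05)
  crop <- crop_growth_zone(r$image)
  d <- dim(r$image$pixels)
  full <- matrix(FALSE, d[1], d[2])
  full[crop$paper_rect$r0:crop$paper_rect$r1,
       crop$paper_rect$c0:crop$paper_rect$c1] <- crop$mask
  pr <- r$truth$paper_rect
  rmask <- matrix(FALSE, d[1], d[2])
  rmask[pr$r0:pr$r1, pr$c0:pr$c1] <- TRUE
  expect_gte(sum(full & rmask) / sum(full | rmask), 0.95)
  # cropped dimensions equal the paper rect
  expect_equal(dim(crop$cropped$pixels)[1:2],
               c(rect_height(crop$paper_rect), rect_width(crop$paper_rect)))
  # exterior is black
  expect_true(all(crop$cropped$pixels[!crop$mask] == 0))
})

test_that("crop_growth_zone rejects constant-colour images and is the
           identity when paper fills the frame", {
  flat <- plate_image(array(rep(c(60, 90, 160), each = 3600), c(60, 60, 3)))
  expect_error(crop_growth_zone(flat), class = "rr_no_paper_region")
  # paper everywhere except a small gray label block: bounding box = frame
  px <- array(rep(c(60, 90, 160), each = 10000), c(100, 100, 3))
  px[40:60, 40:60, ] <- 200
  crop <- crop_growth_zone(plate_image(px), calibrate = FALSE)
  expect_equal(dim(crop$cropped$pixels)[1:2], c(100L, 100L))
})

test_that("calibrate_scale divides the paper width", {
  expect_equal(calibrate_scale(px_rect(1, 100, 1, 990), 99), 0.1)
  expect_equal(calibrate_scale(px_rect(1, 100, 2, 100), 99), 1.0)
  r <- fixture_plate(noise = 0.05)
  crop <- crop_growth_zone(r$image)
  expect_lt(abs(crop$cropped$scale - r$truth$scale) / r$truth$scale, 0.02)
  expect_error(calibrate_scale(px_rect(1, 10, 1, 10), -1),
               class = "rr_bad_params")
})

test_that("file_into_database lays out the 4-level hierarchy", {
  db <- withr::local_tempdir()
  r <- cached("decode_plate",
              render_plate(scene_spec(label = plate_label("barley", "AGOUEB",
                                                          "G017", 3),
                                      noise_sd = 0.05, rng_seed = 11)))
  crop <- crop_growth_zone(r$image)
  lab <- r$truth$label
  paths <- file_into_database(r$image, lab, crop, db)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  expect_match(paths[["raw"]], "barley/AGOUEB/G017/replicate_3/raw.png")
  expect_error(file_into_database(r$image, lab, crop, db),
               class = "rr_exists")
  expect_silent(file_into_database(r$image, lab, crop, db, overwrite = TRUE))
  # grouping: 5 plates over 2 genotypes -> 2 genotype folders
  for (g in c("G001", "G001", "G002", "G002", "G002")) {
    rep_n <- sum(grepl(g, list.dirs(file.path(db, "barley", "AGOUEB")))) + 1L
    file_into_database(r$image, plate_label("barley", "AGOUEB", g, rep_n),
                       crop, db)
  }
  expect_length(list.dirs(file.path(db, "barley", "AGOUEB"),
                          recursive = FALSE), 3L) # G001 G002 G017
})
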