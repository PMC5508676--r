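# Marker refinement: kernel reweighting, candidate extraction, correction,
# CSV round trip.

test_that("kernel_reweight reproduces the closed-form Gaussian sum", {
  I <- matrix(1, 21, 21)
  J <- kernel_reweight(I, cbind(11, 11), sigma = 5)
  expect_equal(which(J == max(J), arr.ind = TRUE)[1, ], c(row = 11L, col = 11L))
  expect_equal(max(J), 1, tolerance = 1e-12)
  # oracle: evaluate the summed Gaussians directly on a small grid
  pos <- rbind(c(8, 10), c(9, 10)) # two markers 1 px apart
  J2 <- kernel_reweight(I, pos, sigma = 3)
  expected <- matrix(0, 21, 21)
  for (r in 1:21) for (c in 1:21)
    expected[r, c] <- sum(exp(-((r - pos[, 1])^2 + (c - pos[, 2])^2) / 18))
  expect_equal(J2, expected, tolerance = 1e-12)
  # annihilation and linearity
  expect_equal(kernel_reweight(matrix(0, 9, 9), cbind(5, 5), sigma = 2),
               matrix(0, 9, 9))
  I3 <- matrix(runif(81), 9, 9)
  expect_equal(kernel_reweight(3 * I3, cbind(5, 5), sigma = 2),
               3 * kernel_reweight(I3, cbind(5, 5), sigma = 2))
  expect_error(kernel_reweight(I, matrix(numeric(0), 0, 2)),
               class = "rr_schema_error")
})

test_that("candidate_positions finds local maxima (exhaustive oracle)", {
  J <- kernel_reweight(matrix(1, 31, 31), cbind(16, 16), sigma = 4)
  cand <- candidate_positions(J, c(14, 14), search_radius = 10)
  expect_equal(nrow(cand), 1L)
  expect_equal(unname(cand[1, ]), c(16, 16))
  expect_equal(nrow(candidate_positions(matrix(1, 15, 15), c(8, 8), 5)), 0L)
  # two ridges inside the radius -> one crest candidate each
  I <- matrix(0, 31, 31)
  I[, 13] <- 200; I[, 19] <- 150
  J2 <- kernel_reweight(I, cbind(16, 16), sigma = 6)
  cand2 <- candidate_positions(J2, c(16, 16), search_radius = 9)
  # oracle: scan every pixel in the disc for a strict 3x3 maximum
  exp_cand <- NULL
  for (r in 8:24) for (c in 8:24) {
    if ((r - 16)^2 + (c - 16)^2 > 81) next
    nbr <- J2[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (J2[r, c] > 0 && J2[r, c] >= max(nbr) && sum(nbr == J2[r, c]) == 1 &&
        J2[r, c] >= 0.05 * max(J2[7:25, 7:25]))
      exp_cand <- rbind(exp_cand, c(r, c))
  }
  expect_equal(nrow(cand2), 2L)
  expect_setequal(paste(cand2[, 1], cand2[, 2]),
                  paste(exp_cand[, 1], exp_cand[, 2]))
  expect_true(all(cand2[, 2] %in% c(13, 19)))
})

test_that("correct_marker picks the brightest candidate with spec tie rules", {
  I <- matrix(0, 31, 31)
  I[, 13] <- 200
  marker <- list(kind = "tip", row = 16, col = 16)
  J <- kernel_reweight(I, cbind(16, 16), sigma = 5)
  cand <- candidate_positions(J, c(16, 16), search_radius = 15)
  res <- correct_marker(I, marker, cand)
  # brute-force argmax of I over the candidates
  expect_equal(I[res$corrected_row, res$corrected_col],
               max(I[cand]))
  expect_equal(res$corrected_col, 13)
  expect_equal(res$accuracy_px,
               sqrt((res$corrected_row - 16)^2 + (res$corrected_col - 16)^2))
  # flat image: no candidates, marker unchanged
  res2 <- correct_marker(matrix(1, 9, 9), marker,
                         matrix(numeric(0), 0, 2))
  expect_equal(res2$corrected_row, 16)
  expect_equal(res2$accuracy_px, 0)
  # tie on brightness -> smallest displacement wins
  res3 <- correct_marker(matrix(5, 31, 31), marker,
                         rbind(c(16, 14), c(16, 10)))
  expect_equal(res3$corrected_col, 14)
})

test_that("correction improves perturbed markers on rendered plates", {
  withr::local_seed(99)
  sigma <- 5
  pre <- c(); post <- c(); onroot <- c(); disp <- c()
  for (seed in 1:4) {
    r <- fixture_plate(noise = 0, rng_seed = seed)
    I <- 0.299 * r$image$pixels[, , 1] + 0.587 * r$image$pixels[, , 2] +
      0.114 * r$image$pixels[, , 3]
    mk <- r$truth$markers$markers
    tip <- mk$kind == "tip"
    true_pos <- mk[tip, c("row", "col")]
    mk$row[tip] <- round(mk$row[tip] + runif(sum(tip), -sigma, sigma))
    mk$col[tip] <- round(mk$col[tip] + runif(sum(tip), -sigma, sigma))
    ms <- correct_markers(I, marker_set(r$truth$image_id, mk, sigma = sigma))
    m <- ms$markers[tip, ]
    pre <- c(pre, sqrt((m$row - true_pos$row)^2 + (m$col - true_pos$col)^2))
    post <- c(post, sqrt((m$corrected_row - true_pos$row)^2 +
                         (m$corrected_col - true_pos$col)^2))
    onroot <- c(onroot,
                r$truth$root_mask[cbind(m$corrected_row, m$corrected_col)])
    disp <- c(disp, m$accuracy_px)
  }
  expect_lt(mean(post), mean(pre))        # correction moves markers closer
  expect_gte(mean(onroot), 0.9)           # and onto rendered root pixels
  expect_lte(max(disp), 3 * sigma + 1e-9) # bounded displacement
})

test_that("marker CSV round trip is lossless and errors name lines", {
  df <- data.frame(kind = c("seed", "tip", "tip"),
                   row = c(10, 40, 60), col = c(20, 25, 30))
  ms <- marker_set("img01", df, sigma = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers(ms, path)
  back <- read_markers(path, sigma = 4)
  expect_equal(back$image_id, "img01")
  expect_equal(back$markers$kind, df$kind)
  expect_equal(back$markers$row, df$row)

  bad <- data.frame(image_id = "x", kind = c("seed", "stem"),
                    row = c(1, 2), col = c(1, 2))
  bad_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, bad_path, row.names = FALSE)
  err <- tryCatch(read_markers(bad_path), error = identity)
  expect_s3_class(err, "rr_schema_error")
  expect_match(conditionMessage(err), "3") # line number of the bad row

  empty_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[0, ], empty_path, row.names = FALSE)
  expect_equal(nrow(read_markers(empty_path)$markers), 0L)

  expect_error(marker_set("x", data.frame(kind = "tip", row = 1, col = 1)),
               class = "rr_schema_error") # tip without seed
})
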