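# Error typology, outlier flags, baseline length measurement.

test_that("classify_errors returns all-ok on the ground truth itself", {
  r <- fixture_plate(noise = 0, rng_seed = 7)
  rep <- classify_errors(truth_as_traced(r$truth), r$truth)
  expect_equal(sum(rep$counts), rep$n_paths)
  expect_equal(unname(rep$counts[["ok"]]), rep$n_paths)
  expect_false(rep$any_error)
  expect_error(classify_errors(truth_as_traced(r$truth), r$truth,
                               traced_image_id = "other"),
               class = "rr_bad_params")
})

test_that("injected error fixtures are classified as intended", {
  r <- fixture_plate(noise = 0, rng_seed = 7)
  truth <- r$truth
  # wrong association: hand a path to the other seed's skeleton
  traced <- truth_as_traced(truth)
  moved <- traced[[1]]$paths[[1]]
  moved$seed <- traced[[2]]$seed
  traced[[2]]$paths <- c(traced[[2]]$paths, list(moved))
  traced[[1]]$paths <- traced[[1]]$paths[-1]
  rep <- classify_errors(traced, truth)
  expect_equal(unname(rep$counts[["wrong_association"]]), 1L)
  expect_equal(unname(rep$counts[["ok"]]), rep$n_paths - 1L)

  # convergence: duplicate a path so two traces share one root
  traced2 <- truth_as_traced(truth)
  dup <- traced2[[1]]$paths[[1]]
  dup$pixels <- dup$pixels[1:(nrow(dup$pixels) - 4), ]
  dup$tip <- dup$pixels[nrow(dup$pixels), ]
  traced2[[1]]$paths <- c(traced2[[1]]$paths, list(dup))
  rep2 <- classify_errors(traced2, truth)
  expect_gte(unname(rep2$counts[["convergence"]]), 1L)

  # shortcut: the true root is a deep bow, the trace is the seed-tip chord
  th <- seq(0, pi / 2, length.out = 200)
  bow <- cbind(100 + 150 * sin(th), 100 + 60 * (1 - cos(th)))
  rb <- cached("bowed", render_plate(
    scene_spec(n_seeds = 1, seeds = cbind(100, 100),
               roots = list(list(bow)), noise_sd = 0)))
  traced3 <- truth_as_traced(rb$truth)
  p <- traced3[[1]]$paths[[1]]
  n <- max(abs(p$tip - p$seed)) + 1
  chord <- cbind(round(seq(p$seed[1], p$tip[1], length.out = n)),
                 round(seq(p$seed[2], p$tip[2], length.out = n)))
  colnames(chord) <- c("row", "col")
  p$pixels <- chord
  traced3[[1]]$paths[[1]] <- p
  rep3 <- classify_errors(traced3, rb$truth)
  expect_equal(unname(rep3$counts[["shortcut"]]), 1L)

  # misadjusted tips: off every root / on the wrong root
  traced4 <- truth_as_traced(truth)
  p4 <- traced4[[1]]$paths[[1]]
  p4$pixels <- rbind(p4$pixels, c(p4$tip[1] + 8L, p4$tip[2] + 8L))
  # keep the appended step for the tip test only; tip far from any root
  p4$pixels <- p4$pixels[c(seq_len(nrow(p4$pixels) - 2),
                           nrow(p4$pixels)), , drop = FALSE]
  p4$tip <- p4$pixels[nrow(p4$pixels), ]
  traced4[[1]]$paths[[1]] <- p4
  rep4 <- classify_errors(traced4, truth)
  expect_gte(unname(rep4$counts[["not_on_root"]] +
                    rep4$counts[["not_on_tip"]] +
                    rep4$counts[["misplacement"]] +
                    rep4$counts[["wrong_association"]]), 1L)

  # error counts are stable under path reordering
  shuffled <- truth_as_traced(truth)
  shuffled[[1]]$paths <- rev(shuffled[[1]]$paths)
  expect_equal(classify_errors(shuffled, truth)$counts,
               classify_errors(truth_as_traced(truth), truth)$counts)
  expect_equal(error_fraction(list(rep, rep2)), 1)
})

test_that("flag_outliers applies median +/- k*MAD per rule", {
  lab <- plate_label("barley", "P", "G001", 1)
  mk_rec <- function(total, id) {
    skel <- list(seed = c(0, 0), paths = list(cbind(0:round(total * 10), 0)))
    list(rec = barley_traits(skel, scale = 0.1, image_id = id, label = lab),
         skel = skel)
  }
  plain <- lapply(1:8, function(i) mk_rec(20, paste0("img", i)))
  fs <- flag_outliers(lapply(plain, `[[`, "rec"),
                      lapply(plain, `[[`, "skel"))
  expect_equal(nrow(fs$flags), 0L) # identical plants: nothing to flag
  # one plant with 5x length is flagged by the length rule
  spiked <- c(lapply(1:7, function(i) mk_rec(20 + 0.01 * i, paste0("img", i))),
              list(mk_rec(100, "img8")))
  fs2 <- flag_outliers(lapply(spiked, `[[`, "rec"),
                       lapply(spiked, `[[`, "skel"))
  expect_true(any(fs2$flags$rule == "total_length" &
                  fs2$flags$image_id == "img8"))
  # straight roots have tortuosity exactly 1, never flagged by that rule
  expect_false(any(fs2$flags$rule == "tortuosity"))
  expect_warning(flag_outliers(lapply(plain[1:3], `[[`, "rec")), "fewer than 5")
})

test_that("max_entropy_threshold separates a bimodal histogram", {
  withr::local_seed(3)
  x <- pmin(pmax(c(rnorm(4000, 40, 6), rnorm(600, 180, 8)), 0), 255)
  t <- max_entropy_threshold(matrix(x, 46, 100))
  is_fg <- rep(c(FALSE, TRUE), c(4000, 600))
  expect_gte(mean(x[is_fg] > t), 0.99)  # foreground kept
  expect_gte(mean(x[!is_fg] <= t), 0.95) # background suppressed
})

test_that("baseline length agrees with truth on a clean straight root", {
  n <- round(30 / 0.2475)
  poly <- cbind(seq(90, 90 + n), 240)
  r <- cached("straight30", render_plate(
    scene_spec(n_seeds = 1, seeds = cbind(90, 240), roots = list(list(poly)),
               noise_sd = 0, contrast = 0.6)))
  crop <- crop_growth_zone(r$image)
  true_mm <- r$truth$skeletons[[1]]$lengths_mm
  expect_lt(abs(baseline_total_length(crop$cropped) - true_mm) / true_mm, 0.1)
  # blank plate -> 0 with a warning
  rb <- cached("blank", render_plate(
    scene_spec(n_seeds = 1, seeds = cbind(90, 240), roots = list(list()),
               noise_sd = 0)))
  cb <- crop_growth_zone(rb$image)
  expect_warning(len0 <- baseline_total_length(cb$cropped), "length 0")
  expect_equal(len0, 0)
})

test_that("baseline underestimates faint noisy roots that tracing recovers", {
  tp <- traced_plate(noise = 0.05, rng_seed = 3, contrast = 0.1)
  traced_mm <- sum(unlist(lapply(tp$skels, function(s)
    vapply(s$paths, path_length, 1, scale = tp$crop$cropped$scale))))
  expect_lt(baseline_total_length(tp$crop$cropped), traced_mm)
})
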