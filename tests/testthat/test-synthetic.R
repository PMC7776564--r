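test_that("image spec validation rejects bad dimensions and intensities", {
  expect_error(image_spec(row_ids = "0"), "at least two rows")
  expect_error(image_spec(row_extent_um = -1), "positive")
  expect_error(image_spec(pixel_size_um = 0), "positive")
  expect_error(image_spec(interface_intensity = -5), "non-negative")
  expect_error(image_spec(interface_intensity = c("0/1" = 1)), "missing interfaces")
})

test_that("seeded image generation is bit-identical", {
  spec <- image_spec()
  a <- gen_segment_image(spec, seed = 7)
  b <- gen_segment_image(spec, seed = 7)
  expect_identical(a$intensity, b$intensity)
  c <- gen_segment_image(spec, seed = 8)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("zero-noise equal-intensity images have identical interface bands", {
  spec <- image_spec(noise_sd = 0, interface_intensity = 80)
  img <- gen_segment_image(spec, seed = 1)
  px <- img$pixel_size_um
  band_mean <- vapply(img$interfaces$x_um, function(x0) {
    cols <- which(abs((seq_len(ncol(img$intensity)) - 0.5) * px - x0) <= 1.5)
    mean(img$intensity[, cols])
  }, numeric(1))
  expect_equal(max(band_mean) - min(band_mean), 0, tolerance = 1e-9)
})

test_that("total image signal scales linearly with puncta density", {
  base <- image_spec(noise_sd = 0, puncta_density = 2, background_mean = 0)
  dbl <- image_spec(noise_sd = 0, puncta_density = 4, background_mean = 0)
  s1 <- sum(gen_segment_image(base, seed = 1)$intensity)
  s2 <- sum(gen_segment_image(dbl, seed = 1)$intensity)
  expect_equal(s2 / s1, 2, tolerance = 0.01)
})

test_that("elevated interfaces rank highest after quantification", {
  spec <- flat_elevated_spec()
  img <- gen_segment_image(spec, seed = 3)
  s <- quantify_image(img, seed = 4)
  top2 <- s$interface_id[order(-s$mean_normalized)][1:2]
  expect_setequal(top2, c("9/T3", "T3/10"))
})

test_that("circular mixture validation enforces closed weights", {
  expect_error(circular_mixture(90, 2, weights = 0.7), "sum to 1")
  expect_error(circular_mixture(c(10, 370), 2, weights = c(0.5, 0.5)),
               "\\[0, 360\\)")
  expect_error(circular_mixture(90, -1, weights = 1), ">= 0")
})

test_that("sampled angles converge to the component means", {
  mix <- circular_mixture(100, kappas = 4, weights = 1)
  a <- sample_angles(mix, 20000, seed = 5)
  th <- a * pi / 180
  mu <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
  expect_lt(abs(mu - 100), 1)  # ~4 sd of the circular mean at this n
  # uniform mixture: quadrants near 0.25
  u <- sample_angles(circular_mixture(numeric(0), numeric(0), uniform_weight = 1),
                     20000, seed = 6)
  qc <- quadrant_counts(u)
  expect_true(all(abs(qc / 20000 - 0.25) < 0.02))
})

test_that("comet tracks respect counts, spacing and seeding", {
  mix <- bimodal_mix()
  tr <- gen_comet_tracks(mix, n_comets = 175, seed = 9)
  expect_equal(length(unique(tr$track_id)), 175)
  expect_equal(unique(diff(tr$t_s[tr$track_id == tr$track_id[1]])), 5.16,
               tolerance = 1e-12)
  tr2 <- gen_comet_tracks(mix, n_comets = 175, seed = 9)
  expect_identical(tr, tr2)
  expect_error(gen_comet_tracks(mix, n_comets = 0), "n_comets")
  expect_error(gen_comet_tracks(mix, 5, frame_interval = 0), "frame_interval")
})

test_that("track-borne bimodal structure survives the full angle pipeline", {
  tr <- gen_comet_dataset(bimodal_mix(), n_cells = 4, comets_per_cell = 150,
                          seed = 17)
  ang <- track_to_angle(tr)
  f <- fit_circular_models(ang$angle_deg, n_restarts = 5, seed = 18)
  expect_true(f$model[1] %in% c("M_axial_equal", "M_axial_weighted",
                                "M_bimodal_free"))
  modes <- sort(c(f$mu1_deg[1], f$mu2_deg[1]))
  expect_lt(abs(modes[1] - 100), 5)
  expect_lt(abs(modes[2] - 280), 5)
})

test_that("predenticle generation respects its probabilities", {
  obs0 <- gen_predenticles(30, p_anterior = c("T1" = 0.5, "row 2" = 0.5),
                           p_unclear = 0, seed = 2)
  expect_false(any(obs0$orientation == "unclear"))
  obs_post <- gen_predenticles(30, p_anterior = c("T1" = 0, "row 2" = 0),
                               p_unclear = 0, seed = 3)
  expect_true(all(obs_post$orientation == "posterior"))
  expect_error(gen_predenticles(10, p_anterior = c(a = 2, b = 0.5)), "\\[0, 1\\]")
})

test_that("wild-type-row-2-like simulations give a non-significant Fisher test", {
  obs <- gen_predenticles(40, p_anterior = c("T1" = 0.02, "row 2" = 0.02),
                          p_unclear = 0.08, seed = 13)
  tab <- build_table(obs, c("T1", "row 2"))
  expect_gt(fisher_exact_2x2(tab)$p_value, 0.05)
})

test_that("image and track round-trips through disk are faithful", {
  spec <- image_spec(row_ids = c("9", "T3", "10"), noise_sd = 4)
  img <- gen_segment_image(spec, seed = 21)
  path <- file.path(tempdir(), "strip.tiff")
  write_image_tiff(img, path)
  back <- read_image_tiff(path)
  expect_equal(back$intensity, img$intensity, tolerance = 1e-6)
  expect_equal(back$interfaces$x_um, img$interfaces$x_um)
  tr <- gen_comet_tracks(bimodal_mix(), 10, seed = 1)
  tpath <- file.path(tempdir(), "tracks.csv")
  write_tracks_csv(tr, tpath)
  tr2 <- read_tracks_csv(tpath)
  expect_equal(tr2$x_um, tr$x_um, tolerance = 1e-12)
  expect_equal(track_to_angle(tr2)$angle_deg, track_to_angle(tr)$angle_deg,
               tolerance = 1e-9)
})
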