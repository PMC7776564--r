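make_flat_image <- function(value = 50, nx = 200, ny = 80, px = 0.25) {
  structure(list(intensity = matrix(value, ny, nx), pixel_size_um = px,
                 interfaces = data.frame(interface_id = character(0),
                                         x_um = numeric(0))),
            class = "fluorescence_image")
}

test_that("line sampling is seeded, width-checked and flat on flat images", {
  img <- make_flat_image()
  p1 <- sample_lines(img, n_lines = 10, seed = 3)
  expect_equal(length(unique(p1$line_id)), 10)
  expect_true(all(p1$intensity == 50))
  p2 <- sample_lines(img, n_lines = 10, seed = 3)
  expect_identical(p1$y_um, p2$y_um)
  expect_error(sample_lines(img, width_um = 30), "smaller than the image height")
})

test_that("peak finding locates Gaussian bumps and ignores flat profiles", {
  x <- seq(0, 50, by = 0.25)
  prof <- data.frame(line_id = "l1", x_um = x,
                     intensity = 10 + 40 * exp(-(x - 20)^2 / 2))
  pk <- find_profile_peaks(prof)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x_um - 20), 0.26)
  # two equal bumps give two equal peaks
  prof2 <- data.frame(line_id = "l1", x_um = x,
                      intensity = 10 + 40 * exp(-(x - 15)^2 / 2) +
                        40 * exp(-(x - 35)^2 / 2))
  pk2 <- find_profile_peaks(prof2)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$height[1], pk2$height[2], tolerance = 1e-10)
  flat <- data.frame(line_id = "l1", x_um = x, intensity = 7)
  expect_equal(nrow(find_profile_peaks(flat)), 0)
})

test_that("synthetic-image peaks fall within 1 um of ground truth", {
  img <- gen_segment_image(flat_elevated_spec(), seed = 31)
  pk <- find_profile_peaks(sample_lines(img, seed = 32))
  assigned <- assign_peaks(pk, img$interfaces, tolerance_um = 1)
  hit <- assigned[!is.na(assigned$interface_id), ]
  gt <- stats::setNames(img$interfaces$x_um, img$interfaces$interface_id)
  expect_true(all(abs(hit$x_um - gt[hit$interface_id]) <= 1))
  # most interfaces are found by most lines
  expect_gt(nrow(hit), 0.8 * 10 * nrow(img$interfaces))
})

test_that("peak assignment applies tolerance and the highest-wins rule", {
  interfaces <- data.frame(interface_id = c("a/b", "b/c"), x_um = c(10, 20))
  pk <- data.frame(line_id = c("l1", "l1", "l1", "l2"),
                   x_um = c(10.0, 10.8, 16, 19.5),
                   height = c(5, 9, 4, 7), prominence = 1)
  out <- assign_peaks(pk, interfaces, tolerance_um = 2)
  # only the higher of the two l1 peaks near a/b survives
  ab <- out[!is.na(out$interface_id) & out$interface_id == "a/b" &
              out$line_id == "l1", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$height, 9)
  # peak at 16 is farther than tolerance from both interfaces
  expect_true(is.na(out$interface_id[out$x_um == 16]))
  expect_equal(out$interface_id[out$x_um == 19.5], "b/c")
})

test_that("interface summaries enforce the 3-line rule and mean-of-means", {
  assigned <- data.frame(
    line_id = c("l1", "l2", "l3", "l1", "l2", "l3", "l1", "l2"),
    x_um = 0, height = c(10, 12, 14, 20, 22, 24, 50, 60), prominence = 1,
    interface_id = c(rep("a/b", 3), rep("b/c", 3), rep("c/d", 2))
  )
  s <- summarize_interfaces(assigned, "img")
  expect_setequal(s$interface_id, c("a/b", "b/c"))  # c/d hit by only 2 lines
  expect_equal(mean(s$mean_normalized), 1)
  expect_equal(s$mean_raw[s$interface_id == "a/b"], 12)
  # scale invariance of normalized values
  assigned2 <- assigned
  assigned2$height <- assigned2$height * 2
  s2 <- summarize_interfaces(assigned2, "img")
  expect_equal(s2$mean_normalized, s$mean_normalized)
})

test_that("the full quantification is invariant to positive rescaling", {
  img <- gen_segment_image(flat_elevated_spec(), seed = 41)
  img2 <- img
  img2$intensity <- img2$intensity * 3.7
  s1 <- quantify_image(img, seed = 42)
  s2 <- quantify_image(img2, seed = 42)
  expect_equal(s2$mean_normalized, s1$mean_normalized, tolerance = 1e-12)
  expect_equal(s2$mean_raw, 3.7 * s1$mean_raw, tolerance = 1e-12)
})

test_that("tukey_compare matches a direct studentized-range computation", {
  set.seed(8)
  d <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(image_id = paste0("i", i),
               interface_id = c("a/b", "b/c", "c/d"),
               n_lines = 10, mean_raw = 1,
               mean_normalized = c(1, 1.2, 0.8) + rnorm(3, 0, 0.05))
  }))
  tr <- tukey_compare(d)
  # oracle: balanced one-way Tukey HSD from first principles
  groups <- sort(unique(d$interface_id))
  k <- length(groups); n <- 6; df <- k * (n - 1)
  means <- tapply(d$mean_normalized, d$interface_id, mean)
  mse <- sum(tapply(d$mean_normalized, d$interface_id,
                    function(v) sum((v - mean(v))^2))) / df
  se <- sqrt(mse / n)
  for (i in seq_len(nrow(tr$tukey))) {
    a <- tr$tukey$group_a[i]; b <- tr$tukey$group_b[i]
    q <- abs(means[a] - means[b]) / se * sqrt(1)
    p_ref <- stats::ptukey(abs(means[a] - means[b]) / se, k, df,
                           lower.tail = FALSE)
    expect_equal(tr$tukey$p_adj[i], unname(p_ref), tolerance = 1e-8)
    expect_equal(tr$tukey$diff[i], unname(means[a] - means[b]),
                 tolerance = 1e-12)
  }
})

test_that("letter display agrees with multcomp's insert-and-absorb", {
  skip_if_not_installed("multcomp")
  set.seed(19)
  d <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(image_id = paste0("i", i),
               interface_id = c("g1", "g2", "g3", "g4"),
               n_lines = 10, mean_raw = 1,
               mean_normalized = c(1, 1.05, 1.4, 1.45) + rnorm(4, 0, 0.05))
  }))
  tr <- tukey_compare(d)
  dd <- data.frame(y = d$mean_normalized, g = factor(d$interface_id))
  glht_fit <- multcomp::glht(stats::aov(y ~ g, dd),
                             linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht_fit)$mcletters$Letters
  # same partition of groups into letter classes (letter names may differ)
  part_mine <- split(tr$letters$interface_id, tr$letters$letters)
  part_ref <- split(names(ref), unname(ref))
  norm <- function(p) unname(lapply(p[order(vapply(p, paste, collapse = ",",
                                                   FUN.VALUE = ""))], sort))
  expect_equal(norm(part_mine), norm(part_ref))
})

test_that("identical groups share a letter with adjusted p of 1", {
  d <- data.frame(image_id = rep(paste0("i", 1:4), each = 2),
                  interface_id = rep(c("a/b", "b/c"), 4),
                  n_lines = 10, mean_raw = 1,
                  mean_normalized = rep(c(1.01, 0.99, 1.0, 1.0), each = 2))
  tr <- tukey_compare(d)
  expect_equal(tr$tukey$p_adj, 1, tolerance = 1e-12)
  expect_equal(tr$letters$letters[1], tr$letters$letters[2])
})

test_that("row asymmetry flags T3-flank rows with opposite signs and mirrors", {
  set.seed(55)
  summ <- do.call(rbind, lapply(1:8, function(i) {
    img <- gen_segment_image(flat_elevated_spec(), seed = 500 + i)
    quantify_image(img, image_id = sprintf("img%02d", i), seed = 600 + i)
  }))
  ra <- suppressWarnings(row_asymmetry(summ))
  r9 <- ra[ra$row_id == "9", ]
  r10 <- ra[ra$row_id == "10", ]
  expect_true(r9$significant && r9$diff > 0)
  expect_true(r10$significant && r10$diff < 0)
  # mirroring the segment negates each row's difference
  rev_ids <- rev(segment_rows()$row_id)
  summ_m <- summ
  summ_m$interface_id <- vapply(strsplit(summ$interface_id, "/", fixed = TRUE),
                                function(p) paste(p[2], p[1], sep = "/"),
                                character(1))
  ra_m <- suppressWarnings(row_asymmetry(summ_m, row_ids = rev_ids))
  both <- intersect(ra$row_id, ra_m$row_id)
  expect_equal(ra_m$diff[match(both, ra_m$row_id)],
               -ra$diff[match(both, ra$row_id)], tolerance = 1e-12)
})
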