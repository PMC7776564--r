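#' Derive comet growth angles from tracks
#'
#' The growth direction of each comet is the direction of the displacement
#' between the first and last timepoint of its track, in the project
#' convention (0 = posterior, 90 = medial, counterclockwise, degrees in
#' `[0, 360)`). Tracks from right hemisegments have their y displacement
#' negated first, matching the flipping of right-hemisegment cells onto the
#' left-hemisegment orientation. Tracks with zero net displacement are
#' dropped with a warning.
#'
#' @param tracks Data.frame with columns `track_id`, `t_s`, `x_um`, `y_um`
#'   and optionally `cell_id`, `compartment`, `hemisegment` (default
#'   `"left"`).
#' @return Data.frame with one row per retained track: `track_id`,
#'   `cell_id`, `compartment`, `hemisegment`, `angle_deg`.
#' @export
#' @examples
#' tr <- data.frame(track_id = "t1", t_s = c(0, 5.16),
#'                  x_um = c(0, 1), y_um = c(0, 0))
#' track_to_angle(tr)$angle_deg  # 0: posterior
track_to_angle <- function(tracks) {
  stopifnot(all(c("track_id", "t_s", "x_um", "y_um") %in% names(tracks)))
  if (is.null(tracks$cell_id)) tracks$cell_id <- "cell_1"
  if (is.null(tracks$compartment)) tracks$compartment <- NA_character_
  if (is.null(tracks$hemisegment)) tracks$hemisegment <- "left"
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  rows <- lapply(idx, function(i) {
    tr <- tracks[i, ]
    if (nrow(tr) < 2 || any(diff(sort(tr$t_s)) <= 0)) {
      stop("each track needs >= 2 points with strictly increasing times",
           call. = FALSE)
    }
    tr <- tr[order(tr$t_s), ]
    dx <- tr$x_um[nrow(tr)] - tr$x_um[1]
    dy <- tr$y_um[nrow(tr)] - tr$y_um[1]
    if (tr$hemisegment[1] == "right") dy <- -dy
    data.frame(track_id = tr$track_id[1], cell_id = tr$cell_id[1],
               compartment = tr$compartment[1], hemisegment = tr$hemisegment[1],
               dx = dx, dy = dy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  zero <- out$dx == 0 & out$dy == 0
  if (any(zero)) {
    warning(sum(zero), " track(s) with zero net displacement dropped")
    out <- out[!zero, ]
  }
  out$angle_deg <- .wrap360(.rad2deg(atan2(out$dy, out$dx)))
  out$dx <- NULL
  out$dy <- NULL
  out <- out[order(out$track_id), ]
  rownames(out) <- NULL
  out
}

#' Bin angles for a rose diagram
#'
#' Half-open bins `[k*w, (k+1)*w)` covering the circle; percentages sum to
#' 100.
#'
#' @param angles_deg Angles in degrees.
#' @param bin_width Bin width in degrees; must divide 360 (display default
#'   4).
#' @return Data.frame with columns `bin_start`, `bin_mid`, `n`, `percent`.
#' @export
rose_bins <- function(angles_deg, bin_width = 4) {
  if (360 %% bin_width != 0) {
    stop("bin_width must divide 360", call. = FALSE)
  }
  a <- .wrap360(angles_deg)
  k <- floor(a / bin_width)
  nb <- 360 %/% bin_width
  n <- tabulate(k + 1L, nbins = nb)
  data.frame(
    bin_start = (seq_len(nb) - 1L) * bin_width,
    bin_mid = (seq_len(nb) - 0.5) * bin_width,
    n = n,
    percent = 100 * n / length(a)
  )
}

.quadrant_of <- function(angles_deg) {
  a <- .wrap360(angles_deg)
  ifelse(a >= 135 & a < 225, "anterior",
  ifelse(a >= 45 & a < 135, "medial",
  ifelse(a >= 225 & a < 315, "lateral", "posterior")))
}

#' Sort angles into the four axis-centred quadrants
#'
#' 90-degree half-open sectors centred on the anteroposterior and
#' mediolateral axes: anterior `[135, 225)`, posterior `[315, 45)`, medial
#' `[45, 135)`, lateral `[225, 315)`. The boundary angles 45, 135, 225 and
#' 315 belong to the sector they open.
#'
#' @param angles_deg Angles in degrees.
#' @return Named integer vector with counts for `anterior`, `posterior`,
#'   `medial`, `lateral`; total sample size in `attr(x, "n")`.
#' @export
#' @examples
#' quadrant_counts(c(0, 90, 180, 270))
quadrant_counts <- function(angles_deg) {
  q <- factor(.quadrant_of(angles_deg),
              levels = c("anterior", "posterior", "medial", "lateral"))
  out <- table(q)
  res <- stats::setNames(as.integer(out), names(out))
  attr(res, "n") <- length(angles_deg)
  res
}

#' Per-cell quadrant fractions
#'
#' @param angles Data.frame with columns `cell_id` and `angle_deg` (as
#'   returned by [track_to_angle()]).
#' @return Data.frame with one row per cell: `cell_id`, `n` and the
#'   fractions `anterior`, `posterior`, `medial`, `lateral` (summing to 1).
#' @export
cell_quadrant_fractions <- function(angles) {
  stopifnot(all(c("cell_id", "angle_deg") %in% names(angles)))
  rows <- lapply(split(angles$angle_deg, angles$cell_id), function(a) {
    qc <- quadrant_counts(a)
    c(n = length(a), qc / length(a))
  })
  out <- data.frame(cell_id = names(rows), do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bootstrap comparison of opposite quadrant fractions across cells
#'
#' Observed statistic: the mean over cells of the difference between a
#' cell's fraction of comets in the first quadrant of the pair and in the
#' opposite quadrant. Cells are resampled with replacement `B` times; the
#' confidence interval is the 0.025/0.975 quantile pair of the resampled
#' differences of means.
#'
#' Two p-values are reported. `p_literal` is the fraction of resampled
#' differences strictly greater than the observed difference — the printed
#' resampling recipe taken at face value, which by construction hovers near
#' 0.5. `p_sign` is a conventional two-sided sign-based value: twice the
#' fraction of resampled differences on the opposite side of zero from the
#' observed difference, capped at 1.
#'
#' @param fractions Data.frame from [cell_quadrant_fractions()] (>= 2
#'   cells).
#' @param pair `"anterior_posterior"` (anterior minus posterior) or
#'   `"medial_lateral"` (medial minus lateral).
#' @param B Number of bootstrap resamples (default 10000).
#' @param alpha Interval level complement (default 0.05).
#' @param seed Integer seed.
#' @return List of class `"bootstrap_md"`: `md` (observed difference of
#'   means), `ci` (length-2 vector), `p_literal`, `p_sign`, `B`, `n_cells`,
#'   `pair`.
#' @export
bootstrap_md <- function(fractions, pair = c("anterior_posterior", "medial_lateral"),
                         B = 10000, alpha = 0.05, seed = 1) {
  pair <- match.arg(pair)
  if (nrow(fractions) < 2) stop("need at least 2 cells", call. = FALSE)
  if (B < 100) warning("B < 100 gives unstable quantiles")
  cols <- if (pair == "anterior_posterior") c("anterior", "posterior")
          else c("medial", "lateral")
  d <- fractions[[cols[1]]] - fractions[[cols[2]]]
  md <- mean(d)
  old <- .restore_seed(seed)
  on.exit(old())
  n <- length(d)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  boot <- colMeans(matrix(d[idx], nrow = n))
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  p_literal <- mean(boot > md)
  p_sign <- min(1, 2 * mean(if (md >= 0) boot < 0 else boot > 0))
  structure(list(md = md, ci = ci, p_literal = p_literal, p_sign = p_sign,
                 B = B, n_cells = n, pair = pair),
            class = "bootstrap_md")
}

#' @export
print.bootstrap_md <- function(x, ...) {
  cat(sprintf("Difference of means (%s), %d cells: md = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$pair, x$n_cells, x$md, x$ci[1], x$ci[2]))
  cat(sprintf("  p (literal resampling definition) = %.4f; p (sign-based, two-sided) = %.4f; B = %d\n",
              x$p_literal, x$p_sign, x$B))
  invisible(x)
}

#' Scan opposite sector pairs for orientation bias
#'
#' Partitions the circle into sectors of `sector_width` degrees and, for
#' every pair of opposite sectors, counts comets, reports the bias
#' (difference of counts) and a two-sided exact binomial p-value against
#' equal splitting. With `anchoring = "centered"` sectors are centred on 0,
#' 22.5, 45, ... degrees so one pair contains the anteroposterior (PCP)
#' axis; `"edge"` places sector edges on 0 degrees instead.
#'
#' @param angles_deg Angles in degrees.
#' @param sector_width Sector width in degrees; `2 * sector_width` must
#'   divide 360 (default 22.5).
#' @param anchoring `"centered"` or `"edge"`.
#' @return Data.frame with one row per opposite pair: `center_1`,
#'   `center_2`, `n_1`, `n_2`, `bias`, `share`, `p_value`.
#' @export
#' @examples
#' sector_scan(c(0, 1, 2, 180), sector_width = 22.5)[1, ]
sector_scan <- function(angles_deg, sector_width = 22.5,
                        anchoring = c("centered", "edge")) {
  anchoring <- match.arg(anchoring)
  if ((360 / (2 * sector_width)) %% 1 != 0) {
    stop("360 must be divisible by 2 * sector_width", call. = FALSE)
  }
  ns <- round(360 / sector_width)
  offset <- if (anchoring == "centered") sector_width / 2 else 0
  a <- .wrap360(angles_deg + offset)
  sec <- floor(a / sector_width)  # 0 .. ns-1
  counts <- tabulate(sec + 1L, nbins = ns)
  half <- ns %/% 2
  n_total <- length(angles_deg)
  rows <- lapply(seq_len(half), function(i) {
    n1 <- counts[i]
    n2 <- counts[i + half]
    p <- if (n1 + n2 == 0) NA_real_ else
      stats::binom.test(n1, n1 + n2, 0.5)$p.value
    data.frame(
      center_1 = .wrap360((i - 1) * sector_width - offset + sector_width / 2),
      center_2 = .wrap360((i - 1 + half) * sector_width - offset + sector_width / 2),
      n_1 = n1, n_2 = n2, bias = n1 - n2,
      share = (n1 + n2) / n_total,
      p_value = p
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw a rose diagram of comet directions
#'
#' Base-graphics polar histogram in the project convention (0 = posterior
#' on the right, 90 = medial up); each wedge's radius is the percentage of
#' comets in that bin.
#'
#' @param angles_deg Angles in degrees.
#' @param bin_width Bin width in degrees (default 4).
#' @param main Plot title.
#' @param col Wedge colour.
#' @return The binned data from [rose_bins()], invisibly.
#' @export
rose_plot <- function(angles_deg, bin_width = 4, main = "", col = "steelblue") {
  rb <- rose_bins(angles_deg, bin_width)
  r_max <- max(rb$percent, 1e-9)
  graphics::plot(NA, xlim = c(-r_max, r_max), ylim = c(-r_max, r_max),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_len(nrow(rb))) {
    if (rb$n[i] == 0) next
    th <- .deg2rad(seq(rb$bin_start[i], rb$bin_start[i] + bin_width,
                       length.out = 8))
    graphics::polygon(c(0, rb$percent[i] * cos(th)),
                      c(0, rb$percent[i] * sin(th)),
                      col = col, border = NA)
  }
  graphics::symbols(0, 0, circles = r_max, inches = FALSE, add = TRUE,
                    fg = "grey50")
  graphics::text(c(r_max, 0, -r_max, 0), c(0, r_max, 0, -r_max) * 1.08,
                 c("posterior", "medial", "anterior", "lateral"),
                 cex = 0.8, xpd = NA)
  invisible(rb)
}
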