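#' Specify a synthetic segment-fluorescence image
#'
#' Describes a strip of aligned epidermal cell rows with punctate membrane
#' signal concentrated at the row interfaces, as seen for tagged Ds imaged
#' in the apical plane. The anteroposterior axis is x; rows are laid out
#' left (anterior) to right (posterior) and interfaces sit at the cumulative
#' row boundaries.
#'
#' @param row_ids Character vector of cell-row identities in anteroposterior
#'   order (default: the full seventeen-row segment).
#' @param row_extent_um Anteroposterior extent of each row in micrometres
#'   (recycled).
#' @param strip_height_um Mediolateral height of the imaged strip.
#' @param interface_intensity Named numeric vector mapping each internal
#'   interface (`"rowA/rowB"`) to its mean peak intensity in arbitrary
#'   units; a single unnamed value is recycled to all interfaces.
#' @param puncta_density Puncta per micrometre of interface length.
#' @param puncta_sigma_um Gaussian radius of a rendered punctum.
#' @param background_mean Constant background intensity.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#'   `noise_sd = 0` requests a fully deterministic calibration image (puncta
#'   evenly spaced, no amplitude jitter).
#' @param amplitude_cv Coefficient of variation of per-punctum amplitudes
#'   (only applied when `noise_sd > 0`).
#' @param pixel_size_um Pixel size in micrometres.
#' @return A list of class `"image_spec"`.
#' @export
#' @examples
#' spec <- image_spec(interface_intensity = 100)
#' names(spec$interface_intensity)[1:3]
image_spec <- function(row_ids = segment_rows()$row_id,
                       row_extent_um = 7,
                       strip_height_um = 30,
                       interface_intensity = 100,
                       puncta_density = 2,
                       puncta_sigma_um = 0.3,
                       background_mean = 20,
                       noise_sd = 8,
                       amplitude_cv = 0.3,
                       pixel_size_um = 0.25) {
  n <- length(row_ids)
  if (n < 2) stop("need at least two rows to have an interface", call. = FALSE)
  row_extent_um <- rep_len(row_extent_um, n)
  if (any(row_extent_um <= 0) || strip_height_um <= 0 || pixel_size_um <= 0) {
    stop("dimensions and pixel size must be positive", call. = FALSE)
  }
  iface_ids <- paste(row_ids[-n], row_ids[-1], sep = "/")
  if (is.null(names(interface_intensity))) {
    interface_intensity <- stats::setNames(
      rep_len(interface_intensity, n - 1), iface_ids)
  } else {
    missing <- setdiff(iface_ids, names(interface_intensity))
    if (length(missing) > 0) {
      stop("interface_intensity missing interfaces: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    interface_intensity <- interface_intensity[iface_ids]
  }
  if (any(interface_intensity < 0) || background_mean < 0 || noise_sd < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  spec <- list(
    row_ids = row_ids,
    row_extent_um = row_extent_um,
    strip_height_um = strip_height_um,
    interface_intensity = interface_intensity,
    puncta_density = puncta_density,
    puncta_sigma_um = puncta_sigma_um,
    background_mean = background_mean,
    noise_sd = noise_sd,
    amplitude_cv = amplitude_cv,
    pixel_size_um = pixel_size_um
  )
  class(spec) <- "image_spec"
  spec
}

#' Generate a synthetic fluorescence image of a segment strip
#'
#' Renders punctate membrane signal at every internal row interface of an
#' [image_spec()], plus constant background and Gaussian pixel noise. Each
#' punctum is a Gaussian spot whose peak brightness averages the
#' interface's specified mean intensity, so total interface signal scales
#' linearly with `puncta_density` and line-profile peak heights are
#' proportional to the specified intensity at fixed density. Puncta are
#' rendered with the mediolateral (y) axis treated as periodic so that edge
#' clipping does not bias per-interface totals.
#'
#' With `noise_sd = 0` the image is fully deterministic: puncta are evenly
#' spaced along each interface with fixed amplitudes, so per-interface
#' signal is strictly proportional to the specified intensity. This
#' calibration mode is what makes zero-noise ground-truth ranking exact.
#'
#' @param spec An [image_spec()].
#' @param seed Integer seed controlling puncta placement, amplitude jitter
#'   and pixel noise.
#' @return A list of class `"fluorescence_image"` with elements `intensity`
#'   (matrix, rows = y, columns = x), `pixel_size_um`, and `interfaces`
#'   (data.frame of ground-truth `interface_id`, `x_um`).
#' @export
#' @examples
#' img <- gen_segment_image(image_spec(noise_sd = 0), seed = 1)
#' dim(img$intensity)
gen_segment_image <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "image_spec"))
  px <- spec$pixel_size_um
  width_um <- sum(spec$row_extent_um)
  nx <- max(2L, round(width_um / px))
  ny <- max(2L, round(spec$strip_height_um / px))
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  H <- ny * px
  iface_x <- cumsum(spec$row_extent_um)[-length(spec$row_extent_um)]
  iface_id <- names(spec$interface_intensity)
  sigma <- spec$puncta_sigma_um

  old <- .restore_seed(seed)
  on.exit(old())

  m <- matrix(spec$background_mean, nrow = ny, ncol = nx)
  n_puncta <- max(1L, round(spec$puncta_density * H))
  # per-punctum peak brightness = the interface's mean intensity, so total
  # interface signal scales linearly with puncta_density and profile peak
  # heights are proportional to intensity at fixed density
  amp_base <- spec$interface_intensity
  deterministic <- spec$noise_sd == 0

  for (j in seq_along(iface_x)) {
    if (deterministic) {
      y0 <- (seq_len(n_puncta) - 0.5) * H / n_puncta
      x0 <- rep(iface_x[j], n_puncta)
      amps <- rep(amp_base[j], n_puncta)
    } else {
      y0 <- stats::runif(n_puncta, 0, H)
      x0 <- iface_x[j] + stats::rnorm(n_puncta, 0, 0.5 * sigma)
      # lognormal amplitude jitter with the requested CV, mean preserved
      s2 <- log(1 + spec$amplitude_cv^2)
      amps <- amp_base[j] * stats::rlnorm(n_puncta, -s2 / 2, sqrt(s2))
    }
    for (k in seq_len(n_puncta)) {
      dx <- abs(xc - x0[k])
      cols <- which(dx < 4 * sigma)
      if (length(cols) == 0) next
      dy <- abs(yc - y0[k])
      dy <- pmin(dy, H - dy)  # periodic y
      gy <- exp(-dy^2 / (2 * sigma^2))
      gx <- exp(-(xc[cols] - x0[k])^2 / (2 * sigma^2))
      m[, cols] <- m[, cols] + amps[k] * (gy %o% gx)
    }
  }
  if (!deterministic) {
    m <- m + matrix(stats::rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
    m[m < 0] <- 0
  }
  out <- list(
    intensity = m,
    pixel_size_um = px,
    interfaces = data.frame(interface_id = iface_id, x_um = iface_x,
                            stringsAsFactors = FALSE),
    spec = spec
  )
  class(out) <- "fluorescence_image"
  out
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("Synthetic fluorescence image: %d x %d px (%.2f um/px), %d interfaces\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              nrow(x$interfaces)))
  invisible(x)
}

#' Specify a circular mixture of von Mises components
#'
#' @param means_deg Component mean directions in degrees, in `[0, 360)`.
#' @param kappas Component concentrations (>= 0).
#' @param weights Component weights; together with `uniform_weight` they
#'   must sum to 1.
#' @param uniform_weight Fraction of angles drawn from the circular uniform.
#' @return A list of class `"circular_mixture"`.
#' @export
#' @examples
#' circular_mixture(c(100, 280), kappas = 2, weights = c(0.5, 0.5))
circular_mixture <- function(means_deg, kappas, weights = NULL,
                             uniform_weight = 0) {
  k <- length(means_deg)
  kappas <- rep_len(kappas, k)
  if (is.null(weights)) weights <- rep((1 - uniform_weight) / k, k)
  if (abs(sum(weights) + uniform_weight - 1) > 1e-8) {
    stop("weights and uniform_weight must sum to 1", call. = FALSE)
  }
  if (any(weights < 0) || uniform_weight < 0 || uniform_weight > 1) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (any(kappas < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(means_deg < 0 | means_deg >= 360)) {
    stop("mean directions must lie in [0, 360)", call. = FALSE)
  }
  structure(list(means_deg = means_deg, kappas = kappas,
                 weights = weights, uniform_weight = uniform_weight),
            class = "circular_mixture")
}

#' Draw angles from a circular mixture
#'
#' @param mixture A [circular_mixture()].
#' @param n Number of draws.
#' @param seed Integer seed (optional; the current RNG stream is used when
#'   `NULL`).
#' @return Numeric vector of angles in degrees in `[0, 360)`.
#' @export
sample_angles <- function(mixture, n, seed = NULL) {
  stopifnot(inherits(mixture, "circular_mixture"), n >= 0)
  old <- .restore_seed(seed)
  on.exit(old())
  probs <- c(mixture$weights, mixture$uniform_weight)
  comp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  out <- numeric(n)
  k_unif <- length(probs)
  for (i in seq_along(mixture$means_deg)) {
    sel <- comp == i
    if (any(sel)) {
      out[sel] <- .rad2deg(rvonmises(sum(sel), .deg2rad(mixture$means_deg[i]),
                                     mixture$kappas[i]))
    }
  }
  sel <- comp == k_unif
  if (any(sel)) out[sel] <- stats::runif(sum(sel), 0, 360)
  .wrap360(out)
}

#' Generate EB1 comet tracks with known direction structure
#'
#' Each comet draws a net growth direction from the supplied circular
#' mixture and advances at constant speed with small per-step angular
#' jitter, sampled at fixed frame intervals. Coordinates follow the project
#' convention (x posterior, y medial); for right-hemisegment cells the
#' stored y is mirrored, which [track_to_angle()] undoes.
#'
#' @param mixture A [circular_mixture()] of true growth directions.
#' @param n_comets Number of tracks.
#' @param frame_interval Seconds between points (imaging default 5.16 s).
#' @param steps_per_track Number of steps after the first point.
#' @param speed Growth speed in micrometres per second (angle extraction is
#'   speed-invariant).
#' @param jitter_sd_deg Per-step angular jitter around the drawn direction.
#' @param cell_id,compartment,hemisegment Metadata stored on every point.
#' @param seed Integer seed.
#' @return Data.frame with columns `track_id`, `cell_id`, `compartment`,
#'   `hemisegment`, `t_s`, `x_um`, `y_um`.
#' @export
#' @examples
#' mix <- circular_mixture(c(90, 270), 2, c(0.5, 0.5))
#' tr <- gen_comet_tracks(mix, n_comets = 5, seed = 1)
#' head(tr)
gen_comet_tracks <- function(mixture, n_comets,
                             frame_interval = 5.16,
                             steps_per_track = 6,
                             speed = 0.15,
                             jitter_sd_deg = 5,
                             cell_id = "cell_1",
                             compartment = "A",
                             hemisegment = "left",
                             seed = 1) {
  stopifnot(inherits(mixture, "circular_mixture"))
  if (n_comets <= 0) stop("n_comets must be > 0", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  hemisegment <- match.arg(hemisegment, c("left", "right"))
  old <- .restore_seed(seed)
  on.exit(old())
  dirs <- sample_angles(mixture, n_comets)
  step_len <- speed * frame_interval
  pieces <- vector("list", n_comets)
  for (i in seq_len(n_comets)) {
    th <- .deg2rad(dirs[i] + stats::rnorm(steps_per_track, 0, jitter_sd_deg))
    x <- cumsum(c(stats::runif(1, 0, 20), step_len * cos(th)))
    y <- cumsum(c(stats::runif(1, 0, 20), step_len * sin(th)))
    if (hemisegment == "right") y <- -y
    pieces[[i]] <- data.frame(
      track_id = sprintf("%s_t%04d", cell_id, i),
      cell_id = cell_id,
      compartment = compartment,
      hemisegment = hemisegment,
      t_s = frame_interval * (0:steps_per_track),
      x_um = x, y_um = y,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, pieces)
}

#' Generate a multi-cell comet dataset
#'
#' Convenience wrapper running [gen_comet_tracks()] for several cells of one
#' compartment, alternating hemisegments, as in an experiment pooling one
#' cell per larva.
#'
#' @param mixture A [circular_mixture()].
#' @param n_cells Number of cells.
#' @param comets_per_cell Comets per cell (the imaging protocol aimed for
#'   150-200).
#' @param compartment Compartment label for all cells.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param ... Passed to [gen_comet_tracks()].
#' @return Data.frame of track points across all cells.
#' @export
gen_comet_dataset <- function(mixture, n_cells = 10, comets_per_cell = 175,
                              compartment = "A", seed = 1, ...) {
  pieces <- lapply(seq_len(n_cells), function(i) {
    gen_comet_tracks(mixture, comets_per_cell,
                     cell_id = sprintf("%s_cell_%02d", compartment, i),
                     compartment = compartment,
                     hemisegment = if (i %% 2 == 0) "right" else "left",
                     seed = (as.numeric(seed) * 1000 + i) %% 2147483647, ...)
  })
  do.call(rbind, pieces)
}

#' Generate per-cell predenticle orientation records
#'
#' Emulates the raw scoring behind predenticle contingency tables: each cell
#' carries a Poisson number of predenticles (at least one), each sitting in
#' a membrane region abutting one of two neighbour classes, pointing
#' anteriorly with a class-specific probability, and scored `"unclear"` at a
#' fixed rate.
#'
#' @param n_cells Number of atypical cells.
#' @param p_anterior Named numeric vector: probability that a predenticle
#'   abutting each neighbour class points anteriorly; the names define the
#'   two neighbour classes.
#' @param mean_predenticles Mean predenticles per cell.
#' @param p_unclear Probability that an observation is unclear.
#' @param cells_per_larva Used to assign larva identifiers.
#' @param seed Integer seed.
#' @return Data.frame with columns `cell_id`, `larva_id`, `neighbour_class`,
#'   `orientation` (`"anterior"`, `"posterior"` or `"unclear"`).
#' @export
#' @examples
#' obs <- gen_predenticles(10, p_anterior = c("T1" = 0, "row 2" = 0), seed = 1)
#' table(obs$neighbour_class, obs$orientation)
gen_predenticles <- function(n_cells,
                             p_anterior,
                             mean_predenticles = 3,
                             p_unclear = 0.05,
                             cells_per_larva = 3,
                             seed = 1) {
  if (is.null(names(p_anterior)) || length(p_anterior) != 2) {
    stop("p_anterior must be a named vector of two neighbour classes",
         call. = FALSE)
  }
  if (any(p_anterior < 0 | p_anterior > 1) || p_unclear < 0 || p_unclear > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  old <- .restore_seed(seed)
  on.exit(old())
  classes <- names(p_anterior)
  pieces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    n_pd <- max(1L, stats::rpois(1, mean_predenticles))
    cls <- sample(classes, n_pd, replace = TRUE)
    u <- stats::runif(n_pd)
    orient <- ifelse(u < p_unclear, "unclear",
              ifelse(stats::runif(n_pd) < p_anterior[cls],
                     "anterior", "posterior"))
    pieces[[i]] <- data.frame(
      cell_id = sprintf("cell_%03d", i),
      larva_id = sprintf("larva_%03d", 1L + (i - 1L) %/% cells_per_larva),
      neighbour_class = cls,
      orientation = orient,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
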