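#' Sample random line profiles across an image
#'
#' Draws horizontal lines (parallel to the anteroposterior axis) of a given
#' width at independent uniform random heights and averages intensity over
#' the width, giving one intensity profile per line. Lines may overlap.
#'
#' @param image A `"fluorescence_image"` (see [gen_segment_image()] or
#'   [read_image_tiff()]).
#' @param n_lines Number of lines (protocol default 10).
#' @param width_um Averaging width in micrometres (protocol default 4).
#' @param seed Integer seed for the line heights.
#' @return Data.frame with columns `line_id`, `y_um` (line centre), `x_um`,
#'   `intensity`.
#' @export
sample_lines <- function(image, n_lines = 10, width_um = 4, seed = 1) {
  stopifnot(inherits(image, "fluorescence_image"))
  px <- image$pixel_size_um
  m <- image$intensity
  h_um <- nrow(m) * px
  if (width_um >= h_um) {
    stop("line width must be smaller than the image height", call. = FALSE)
  }
  old <- .restore_seed(seed)
  on.exit(old())
  y0 <- stats::runif(n_lines, width_um / 2, h_um - width_um / 2)
  xs <- (seq_len(ncol(m)) - 0.5) * px
  pieces <- lapply(seq_len(n_lines), function(i) {
    r0 <- max(1L, ceiling((y0[i] - width_um / 2) / px))
    r1 <- min(nrow(m), floor((y0[i] + width_um / 2) / px))
    prof <- colMeans(m[r0:r1, , drop = FALSE])
    data.frame(line_id = sprintf("line_%02d", i), y_um = y0[i],
               x_um = xs, intensity = prof, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# topographic prominence of local maxima in a numeric signal
.find_peaks_1d <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  # plateau-safe local maxima: strictly greater than the nearest differing
  # neighbours on both sides
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[j]) j <- j + 1L
      if (j < n && v[j + 1] < v[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

.prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l) > 0) {
      min(v[(max(higher_l) + 1):(p - 1)])
    } else {
      min(left)
    }
    right <- v[(p + 1):length(v)]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r) > 0) {
      min(v[(p + 1):(p + min(higher_r) - 1)])
    } else {
      min(right)
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Find peaks in line profiles
#'
#' Local maxima of each profile whose topographic prominence is at least
#' `min_prominence` times the profile's intensity range; profiles show such
#' peaks where a line crosses a cell boundary. A flat profile yields no
#' peaks.
#'
#' @param profiles Data.frame from [sample_lines()] (columns `line_id`,
#'   `x_um`, `intensity`).
#' @param min_prominence Prominence threshold as a fraction of each
#'   profile's range (default 0.1).
#' @return Data.frame with columns `line_id`, `x_um`, `height`,
#'   `prominence`.
#' @export
find_profile_peaks <- function(profiles, min_prominence = 0.1) {
  stopifnot(all(c("line_id", "x_um", "intensity") %in% names(profiles)))
  pieces <- lapply(split(profiles, profiles$line_id), function(pr) {
    pr <- pr[order(pr$x_um), ]
    v <- pr$intensity
    rng <- diff(range(v))
    if (rng == 0) return(NULL)
    pk <- .find_peaks_1d(v)
    if (length(pk) == 0) return(NULL)
    prom <- .prominence(v, pk)
    keep <- prom >= min_prominence * rng
    if (!any(keep)) return(NULL)
    data.frame(line_id = pr$line_id[1], x_um = pr$x_um[pk][keep],
               height = v[pk][keep], prominence = prom[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(line_id = character(0), x_um = numeric(0),
                      height = numeric(0), prominence = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Assign profile peaks to cellular interfaces
#'
#' Each peak is assigned to the nearest annotated interface within
#' `tolerance_um`, otherwise left unassigned. When several peaks of the
#' same line land on one interface only the highest is kept.
#'
#' @param peaks Data.frame from [find_profile_peaks()].
#' @param interfaces Data.frame with columns `interface_id`, `x_um`.
#' @param tolerance_um Maximum peak-to-interface distance; defaults to half
#'   the minimum interface spacing.
#' @return The peaks with an added `interface_id` column (`NA` when
#'   unassigned), duplicates per line and interface resolved.
#' @export
assign_peaks <- function(peaks, interfaces, tolerance_um = NULL) {
  if (is.null(tolerance_um)) {
    spacing <- diff(sort(interfaces$x_um))
    tolerance_um <- if (length(spacing) > 0) min(spacing) / 2 else Inf
  }
  if (tolerance_um <= 0) stop("tolerance must be positive", call. = FALSE)
  if (nrow(peaks) == 0) {
    peaks$interface_id <- character(0)
    return(peaks)
  }
  d <- abs(outer(peaks$x_um, interfaces$x_um, "-"))
  j <- apply(d, 1, which.min)
  dist <- d[cbind(seq_len(nrow(peaks)), j)]
  peaks$interface_id <- ifelse(dist <= tolerance_um,
                               interfaces$interface_id[j], NA_character_)
  # keep only the highest peak per line per interface
  assigned <- !is.na(peaks$interface_id)
  key <- paste(peaks$line_id, peaks$interface_id)
  ord <- order(-peaks$height)
  dup <- duplicated(key[ord]) & assigned[ord]
  keep <- rep(TRUE, nrow(peaks))
  keep[ord][dup] <- FALSE
  out <- peaks[keep, ]
  rownames(out) <- NULL
  out
}

#' Summarize assigned peaks per interface
#'
#' Mean peak height per interface over the lines that measured it, retained
#' only for interfaces intersected by at least `min_lines` lines (protocol
#' rule: 3). Normalized means divide by the mean of the image's retained
#' interface means ("mean of means"), so the normalized values of one image
#' always average to 1.
#'
#' @param assigned Data.frame from [assign_peaks()].
#' @param image_id Identifier recorded in the output.
#' @param min_lines Minimum number of distinct lines per interface.
#' @return Data.frame with columns `image_id`, `interface_id`, `n_lines`,
#'   `mean_raw`, `mean_normalized`.
#' @export
summarize_interfaces <- function(assigned, image_id = "image_1", min_lines = 3) {
  ok <- assigned[!is.na(assigned$interface_id), ]
  if (nrow(ok) == 0) {
    warning("no assigned peaks; empty summary")
    return(data.frame(image_id = character(0), interface_id = character(0),
                      n_lines = integer(0), mean_raw = numeric(0),
                      mean_normalized = numeric(0)))
  }
  agg <- stats::aggregate(ok$height, by = list(interface_id = ok$interface_id),
                          FUN = mean)
  names(agg)[2] <- "mean_raw"
  nl <- stats::aggregate(ok$line_id, by = list(interface_id = ok$interface_id),
                         FUN = function(z) length(unique(z)))
  agg$n_lines <- nl$x[match(agg$interface_id, nl$interface_id)]
  agg <- agg[agg$n_lines >= min_lines, ]
  if (nrow(agg) == 0) {
    warning("no interface intersected by >= ", min_lines, " lines; empty summary")
    return(data.frame(image_id = character(0), interface_id = character(0),
                      n_lines = integer(0), mean_raw = numeric(0),
                      mean_normalized = numeric(0)))
  }
  agg$mean_normalized <- agg$mean_raw / mean(agg$mean_raw)
  out <- data.frame(image_id = image_id, interface_id = agg$interface_id,
                    n_lines = agg$n_lines, mean_raw = agg$mean_raw,
                    mean_normalized = agg$mean_normalized,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Quantify one image end to end
#'
#' Runs [sample_lines()], [find_profile_peaks()], [assign_peaks()] (against
#' the image's annotated interfaces) and [summarize_interfaces()].
#'
#' @param image A `"fluorescence_image"`.
#' @param image_id Identifier for the output.
#' @param n_lines,width_um,seed Passed to [sample_lines()].
#' @param min_prominence Passed to [find_profile_peaks()].
#' @param tolerance_um Passed to [assign_peaks()].
#' @param min_lines Passed to [summarize_interfaces()].
#' @return Per-interface summary data.frame.
#' @export
quantify_image <- function(image, image_id = "image_1", n_lines = 10,
                           width_um = 4, min_prominence = 0.1,
                           tolerance_um = NULL, min_lines = 3, seed = 1) {
  profiles <- sample_lines(image, n_lines = n_lines, width_um = width_um,
                           seed = seed)
  peaks <- find_profile_peaks(profiles, min_prominence = min_prominence)
  assigned <- assign_peaks(peaks, image$interfaces, tolerance_um = tolerance_um)
  summarize_interfaces(assigned, image_id = image_id, min_lines = min_lines)
}

# compact letter display by insert-and-absorb on a logical "significantly
# different" matrix; returns a character vector of letter strings
.letter_display <- function(diff_mat, order_by = NULL) {
  g <- rownames(diff_mat)
  n <- length(g)
  cols <- list(rep(TRUE, n))  # start: one letter containing all groups
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a == b || drop[a] || drop[b]) next
        subset_b <- all(!cols[[b]] | cols[[a]])
        if (subset_b && (!identical(cols[[a]], cols[[b]]) || a < b)) {
          drop[b] <- TRUE
        }
      }
    }
    cols[!drop]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || !diff_mat[i, j]) next
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          # duplicate the offending letter, dropping one group from each copy
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          newcols <- c(newcols, list(c1, c2))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      cols <- absorb(newcols)
    }
  }
  if (!is.null(order_by)) {
    # order letter columns by the best-ranked member each contains
    rank_first <- vapply(cols, function(col) {
      min(rank(-order_by)[col])
    }, numeric(1))
    cols <- cols[order(rank_first)]
  }
  letters_vec <- vapply(seq_along(g), function(i) {
    paste0(letters[which(vapply(cols, function(col) col[i], logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(letters_vec, g)
}

#' Tukey comparison of normalized interface means across images
#'
#' One-way layout with the interface as group and each image's normalized
#' interface mean as one observation; all pairwise contrasts are tested
#' with Tukey's honest significant difference, and a compact letter display
#' is built by insert-and-absorb so that interfaces sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param summaries Row-bound output of [quantify_image()] /
#'   [summarize_interfaces()] over several images.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param value Observation column (default `"mean_normalized"`).
#' @return List of class `"tukey_result"` with elements `tukey` (pairwise
#'   contrasts: `contrast`, `diff`, `lwr`, `upr`, `p_adj`), `letters`
#'   (per-interface letters and group means), `fit` (the `aov` object).
#' @export
tukey_compare <- function(summaries, alpha = 0.05, value = "mean_normalized") {
  stopifnot(value %in% names(summaries))
  counts <- table(summaries$interface_id)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping interface(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    summaries <- summaries[!summaries$interface_id %in% small, ]
  }
  if (length(unique(summaries$interface_id)) < 2) {
    stop("need at least 2 interfaces with >= 2 observations", call. = FALSE)
  }
  d <- data.frame(y = summaries[[value]],
                  interface_id = factor(summaries$interface_id))
  fit <- stats::aov(y ~ interface_id, data = d)
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$interface_id
  groups <- levels(d$interface_id)
  # TukeyHSD lists the lower triangle in column-major order; rebuild the
  # pairs from the levels rather than parsing contrast labels (interface
  # ids may themselves contain "-")
  idx <- which(lower.tri(matrix(0, length(groups), length(groups))),
               arr.ind = TRUE)
  tk <- data.frame(contrast = rownames(th),
                   group_a = groups[idx[, 1]], group_b = groups[idx[, 2]],
                   diff = th[, "diff"], lwr = th[, "lwr"], upr = th[, "upr"],
                   p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  rownames(tk) <- NULL
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_len(nrow(tk))) {
    a <- tk$group_a[i]; b <- tk$group_b[i]
    sig[a, b] <- sig[b, a] <- tk$p_adj[i] < alpha
  }
  means <- tapply(d$y, d$interface_id, mean)
  lett <- .letter_display(sig, order_by = as.numeric(means))
  letters_df <- data.frame(interface_id = groups, mean = as.numeric(means[groups]),
                           letters = unname(lett[groups]),
                           stringsAsFactors = FALSE)
  structure(list(tukey = tk, letters = letters_df, fit = fit, alpha = alpha),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD over", nrow(x$letters), "interfaces\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}

#' Per-row asymmetry of flanking interface intensities
#'
#' For every cell row with both flanking interfaces measured, the signed
#' difference (posterior-interface mean minus anterior-interface mean) of
#' normalized fluorescence, with the Tukey 95% interval and adjusted
#' p-value of that pairwise contrast; a row is flagged significant when the
#' interval excludes zero. A positive difference means more Ds on the
#' row's posterior side.
#'
#' @param summaries Pooled per-image interface summaries.
#' @param row_ids Cell-row order defining the interface map (default: the
#'   seventeen-row segment).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with columns `row_id`, `anterior_interface`,
#'   `posterior_interface`, `diff`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
row_asymmetry <- function(summaries, row_ids = segment_rows()$row_id,
                          alpha = 0.05) {
  tr <- tukey_compare(summaries, alpha = alpha)
  tk <- tr$tukey
  present <- tr$letters$interface_id
  n <- length(row_ids)
  iface <- paste(row_ids[-n], row_ids[-1], sep = "/")
  rows <- list()
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next  # outermost rows lack one flank
    ant <- iface[i - 1]
    post <- iface[i]
    if (!(ant %in% present) || !(post %in% present)) {
      warning("row ", row_ids[i], " skipped: flanking interface not measured")
      next
    }
    hit <- which(tk$group_a == post & tk$group_b == ant)
    flip <- 1
    if (length(hit) == 0) {
      hit <- which(tk$group_a == ant & tk$group_b == post)
      flip <- -1
    }
    est <- flip * tk$diff[hit]
    ci <- if (flip == 1) c(tk$lwr[hit], tk$upr[hit]) else
      -c(tk$upr[hit], tk$lwr[hit])
    rows[[length(rows) + 1]] <- data.frame(
      row_id = row_ids[i], anterior_interface = ant, posterior_interface = post,
      diff = est, lwr = ci[1], upr = ci[2], p_adj = tk$p_adj[hit],
      significant = ci[1] > 0 | ci[2] < 0,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
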