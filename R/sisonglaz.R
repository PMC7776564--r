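# Central and factorial moments of a Poisson(lambda) truncated to
# [lambda - c, lambda + c], plus its probability mass; the building block of
# the Sison-Glaz joint coverage approximation.
.sg_moments <- function(c, lambda) {
  a <- lambda + c
  b <- max(lambda - c, 0)
  den <- if (lambda > 0) stats::ppois(a, lambda) - stats::ppois(b - 1, lambda) else 1
  mu <- numeric(4)
  for (r in 1:4) {
    poisA <- if ((a - r) >= 0) {
      stats::ppois(a, lambda) - stats::ppois(a - r, lambda)
    } else {
      stats::ppois(a, lambda)
    }
    poisB <- if ((b - r - 1) >= 0) {
      stats::ppois(b - 1, lambda) - stats::ppois(b - r - 1, lambda)
    } else {
      stats::ppois(b - 1, lambda)
    }
    mu[r] <- lambda^r * (1 - (poisA - poisB) / den)
  }
  m1 <- mu[1]
  m2 <- mu[2] + mu[1] - mu[1]^2
  m3 <- mu[3] + mu[2] * (3 - 3 * mu[1]) + (mu[1] - 3 * mu[1]^2 + 2 * mu[1]^3)
  m4 <- mu[4] + mu[3] * (6 - 4 * mu[1]) +
    mu[2] * (7 - 12 * mu[1] + 6 * mu[1]^2) +
    mu[1] - 4 * mu[1]^2 + 6 * mu[1]^3 - 3 * mu[1]^4
  c(m1, m2, m3, m4, den)
}

# Edgeworth-corrected approximation to the joint probability that every
# category count lies within +/- c of its observed value, conditional on the
# total: the truncated-Poisson representation of the multinomial.
.sg_coverage <- function(c, x, n) {
  k <- length(x)
  m <- t(vapply(x, function(xi) .sg_moments(c, xi), numeric(5)))
  m[, 4] <- m[, 4] - 3 * m[, 2]^2  # to cumulant form
  s <- colSums(m[, 1:4, drop = FALSE])
  s1 <- s[1]; s2 <- s[2]; s3 <- s[3]; s4 <- s[4]
  if (!is.finite(s2) || s2 <= 0) return(0)  # degenerate truncation (c = 0)
  probn <- 1 / (stats::ppois(n, n) - stats::ppois(n - 1, n))
  z <- (n - s1) / sqrt(s2)
  g1 <- s3 / s2^(3 / 2)
  g2 <- s4 / s2^2
  poly <- 1 + g1 * (z^3 - 3 * z) / 6 +
    g2 * (z^4 - 6 * z^2 + 3) / 24 +
    g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72
  f <- poly * exp(-z^2 / 2) / sqrt(2 * pi * s2)
  unname(probn * prod(m[, 5]) * f)
}

#' Sison-Glaz simultaneous confidence intervals for multinomial proportions
#'
#' Simultaneous intervals for the category proportions of a multinomial
#' sample. The half-width `c` is the largest integer whose approximate
#' joint coverage (computed through the truncated-Poisson representation
#' with an Edgeworth-corrected central term) is still below `1 - alpha`;
#' linear interpolation towards `c + 1` supplies the fractional widening
#' `2 * gamma / n` of the upper limits. Intervals are
#' `[max(0, p_i - c/n), min(1, p_i + c/n + 2*gamma/n)]`.
#'
#' @param counts Non-negative integer counts per category (e.g. a
#'   [quadrant_counts()] result); `n = sum(counts)` must be positive.
#' @param alpha Simultaneous miscoverage level (default 0.05).
#' @return Data.frame with columns `category`, `count`, `estimate`,
#'   `lower`, `upper`; the selected `c` and interpolation `gamma` are kept
#'   as attributes.
#' @export
#' @examples
#' sison_glaz_ci(c(anterior = 10, posterior = 20, medial = 30, lateral = 40))
sison_glaz_ci <- function(counts, alpha = 0.05) {
  x <- as.integer(round(counts))
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(x)
  if (n == 0) stop("total count must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  p_hat <- x / n

  cc <- 1L
  nu_prev <- .sg_coverage(0L, x, n)
  repeat {
    nu <- .sg_coverage(cc, x, n)
    if (nu > 1 - alpha || cc >= n) break
    nu_prev <- nu
    cc <- cc + 1L
  }
  gamma <- ((1 - alpha) - nu_prev) / (nu - nu_prev)
  c_sel <- cc - 1L
  lower <- pmax(0, p_hat - c_sel / n)
  upper <- pmin(1, p_hat + c_sel / n + 2 * gamma / n)
  nms <- if (!is.null(names(counts))) names(counts) else
    paste0("cat", seq_along(x))
  out <- data.frame(category = nms, count = x, estimate = p_hat,
                    lower = lower, upper = upper, stringsAsFactors = FALSE)
  attr(out, "c") <- c_sel
  attr(out, "gamma") <- gamma
  attr(out, "alpha") <- alpha
  out
}
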