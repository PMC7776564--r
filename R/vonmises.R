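# log density of the von Mises distribution, stable for large kappa:
# log I0(kappa) computed via the exponentially scaled Bessel function.
.log_dvm <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

#' von Mises random deviates
#'
#' Best-Fisher rejection sampler; reduces to the circular uniform for
#' `kappa` near zero.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling(1.3 * (n - length(out))) + 5L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok]))))
  }
  (out[seq_len(n)] + mu) %% (2 * pi)
}

# moment estimate of kappa from the mean resultant length (standard
# three-regime approximation)
.kappa_from_rbar <- function(rbar) {
  if (rbar < 1e-12) return(0)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

# circular sample mean direction and resultant length
.circ_moments <- function(theta) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  list(mu = atan2(S, C) %% (2 * pi), rbar = sqrt(C^2 + S^2))
}

.vm_models <- c("M_uniform", "M_vonmises", "M_axial_equal",
                "M_axial_weighted", "M_bimodal_free")

# per-model log-likelihood on natural parameters
# par layouts: vonmises (mu, kappa); axial_equal (mu, kappa);
# axial_weighted (mu, kappa, w); bimodal_free (mu1, mu2, k1, k2, w)
.model_loglik <- function(model, theta, par) {
  switch(model,
    M_uniform = -length(theta) * log(2 * pi),
    M_vonmises = sum(.log_dvm(theta, par[1], par[2])),
    M_axial_equal = {
      d <- 0.5 * exp(.log_dvm(theta, par[1], par[2])) +
           0.5 * exp(.log_dvm(theta, par[1] + pi, par[2]))
      sum(log(d))
    },
    M_axial_weighted = {
      d <- par[3] * exp(.log_dvm(theta, par[1], par[2])) +
           (1 - par[3]) * exp(.log_dvm(theta, par[1] + pi, par[2]))
      sum(log(d))
    },
    M_bimodal_free = {
      d <- par[5] * exp(.log_dvm(theta, par[1], par[3])) +
           (1 - par[5]) * exp(.log_dvm(theta, par[2], par[4]))
      sum(log(d))
    }
  )
}

.model_npar <- c(M_uniform = 0L, M_vonmises = 2L, M_axial_equal = 2L,
                 M_axial_weighted = 3L, M_bimodal_free = 5L)

# optimisation on transformed scale: kappa = exp(s) capped at kappa_max,
# w = plogis(t); mean directions unconstrained (wrapped by the density)
.fit_one_model <- function(model, theta, starts, kappa_max) {
  n <- length(theta)
  if (model == "M_uniform") {
    return(list(model = model, par = numeric(0),
                logL = -n * log(2 * pi), convergence = 0L))
  }
  to_nat <- function(p) {
    switch(model,
      M_vonmises = c(p[1] %% (2 * pi), min(exp(p[2]), kappa_max)),
      M_axial_equal = c(p[1] %% (2 * pi), min(exp(p[2]), kappa_max)),
      M_axial_weighted = c(p[1] %% (2 * pi), min(exp(p[2]), kappa_max),
                           stats::plogis(p[3])),
      M_bimodal_free = c(p[1] %% (2 * pi), p[2] %% (2 * pi),
                         min(exp(p[3]), kappa_max), min(exp(p[4]), kappa_max),
                         stats::plogis(p[5]))
    )
  }
  nll <- function(p) {
    ll <- .model_loglik(model, theta, to_nat(p))
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(model = model, par = to_nat(best$par), logL = -best$value,
       convergence = best$convergence)
}

# start values on the transformed scale for each model
.model_starts <- function(model, theta, n_restarts, fits) {
  mom <- .circ_moments(theta)
  # axial moments: mean of doubled angles locates an axis
  mom2 <- .circ_moments(2 * theta)
  axis_mu <- mom2$mu / 2
  k1 <- max(.kappa_from_rbar(mom$rbar), 0.05)
  k2 <- max(.kappa_from_rbar(mom2$rbar), 0.05)
  rnd <- function() {
    mu <- stats::runif(1, 0, 2 * pi)
    lk <- log(sample(c(0.5, 2, 8), 1))
    switch(model,
      M_vonmises = c(mu, lk),
      M_axial_equal = c(mu, lk),
      M_axial_weighted = c(mu, lk, stats::qlogis(stats::runif(1, 0.2, 0.8))),
      M_bimodal_free = c(mu, stats::runif(1, 0, 2 * pi), lk,
                         log(sample(c(0.5, 2, 8), 1)),
                         stats::qlogis(stats::runif(1, 0.2, 0.8)))
    )
  }
  det <- switch(model,
    M_vonmises = list(c(mom$mu, log(k1))),
    M_axial_equal = list(c(axis_mu, log(k2)), c(mom$mu, log(k1))),
    M_axial_weighted = {
      s <- list(c(axis_mu, log(k2), 0))
      if (!is.null(fits$M_axial_equal)) {
        p <- fits$M_axial_equal$par
        s <- c(s, list(c(p[1], log(max(p[2], 1e-3)), 0)))
      }
      s
    },
    M_bimodal_free = {
      s <- list(c(axis_mu, axis_mu + pi, log(k2), log(k2), 0))
      if (!is.null(fits$M_axial_weighted)) {
        p <- fits$M_axial_weighted$par
        s <- c(s, list(c(p[1], p[1] + pi, log(max(p[2], 1e-3)),
                         log(max(p[2], 1e-3)), stats::qlogis(min(max(p[3], 0.02), 0.98)))))
      }
      if (!is.null(fits$M_vonmises)) {
        p <- fits$M_vonmises$par
        s <- c(s, list(c(p[1], p[1] + pi, log(max(p[2], 1e-3)), log(0.5),
                         stats::qlogis(0.95))))
      }
      s
    }
  )
  c(det, replicate(n_restarts, rnd(), simplify = FALSE))
}

#' Fit and rank circular models for an angle sample
#'
#' Fits, by numerical maximum likelihood with multiple restarts, a ladder of
#' circular models: uniform; unimodal von Mises; axial bimodal (modes 180
#' degrees apart, equal weights, shared concentration); weighted axial
#' bimodal; and a free two-component von Mises mixture. Models are ranked by
#' AIC (`2k - 2 logL`), lowest first. Nested solutions are reused as start
#' values for the larger models, so the fitted log-likelihoods respect the
#' model nesting.
#'
#' @param angles_deg Angles in degrees.
#' @param models Subset of model identifiers to fit.
#' @param n_restarts Random restarts per model in addition to deterministic
#'   moment-based starts.
#' @param kappa_max Upper bound on fitted concentrations.
#' @param seed Master seed for the random restarts.
#' @return An object of class `"circular_model_set"`: a data.frame with one
#'   row per model (`model`, `k`, `logL`, `AIC`, `delta_AIC`, parameter
#'   columns `mu1_deg`, `mu2_deg`, `kappa1`, `kappa2`, `w1`), ranked by AIC;
#'   full fits in `attr(x, "fits")`.
#' @export
#' @examples
#' mix <- circular_mixture(90, kappas = 2, weights = 1)
#' a <- sample_angles(mix, 300, seed = 1)
#' fits <- fit_circular_models(a, n_restarts = 5, seed = 1)
#' fits$model[1]
fit_circular_models <- function(angles_deg,
                                models = .vm_models,
                                n_restarts = 20,
                                kappa_max = 500,
                                seed = 1) {
  models <- match.arg(models, .vm_models, several.ok = TRUE)
  if (length(angles_deg) < 10) {
    stop("need at least 10 angles to fit circular models", call. = FALSE)
  }
  theta <- .deg2rad(.wrap360(angles_deg))
  old <- .restore_seed(seed)
  on.exit(old())
  fits <- list()
  for (m in intersect(.vm_models, models)) {  # small models first
    if (m == "M_uniform") {
      fits[[m]] <- .fit_one_model(m, theta, list(), kappa_max)
      next
    }
    starts <- .model_starts(m, theta, n_restarts, fits)
    f <- .fit_one_model(m, theta, starts, kappa_max)
    if (is.null(f)) {
      warning("model ", m, " failed to converge and was excluded")
      next
    }
    fits[[m]] <- f
  }
  rows <- lapply(fits, function(f) {
    k <- .model_npar[[f$model]]
    p <- f$par
    par_row <- switch(f$model,
      M_uniform = c(NA, NA, NA, NA, NA),
      M_vonmises = c(.rad2deg(p[1]), NA, p[2], NA, 1),
      M_axial_equal = c(.rad2deg(p[1]), .rad2deg((p[1] + pi) %% (2 * pi)),
                        p[2], p[2], 0.5),
      M_axial_weighted = c(.rad2deg(p[1]), .rad2deg((p[1] + pi) %% (2 * pi)),
                           p[2], p[2], p[3]),
      M_bimodal_free = c(.rad2deg(p[1]), .rad2deg(p[2]), p[3], p[4], p[5])
    )
    data.frame(model = f$model, k = k, logL = f$logL,
               AIC = 2 * k - 2 * f$logL,
               mu1_deg = .wrap360(par_row[1]), mu2_deg = .wrap360(par_row[2]),
               kappa1 = par_row[3], kappa2 = par_row[4], w1 = par_row[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), ]
  out$delta_AIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "n") <- length(theta)
  class(out) <- c("circular_model_set", "data.frame")
  out
}

#' @export
print.circular_model_set <- function(x, ...) {
  need <- c("model", "k", "logL", "AIC", "delta_AIC",
            "mu1_deg", "mu2_deg", "kappa1", "kappa2", "w1")
  if (!all(need %in% names(x))) {
    return(invisible(print.data.frame(x, ...)))
  }
  cat("Circular model selection (n = ", attr(x, "n"), " angles)\n", sep = "")
  print.data.frame(cbind(x[, c("model", "k", "logL", "AIC", "delta_AIC")],
                         round(x[, c("mu1_deg", "mu2_deg", "kappa1", "kappa2", "w1")], 2)),
                   row.names = FALSE, digits = 6)
  invisible(x)
}

#' Deviation of fitted modes from the mediolateral axis
#'
#' Reports, for each mode of a fitted circular model, the signed angular
#' deviation from the nearest mediolateral direction (90 or 270 degrees).
#' The sign is positive when the mode is tilted from the axis towards the
#' anterior direction (180 degrees): mode 100 gives +10, mode 80 gives -10,
#' mode 270 gives 0.
#'
#' @param fit A `"circular_model_set"` (its best model is used) or a single
#'   model name present in the set via `model`.
#' @param model Optional model id to report instead of the AIC-best model.
#' @return Data.frame with columns `model`, `mode_deg`, `nearest_axis_deg`,
#'   `deviation_deg`; zero rows for the uniform model.
#' @export
mode_deviation <- function(fit, model = NULL) {
  stopifnot(inherits(fit, "circular_model_set"))
  row <- if (is.null(model)) fit[1, ] else fit[fit$model == model, ]
  if (nrow(row) == 0) stop("model not present in fit", call. = FALSE)
  if (row$model == "M_uniform") {
    return(data.frame(model = character(0), mode_deg = numeric(0),
                      nearest_axis_deg = numeric(0), deviation_deg = numeric(0)))
  }
  modes <- c(row$mu1_deg, row$mu2_deg)
  modes <- modes[!is.na(modes)]
  nearest <- ifelse(abs(.wrap180(modes - 90)) <= abs(.wrap180(modes - 270)),
                    90, 270)
  dev <- ifelse(nearest == 90, .wrap180(modes - 90), .wrap180(270 - modes))
  data.frame(model = row$model, mode_deg = modes, nearest_axis_deg = nearest,
             deviation_deg = dev, stringsAsFactors = FALSE)
}
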