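#' Validate a set of kinetic rate constants
#'
#' The two-compartment model describes a gene by four rate constants:
#' initiation \code{k_init} (RNAP/min, entry into the pause region),
#' premature termination \code{k_pre} (1/min, dissociation of a paused
#' polymerase), pause release \code{k_rel} (1/min, escape into productive
#' elongation) and elongation \code{k_elong} (bp/min, travel through the
#' gene body). All rates must be non-negative.
#'
#' @param k_init Initiation rate, RNAP per minute.
#' @param k_pre Premature termination rate constant, per minute.
#' @param k_rel Pause release rate constant, per minute.
#' @param k_elong Elongation rate, bp per minute.
#' @return A named list of class \code{rate_set}.
#' @export
#' @examples
#' rate_set(k_init = 0.5, k_pre = 1.7, k_rel = 0.25, k_elong = 2000)
rate_set <- function(k_init, k_pre, k_rel, k_elong) {
  vals <- c(k_init = k_init, k_pre = k_pre, k_rel = k_rel,
            k_elong = k_elong)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(vals), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(
    "kinetic rates: k_init=%g RNAP/min, k_pre=%g /min, k_rel=%g /min, k_elong=%g bp/min\n",
    x$k_init, x$k_pre, x$k_rel, x$k_elong))
  invisible(x)
}

#' Steady-state pause and body densities
#'
#' At steady state the pause density is \code{p = k_init/(k_pre + k_rel)}
#' and the mean gene-body density is \code{b = (k_rel/k_elong) * p}.
#'
#' @param rates A \code{\link{rate_set}}, or k_init when the individual
#'   rates are given.
#' @param k_pre,k_rel,k_elong Individual rates, used when \code{rates} is
#'   the numeric k_init.
#' @return List with elements \code{p} (pause density, RNAP per pause
#'   region when occupancy-scaled) and \code{b} (body density per bp).
#' @export
#' @examples
#' steady_state(rate_set(0.5, 1.7, 0.25, 2000))
steady_state <- function(rates, k_pre = NULL, k_rel = NULL,
                         k_elong = NULL) {
  r <- as_rate_args(rates, k_pre, k_rel, k_elong)
  if (r$k_pre + r$k_rel <= 0) {
    stop("degenerate steady state: k_pre + k_rel must be > 0",
         call. = FALSE)
  }
  if (r$k_elong <= 0) {
    stop("k_elong must be > 0 to define a body density", call. = FALSE)
  }
  p <- r$k_init / (r$k_pre + r$k_rel)
  list(p = p, b = r$k_rel / r$k_elong * p)
}

as_rate_args <- function(rates, k_pre, k_rel, k_elong) {
  if (inherits(rates, "rate_set")) return(rates)
  rate_set(rates, k_pre, k_rel, k_elong)
}

#' Closed-form trajectory of pause and body densities
#'
#' Integrates the coupled linear system
#' \code{dp/dt = k_init - (k_pre + k_rel) p},
#' \code{db/dt = k_rel p - k_elong b}
#' exactly. The system is linear with constant coefficients, so the
#' solution is a sum of exponentials and no numeric stepping (or step-size
#' tolerance) is involved; \code{step} only controls the reported grid.
#'
#' @param rates A \code{\link{rate_set}}.
#' @param p0,b0 Initial pause and body densities (>= 0).
#' @param duration Total time, minutes (> 0).
#' @param step Output grid spacing, minutes (> 0).
#' @return A data.frame with columns \code{time}, \code{p}, \code{b}.
#' @export
#' @examples
#' tr <- simulate_pause_body(rate_set(0.5, 1.7, 0.25, 2000), 0, 0, 60, 1)
#' tail(tr, 1)  # converged to the steady state
simulate_pause_body <- function(rates, p0, b0, duration, step = duration / 100) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.finite(p0) || !is.finite(b0) || p0 < 0 || b0 < 0) {
    stop("initial densities must be finite and >= 0", call. = FALSE)
  }
  if (duration <= 0 || step <= 0) {
    stop("duration and step must be > 0", call. = FALSE)
  }
  tt <- seq(0, duration, by = step)
  if (tt[length(tt)] < duration) tt <- c(tt, duration)
  a <- rates$k_pre + rates$k_rel

  if (a > 0) {
    p_ss <- rates$k_init / a
    p <- p_ss + (p0 - p_ss) * exp(-a * tt)
  } else {
    p <- p0 + rates$k_init * tt
  }

  ke <- rates$k_elong
  kr <- rates$k_rel
  if (ke > 0 && a > 0) {
    b_ss <- kr * (rates$k_init / a) / ke
    dp0 <- p0 - rates$k_init / a
    if (abs(ke - a) > 1e-12 * max(ke, a)) {
      c2 <- kr * dp0 / (ke - a)
      c1 <- b0 - b_ss - c2
      b <- b_ss + c2 * exp(-a * tt) + c1 * exp(-ke * tt)
    } else {
      # degenerate eigenvalues: resonance term t * exp(-a t)
      b <- b_ss + kr * dp0 * tt * exp(-a * tt) + (b0 - b_ss) * exp(-a * tt)
    }
  } else if (ke > 0) {
    # a == 0: p grows linearly, forced first-order decay in b
    beta <- kr * rates$k_init / ke
    alpha <- (kr * p0 - beta) / ke
    b <- alpha + beta * tt + (b0 - alpha) * exp(-ke * tt)
  } else if (a > 0) {
    # no elongation: b accumulates the released flux
    p_ss <- rates$k_init / a
    b <- b0 + kr * (p_ss * tt + (p0 - p_ss) * (1 - exp(-a * tt)) / a)
  } else {
    b <- b0 + kr * (p0 * tt + rates$k_init * tt^2 / 2)
  }
  data.frame(time = tt, p = p, b = b)
}

#' Fold change in pause release rate between conditions
#'
#' The fold change in pause release equals the inverse of the fold change
#' in pausing index: \code{fc(k_rel) = fc(b) / fc(p)}. It is independent
#' of normalization because any common scale cancels in the ratio.
#'
#' @param fc_b Fold change (treatment/control) in body density.
#' @param fc_p Fold change (treatment/control) in pause density.
#' @return Fold change in k_rel. Vectorized.
#' @export
fold_change_pause_release <- function(fc_b, fc_p) {
  check_positive(fc_b, "fc_b")
  check_positive(fc_p, "fc_p")
  fc_b / fc_p
}

#' Bounds on the fold change in initiation rate
#'
#' The fold change in initiation lies between the fold change in pause
#' density (attained when premature termination dominates, k_pre >> k_rel)
#' and the fold change in body density (attained when pause release
#' dominates, k_pre << k_rel). Which bound is lower depends on the gene.
#'
#' @param fc_p,fc_b Fold changes in pause and body density.
#' @return List with vectors \code{lower} and \code{upper}.
#' @export
fold_change_initiation_bounds <- function(fc_p, fc_b) {
  check_positive(fc_p, "fc_p")
  check_positive(fc_b, "fc_b")
  list(lower = pmin(fc_p, fc_b), upper = pmax(fc_p, fc_b))
}

#' Fold change in initiation at a known termination/release ratio
#'
#' With \code{r = k_pre / k_rel(control)} assumed constant between
#' conditions, the exact fold change in initiation is
#' \code{fc_p * (r + fc_krel) / (r + 1)}. The limits r -> Inf and r -> 0
#' recover the pause-density and body-density bounds respectively.
#'
#' @param fc_p Fold change in pause density.
#' @param fc_krel Fold change in pause release rate.
#' @param r Ratio k_pre / k_rel in the control condition (>= 0).
#' @return Fold change in k_init. Vectorized.
#' @export
fold_change_initiation_given_ratio <- function(fc_p, fc_krel, r) {
  check_positive(fc_p, "fc_p")
  check_positive(fc_krel, "fc_krel")
  if (any(is.nan(r)) || any(r < 0)) {
    stop("r must be >= 0", call. = FALSE)
  }
  n <- max(length(fc_p), length(fc_krel), length(r))
  fc_p <- rep_len(fc_p, n)
  fc_krel <- rep_len(fc_krel, n)
  r <- rep_len(r, n)
  out <- fc_p * (r + fc_krel) / (r + 1)
  out[is.infinite(r)] <- fc_p[is.infinite(r)]
  out
}

#' Absolute pause release rate from densities
#'
#' \code{k_rel = k_elong * b / p}. Because only the body-to-pause ratio
#' enters, the result is invariant to any common scaling of p and b and
#' thus does not require occupancy calibration.
#'
#' @param k_elong Elongation rate, bp/min.
#' @param p Pause density (summed signal over the pause window).
#' @param b Body density (mean signal per bp).
#' @return k_rel in 1/min. Vectorized.
#' @export
pause_release_rate <- function(k_elong, p, b) {
  check_positive(k_elong, "k_elong")
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be >= 0", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("undefined rate: pause density p must be > 0", call. = FALSE)
  }
  k_elong * b / p
}

#' Absolute initiation rate from occupancy-scaled densities
#'
#' \code{k_init = p * k_pre + k_elong * b}. Unlike the fold changes, the
#' absolute initiation rate depends on the absolute number of polymerases
#' in each compartment, so \code{p} and \code{b} must be occupancy-scaled
#' (p in RNAP per pause region, at most 1; b in RNAP per bp). Calling this
#' on unscaled signal is a contract violation and raises an error.
#'
#' @param p Occupancy-scaled pause density, 0..1.
#' @param b Occupancy-scaled body density, RNAP per bp.
#' @param k_pre Premature termination rate, 1/min.
#' @param k_elong Elongation rate, bp/min.
#' @param scaled Assertion by the caller that densities are
#'   occupancy-scaled. Records produced by \code{\link{scale_to_occupancy}}
#'   satisfy this.
#' @return k_init in RNAP/min. Vectorized.
#' @export
initiation_rate <- function(p, b, k_pre, k_elong, scaled = TRUE) {
  if (!isTRUE(scaled)) {
    stop("initiation_rate requires occupancy-scaled densities ",
         "(absolute k_init is meaningless on arbitrary signal units)",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("occupancy-scaled pause density must lie in [0, 1]; ",
         "scale with scale_to_occupancy() first", call. = FALSE)
  }
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be >= 0", call. = FALSE)
  if (any(!is.finite(k_pre)) || any(k_pre < 0)) {
    stop("k_pre must be >= 0", call. = FALSE)
  }
  check_positive(k_elong, "k_elong")
  p * k_pre + k_elong * b
}

#' Effective pause release rate
#'
#' The number of polymerases entering productive elongation per minute:
#' the product of the pause release rate constant and the occupancy-scaled
#' pause density.
#'
#' @param k_rel Pause release rate constant, 1/min.
#' @param p Occupancy-scaled pause density, 0..1.
#' @return RNAP per minute. Vectorized.
#' @export
effective_pause_release <- function(k_rel, p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be an occupancy in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(k_rel)) || any(k_rel < 0)) {
    stop("k_rel must be >= 0", call. = FALSE)
  }
  k_rel * p
}

#' Spacing between polymerases on the gene body
#'
#' The reciprocal of the occupancy-scaled body density: with b polymerases
#' per bp, consecutive polymerases are 1/b bp apart on average.
#'
#' @param b Occupancy-scaled body density, RNAP per bp.
#' @return Spacing in bp; \code{Inf} when b is 0. Vectorized.
#' @export
polymerase_spacing <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be >= 0", call. = FALSE)
  ifelse(b == 0, Inf, 1 / b)
}

#' Ratio of premature termination to pause release
#'
#' Given fold changes in pause release, initiation and pause density, the
#' control-condition ratio r = k_pre / k_rel satisfies
#' \code{r = (fc_krel - X) / (X - 1)} with \code{X = fc_kinit / fc_p}.
#' The ratio degenerates at the bounds of the admissible initiation fold
#' change: it is exactly 0 when fc_kinit equals the body-density fold
#' change (X = fc_krel) and undefined when fc_kinit equals the
#' pause-density fold change (X = 1). A finite negative value means the
#' supplied fc_kinit lies outside its admissible bounds and is flagged
#' rather than clipped.
#'
#' @param fc_krel Fold change in pause release rate.
#' @param fc_kinit Fold change in initiation rate.
#' @param fc_p Fold change in pause density.
#' @param tol Relative tolerance for detecting the degenerate boundaries.
#' @return A data.frame with columns \code{ratio} (k_pre/k_rel; 0 at the
#'   zero boundary, NA at the undefined boundary) and \code{status}, one
#'   of \code{"ok"}, \code{"zero_boundary"}, \code{"undefined_boundary"},
#'   \code{"negative"}. Vectorized.
#' @export
termination_release_ratio <- function(fc_krel, fc_kinit, fc_p,
                                      tol = 1e-9) {
  check_positive(fc_krel, "fc_krel")
  check_positive(fc_kinit, "fc_kinit")
  check_positive(fc_p, "fc_p")
  n <- max(length(fc_krel), length(fc_kinit), length(fc_p))
  fc_krel <- rep_len(fc_krel, n)
  fc_kinit <- rep_len(fc_kinit, n)
  fc_p <- rep_len(fc_p, n)

  x <- fc_kinit / fc_p
  zero_b <- abs(x - fc_krel) <= tol * pmax(abs(x), abs(fc_krel))
  undef_b <- abs(x - 1) <= tol * pmax(abs(x), 1)
  ratio <- (fc_krel - x) / (x - 1)
  status <- rep("ok", n)
  status[ratio < 0] <- "negative"
  ratio[zero_b] <- 0
  status[zero_b] <- "zero_boundary"
  ratio[undef_b] <- NA_real_
  status[undef_b] <- "undefined_boundary"
  data.frame(ratio = ratio, status = status)
}

#' Half-life of a paused polymerase
#'
#' A paused polymerase leaves the pause region by premature termination or
#' pause release, so its residence time decays with total rate
#' k_pre + k_rel and half-life \code{ln(2) / (k_pre + k_rel)} minutes,
#' reported in seconds.
#'
#' @param k_pre,k_rel Rates in 1/min.
#' @return Half-life in seconds; \code{Inf} when both rates are 0.
#'   Vectorized.
#' @export
pause_half_life <- function(k_pre, k_rel) {
  if (any(!is.finite(k_pre)) || any(k_pre < 0) ||
      any(!is.finite(k_rel)) || any(k_rel < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  total <- k_pre + k_rel
  ifelse(total == 0, Inf, 60 * log(2) / total)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}
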