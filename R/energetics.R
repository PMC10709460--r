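#' Thermodynamic integration over a lambda schedule
#'
#' Free-energy difference as the integral of the mean coupling derivative,
#' \deqn{\Delta G = \int_0^1 \langle \partial H/\partial\lambda
#'   \rangle_\lambda\, d\lambda,}
#' evaluated by trapezoidal quadrature of the per-window sample means over
#' the (possibly non-uniform) lambda grid; exact for integrands affine in
#' lambda. The standard error is a seeded bootstrap over the per-window
#' samples.
#'
#' @param samples a \code{\link{lambda_samples}} object with dH/dlambda
#'   samples at >= 2 lambda points.
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed RNG seed for the bootstrap.
#' @param discard_fraction fraction of each window's initial samples dropped
#'   as equilibration (default 0).
#' @return list (class \code{free_energy_result}) with \code{dG} (kJ/mol),
#'   \code{se}, \code{method = "TI"}, \code{per_window} (lambda, mean dH/dl,
#'   n).
#' @export
ti_integrate <- function(samples, n_boot = 200L, seed = 1L,
                         discard_fraction = 0) {
  if (!inherits(samples, "lambda_samples")) stopf("need a lambda_samples object")
  lam <- samples$lambdas
  if (length(lam) < 2L) stopf("TI needs at least 2 lambda points")
  if (is.null(samples$dhdl) || any(lengths(samples$dhdl) == 0L))
    stopf("TI needs dH/dlambda samples at every lambda point")
  dh <- lapply(samples$dhdl, function(v) {
    drop <- floor(discard_fraction * length(v))
    if (drop > 0) v <- v[-seq_len(drop)]
    v
  })
  trapz <- function(means) sum(diff(lam) * (head(means, -1) + tail(means, -1)) / 2)
  dg <- trapz(vapply(dh, mean, numeric(1)))
  se <- 0
  if (n_boot > 1L) {
    old <- .Random.seed_save()
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      trapz(vapply(dh, function(v) mean(sample(v, replace = TRUE)), numeric(1)))
    }, numeric(1))
    .Random.seed_restore(old)
    se <- sd(reps)
  }
  structure(list(dG = dg, se = se, method = "TI",
                 per_window = data.frame(lambda = lam,
                                         mean_dhdl = vapply(dh, mean, numeric(1)),
                                         n = lengths(dh))),
            class = "free_energy_result")
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("%s free energy: %.4f +/- %.4f kJ/mol\n", x$method, x$dG, x$se))
  invisible(x)
}

# one two-state BAR solve; wf, wr in kJ/mol, monotone residual root-find.
# Residual g(x) = sum f(beta(wf - x + M)) - sum f(beta(wr + x - M)) with
# f the logistic 1/(1+e^t); g is strictly increasing in x with a unique root.
bar_solve <- function(wf, wr, kT, tol = 1e-12, x0 = NULL) {
  beta <- 1 / kT
  M <- kT * log(length(wf) / length(wr))
  af <- beta * (wf + M)            # residual g(x) = sum f(af - beta x) - sum f(ar + beta x)
  ar <- beta * (wr - M)            # with f the logistic; g strictly increasing in x
  x <- if (is.null(x0)) (mean(wf) - mean(wr)) / 2 else x0
  lo <- -Inf; hi <- Inf
  gx <- NA_real_
  for (it in 1:200) {
    a <- stats::plogis(beta * x - af)
    b <- stats::plogis(-(ar + beta * x))
    gx <- sum(a) - sum(b)
    if (gx > 0) hi <- min(hi, x) else lo <- max(lo, x)
    d <- beta * (sum(a * (1 - a)) + sum(b * (1 - b)))
    x_new <- if (d > 0) x - gx / d else NA_real_
    # fall back to bisection when Newton leaves the bracket or stalls
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      if (!is.finite(lo) || !is.finite(hi)) {
        span <- max(1, abs(x)) * 2
        x_new <- if (gx > 0) x - span else x + span
      } else x_new <- (lo + hi) / 2
    }
    if (is.finite(x_new) && abs(x_new - x) < tol * max(1, abs(x))) {
      x <- x_new; break
    }
    x <- x_new
  }
  if (!is.finite(x) || abs(gx) > 1e-6 * (length(wf) + length(wr)))
    stopf("BAR failed to converge; forward/reverse work distributions may not overlap")
  x
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Solves Bennett's implicit equation for the free-energy difference
#' between two states from forward and reverse work samples:
#' \deqn{\sum_F f(\beta(W_F - \Delta G + M)) =
#'       \sum_R f(\beta(W_R + \Delta G - M)),}
#' with \eqn{f} the logistic function and \eqn{M = kT \ln(n_F/n_R)}, by
#' safeguarded Newton iteration on the strictly monotone residual. Standard
#' errors are a seeded bootstrap. Given a \code{\link{lambda_samples}}
#' object, per-adjacent-pair estimates are computed and summed; the total
#' \code{dG} is exactly the sum of the window contributions.
#'
#' @param forward_work numeric forward work samples (kJ/mol), or a
#'   \code{lambda_samples} object carrying forward/reverse differences.
#' @param reverse_work numeric reverse work samples (kJ/mol); ignored when
#'   \code{forward_work} is a \code{lambda_samples} object.
#' @param kT thermal energy, kJ/mol (2.577 at 310 K).
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed RNG seed for the bootstrap.
#' @return a \code{free_energy_result} with \code{dG}, \code{se},
#'   \code{method = "BAR"} and \code{per_window} contributions.
#' @export
bar_estimate <- function(forward_work, reverse_work = NULL, kT = 2.577,
                         n_boot = 200L, seed = 1L) {
  if (kT <= 0) stopf("'kT' must be > 0")
  if (inherits(forward_work, "lambda_samples")) {
    s <- forward_work
    if (is.null(s$forward) || is.null(s$reverse))
      stopf("lambda_samples lacks forward/reverse energy differences")
    np <- length(s$lambdas) - 1L
    res <- lapply(seq_len(np), function(i)
      bar_estimate(s$forward[[i]], s$reverse[[i]], kT,
                   n_boot = n_boot, seed = seed + i))
    dg_w <- vapply(res, function(r) r$dG, numeric(1))
    se_w <- vapply(res, function(r) r$se, numeric(1))
    return(structure(list(dG = sum(dg_w), se = sqrt(sum(se_w^2)),
                          method = "BAR",
                          per_window = data.frame(
                            lambda_from = s$lambdas[-length(s$lambdas)],
                            lambda_to = s$lambdas[-1],
                            dG = dg_w, se = se_w)),
                     class = "free_energy_result"))
  }
  wf <- as.numeric(forward_work); wr <- as.numeric(reverse_work)
  if (length(wf) == 0L || length(wr) == 0L)
    stopf("both forward and reverse work sample sets must be non-empty")
  dg <- bar_solve(wf, wr, kT)
  se <- 0
  if (n_boot > 1L) {
    old <- .Random.seed_save()
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b)
      bar_solve(sample(wf, replace = TRUE), sample(wr, replace = TRUE), kT,
                x0 = dg),
      numeric(1))
    .Random.seed_restore(old)
    se <- sd(reps)
  }
  structure(list(dG = dg, se = se, method = "BAR",
                 per_window = data.frame(lambda_from = 0, lambda_to = 1,
                                         dG = dg, se = se)),
            class = "free_energy_result")
}

#' Binding free energy from the alchemical thermodynamic cycle
#'
#' Composes the two decoupling legs of the double-decoupling cycle. With
#' \eqn{\Delta G_{decouple}} the work to annihilate guest-environment
#' interactions, the binding free energy is
#' \deqn{\Delta G_{bind} = \Delta G_{decouple,water} -
#'   \Delta G_{decouple,complex},}
#' so that binding which makes decoupling harder from the complex is
#' favourable (negative). The convention is recorded in the result.
#'
#' @param dg_water decoupling free energy of the free guest in water
#'   (kJ/mol): a number or a \code{free_energy_result}.
#' @param dg_complex decoupling free energy of the bound guest in the
#'   complex (kJ/mol): a number or a \code{free_energy_result}.
#' @return a \code{free_energy_result} with \code{dG} = binding free energy
#'   and propagated \code{se}; attribute \code{convention} documents signs.
#' @export
binding_cycle <- function(dg_water, dg_complex) {
  val <- function(x) if (inherits(x, "free_energy_result")) x$dG else as.numeric(x)
  err <- function(x) if (inherits(x, "free_energy_result")) x$se else 0
  out <- structure(list(dG = val(dg_water) - val(dg_complex),
                        se = sqrt(err(dg_water)^2 + err(dg_complex)^2),
                        method = "cycle",
                        per_window = data.frame(
                          leg = c("decouple_in_water", "decouple_in_complex"),
                          dG = c(val(dg_water), val(dg_complex)),
                          se = c(err(dg_water), err(dg_complex)))),
                   class = "free_energy_result")
  attr(out, "convention") <-
    "dG_bind = dG_decouple(water) - dG_decouple(complex); favourable binding < 0"
  out
}

#' Block-averaged mean and standard error
#'
#' Splits a (possibly autocorrelated) series into \code{n_blocks} contiguous
#' equal-length blocks (truncating the earliest samples when the length is
#' not divisible) and reports the mean of block means and its standard
#' error, sd(block means)/sqrt(n_blocks).
#'
#' @param series numeric vector, length >= \code{n_blocks}.
#' @param n_blocks number of blocks (>= 2; a length-1 series returns se 0).
#' @return list with \code{mean}, \code{se}, \code{n_blocks}.
#' @export
block_average <- function(series, n_blocks = 5L) {
  n <- length(series)
  if (n == 1L) return(list(mean = series, se = 0, n_blocks = 1L))
  if (n_blocks < 2L) stopf("'n_blocks' must be >= 2")
  if (n < n_blocks) stopf("series (length %d) shorter than n_blocks (%d)", n, n_blocks)
  len <- n %/% n_blocks
  x <- series[(n - n_blocks * len + 1L):n]
  bm <- colMeans(matrix(x, nrow = len))
  list(mean = mean(bm), se = sd(bm) / sqrt(n_blocks), n_blocks = n_blocks)
}

#' Dipole moment magnitude of a charge distribution
#'
#' \eqn{|\sum_i q_i r_i|} converted from e nm to Debye (1 e nm = 48.0321 D).
#' For a neutral group the result is origin-independent; for a net-charged
#' group the origin is placed at the absolute-charge-weighted centre of the
#' group (documented convention, since the dipole of a charged distribution
#' is origin-dependent).
#'
#' @param positions \code{n x 3} coordinate matrix (nm).
#' @param charges per-atom partial charges (e).
#' @return dipole magnitude in Debye.
#' @export
dipole_moment <- function(positions, charges) {
  x <- matrix(as.numeric(positions), ncol = 3L)
  if (is.null(charges) || length(charges) != nrow(x))
    stopf("need one charge per atom")
  qtot <- sum(charges)
  if (abs(qtot) > 1e-9 && sum(abs(charges)) > 0) {
    ctr <- colSums(x * abs(charges)) / sum(abs(charges))
    x <- sweep(x, 2L, ctr)
  }
  mu <- colSums(x * charges)   # e nm
  sqrt(sum(mu^2)) * 48.0321
}
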