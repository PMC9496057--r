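#' Five-parameter logistic model and its derivatives
#'
#' The positive-curve model is the asymmetric sigmoid
#' \deqn{F(x) = F_b + (F_{max} - F_b) \, / \, (1 + e^{-(x - x_0)/k})^s}
#' with baseline `fb`, plateau `fmax` (fluorescence units), midpoint-scale
#' location `x0` (cycles), slope scale `k > 0` (cycles) and asymmetry
#' `s > 0` (dimensionless; `s = 1` recovers the symmetric 4PL logistic).
#' `fivepl_d1()` and `fivepl_d2()` are the analytic first and second
#' derivatives with respect to cycle number; the second derivative's maximum
#' locates the Ct (see [ct_from_fit()]).
#'
#' Writing `p = 1/(1 + e^{-(x-x_0)/k})`, `q = 1 - p`, `g = p^s`:
#' `F' = A s g q / k` and `F'' = A s g q (s q - p) / k^2` with
#' `A = fmax - fb`.
#'
#' @param params named list or vector with `fb`, `fmax`, `x0`, `k`, `s`.
#' @param x cycle positions (may be fractional).
#' @return numeric vector of model values / derivatives at `x`.
#' @export
fivepl <- function(params, x) {
  with(as.list(params), fb + (fmax - fb) / (1 + exp(-(x - x0) / k))^s)
}

#' @rdname fivepl
#' @export
fivepl_d1 <- function(params, x) {
  with(as.list(params), {
    p <- 1 / (1 + exp(-(x - x0) / k))
    (fmax - fb) * s * p^s * (1 - p) / k
  })
}

#' @rdname fivepl
#' @export
fivepl_d2 <- function(params, x) {
  with(as.list(params), {
    p <- 1 / (1 + exp(-(x - x0) / k))
    q <- 1 - p
    (fmax - fb) * s * p^s * q * (s * q - p) / k^2
  })
}

# Jacobian of model values wrt (fb, fmax, x0, k, s); rows = x, cols = params
.fivepl_jacobian <- function(params, x) {
  with(as.list(params), {
    z <- (x - x0) / k
    w <- exp(-z)
    p <- 1 / (1 + w)
    q <- 1 - p
    g <- p^s
    A <- fmax - fb
    cbind(fb = 1 - g,
          fmax = g,
          x0 = -A * s * g * q / k,
          k = -A * s * g * q * z / k,
          s = -A * g * log1p(w))
  })
}

#' Initial 5PL guess from a raw trace
#'
#' Baseline = mean of cycles 1-5; plateau = trace maximum; `x0` = first
#' crossing of the half-height `(fb + fmax)/2`, linearly interpolated;
#' `k = 1`, `s = 1`. A trace whose dynamic range (max minus baseline) is
#' below `min_range` is rejected as not amplifying.
#'
#' @param curve a [fluorescence_curve()] or numeric vector.
#' @param min_range smallest acceptable dynamic range, in the curve's
#'   fluorescence units (default 0.05, suited to traces on a ~unit scale;
#'   raise it for raw instrument counts).
#' @return named list with `fb`, `fmax`, `x0`, `k`, `s`.
#' @export
init_guess <- function(curve, min_range = 0.05) {
  y <- if (inherits(curve, "fluorescence_curve")) curve$rfu else as.numeric(curve)
  x <- seq_along(y)
  fb <- mean(y[1:5])
  fmax <- max(y)
  if (fmax - fb < min_range)
    stop("not-amplifying: dynamic range ", signif(fmax - fb, 3),
         " below threshold ", min_range, call. = FALSE)
  half <- (fb + fmax) / 2
  above <- which(y >= half)
  i <- above[above > 1][1]
  x0 <- if (is.na(i)) x[above[1]]
        else x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1])
  list(fb = fb, fmax = fmax, x0 = as.numeric(x0), k = 1, s = 1)
}

#' Gauss-Newton fit of the 5PL model
#'
#' Plain Gauss-Newton on the residuals with the analytic Jacobian,
#' augmented with Levenberg-style diagonal damping whenever the normal
#' equations are ill-conditioned or an undamped step increases the sum of
#' squared residuals; accepted iterations therefore never increase the SSR.
#' `k` and `s` are kept positive by projection onto `>= 1e-6`.
#'
#' Convergence is declared when the step's infinity norm or the relative
#' SSR change drops below `tol`. Hitting `max_iter` returns
#' `converged = FALSE` rather than an error, leaving the decision to the
#' caller; a singular system that damping cannot rescue is an error.
#'
#' @param curve a [fluorescence_curve()] or numeric vector.
#' @param init initial parameters, e.g. from [init_guess()].
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 200).
#' @return A `fivepl_fit`: list with `params`, `residual_norm` (SSR),
#'   `iterations`, `converged`, `damping_used`.
#' @export
gauss_newton_fit <- function(curve, init, tol = 1e-8, max_iter = 200L) {
  y <- if (inherits(curve, "fluorescence_curve")) curve$rfu else as.numeric(curve)
  x <- seq_along(y)
  beta <- c(fb = init$fb, fmax = init$fmax, x0 = init$x0,
            k = init$k, s = init$s)
  project <- function(b) {
    b["k"] <- max(b["k"], 1e-6)
    b["s"] <- max(b["s"], 1e-6)
    b
  }
  beta <- project(beta)
  ssr_of <- function(b) sum((y - fivepl(b, x))^2)
  ssr <- ssr_of(beta)
  converged <- FALSE
  damping_used <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- .fivepl_jacobian(beta, x)
    r <- y - fivepl(beta, x)
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    # undamped Gauss-Newton step first; fall back to Levenberg damping
    step <- tryCatch(solve(JtJ, Jtr), error = function(e) NULL)
    new_beta <- if (!is.null(step)) project(beta + drop(step)) else NULL
    new_ssr <- if (!is.null(new_beta)) ssr_of(new_beta) else Inf
    if (!is.finite(new_ssr) || new_ssr > ssr) {
      damping_used <- TRUE
      lambda <- 1e-4
      repeat {
        step <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ) + 1e-12),
                               Jtr),
                         error = function(e) NULL)
        if (!is.null(step)) {
          cand <- project(beta + drop(step))
          cand_ssr <- ssr_of(cand)
          if (is.finite(cand_ssr) && cand_ssr <= ssr) {
            new_beta <- cand
            new_ssr <- cand_ssr
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) {
          new_beta <- NULL
          break
        }
      }
      if (is.null(new_beta)) {
        if (ssr <= tol) converged <- TRUE # already at a minimum
        break
      }
    }
    step_norm <- max(abs(new_beta - beta))
    rel_change <- if (ssr > 0) (ssr - new_ssr) / ssr else 0
    beta <- new_beta
    ssr <- new_ssr
    if (step_norm < tol || (rel_change >= 0 && rel_change < tol)) {
      converged <- TRUE
      break
    }
  }
  structure(list(params = as.list(beta), residual_norm = ssr,
                 iterations = iter, converged = converged,
                 damping_used = damping_used,
                 n_cycles = length(y)),
            class = "fivepl_fit")
}

#' Ct as the second-derivative maximum of a fitted 5PL curve
#'
#' The Ct is the abscissa of the maximum of the fitted curve's second
#' derivative, located on a dense grid (0.01-cycle steps) over the measured
#' cycle domain and polished by Newton steps on the third derivative
#' (finite-differenced from the analytic second derivative). A maximum on
#' the domain boundary means no interior inflection exists and is refused.
#' In the symmetric limit `s = 1` the position is available in closed form,
#' `x0 - k log(2 + sqrt(3))`.
#'
#' @param fit a `fivepl_fit` from [gauss_newton_fit()].
#' @param domain search interval in cycles; default `c(1, n_cycles)` of the
#'   fitted trace.
#' @return A `ct_result`: list with `ct` (fractional cycles), `fit`, and
#'   `method = "SDM"`.
#' @export
ct_from_fit <- function(fit, domain = NULL) {
  stopifnot(inherits(fit, "fivepl_fit"))
  if (!fit$converged)
    stop("ct-undefined: fit did not converge", call. = FALSE)
  p <- fit$params
  if (!(p$fmax > p$fb))
    stop("ct-undefined: fitted plateau does not exceed baseline", call. = FALSE)
  if (is.null(domain)) domain <- c(1, fit$n_cycles)
  grid <- seq(domain[1], domain[2], by = 0.01)
  d2 <- fivepl_d2(p, grid)
  i <- which.max(d2)
  if (i == 1L || i == length(grid))
    stop("ct-undefined: second-derivative maximum lies on the domain boundary",
         call. = FALSE)
  ct <- grid[i]
  # Newton polish on d3 (first derivative of d2), d3/d4 by central differences
  h <- 1e-5
  for (it in 1:25) {
    d3 <- (fivepl_d2(p, ct + h) - fivepl_d2(p, ct - h)) / (2 * h)
    d4 <- (fivepl_d2(p, ct + h) - 2 * fivepl_d2(p, ct) +
             fivepl_d2(p, ct - h)) / h^2
    if (!is.finite(d3) || !is.finite(d4) || d4 >= 0) break
    delta <- d3 / d4
    ct_new <- ct - delta
    if (ct_new < domain[1] || ct_new > domain[2]) break
    ct <- ct_new
    if (abs(delta) < 1e-10) break
  }
  structure(list(ct = ct, fit = fit, method = "SDM"), class = "ct_result")
}

#' Full Ct call on a positive curve
#'
#' Chains [init_guess()], [gauss_newton_fit()] and [ct_from_fit()]. Any
#' failure along the chain (flat trace, non-convergence, boundary maximum)
#' is captured as status `"positive-but-uncallable"` instead of an error, so
#' batch analysis never aborts on one well.
#'
#' @param curve a [fluorescence_curve()] or numeric vector.
#' @param min_range passed to [init_guess()].
#' @param tol,max_iter passed to [gauss_newton_fit()].
#' @return A `ct_call`: list with `status` (`"ok"` or
#'   `"positive-but-uncallable"`), `ct` (NA when uncallable), `fit` (may be
#'   NULL), and `message` describing a failure.
#' @examples
#' truth <- list(fb = 0.05, fmax = 0.9, x0 = 25, k = 1, s = 1)
#' cc <- call_ct(fivepl(truth, 1:40))
#' round(cc$ct, 2) # 25 - log(2 + sqrt(3)) = 23.68
#' @export
call_ct <- function(curve, min_range = 0.05, tol = 1e-8, max_iter = 200L) {
  out <- tryCatch({
    init <- init_guess(curve, min_range = min_range)
    fit <- gauss_newton_fit(curve, init, tol = tol, max_iter = max_iter)
    ct <- ct_from_fit(fit)
    list(status = "ok", ct = ct$ct, fit = fit, message = NULL)
  }, error = function(e) {
    list(status = "positive-but-uncallable", ct = NA_real_, fit = NULL,
         message = conditionMessage(e))
  })
  structure(out, class = "ct_call")
}

#' Round a Ct for reporting (two decimals, half-up)
#'
#' Report-layer convention: Ct values are printed with two decimal places,
#' rounding halves away from zero (so 23.685 prints as 23.69).
#'
#' @param ct numeric Ct value(s).
#' @return numeric rounded to two decimals.
#' @export
round_ct <- function(ct) {
  sign(ct) * floor(abs(ct) * 100 + 0.5) / 100
}
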