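#' Balloon-model hemodynamic parameters
#'
#' Standard one-compartment balloon model constants: vasodilatory signal
#' decay `kappa` (1/s), flow feedback `gamma` (1/s), mean transit time
#' `tau` (s), vessel stiffness `alpha`, resting oxygen extraction `E0`,
#' and resting venous volume fraction `V0`.
#'
#' @param kappa,gamma,tau,alpha,E0,V0 see description; defaults 0.64, 0.32,
#'   2, 0.32, 0.4, 0.04.
#' @return a `hemo_params` object.
#' @export
hemo_params <- function(kappa = 0.64, gamma = 0.32, tau = 2,
                        alpha = 0.32, E0 = 0.4, V0 = 0.04) {
  stopifnot(kappa > 0, gamma > 0, all(tau > 0), alpha > 0, alpha < 1,
            E0 > 0, E0 < 1, V0 > 0)
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0), class = "hemo_params")
}

#' BOLD observation constants of the balloon model
#'
#' `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`.
#'
#' @param E0 resting oxygen extraction fraction.
#' @return named numeric vector `c(k1, k2, k3)`.
#' @export
bold_constants <- function(E0) c(k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2)

#' Neural drift of the nonlinear DCM
#'
#' `dx/dt = (A + sum_j u_j B_j + sum_k x_k D_k) x + C u`, where A carries
#' the negative self-connections, B_j are the input-modulatory matrices,
#' D_k the gating matrix attached to region k, and C the driving-input
#' weights. With all D zero this is exactly the bilinear form; at x = 0,
#' u = 0 the drift vanishes (rest is a fixed point).
#'
#' @param x neural state vector.
#' @param u input values (one per input stream).
#' @param params a `dcm_params`.
#' @param model the matching `dcm_model` (dimension check only).
#' @return the state derivative in 1/s.
#' @export
neural_drift <- function(x, u, params, model) {
  stopifnot(inherits(params, "dcm_params"))
  n <- length(x)
  if (n != nrow(params$A) || length(u) != ncol(params$C))
    stop_invalid("state/input dimensions do not match the model")
  if (!missing(model) && !is.null(model) &&
      n != length(model$nodes))
    stop_invalid("state length does not match the model's node count")
  M <- effective_A(params)
  for (j in seq_along(u)) M <- M + u[j] * params$B[[j]]
  for (k in seq_len(n)) M <- M + x[k] * params$D[[k]]
  as.numeric(M %*% x + params$C %*% u)
}

#' One evaluation of the balloon hemodynamics
#'
#' Given the per-region hemodynamic state `h = (s, f, v, q)` and neural
#' activity `x`, returns the state derivatives and the instantaneous BOLD
#' value. At rest (`x = 0`, `h = (0, 1, 1, 1)`) all derivatives and the
#' BOLD signal are zero.
#'
#' @param h numeric length-4 vector `(s, f, v, q)` for one region.
#' @param x scalar neural activity of that region.
#' @param p a [hemo_params()] (its `tau` may be region-specific; pass the
#'   scalar for this region).
#' @return list with `dh` (length-4 derivative) and `bold`.
#' @export
hemodynamics_step <- function(h, x, p) {
  stopifnot(inherits(p, "hemo_params"), length(h) == 4L)
  s <- h[1]; f <- h[2]; v <- h[3]; q <- h[4]
  if (v <= 0 || q <= 0)
    stop_invalid("non-positive volume or deoxyhemoglobin state")
  v_a <- v^(1 / p$alpha)
  ds <- x - p$kappa * s - p$gamma * (f - 1)
  df <- s
  dv <- (f - v_a) / p$tau[1]
  dq <- (f * (1 - (1 - p$E0)^(1 / f)) / p$E0 - v_a * q / v) / p$tau[1]
  k <- bold_constants(p$E0)
  bold <- p$V0 * (k["k1"] * (1 - q) + k["k2"] * (1 - q / v) +
                    k["k3"] * (1 - v))
  list(dh = c(ds, df, dv, dq), bold = unname(bold))
}

#' Stability of the intrinsic connectivity
#'
#' Checks that every eigenvalue of the effective A matrix (the Jacobian of
#' the neural dynamics at rest, where all gating terms vanish) has a
#' negative real part.
#'
#' @param params a `dcm_params`.
#' @param model optional matching `dcm_model` (dimension check).
#' @return list with `pass` (logical) and `margin` (`-max Re(eigenvalue)`;
#'   positive when stable).
#' @export
stability_check <- function(params, model = NULL) {
  A <- effective_A(params)
  if (!is.null(model) && nrow(A) != length(model$nodes))
    stop_invalid("parameter dimension does not match the model")
  ev <- eigen(A, only.values = TRUE)$values
  margin <- -max(Re(ev))
  list(pass = margin > 0, margin = margin)
}

params_to_arrays <- function(params) {
  n <- nrow(params$A)
  m <- ncol(params$C)
  Barr <- array(0, c(n, n, m))
  for (j in seq_len(m)) Barr[, , j] <- params$B[[j]]
  Darr <- array(0, c(n, n, n))
  for (k in seq_len(n)) Darr[, , k] <- params$D[[k]]
  list(A = effective_A(params), Barr = Barr, C = unname(params$C),
       Darr = Darr)
}

#' Simulate a BOLD series from a DCM
#'
#' Fixed-step RK4 integration of the neural and balloon equations at the
#' input grid step, with BOLD sampled every `TR` and optional additive
#' Gaussian observation noise (AR(1) option via `ar1`).
#'
#' @param model a `dcm_model`.
#' @param params a matching `dcm_params`; must pass [stability_check()].
#' @param hemo a [hemo_params()]; its `tau` may be a length-n vector.
#' @param inputs an input set from [build_dcm_inputs()] (fields `dt`, `U`).
#' @param TR repetition time in s; must be a multiple of `inputs$dt`.
#' @param noise_sd observation noise SD in BOLD signal units (0 = none).
#' @param seed RNG seed for the observation noise.
#' @param ar1 lag-one autocorrelation of the observation noise (default 0).
#' @return a `bold_series`: list with `Y` (time x region matrix), `TR`,
#'   and provenance (`model`, `seed`, `noise_sd`).
#' @export
simulate_bold <- function(model, params, hemo = hemo_params(), inputs,
                          TR = 2, noise_sd = 0, seed = NULL, ar1 = 0) {
  stopifnot(inherits(model, "dcm_model"), inherits(params, "dcm_params"),
            inherits(hemo, "hemo_params"))
  st <- stability_check(params, model)
  if (!st$pass)
    stop_invalid("unstable intrinsic connectivity (margin %.3g)", st$margin)
  pred <- predict_bold_core(params, hemo, inputs, TR)
  if (!pred$ok)
    stop_invalid("simulation diverged at t = %.2f s", pred$fail_time)
  Y <- pred$bold
  colnames(Y) <- model$nodes
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    E <- matrix(rnorm(length(Y), 0, noise_sd), nrow(Y), ncol(Y))
    if (ar1 != 0) {
      for (t in 2:nrow(E)) E[t, ] <- ar1 * E[t - 1, ] + E[t, ]
      E <- E * sqrt(1 - ar1^2)  # keep marginal sd = noise_sd
    }
    Y <- Y + E
  }
  structure(list(Y = Y, TR = TR, model = model$name, seed = seed,
                 noise_sd = noise_sd, dt = inputs$dt),
            class = "bold_series")
}

# Deterministic forward prediction shared by simulate_bold() and the
# fitting code. tau may be scalar or per-region.
predict_bold_core <- function(params, hemo, inputs, TR) {
  dt <- inputs$dt
  k <- TR / dt
  if (abs(k - round(k)) > 1e-8)
    stop_invalid("TR (%g s) must be an integer multiple of dt (%g s)", TR, dt)
  arr <- params_to_arrays(params)
  n <- nrow(arr$A)
  tau <- rep(hemo$tau, length.out = n)
  res <- dcm_integrate_cpp(arr$A, arr$Barr, arr$C, arr$Darr, inputs$U,
                           dt, as.integer(round(k)), tau, hemo$kappa,
                           hemo$gamma, hemo$alpha, hemo$E0, hemo$V0)
  list(bold = res$bold, ok = res$ok, fail_time = res$fail_time)
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d volumes x %d regions, TR %g s, model %s, noise sd %g\n",
              nrow(x$Y), ncol(x$Y), x$TR, x$model %||% "?", x$noise_sd))
  invisible(x)
}

#' Export a BOLD series as CSV
#'
#' Columns: time_s, then one column per region.
#'
#' @param series a `bold_series`.
#' @param path output file path.
#' @export
write_bold_csv <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  df <- data.frame(time_s = seq_len(nrow(series$Y)) * series$TR,
                   series$Y, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
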