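# Parameter vector layout for inversion. Each row of the map describes one
# free parameter: its block (A off-diagonal, B, C, D, self-connection
# log-scale, per-region log transit time), matrix indices, and Gaussian
# prior moments.

#' Gaussian shrinkage priors for a DCM motif
#'
#' Zero-mean Gaussian priors on every free parameter: variance 0.25 for A
#' off-diagonal, B, C and gating (D) entries; 0.0625 for the self-connection
#' log-scales; and 0.0625 for per-region log transit-time deviations (a
#' log-normal prior on tau around its default). All other hemodynamic
#' constants are fixed.
#'
#' @param model a `dcm_model`.
#' @param var_a,var_b,var_c,var_d,var_self,var_logtau prior variances per
#'   block.
#' @return a `prior_spec`: data frame with one row per free parameter.
#' @export
prior_spec <- function(model, var_a = 0.25, var_b = 0.25, var_c = 0.25,
                       var_d = 0.25, var_self = 0.0625,
                       var_logtau = 0.0625) {
  stopifnot(inherits(model, "dcm_model"))
  n <- length(model$nodes)
  rows <- list()
  add <- function(block, i, j, k, v) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, i = i, j = j, k = k, prior_mean = 0, prior_var = v,
      stringsAsFactors = FALSE)
  }
  off <- model$A_mask & !diag(n)
  for (j in seq_len(n)) for (i in seq_len(n))
    if (off[i, j]) add("A", i, j, 0L, var_a)
  for (u in seq_along(model$inputs)) {
    mk <- model$B_masks[[u]]
    for (j in seq_len(n)) for (i in seq_len(n))
      if (mk[i, j]) add("B", i, j, u, var_b)
  }
  for (u in seq_along(model$inputs)) for (i in seq_len(n))
    if (model$C_mask[i, u]) add("C", i, u, 0L, var_c)
  for (g in seq_len(n)) {
    mk <- model$D_masks[[g]]
    for (j in seq_len(n)) for (i in seq_len(n))
      if (mk[i, j]) add("D", i, j, g, var_d)
  }
  for (i in seq_len(n)) add("self", i, 0L, 0L, var_self)
  for (i in seq_len(n)) add("logtau", i, 0L, 0L, var_logtau)
  out <- do.call(rbind, rows)
  out$name <- param_names(out, model)
  class(out) <- c("prior_spec", "data.frame")
  out
}

param_names <- function(map, model) {
  nd <- model$nodes
  ins <- model$inputs
  vapply(seq_len(nrow(map)), function(r) {
    switch(map$block[r],
           A = sprintf("A[%s<-%s]", nd[map$i[r]], nd[map$j[r]]),
           B = sprintf("B.%s[%s<-%s]", ins[map$k[r]], nd[map$i[r]],
                       nd[map$j[r]]),
           C = sprintf("C.%s[%s]", ins[map$j[r]], nd[map$i[r]]),
           D = sprintf("D.%s[%s<-%s]", nd[map$k[r]], nd[map$i[r]],
                       nd[map$j[r]]),
           self = sprintf("self[%s]", nd[map$i[r]]),
           logtau = sprintf("logtau[%s]", nd[map$i[r]]))
  }, "")
}

#' Assemble DCM parameters from a free-parameter vector
#'
#' @param theta numeric vector matching `priors`.
#' @param model the `dcm_model`.
#' @param priors the [prior_spec()] defining the layout.
#' @return list with a `dcm_params` object and the per-region `logtau`.
#' @export
unpack_params <- function(theta, model, priors) {
  n <- length(model$nodes)
  A <- matrix(0, n, n, dimnames = dimnames(model$A_mask))
  B <- lapply(model$B_masks, function(m) m * 0)
  C <- model$C_mask * 0
  D <- lapply(model$D_masks, function(m) m * 0)
  theta_self <- rep(0, n)
  logtau <- rep(0, n)
  for (r in seq_len(nrow(priors))) {
    v <- theta[r]
    switch(priors$block[r],
           A = A[priors$i[r], priors$j[r]] <- v,
           B = B[[priors$k[r]]][priors$i[r], priors$j[r]] <- v,
           C = C[priors$i[r], priors$j[r]] <- v,
           D = D[[priors$k[r]]][priors$i[r], priors$j[r]] <- v,
           self = theta_self[priors$i[r]] <- v,
           logtau = logtau[priors$i[r]] <- v)
  }
  params <- make_dcm_params(model, A = A, B = B, C = C, D = D,
                            theta_self = theta_self)
  list(params = params, logtau = logtau)
}

#' Flatten generating DCM parameters onto a prior layout
#'
#' Inverse of [unpack_params()] for parameter-recovery comparisons.
#'
#' @param params a `dcm_params`.
#' @param model the `dcm_model`.
#' @param priors the [prior_spec()] layout.
#' @param logtau per-region log transit-time deviations (default 0).
#' @return named numeric vector of generating values.
#' @export
pack_params <- function(params, model, priors,
                        logtau = rep(0, length(model$nodes))) {
  theta <- numeric(nrow(priors))
  for (r in seq_len(nrow(priors))) {
    theta[r] <- switch(priors$block[r],
                       A = params$A[priors$i[r], priors$j[r]],
                       B = params$B[[priors$k[r]]][priors$i[r], priors$j[r]],
                       C = params$C[priors$i[r], priors$j[r]],
                       D = params$D[[priors$k[r]]][priors$i[r], priors$j[r]],
                       self = params$theta_self[priors$i[r]],
                       logtau = logtau[priors$i[r]])
  }
  setNames(theta, priors$name)
}

predict_from_theta <- function(theta, model, priors, hemo, inputs, TR) {
  up <- unpack_params(theta, model, priors)
  if (!stability_check(up$params)$pass) return(NULL)
  h <- hemo
  h$tau <- rep(hemo$tau, length.out = length(model$nodes)) * exp(up$logtau)
  pred <- predict_bold_core(up$params, h, inputs, TR)
  if (!pred$ok || anyNA(pred$bold)) return(NULL)
  pred$bold
}

#' Fitting controls for [fit_model()]
#'
#' @param max_iter iteration cap for the damped Gauss-Newton loop.
#' @param tol free-energy convergence tolerance; the fit stops when
#'   `|dF| < tol` on three successive iterations.
#' @param n_starts number of starts; the first is the prior mean, further
#'   starts are seeded Gaussian jitters around it, and the best-F solution
#'   is retained.
#' @param start_jitter_sd SD of the start jitter.
#' @param fd_step forward finite-difference step for the BOLD Jacobian.
#' @param seed seed for the start jitter.
#' @return a list of control settings.
#' @export
fit_control <- function(max_iter = 24L, tol = 1e-4, n_starts = 1L,
                        start_jitter_sd = 0.1, fd_step = 1e-4, seed = 1L) {
  list(max_iter = as.integer(max_iter), tol = tol,
       n_starts = as.integer(n_starts), start_jitter_sd = start_jitter_sd,
       fd_step = fd_step, seed = seed)
}

gauss_loglik <- function(res, lambda) {
  Tn <- nrow(res)
  sum(Tn / 2 * log(lambda / (2 * pi)) - lambda / 2 * colSums(res^2))
}

#' Laplace free energy (approximate log model evidence)
#'
#' `F = log-likelihood at the posterior mean - 1/2 [ (mu_p - mu_0)' P_0
#' (mu_p - mu_0) + log det(Sigma_0) - log det(Sigma_p) ]`: accuracy minus
#' a complexity term that is the KL-type penalty for moving away from (and
#' sharpening relative to) the prior. When the posterior equals the prior
#' the complexity term vanishes and F is the log-likelihood; for a
#' linear-Gaussian model with known noise this expression is the exact log
#' evidence.
#'
#' @param log_lik Gaussian log-likelihood at the posterior mean (nats).
#' @param mu_post,Sigma_post posterior mean and covariance.
#' @param mu_prior,Sigma_prior prior mean and covariance.
#' @return free energy in nats.
#' @export
free_energy <- function(log_lik, mu_post, Sigma_post, mu_prior,
                        Sigma_prior) {
  d <- mu_post - mu_prior
  ch0 <- tryCatch(chol(Sigma_prior), error = function(e) NULL)
  chp <- tryCatch(chol(Sigma_post), error = function(e) NULL)
  if (is.null(ch0) || is.null(chp))
    stop_invalid("covariances must be positive definite")
  quad <- sum(backsolve(ch0, d, transpose = TRUE)^2)
  logdet0 <- 2 * sum(log(diag(ch0)))
  logdetp <- 2 * sum(log(diag(chp)))
  log_lik - 0.5 * (quad + logdet0 - logdetp)
}

#' Invert one DCM on a BOLD series (MAP + Laplace)
#'
#' Maximizes the Gaussian log-joint (likelihood of the RK4-predicted BOLD
#' plus the shrinkage prior) by Levenberg-damped Gauss-Newton with a
#' forward-difference Jacobian, interleaved with closed-form EM updates of
#' the per-region observation-noise precision. Returns the MAP mean, the
#' Laplace covariance (inverse curvature of the negative log-joint), and
#' the free energy. Non-convergence is flagged, not raised; a singular
#' curvature is ridge-repaired with a warning.
#'
#' @param model a `dcm_model`.
#' @param data a `bold_series` (regions must match the model).
#' @param inputs the `dcm_inputs` the data were generated/acquired with.
#' @param priors a [prior_spec()] for the model.
#' @param hemo fixed hemodynamic constants ([hemo_params()]); per-region
#'   transit time is estimated around `hemo$tau` via its log-normal prior.
#' @param control a [fit_control()] list.
#' @return a `dcm_fit`: `mu` (posterior mean), `Sigma` (posterior
#'   covariance), `lambda` (noise precisions), `F` (free energy),
#'   `iterations`, `converged`, `predicted` (fitted BOLD).
#' @export
fit_model <- function(model, data, inputs, priors = prior_spec(model),
                      hemo = hemo_params(), control = fit_control()) {
  stopifnot(inherits(model, "dcm_model"), inherits(data, "bold_series"))
  n <- length(model$nodes)
  if (ncol(data$Y) != n)
    stop_invalid("data has %d regions but model '%s' has %d",
                 ncol(data$Y), model$name, n)
  Y <- unname(data$Y)
  Tn <- nrow(Y)
  p <- nrow(priors)
  mu0 <- priors$prior_mean
  Pi0 <- diag(1 / priors$prior_var, p)
  Sigma0 <- diag(priors$prior_var, p)

  starts <- list(mu0)
  if (control$n_starts > 1L) {
    set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1L))
      starts[[s + 1L]] <- mu0 + rnorm(p, 0, control$start_jitter_sd)
  }
  best <- NULL
  for (start in starts) {
    fit <- fit_model_once(start, model, priors, hemo, inputs, data$TR, Y,
                          Tn, p, mu0, Pi0, Sigma0, control)
    if (is.null(best) || (is.finite(fit$F) && fit$F > best$F)) best <- fit
  }
  best$model <- model$name
  best$priors <- priors
  class(best) <- "dcm_fit"
  best
}

fit_model_once <- function(theta, model, priors, hemo, inputs, TR, Y, Tn,
                           p, mu0, Pi0, Sigma0, control) {
  lambda_cap <- 1e8
  pred <- predict_from_theta(theta, model, priors, hemo, inputs, TR)
  if (is.null(pred)) {  # degenerate start: fall back to the prior mean
    theta <- mu0
    pred <- predict_from_theta(theta, model, priors, hemo, inputs, TR)
  }
  res <- Y - pred
  lambda <- pmin(Tn / (colSums(res^2) + 1e-10), lambda_cap)
  compute_F <- function(theta, res, lambda, Sigma_post) {
    free_energy(gauss_loglik(res, lambda), theta, Sigma_post, mu0, Sigma0)
  }
  obj <- function(res, theta, lambda)  # negative penalized log-joint core
    sum(lambda / 2 * colSums(res^2)) +
      0.5 * sum((theta - mu0)^2 / priors$prior_var)

  if (control$max_iter == 0L) {
    F0 <- compute_F(mu0, Y - predict_from_theta(mu0, model, priors, hemo,
                                                inputs, TR),
                    lambda, Sigma0)
    return(list(mu = setNames(mu0, priors$name), Sigma = Sigma0,
                lambda = lambda, F = F0, iterations = 0L,
                converged = FALSE, predicted = pred,
                final_step = NA_real_))
  }

  damping <- 1e-2
  F_old <- -Inf
  n_small <- 0L
  iterations <- 0L
  converged <- FALSE
  H_gn <- Pi0
  final_step <- NA_real_
  for (iter in seq_len(control$max_iter)) {
    iterations <- iter
    # EM precision update with the current residuals
    lambda <- pmin(Tn / (colSums(res^2) + 1e-10), lambda_cap)
    # forward-difference Jacobian of the prediction
    Jmat <- array(0, c(Tn, ncol(Y), p))
    ok_fd <- TRUE
    for (r in seq_len(p)) {
      th2 <- theta
      th2[r] <- th2[r] + control$fd_step
      pr2 <- predict_from_theta(th2, model, priors, hemo, inputs, TR)
      if (is.null(pr2)) { ok_fd <- FALSE; break }
      Jmat[, , r] <- (pr2 - pred) / control$fd_step
    }
    if (!ok_fd) break
    H_gn <- Pi0
    g <- -as.numeric(Pi0 %*% (theta - mu0))
    for (rgn in seq_len(ncol(Y))) {
      Jr <- matrix(Jmat[, rgn, ], Tn, p)
      H_gn <- H_gn + lambda[rgn] * crossprod(Jr)
      g <- g + lambda[rgn] * as.numeric(crossprod(Jr, res[, rgn]))
    }
    # Levenberg loop: damp until the penalized objective improves
    obj_cur <- obj(res, theta, lambda)
    accepted <- FALSE
    for (try in 1:12) {
      step <- tryCatch(solve(H_gn + damping * diag(diag(H_gn) + 1e-8),
                             g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        th_new <- theta + step
        pred_new <- predict_from_theta(th_new, model, priors, hemo,
                                       inputs, TR)
        if (!is.null(pred_new)) {
          res_new <- Y - pred_new
          if (obj(res_new, th_new, lambda) < obj_cur) {
            theta <- th_new; pred <- pred_new; res <- res_new
            damping <- max(damping / 3, 1e-8)
            final_step <- sqrt(sum(step^2))
            accepted <- TRUE
            break
          }
        }
      }
      damping <- damping * 10
    }
    Sigma_post <- solve_ridged(H_gn)
    F_new <- compute_F(theta, res, lambda, Sigma_post)
    if (is.finite(F_old) && abs(F_new - F_old) < control$tol) {
      n_small <- n_small + 1L
      if (n_small >= 3L) { converged <- TRUE; F_old <- F_new; break }
    } else n_small <- 0L
    F_old <- F_new
    if (!accepted && damping > 1e9) break
  }
  lambda <- pmin(Tn / (colSums(res^2) + 1e-10), lambda_cap)
  Sigma_post <- solve_ridged(H_gn)
  F_final <- compute_F(theta, res, lambda, Sigma_post)
  list(mu = setNames(theta, priors$name), Sigma = Sigma_post,
       lambda = lambda, F = F_final, iterations = iterations,
       converged = converged, predicted = pred, final_step = final_step)
}

solve_ridged <- function(H) {
  out <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  ridge <- 1e-8
  while (is.null(out) && ridge < 1) {
    out <- tryCatch(chol2inv(chol(H + ridge * diag(nrow(H)))),
                    error = function(e) NULL)
    if (is.null(out)) ridge <- ridge * 10
  }
  if (is.null(out)) stop_invalid("curvature matrix could not be inverted")
  if (ridge > 1e-8)
    warning("singular curvature: posterior covariance ridge-repaired",
            call. = FALSE)
  (out + t(out)) / 2
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %s: F = %.2f, %d iterations%s\n",
              x$model, x$F, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' 90% posterior credible intervals of a fit
#'
#' Gaussian (Laplace) intervals `mu +/- 1.645 sd` for every free
#' parameter.
#'
#' @param fit a `dcm_fit`.
#' @param level credible level (default 0.90).
#' @return data frame with name, block, posterior mean, sd, lower, upper.
#' @export
credible_intervals <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "dcm_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  sdv <- sqrt(pmax(diag(fit$Sigma), 0))
  data.frame(name = names(fit$mu), block = fit$priors$block,
             mean = unname(fit$mu), sd = sdv,
             lower = unname(fit$mu) - z * sdv,
             upper = unname(fit$mu) + z * sdv,
             stringsAsFactors = FALSE)
}
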