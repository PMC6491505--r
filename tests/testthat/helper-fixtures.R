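# Shared fixtures built in code.

# A hand-built two-node model (R1 -> R2 with one driving input and one
# gate of the R1->R2 edge by R2 activity) for oracle checks that expand
# the neural equation symbolically.
make_2node_model <- function() {
  nodes <- c("R1", "R2")
  mk <- function(entries) {
    m <- matrix(FALSE, 2, 2, dimnames = list(nodes, nodes))
    for (e in entries) m[e[2], e[1]] <- TRUE
    m
  }
  structure(list(
    name = "toy2", class = "nonlinear", nodes = nodes, inputs = "u",
    A_mask = mk(list(c("R1", "R2"))) | diag(2) > 0,
    B_masks = list(u = mk(list())),
    C_mask = matrix(c(TRUE, FALSE), 2, 1, dimnames = list(nodes, "u")),
    D_masks = list(R1 = mk(list()), R2 = mk(list(c("R1", "R2"))))),
    class = "dcm_model")
}

# Plain-R RK4 reference for the coupled neural + balloon system, built
# from the exported single-evaluation functions. Independent of the
# compiled integrator's code path.
r_reference_bold <- function(params, hemo, inputs, TR) {
  n <- nrow(params$A)
  dt <- inputs$dt
  x <- rep(0, n)
  h <- matrix(rep(c(0, 1, 1, 1), each = n), n, 4)  # s, f, v, q
  tau <- rep(hemo$tau, length.out = n)
  k <- TR / dt
  out <- NULL
  deriv <- function(x, h, u) {
    dx <- neural_drift(x, u, params, NULL)
    dh <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      p_i <- hemo
      p_i$tau <- tau[i]
      dh[i, ] <- hemodynamics_step(h[i, ], x[i], p_i)$dh
    }
    list(dx = dx, dh = dh)
  }
  for (step in seq_len(nrow(inputs$U))) {
    u <- inputs$U[step, ]
    k1 <- deriv(x, h, u)
    k2 <- deriv(x + dt / 2 * k1$dx, h + dt / 2 * k1$dh, u)
    k3 <- deriv(x + dt / 2 * k2$dx, h + dt / 2 * k2$dh, u)
    k4 <- deriv(x + dt * k3$dx, h + dt * k3$dh, u)
    x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    h <- h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    if (step %% k == 0) {
      kk <- bold_constants(hemo$E0)
      b <- hemo$V0 * (kk["k1"] * (1 - h[, 4]) +
                        kk["k2"] * (1 - h[, 4] / h[, 3]) +
                        kk["k3"] * (1 - h[, 3]))
      out <- rbind(out, unname(b))
    }
  }
  out
}

# Upsample a dcm_inputs object by an integer factor (zero-order hold), so
# a finer integration grid sees identical input timing.
refine_inputs <- function(inputs, factor) {
  U <- inputs$U[rep(seq_len(nrow(inputs$U)), each = factor), , drop = FALSE]
  structure(list(dt = inputs$dt / factor, U = U,
                 duration = inputs$duration), class = "dcm_inputs")
}

# Conjugate linear-Gaussian evidence for the free-energy oracle.
lm_log_evidence <- function(y, X, Sigma0, sigma) {
  S <- sigma^2 * diag(length(y)) + X %*% Sigma0 %*% t(X)
  ch <- chol(S)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}
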