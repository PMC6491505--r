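# Connectivity matrices follow the usual DCM convention: element [i, j] is
# the connection from region j to region i.

edge_mask <- function(edges, nodes) {
  m <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) m[e[[2]], e[[1]]] <- TRUE  # edge stored as [from, to]
  m
}

#' Build the seven-model effective-connectivity space
#'
#' Four regions (IPL, rPFC, DLPFC, SFG) with a common base: a driving
#' stimulus input to the IPL, an IPL-to-rPFC connection modulated on
#' regular trials, an IPL-to-DLPFC connection modulated on different
#' trials, and a DLPFC-to-IPL backward connection. The seven motifs differ
#' in how activity reaches the SFG:
#' serial via both intermediate regions (`Diamond`); a direct parallel
#' IPL-to-SFG route carrying both modulations (`Fork`); hierarchical
#' bilinear with the regular (`Legs1`) or different (`Legs2`) modulation at
#' the higher level; and nonlinear variants in which rPFC activity gates
#' DLPFC-to-SFG (`Stork1`), DLPFC activity gates rPFC-to-SFG (`Stork2`), or
#' both gates operate at once (`Stork3`, the "double nonlinear" motif).
#' Only the Stork models have non-empty gating (D) masks.
#'
#' The edge lists live in a JSON data file, so an alternative reading of a
#' motif is a configuration change rather than a code change.
#'
#' @param path JSON file describing the model space; defaults to the
#'   definition shipped with the package.
#' @return a named list of seven `dcm_model` objects.
#' @export
build_model_space <- function(path = system.file("extdata",
                                                 "dcm_model_space.json",
                                                 package = "precistim")) {
  spec <- jsonlite::read_json(path)
  nodes <- unlist(spec$nodes)
  inputs <- unlist(spec$inputs)
  n <- length(nodes)
  base_a <- spec$base$a
  base_b <- spec$base$b
  base_c <- spec$base$c
  models <- lapply(spec$models, function(m) {
    A <- edge_mask(c(base_a, m$a), nodes)
    diag(A) <- TRUE  # self-connections always present
    B <- lapply(setNames(inputs, inputs), function(u) {
      edge_mask(c(base_b[[u]], m$b[[u]]), nodes)
    })
    C <- matrix(FALSE, n, length(inputs), dimnames = list(nodes, inputs))
    for (u in names(base_c)) C[unlist(base_c[[u]]), u] <- TRUE
    D <- lapply(setNames(nodes, nodes), function(k) {
      edge_mask(m$d[[k]], nodes)
    })
    structure(list(name = m$name, class = m$class, nodes = nodes,
                   inputs = inputs, A_mask = A, B_masks = B, C_mask = C,
                   D_masks = D),
              class = "dcm_model")
  })
  setNames(models, vapply(models, `[[`, "", "name"))
}

#' @export
print.dcm_model <- function(x, ...) {
  n_d <- sum(vapply(x$D_masks, sum, 0))
  cat(sprintf("<dcm_model> %s (%s): %d intrinsic, %d modulatory, %d driving, %d gating entries\n",
              x$name, x$class, sum(x$A_mask & !diag(nrow(x$A_mask))),
              sum(vapply(x$B_masks, sum, 0)), sum(x$C_mask), n_d))
  invisible(x)
}

#' Create a parameter set for a DCM motif
#'
#' Off-diagonal entries of A, B, C and D are free rate constants (per
#' second) on the edges the motif allows; entries outside the masks are
#' fixed at zero. Self-connections are parameterized as
#' `a_ii = -0.5 * exp(theta_self_i)`, which keeps them strictly negative.
#'
#' @param model a `dcm_model`.
#' @param A,C numeric matrices of intrinsic and driving strengths (masked
#'   entries ignored); `A`'s diagonal is ignored in favour of `theta_self`.
#' @param B,D named lists of numeric matrices per input / per gating
#'   region.
#' @param theta_self length-4 log-scaling of the self-connections.
#' @return a `dcm_params` object.
#' @export
make_dcm_params <- function(model, A = NULL, B = NULL, C = NULL, D = NULL,
                            theta_self = rep(0, length(model$nodes))) {
  stopifnot(inherits(model, "dcm_model"))
  n <- length(model$nodes)
  zero <- matrix(0, n, n, dimnames = dimnames(model$A_mask))
  fill <- function(values, mask) {
    out <- zero
    if (!is.null(values)) out[mask] <- values[mask]
    out
  }
  Af <- fill(A, model$A_mask & !diag(n))
  Bf <- lapply(setNames(model$inputs, model$inputs), function(u)
    fill(B[[u]], model$B_masks[[u]]))
  Cf <- matrix(0, n, length(model$inputs),
               dimnames = dimnames(model$C_mask))
  if (!is.null(C)) Cf[model$C_mask] <- C[model$C_mask]
  Df <- lapply(setNames(model$nodes, model$nodes), function(k)
    fill(D[[k]], model$D_masks[[k]]))
  structure(list(model_name = model$name, A = Af, B = Bf, C = Cf, D = Df,
                 theta_self = theta_self),
            class = "dcm_params")
}

#' Effective intrinsic connectivity matrix
#'
#' Adds the self-connections `-0.5 * exp(theta_self)` to the off-diagonal
#' intrinsic strengths. This is the Jacobian of the neural dynamics at
#' rest (all gating terms vanish at x = 0).
#'
#' @param params a `dcm_params`.
#' @return the numeric A matrix in 1/s.
#' @export
effective_A <- function(params) {
  stopifnot(inherits(params, "dcm_params"))
  A <- params$A
  diag(A) <- -0.5 * exp(params$theta_self)
  A
}

#' Reference group-level generating parameters for a motif
#'
#' Group means used when simulating synthetic group data. The design
#' mirrors the factorial logic of the task: the IPL-to-rPFC and
#' IPL-to-DLPFC routes have weak baselines (0.2/s) and strong condition
#' modulations (0.8/s), so rPFC activity is largely specific to regular
#' trials and DLPFC activity to different trials; the routes into SFG
#' (0.15/s) and the gates (1.0 per unit state) then give the SFG signal
#' three components of comparable variance - two condition main effects
#' and an activity-dependent interaction - which is what makes the seven
#' motifs distinguishable in principle. A -0.3/s backward DLPFC-to-IPL
#' connection, a unit driving input to IPL, and unit-scaled
#' self-connections (-0.5/s) complete the set. SFG is a sink in every
#' motif, so gating strength does not affect stability.
#'
#' @param model a `dcm_model`.
#' @return a `dcm_params` object.
#' @export
default_group_params <- function(model) {
  stopifnot(inherits(model, "dcm_model"))
  n <- length(model$nodes)
  A <- matrix(0, n, n, dimnames = dimnames(model$A_mask))
  A[model$A_mask & !diag(n)] <- 0.15
  A["rPFC", "IPL"] <- 0.2
  A["DLPFC", "IPL"] <- 0.2
  A["IPL", "DLPFC"] <- -0.3
  B <- lapply(model$B_masks, function(m) ifelse(m, 0.8, 0))
  C <- ifelse(model$C_mask, 1.0, 0)
  D <- lapply(model$D_masks, function(m) ifelse(m, 1.0, 0))
  make_dcm_params(model, A = A, B = B, C = C, D = D,
                  theta_self = rep(0, n))
}

#' Export the model space as JSON
#'
#' Writes node labels and the boolean A/B/C/D masks of every motif.
#'
#' @param space result of [build_model_space()].
#' @param path output file path.
#' @export
write_model_space_json <- function(space, path) {
  out <- lapply(space, function(m)
    list(name = m$name, class = m$class, nodes = m$nodes,
         inputs = m$inputs, A = m$A_mask * 1L,
         B = lapply(m$B_masks, `*`, 1L), C = m$C_mask * 1L,
         D = lapply(m$D_masks, `*`, 1L)))
  jsonlite::write_json(out, path, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}
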