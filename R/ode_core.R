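#' Hill activation function
#'
#' Increasing Hill function \eqn{\sigma(x, k, p) = x^p / (k^p + x^p)} used
#' for transcriptional activation (here: NICD-driven Notch transcription in
#' the positive-feedback arm).
#'
#' @param x regulator level (nonnegative).
#' @param k saturation coefficient (positive).
#' @param p Hill coefficient (>= 1).
#' @return activation fraction in \[0, 1\]; vectorized over \code{x}.
#' @export
hill_activation <- function(x, k, p) {
  if (!is.numeric(k) || any(k <= 0)) stop("saturation coefficient k must be positive")
  if (!is.numeric(p) || any(p < 1)) stop("Hill coefficient must be >= 1")
  if (any(x < 0)) stop("regulator level x must be nonnegative")
  xp <- (x / k)^p
  ifelse(is.infinite(xp), 1, xp / (1 + xp))
}

#' Hill repression function
#'
#' Decreasing Hill function \eqn{\delta(x, k, h) = k^h / (k^h + x^h)} used
#' for transcriptional suppression (here: Notch-signaling repression of Dll
#' transcription in the lateral-inhibition arm). Complementary to
#' [hill_activation()]: \code{sigma + delta == 1} for equal arguments.
#'
#' @param x regulator level (nonnegative).
#' @param k saturation coefficient (positive).
#' @param h Hill coefficient (>= 1).
#' @return repression fraction in \[0, 1\]; vectorized over \code{x}.
#' @export
hill_repression <- function(x, k, h) {
  1 - hill_activation(x, k, h)
}

# derivative of sigma w.r.t. x (used by analytic Jacobians)
hill_activation_deriv <- function(x, k, p) {
  xp <- (x / k)^p
  ifelse(x == 0 & p > 1, 0,
         ifelse(x == 0 & p == 1, 1 / k,
                p * xp / (x * (1 + xp)^2)))
}

#' Right-hand side of the five-species dimensionless model
#'
#' Time derivatives of one cell's state in MODEL2 (Notch mRNA, NOTCH
#' receptor, Dll mRNA, DLL ligand, NICD), given the neighborhood averages
#' \code{meanD} and \code{meanN}. The trans-activation flux \code{N * meanD}
#' produces NICD while depleting the cell's receptor; the reciprocal flux
#' \code{meanN * D} depletes the cell's ligand.
#'
#' @param state numeric vector \code{c(Nm, N, Dm, D, R)} (nonnegative).
#' @param params MODEL2 \code{circuit_params}.
#' @param meanD,meanN neighborhood-averaged DLL and NOTCH levels.
#' @return numeric vector of the five derivatives, in state order.
#' @export
rhs_model2 <- function(state, params, meanD, meanN) {
  if (params$model_form != "MODEL2") stop("rhs_model2 expects MODEL2 parameters")
  if (any(state < 0)) stop("negative state components")
  if (meanD < 0 || meanN < 0) stop("neighborhood averages must be nonnegative")
  state <- unname(state)
  Nm <- state[1]; N <- state[2]; Dm <- state[3]; D <- state[4]; R <- state[5]
  x <- N * meanD
  c(params$beta_nm * ((1 - params$S_PF) +
      params$S_PF * hill_activation(x, params$k_p, params$p)) -
      params$alpha_n * Nm,
    params$beta_N * Nm - params$alpha_N * N - x,
    params$beta_dm * ((1 - params$S_LI) +
      params$S_LI * hill_repression(x, params$k_d, params$h)) -
      params$alpha_d * Dm,
    params$beta_D * Dm - params$alpha_D * D - meanN * D,
    x - params$alpha_R * R)
}

#' Right-hand side of the three-species protein model
#'
#' Time derivatives of one cell's state in MODEL3 (NOTCH, DLL, NICD), the
#' quasi-steady-state reduction of MODEL2. \code{S_PF = 0} recovers the pure
#' lateral-inhibition circuit; \code{S_LI = 0} removes ligand repression.
#'
#' @param state numeric vector \code{c(N, D, R)} (nonnegative).
#' @param params MODEL3 \code{circuit_params}.
#' @param meanD,meanN neighborhood-averaged DLL and NOTCH levels.
#' @return numeric vector of the three derivatives.
#' @export
rhs_model3 <- function(state, params, meanD, meanN) {
  if (params$model_form != "MODEL3") stop("rhs_model3 expects MODEL3 parameters")
  if (any(state < 0)) stop("negative state components")
  if (meanD < 0 || meanN < 0) stop("neighborhood averages must be nonnegative")
  state <- unname(state)
  N <- state[1]; D <- state[2]; R <- state[3]
  x <- N * meanD
  c(params$beta_N * ((1 - params$S_PF) +
      params$S_PF * hill_activation(x, params$k_p, params$p)) -
      params$alpha_N * N - x,
    params$beta_D * ((1 - params$S_LI) +
      params$S_LI * hill_repression(x, params$k_d, params$h)) -
      params$alpha_D * D - meanN * D,
    x - params$alpha_R * R)
}

# Vectorized multicell MODEL3 RHS. `y` stacks per-species blocks
# (N_1..N_n, D_1..D_n, R_1..R_n); W is the row-normalized averaging matrix.
rhs_lattice3 <- function(y, params, W, clamp = TRUE) {
  n <- nrow(W)
  N <- y[seq_len(n)]; D <- y[n + seq_len(n)]; R <- y[2L * n + seq_len(n)]
  if (clamp) { N <- pmax(N, 0); D <- pmax(D, 0); R <- pmax(R, 0) }
  meanD <- as.vector(W %*% D)
  meanN <- as.vector(W %*% N)
  x <- N * meanD
  dN <- params$beta_N * ((1 - params$S_PF) +
          params$S_PF * hill_activation(x, params$k_p, params$p)) -
        params$alpha_N * N - x
  dD <- params$beta_D * ((1 - params$S_LI) +
          params$S_LI * hill_repression(x, params$k_d, params$h)) -
        params$alpha_D * D - meanN * D
  dR <- x - params$alpha_R * R
  c(dN, dD, dR)
}

# Vectorized multicell MODEL2 RHS; y stacks (Nm, N, Dm, D, R) blocks.
rhs_lattice2 <- function(y, params, W, clamp = TRUE) {
  n <- nrow(W)
  idx <- function(k) (k - 1L) * n + seq_len(n)
  Nm <- y[idx(1)]; N <- y[idx(2)]; Dm <- y[idx(3)]; D <- y[idx(4)]; R <- y[idx(5)]
  if (clamp) {
    Nm <- pmax(Nm, 0); N <- pmax(N, 0); Dm <- pmax(Dm, 0)
    D <- pmax(D, 0); R <- pmax(R, 0)
  }
  meanD <- as.vector(W %*% D)
  meanN <- as.vector(W %*% N)
  x <- N * meanD
  c(params$beta_nm * ((1 - params$S_PF) +
      params$S_PF * hill_activation(x, params$k_p, params$p)) - params$alpha_n * Nm,
    params$beta_N * Nm - params$alpha_N * N - x,
    params$beta_dm * ((1 - params$S_LI) +
      params$S_LI * hill_repression(x, params$k_d, params$h)) - params$alpha_d * Dm,
    params$beta_D * Dm - params$alpha_D * D - meanN * D,
    x - params$alpha_R * R)
}

#' Integrate the multicell circuit ODEs
#'
#' Deterministic integration of the coupled per-cell equations on a neighbor
#' graph with a stiff-capable solver (\code{deSolve::ode}, \code{lsoda}).
#' Species values within \code{-atol} of zero are clamped to zero after each
#' output step; larger negativity raises an error, since it indicates solver
#' failure rather than roundoff.
#'
#' @param params \code{circuit_params} (MODEL2 or MODEL3).
#' @param init numeric matrix, one row per cell; 3 columns \code{(N, D, R)}
#'   for MODEL3, 5 columns \code{(Nm, N, Dm, D, R)} for MODEL2.
#' @param graph a [neighbor_graph] (or its weight matrix) defining the
#'   neighborhood averages; a single decoupled cell may pass a 1x1 zero
#'   matrix.
#' @param times output time points (dimensionless).
#' @param rtol,atol solver tolerances. Bistable dynamics near saddle points
#'   need tight tolerances for reproducible basin assignment.
#' @return object of class \code{circuit_trajectory}: list with \code{times},
#'   \code{species} (array time x cell x species), and the raw deSolve matrix.
#' @export
integrate_circuit <- function(params, init, graph, times,
                              rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  W <- graph_weights(graph)
  n <- nrow(W)
  ns <- if (params$model_form == "MODEL3") 3L else 5L
  init <- as.matrix(init)
  if (nrow(init) != n || ncol(init) != ns)
    stop(sprintf("init must be %d x %d for %s on this graph", n, ns, params$model_form))
  y0 <- as.vector(init)              # column-major: species blocks stacked
  rhs <- if (ns == 3L) rhs_lattice3 else rhs_lattice2
  out <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, p) list(rhs(y, params, W)),
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE solver failed near t = %g", out[nrow(out), 1]))
  ymat <- out[, -1, drop = FALSE]
  neg <- ymat < 0
  if (any(ymat < -100 * atol))
    stop("trajectory became negative beyond tolerance: solver failure")
  ymat[neg] <- 0
  species_names <- if (ns == 3L) c("N", "D", "R") else c("Nm", "N", "Dm", "D", "R")
  arr <- array(ymat, dim = c(nrow(ymat), n, ns),
               dimnames = list(NULL, NULL, species_names))
  structure(list(times = out[, 1], species = arr, params = params),
            class = "circuit_trajectory")
}

#' Long-format export of a trajectory
#'
#' @param traj a \code{circuit_trajectory}.
#' @return data.frame with columns \code{time}, \code{cell_id},
#'   \code{species}, \code{value}.
#' @export
trajectory_long <- function(traj) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  d <- dim(traj$species)
  sp <- dimnames(traj$species)[[3]]
  data.frame(
    time = rep(traj$times, times = d[2] * d[3]),
    cell_id = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    species = rep(sp, each = d[1] * d[2]),
    value = as.vector(traj$species))
}
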