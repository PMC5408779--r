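#' Homogeneous steady state of the multicell circuit
#'
#' On a vertex-transitive graph every cell sees the same neighborhood, so a
#' spatially uniform state is a fixed point when one cell's state solves the
#' single-cell system with its own levels as the neighborhood averages
#' (\code{<D> = D*}, \code{<N> = N*}). Solved by damped Newton on the
#' reduced \code{(N, D)} system with NICD following algebraically; the full
#' lattice residual is verified before returning.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param graph a [neighbor_graph] (used for the residual check; the
#'   uniform state itself is graph-independent on regular lattices).
#' @return a [classify_stability()] style \code{steady_state} whose
#'   \code{state} is the 1 x 3 uniform cell state; eigenvalues are those of
#'   the single cell coupled to itself (mean-field block).
#' @export
homogeneous_fixed_point <- function(params, graph = NULL) {
  validate_params(params)
  sc <- species_scales(params)
  # exact 1-D reduction: for given N, the uniform ligand balance
  #   beta_D g(N D) - (alpha_D + N) D = 0
  # is strictly decreasing in D, so D(N) is unique; the uniform receptor
  # balance then becomes a scalar equation in N, bracketed densely. With a
  # strong positive feedback several uniform states can coexist; the
  # patterning analyses linearize around the active (largest-N) branch.
  D_of_N <- function(N) {
    G <- function(D) params$beta_D * reg_g(N * D, params) -
      (params$alpha_D + N) * D
    uniroot(G, c(0, sc[["D"]] * 1.001), tol = 1e-14)$root
  }
  FN <- function(N) {
    D <- D_of_N(N)
    params$beta_N * reg_f(N * D, params) - params$alpha_N * N - N * D
  }
  # coarse bracketing suffices: the scalar reduction has at most a few
  # well-separated roots in the physical range
  Ns <- bracket_roots(FN, 0, 1.05 * sc[["N"]], n = 220)
  if (!length(Ns))
    stop("no homogeneous fixed point found in the physical range")
  Nstar <- max(Ns)
  Dstar <- D_of_N(Nstar)
  state <- matrix(c(Nstar, Dstar, Nstar * Dstar / params$alpha_R), 1, 3,
                  dimnames = list(NULL, c("N", "D", "R")))
  if (!is.null(graph)) {
    W <- graph_weights(graph)
    n <- nrow(W)
    full <- matrix(rep(state, each = n), n, 3)
    res <- rhs_lattice3(as.vector(full), params, W, clamp = FALSE)
    if (sqrt(sum(res^2)) > 1e-7 * n)
      stop("uniform state fails the full lattice residual check (graph not vertex-transitive?)")
  }
  # stability w.r.t. uniform (mean-field) perturbations: mu = 1 block
  AB <- linearization_blocks(state, params)
  eigs <- eigen(AB$A + AB$B, only.values = TRUE)$values
  re <- Re(eigs)
  structure(list(state = state, eigenvalues = eigs,
                 stability = if (all(re < -1e-9)) "STABLE" else "UNSTABLE",
                 marginal = any(abs(re) <= 1e-9),
                 residual = abs(FN(Nstar))),
            class = "steady_state")
}

# Same-cell (A) and neighbor-coupling (B) blocks of the linearization at a
# uniform state: the full Jacobian is I (x) A + W (x) B, so its spectrum is
# the union over eigenvalues mu of W of eig(A + mu B).
linearization_blocks <- function(state, params) {
  N <- state[1]; D <- state[2]
  x <- N * D
  fp <- params$beta_N * reg_fp(x, params)
  gp <- params$beta_D * reg_gp(x, params)
  A <- matrix(c(
    (fp - 1) * D - params$alpha_N, 0, 0,
    gp * D, -params$alpha_D - N, 0,
    D, 0, -params$alpha_R), 3, 3, byrow = TRUE)
  B <- matrix(c(
    0, (fp - 1) * N, 0,
    -D, gp * N, 0,
    0, N, 0), 3, 3, byrow = TRUE)
  list(A = A, B = B)
}

#' Maximum Lyapunov exponent of the patterning linearization
#'
#' Largest real part over the spectrum of the full multicell Jacobian
#' linearized at the homogeneous steady state. A positive value means the
#' uniform state is unstable to some spatial mode and the tissue is
#' patterning-competent; a negative value means perturbations decay back to
#' uniformity. Computed by the lattice-mode reduction: the Jacobian is
#' \code{I (x) A + W (x) B}, so its eigenvalues are the union over the
#' averaging-matrix eigenvalues \code{mu} of the 3 x 3 spectra
#' \code{eig(A + mu B)}.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param graph a [neighbor_graph].
#' @return scalar MLE, with attributes \code{hom} (the homogeneous
#'   \code{steady_state}) and \code{mode_mu} (the averaging-matrix
#'   eigenvalue attaining the maximum).
#' @export
compute_mle <- function(params, graph) {
  hom <- homogeneous_fixed_point(params, graph)
  AB <- linearization_blocks(hom$state, params)
  W <- graph_weights(graph)
  mus <- eigen(W, only.values = TRUE)$values
  best <- -Inf; best_mu <- NA
  for (mu in mus) {
    lam <- eigen(AB$A + mu * AB$B, only.values = TRUE)$values
    m <- max(Re(lam))
    if (m > best) { best <- m; best_mu <- mu }
  }
  structure(best, hom = hom, mode_mu = best_mu)
}

#' Sweep the MLE over production-rate grids
#'
#' Recomputes [compute_mle()] on a grid of effective maximum production
#' rates (\code{beta_N} x \code{beta_D}) for each cooperativity level
#' \code{H} (applied to the lateral-inhibition Hill coefficient \code{h};
#' the positive-feedback cooperativity \code{p} keeps its configured value)
#' and for each requested feedback strength (\code{S_PF = 0} is the LI-only
#' circuit).
#'
#' @param params base MODEL3 \code{circuit_params}.
#' @param beta_N_grid,beta_D_grid strictly increasing positive rate grids.
#' @param H_values cooperativity levels to sweep.
#' @param s_pf_values feedback strengths; default LI (0) and the base set's.
#' @param graph lattice to linearize on (default 4 x 4 periodic hex, which
#'   carries all distinct modes of the checkerboard-type instabilities).
#' @return tidy data.frame with columns \code{beta_N, beta_D, H, s_pf,
#'   circuit, mle, patterned}; failed grid points carry \code{NA}.
#' @export
mle_sweep <- function(params, beta_N_grid, beta_D_grid, H_values = c(1, 2, 4),
                      s_pf_values = unique(c(0, params$S_PF)),
                      graph = build_lattice(4, 4, "HEX_PERIODIC")) {
  if (any(diff(beta_N_grid) <= 0) || any(diff(beta_D_grid) <= 0))
    stop("rate grids must be strictly increasing")
  grid <- expand.grid(beta_N = beta_N_grid, beta_D = beta_D_grid,
                      H = H_values, s_pf = s_pf_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$circuit <- ifelse(grid$s_pf == 0, "LI", "PFLI")
  grid$mle <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i$beta_N <- grid$beta_N[i]; p_i$beta_D <- grid$beta_D[i]
    p_i$h <- grid$H[i]; p_i$S_PF <- grid$s_pf[i]
    grid$mle[i] <- tryCatch(as.numeric(compute_mle(p_i, graph)),
                            error = function(e) NA_real_)
  }
  grid$patterned <- grid$mle > 0
  grid
}

#' Patterned-area fraction of an MLE sweep
#'
#' @param sweep a [mle_sweep()] data.frame.
#' @return data.frame with the fraction of grid points with positive MLE per
#'   \code{(H, circuit)} combination.
#' @export
patterned_fraction <- function(sweep) {
  agg <- aggregate(patterned ~ H + circuit, data = sweep,
                   FUN = function(z) mean(z, na.rm = TRUE))
  names(agg)[names(agg) == "patterned"] <- "fraction"
  agg[order(agg$H, agg$circuit), ]
}

#' Deterministic patterning simulation from a perturbed uniform state
#'
#' Integrates the multicell circuit from the homogeneous steady state
#' perturbed by multiplicative i.i.d. uniform noise of relative magnitude
#' \code{init_noise} (seeded). When the uniform state is linearly unstable
#' the tissue diverges into a heterogeneous mosaic; the final cells are
#' partitioned into NICD-high and NICD-low sets by a 2-means split on the
#' final NICD levels.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param graph a [neighbor_graph].
#' @param seed integer RNG seed (recorded in the result).
#' @param init_noise relative perturbation magnitude (default 0.01).
#' @param t_end final dimensionless time.
#' @param n_out number of saved time points.
#' @return object of class \code{patterning_run}: list with
#'   \code{trajectory}, \code{pattern_time}, \code{high_set},
#'   \code{low_set}, \code{converged}, \code{uniform}, \code{seed},
#'   \code{init_noise}.
#' @export
simulate_patterning <- function(params, graph, seed, init_noise = 0.01,
                                t_end = 200, n_out = 401) {
  hom <- homogeneous_fixed_point(params, graph)
  n <- graph$n_cells
  set.seed(seed)
  noise <- matrix(runif(3 * n, -1, 1), n, 3)
  init <- matrix(rep(hom$state, each = n), n, 3) * (1 + init_noise * noise)
  times <- seq(0, t_end, length.out = n_out)
  traj <- integrate_circuit(params, init, graph, times)
  final <- traj$species[n_out, , ]
  W <- graph_weights(graph)
  res <- rhs_lattice3(as.vector(final), params, W, clamp = FALSE)
  converged <- sqrt(sum(res^2)) < 1e-6
  Rfinal <- final[, 3]
  spread <- diff(range(Rfinal))
  uniform <- spread < 1e-3 * (1 + mean(Rfinal))
  if (uniform) {
    high <- integer(0); low <- seq_len(n); boundary <- NA_real_
  } else {
    km <- stats::kmeans(Rfinal, centers = matrix(range(Rfinal), 2, 1))
    hi_cluster <- which.max(km$centers)
    high <- which(km$cluster == hi_cluster)
    low <- setdiff(seq_len(n), high)
    boundary <- mean(km$centers)
  }
  run <- structure(list(trajectory = traj, high_set = high, low_set = low,
                        boundary = boundary, converged = converged,
                        uniform = uniform, seed = seed,
                        init_noise = init_noise, params = params,
                        graph = graph),
                   class = "patterning_run")
  run$pattern_time <- pattern_time(run)
  run
}

#' Time at which the patterning transition completes
#'
#' The transition band is delimited by the DLL change rate: the pattern time
#' is the last moment at which the maximum over cells of \code{|dD/dtau|}
#' falls below \code{rate_threshold} after having exceeded it. A run that
#' never exceeds the threshold (uniform, already-settled dynamics) reports 0.
#'
#' @param run a \code{patterning_run}.
#' @param rate_threshold dimensionless DLL rate threshold (default 1e-4).
#' @return dimensionless time; attribute \code{uniform_run} flags the
#'   never-exceeded case.
#' @export
pattern_time <- function(run, rate_threshold = 1e-4) {
  traj <- run$trajectory
  W <- graph_weights(run$graph)
  nt <- length(traj$times)
  maxrate <- vapply(seq_len(nt), function(k) {
    y <- as.vector(traj$species[k, , ])
    d <- rhs_lattice3(y, run$params, W)
    n <- nrow(W)
    max(abs(d[n + seq_len(n)]))
  }, numeric(1))
  above <- maxrate > rate_threshold
  if (!any(above))
    return(structure(0, uniform_run = TRUE))
  last_above <- max(which(above))
  if (last_above == nt)
    return(structure(traj$times[nt], incomplete = TRUE))
  structure(traj$times[last_above + 1L], uniform_run = FALSE)
}

#' Match the LI circuit's Notch signaling level to a PFLI reference
#'
#' Rescales the LI circuit's maximum Notch production rate \code{beta_N} so
#' that the NICD level of its Notch-high cell (from the pair-cell census)
#' matches the PFLI circuit's within a relative tolerance. This makes the
#' two circuits comparable: any remaining difference in patterning behavior
#' is then due to the feedback architecture, not to signaling amplitude.
#'
#' @param li_params LI MODEL3 \code{circuit_params} (\code{S_PF = 0}).
#' @param pfli_params PFLI MODEL3 \code{circuit_params}, or a target NICD
#'   level passed as \code{target_R}.
#' @param target_R optional explicit NICD target overriding
#'   \code{pfli_params}.
#' @param tol relative matching tolerance (default 0.02).
#' @return adjusted LI \code{circuit_params} with attribute
#'   \code{scale_factor}.
#' @export
match_notch_levels <- function(li_params, pfli_params = NULL, target_R = NULL,
                               tol = 0.02) {
  high_R <- function(p) {
    census <- pair_fixed_points(p)
    stable <- Filter(function(s) s$stability == "STABLE", census)
    if (!length(stable)) return(NA_real_)
    max(vapply(stable, function(s) max(s$state[, 3]), numeric(1)))
  }
  if (is.null(target_R)) {
    if (identical(pfli_params$S_PF, 0) &&
        isTRUE(all.equal(unclass(li_params), unclass(pfli_params))))
      return(structure(li_params, scale_factor = 1))
    target_R <- high_R(pfli_params)
    if (is.na(target_R)) stop("PFLI reference has no stable pair fixed point")
  }
  value_at <- function(scale) {
    p <- li_params
    p$beta_N <- li_params$beta_N * scale
    high_R(p)
  }
  lo <- 0.2; hi <- 1
  v_hi <- value_at(hi)
  if (!is.na(v_hi) && abs(v_hi - target_R) <= tol * target_R)
    return(structure(li_params, scale_factor = 1))
  # expand the bracket upward until the high-state NICD overshoots the target
  while (hi < 200) {
    if (!is.na(v_hi) && v_hi >= target_R) break
    hi <- hi * 2
    v_hi <- value_at(hi)
  }
  if (is.na(v_hi) || v_hi < target_R)
    stop(sprintf("no beta_N scale in [%.2g, %.2g] reaches the NICD target (best %.4g vs %.4g)",
                 lo, hi, v_hi, target_R))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    v <- value_at(mid)
    if (is.na(v) || v < target_R) lo <- mid else hi <- mid
    if (!is.na(v) && abs(v - target_R) <= 0.25 * tol * target_R) { hi <- mid; break }
  }
  scale <- hi
  v <- value_at(scale)
  if (is.na(v) || abs(v - target_R) > tol * target_R)
    stop(sprintf("NICD matching failed: achieved %.4g vs target %.4g", v, target_R))
  out <- li_params
  out$beta_N <- li_params$beta_N * scale
  structure(out, scale_factor = scale, achieved_R = v, target_R = target_R)
}
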