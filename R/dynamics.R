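#' @importFrom stats uniroot
NULL

# f(x) = (1-S_PF) + S_PF*sigma; g(x) = (1-S_LI) + S_LI*delta, and derivatives
reg_f <- function(x, params)
  (1 - params$S_PF) + params$S_PF * hill_activation(x, params$k_p, params$p)
reg_fp <- function(x, params)
  params$S_PF * hill_activation_deriv(x, params$k_p, params$p)
reg_g <- function(x, params)
  (1 - params$S_LI) + params$S_LI * hill_repression(x, params$k_d, params$h)
reg_gp <- function(x, params)
  -params$S_LI * hill_activation_deriv(x, params$k_d, params$h)

# Analytic Jacobian of the multicell MODEL3 system at `states` (n x 3 matrix,
# columns N, D, R), stacked per-species: d(dN,dD,dR)/d(N,D,R) as 3n x 3n.
jacobian_lattice3 <- function(states, params, W) {
  n <- nrow(W)
  N <- states[, 1]; D <- states[, 2]
  meanD <- as.vector(W %*% D)
  meanN <- as.vector(W %*% N)
  x <- N * meanD
  fp <- reg_fp(x, params) * params$beta_N
  gp <- reg_gp(x, params) * params$beta_D
  J <- matrix(0, 3 * n, 3 * n)
  iN <- seq_len(n); iD <- n + iN; iR <- 2 * n + iN
  # dN rows
  J[cbind(iN, iN)] <- (fp - 1) * meanD - params$alpha_N
  J[iN, iD] <- ((fp - 1) * N) * W
  # dD rows
  J[cbind(iD, iN)] <- gp * meanD
  J[iD, iN] <- J[iD, iN] - D * W
  J[iD, iD] <- (gp * N) * W
  J[cbind(iD, iD)] <- J[cbind(iD, iD)] - params$alpha_D - meanN
  # dR rows
  J[cbind(iR, iN)] <- meanD
  J[iR, iD] <- N * W
  J[cbind(iR, iR)] <- -params$alpha_R
  J
}

# Central finite-difference Jacobian of an arbitrary vector field (test oracle
# and MODEL2 fallback).
jacobian_fd <- function(fun, y, eps = 1e-6) {
  m <- length(fun(y))
  J <- matrix(0, m, length(y))
  for (k in seq_along(y)) {
    hk <- eps * max(1, abs(y[k]))
    yp <- y; yp[k] <- y[k] + hk
    ym <- y; ym[k] <- max(y[k] - hk, 0)  # keep evaluations in the domain
    J[, k] <- (fun(yp) - fun(ym)) / (yp[k] - ym[k])
  }
  J
}

#' Classify the stability of a candidate fixed point
#'
#' Evaluates the Jacobian of the multicell system at a state, computes its
#' spectrum, and classifies the point: \code{STABLE} if every eigenvalue has
#' negative real part, \code{SADDLE} if real parts of both signs occur,
#' \code{UNSTABLE} otherwise. Real parts within \code{1e-9} of zero are
#' treated as nonnegative and the point is flagged \code{marginal}
#' (conservative: marginal points never count as patterning-stable).
#'
#' @param states n x 3 matrix of per-cell \code{(N, D, R)} states.
#' @param params MODEL3 \code{circuit_params}.
#' @param graph a [neighbor_graph]; for the single-cell protocol pass
#'   \code{d_ext} instead.
#' @param d_ext if non-NULL, classify the single-cell system driven by a
#'   fixed external ligand level (neighbor averages \code{<D> = d_ext},
#'   \code{<N> = 0}).
#' @param residual_tol maximum RHS norm accepted as "a fixed point".
#' @return object of class \code{steady_state}: list with \code{state},
#'   \code{eigenvalues}, \code{stability}, \code{marginal}, \code{residual}.
#' @export
classify_stability <- function(states, params, graph = NULL, d_ext = NULL,
                               residual_tol = 1e-6) {
  states <- matrix(states, ncol = 3)
  if (!is.null(d_ext)) {
    stopifnot(nrow(states) == 1)
    fun <- function(y) rhs_model3(pmax(y, 0), params, meanD = d_ext, meanN = 0)
    res <- fun(as.vector(states))
    N <- states[1, 1]
    # triangular structure: N decouples, D and R are slaved
    eigs <- c((reg_fp(N * d_ext, params) * params$beta_N - 1) * d_ext - params$alpha_N,
              -params$alpha_D, -params$alpha_R)
  } else {
    W <- graph_weights(graph)
    res <- rhs_lattice3(as.vector(states), params, W, clamp = FALSE)
    eigs <- eigen(jacobian_lattice3(states, params, W), only.values = TRUE)$values
  }
  rnorm_ <- sqrt(sum(res^2))
  if (rnorm_ > residual_tol)
    stop(sprintf("not a fixed point: RHS norm %.3e exceeds %.1e", rnorm_, residual_tol))
  re <- Re(eigs)
  marginal <- any(abs(re) <= 1e-9)
  nonneg <- re > -1e-9
  stability <- if (!any(nonneg)) "STABLE"
               else if (all(nonneg)) "UNSTABLE"
               else "SADDLE"
  structure(list(state = states, eigenvalues = eigs, stability = stability,
                 marginal = marginal, residual = rnorm_),
            class = "steady_state")
}

# Deterministic low-discrepancy sequence (Halton, prime bases), used for
# multistart initial points so censuses are reproducible without seeds.
halton_seq <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("halton_seq supports up to 10 dimensions")
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  sapply(seq_len(dim), function(d)
    vapply(seq_len(n), radical_inverse, numeric(1), base = primes[d]))
}

# Damped Newton for F(y) = 0 with analytic Jacobian.
newton_multicell <- function(y0, params, W, max_iter = 60, tol = 1e-11) {
  n <- nrow(W)
  y <- y0
  for (it in seq_len(max_iter)) {
    Fy <- rhs_lattice3(y, params, W, clamp = FALSE)
    nf <- sqrt(sum(Fy^2))
    if (nf < tol) return(list(root = y, converged = TRUE, fnorm = nf))
    J <- jacobian_lattice3(matrix(y, ncol = 3), params, W)
    step <- tryCatch(solve(J, -Fy), error = function(e) NULL)
    if (is.null(step)) return(list(root = y, converged = FALSE, fnorm = nf))
    lambda <- 1
    repeat {
      ynew <- y + lambda * step
      fnew <- tryCatch(sqrt(sum(rhs_lattice3(ynew, params, W, clamp = FALSE)^2)),
                       error = function(e) Inf)
      if (is.finite(fnew) && (fnew < nf || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    y <- ynew
  }
  Fy <- rhs_lattice3(y, params, W, clamp = FALSE)
  list(root = y, converged = sqrt(sum(Fy^2)) < 1e-8, fnorm = sqrt(sum(Fy^2)))
}

# Natural per-species scales used to span multistart boxes.
species_scales <- function(params) {
  NU <- params$beta_N / params$alpha_N
  DU <- params$beta_D / params$alpha_D
  c(N = NU, D = DU, R = NU * DU / params$alpha_R)
}

#' Fixed-point census of the two-cell circuit
#'
#' Finds the fixed points of the coupled six-species pair-cell MODEL3 system
#' by deterministic multistart damped-Newton root finding (Halton initial
#' points spanning \[0, 2 beta/alpha\] per species, plus the symmetric
#' self-consistent point as a warm start). Roots closer than \code{1e-6}
#' relative distance are merged; each survivor is classified with the
#' analytic Jacobian. The system is exchange-symmetric, so the census always
#' contains a symmetric point and asymmetric points arrive in swap-mirror
#' pairs.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param n_starts number of Halton multistart points (default 64).
#' @return list of [classify_stability()] results, symmetric point first.
#' @export
pair_fixed_points <- function(params, n_starts = 64) {
  validate_params(params)
  graph <- pair_graph()
  W <- graph$W
  sc <- species_scales(params)
  ub <- 2 * sc[c(1, 1, 2, 2, 3, 3)]   # layout N1 N2 D1 D2 R1 R2
  pts <- halton_seq(n_starts, 6)
  starts <- sweep(pts, 2, ub, `*`)
  # warm starts: homogeneous self-consistent state, and strongly asymmetric corners
  hom <- tryCatch(homogeneous_fixed_point(params, graph)$state,
                  error = function(e) NULL)
  extra <- rbind(
    c(sc[1], 0.01 * sc[1], 0.01 * sc[2], sc[2], sc[3], 0.01 * sc[3]),
    c(0.01 * sc[1], sc[1], sc[2], 0.01 * sc[2], 0.01 * sc[3], sc[3]))
  if (!is.null(hom)) extra <- rbind(extra, as.vector(hom[c(1, 1), ]))
  starts <- rbind(starts, extra)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_multicell(starts[i, ], params, W)
    if (!r$converged) next
    y <- r$root
    if (any(y < -1e-8)) next
    y <- pmax(y, 0)
    dup <- any(vapply(roots, function(z)
      sqrt(sum((z - y)^2)) / (1 + sqrt(sum(z^2))) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- y
  }
  out <- lapply(roots, function(y)
    classify_stability(matrix(y, ncol = 3), params, graph))
  # symmetric point(s) first, then by N of cell 1
  sym <- vapply(out, function(s)
    max(abs(s$state[1, ] - s$state[2, ])) < 1e-6 * (1 + max(abs(s$state))), logical(1))
  out[order(!sym, vapply(out, function(s) s$state[1, 1], numeric(1)))]
}

#' Single-cell input-output bifurcation branch
#'
#' Exposes one cell to a fixed external ligand level \code{D_ext} (with
#' \code{<N> = 0}: the surrounding source presents ligand but no receptor)
#' and computes every fixed point of the cell's MODEL3 system at each grid
#' value. The NOTCH level solves the scalar self-consistency equation
#' \code{beta_N f(N D_ext) - alpha_N N - N D_ext = 0}, located by dense sign
#' bracketing; DLL and NICD follow algebraically. Pure LI yields a single
#' branch monotone nonincreasing in \code{D_ext}; the positive feedback can
#' fold the branch into an S-shape with a bistable window.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param d_ext_grid increasing nonnegative external ligand levels.
#' @param n_bracket number of bracketing nodes for the scalar root search.
#' @return object of class \code{bifurcation_branch}: data.frame with
#'   columns \code{d_ext, N, D, R, stable} (several rows per \code{d_ext}
#'   where multiple fixed points coexist) plus attribute \code{fold_points}.
#' @export
single_cell_response <- function(params, d_ext_grid, n_bracket = 600) {
  validate_params(params)
  if (is.unsorted(d_ext_grid) || any(d_ext_grid < 0))
    stop("d_ext_grid must be sorted and nonnegative")
  sc <- species_scales(params)
  Nmax <- 1.05 * sc[["N"]]
  rows <- list()
  counts <- integer(length(d_ext_grid))
  for (gi in seq_along(d_ext_grid)) {
    de <- d_ext_grid[gi]
    Fn <- function(N) params$beta_N * reg_f(N * de, params) -
      params$alpha_N * N - N * de
    Ns <- tryCatch(bracket_roots(Fn, 0, Nmax, n_bracket),
                   error = function(e) numeric(0))
    if (!length(Ns)) { warning(sprintf("no root at d_ext = %g; skipped", de)); next }
    counts[gi] <- length(Ns)
    for (N in Ns) {
      x <- N * de
      D <- params$beta_D * reg_g(x, params) / params$alpha_D
      R <- x / params$alpha_R
      stable <- (reg_fp(x, params) * params$beta_N - 1) * de - params$alpha_N < -1e-9
      rows[[length(rows) + 1L]] <-
        data.frame(d_ext = de, N = N, D = D, R = R, stable = stable)
    }
  }
  br <- do.call(rbind, rows)
  # folds: midpoints of grid intervals where the root count changes
  chg <- which(diff(counts) != 0)
  folds <- (d_ext_grid[chg] + d_ext_grid[chg + 1]) / 2
  structure(br, fold_points = folds, class = c("bifurcation_branch", "data.frame"))
}

# All simple roots of a scalar function on [lo, hi] by dense sign bracketing.
bracket_roots <- function(f, lo, hi, n = 600, tol = 1e-12) {
  xs <- seq(lo, hi, length.out = n)
  fs <- vapply(xs, f, numeric(1))
  roots <- numeric(0)
  if (abs(fs[1]) < tol) roots <- c(roots, xs[1])
  for (i in seq_len(n - 1)) {
    if (is.na(fs[i]) || is.na(fs[i + 1])) next
    if (fs[i] == 0) next
    if (fs[i] * fs[i + 1] < 0) {
      r <- uniroot(f, c(xs[i], xs[i + 1]), tol = tol)$root
      roots <- c(roots, r)
    } else if (fs[i + 1] == 0) roots <- c(roots, xs[i + 1])
  }
  unique_within(roots, 1e-9 * max(1, hi))
}

unique_within <- function(x, tol) {
  if (!length(x)) return(x)
  x <- sort(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

#' Detect a hysteresis (bistable) window on a bifurcation branch
#'
#' Scans a [single_cell_response()] branch for the maximal interval of
#' external ligand levels carrying at least two stable fixed points — the
#' signature of a switch-like, history-dependent response.
#'
#' @param branch a \code{bifurcation_branch}.
#' @return list with \code{bistable} (logical), \code{window} = c(D_lo,
#'   D_hi) or NULL, and \code{fold_points} carried from the branch.
#' @export
detect_hysteresis <- function(branch) {
  stopifnot(inherits(branch, "bifurcation_branch"))
  tab <- table(branch$d_ext[branch$stable])
  multi <- as.numeric(names(tab)[tab >= 2])
  if (!length(multi))
    return(list(bistable = FALSE, window = NULL,
                fold_points = attr(branch, "fold_points")))
  list(bistable = TRUE, window = c(min(multi), max(multi)),
       fold_points = attr(branch, "fold_points"))
}

#' Bistability map of the pair-cell circuit over Hill-coefficient grids
#'
#' Runs the pair fixed-point census at every combination of the
#' lateral-inhibition cooperativity \code{h} and the positive-feedback
#' cooperativity \code{p}, recording whether at least two stable fixed
#' points coexist (intercellular bistability, i.e. the two cells can lock
#' into opposite Notch-high/Notch-low states).
#'
#' @param params base MODEL3 \code{circuit_params}; \code{S_PF = 0} encodes
#'   the pure LI circuit, in which case \code{p} is inert.
#' @param h_grid,p_grid Hill-coefficient grids (each >= 1).
#' @return logical matrix \code{length(h_grid) x length(p_grid)} with
#'   dimnames, attribute \code{n_stable} holding the stable-root counts.
#' @export
pair_bistability_map <- function(params, h_grid, p_grid = params$p) {
  bist <- matrix(NA, length(h_grid), length(p_grid),
                 dimnames = list(h = h_grid, p = p_grid))
  nstab <- bist
  for (i in seq_along(h_grid)) for (j in seq_along(p_grid)) {
    pij <- params
    pij$h <- h_grid[i]; pij$p <- p_grid[j]
    census <- pair_fixed_points(pij)
    ns <- sum(vapply(census, function(s) s$stability == "STABLE", logical(1)))
    nstab[i, j] <- ns
    bist[i, j] <- ns >= 2
  }
  structure(bist, n_stable = nstab)
}

#' Minimum lateral-inhibition cooperativity for pair bistability
#'
#' @param map a [pair_bistability_map()] result.
#' @param p_value which p column to read (default: first).
#' @return the smallest h in the map's grid with a bistable entry, or
#'   \code{Inf} if none.
#' @export
min_h_bistable <- function(map, p_value = NULL) {
  h_grid <- as.numeric(rownames(map))
  col <- if (is.null(p_value)) 1L else match(as.character(p_value), colnames(map))
  hit <- which(map[, col])
  if (!length(hit)) Inf else min(h_grid[hit])
}

#' Nullclines of the pair-cell system in a 2-D projection
#'
#' Projects the six-dimensional pair-cell system onto the \code{(N_i, N_j)}
#' plane by eliminating the non-projected species through their own
#' steady-state relations (DLL by damped Picard iteration of the coupled
#' ligand balance, NICD algebraically), then extracts the zero contours of
#' the two reduced NOTCH rate functions.
#'
#' @param params MODEL3 \code{circuit_params}.
#' @param grid_n number of grid nodes per axis.
#' @param upper upper bound of both axes (default \code{1.05 beta_N/alpha_N}).
#' @return object of class \code{phase_portrait}: list with
#'   \code{nullclines} (named list of data.frames \code{x, y, curve}),
#'   \code{fixed_points} (the pair census), and \code{hill_pair}.
#' @export
nullclines <- function(params, grid_n = 121, upper = NULL) {
  validate_params(params)
  sc <- species_scales(params)
  if (is.null(upper)) upper <- 1.05 * sc[["N"]]
  axis <- seq(0, upper, length.out = grid_n)
  DU <- sc[["D"]]
  # QSS ligand levels for a pair with NOTCH clamped at (Ni, Nj)
  qss_D <- function(Ni, Nj) {
    Di <- DU / 2; Dj <- DU / 2
    for (it in 1:200) {
      Di_new <- params$beta_D * reg_g(Ni * Dj, params) / (params$alpha_D + Nj)
      Dj_new <- params$beta_D * reg_g(Nj * Di, params) / (params$alpha_D + Ni)
      if (max(abs(Di_new - Di), abs(Dj_new - Dj)) < 1e-12 * (1 + DU)) {
        Di <- Di_new; Dj <- Dj_new; break
      }
      Di <- 0.5 * Di + 0.5 * Di_new
      Dj <- 0.5 * Dj + 0.5 * Dj_new
    }
    c(Di, Dj)
  }
  Z1 <- matrix(0, grid_n, grid_n)  # dN_i/dt
  Z2 <- matrix(0, grid_n, grid_n)  # dN_j/dt
  for (a in seq_len(grid_n)) for (b in seq_len(grid_n)) {
    Ds <- qss_D(axis[a], axis[b])
    Z1[a, b] <- params$beta_N * reg_f(axis[a] * Ds[2], params) -
      params$alpha_N * axis[a] - axis[a] * Ds[2]
    Z2[a, b] <- params$beta_N * reg_f(axis[b] * Ds[1], params) -
      params$alpha_N * axis[b] - axis[b] * Ds[1]
  }
  as_df <- function(cl) do.call(rbind, lapply(seq_along(cl), function(k)
    data.frame(x = cl[[k]]$x, y = cl[[k]]$y, curve = k)))
  lines1 <- grDevices::contourLines(axis, axis, Z1, levels = 0)
  lines2 <- grDevices::contourLines(axis, axis, Z2, levels = 0)
  if (!length(lines1) || !length(lines2))
    warning("degenerate nullcline: empty zero contour in the chosen window")
  structure(list(
    nullclines = list(dNi = as_df(lines1), dNj = as_df(lines2)),
    fixed_points = pair_fixed_points(params),
    hill_pair = c(h = params$h, p = params$p),
    axis = axis, rate_grids = list(dNi = Z1, dNj = Z2)),
    class = "phase_portrait")
}
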