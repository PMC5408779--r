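# brute-force attractor search: integrate the pair system to convergence
# from scattered initial conditions and cluster the endpoints
pair_attractors_oracle <- function(params, n_starts = 24, t_end = 400) {
  g <- pair_graph()
  set.seed(1234)
  ub <- c(params$beta_N / params$alpha_N, params$beta_D / params$alpha_D)
  ub <- c(ub, prod(ub) / params$alpha_R)
  ends <- list()
  for (i in seq_len(n_starts)) {
    init <- matrix(runif(6), 2, 3) %*% diag(1.5 * ub)
    tr <- integrate_circuit(params, init, g, c(0, t_end, t_end * 1.1))
    a <- tr$species[2, , ]; b <- tr$species[3, , ]
    if (max(abs(a - b)) > 1e-6 * (1 + max(abs(b)))) next  # not settled
    dup <- any(vapply(ends, function(z)
      max(abs(z - b)) < 1e-4 * (1 + max(abs(z))), logical(1)))
    if (!dup) ends[[length(ends) + 1L]] <- b
  }
  ends
}

test_that("LI single-cell response is a single monotone branch", {
  grid <- seq(0, 12, length.out = 81)
  br <- single_cell_response(li(), grid)
  expect_true(all(table(br$d_ext) == 1))
  expect_true(all(br$stable))
  expect_true(all(diff(br$D) <= 1e-9))
  # no external ligand: internal ligand at its unrepressed level
  expect_equal(br$D[br$d_ext == 0], li()$beta_D / li()$alpha_D)
  expect_false(detect_hysteresis(br)$bistable)
})

test_that("positive feedback folds the single-cell branch into a bistable window", {
  grid <- seq(0, 12, length.out = 161)
  br <- single_cell_response(pfli(), grid)
  counts <- table(br$d_ext)
  expect_true(all(counts %in% c(1, 3)))
  expect_gt(sum(counts == 3), 0)
  hy <- detect_hysteresis(br)
  expect_true(hy$bistable)
  expect_length(hy$fold_points, 2)
  expect_lt(hy$fold_points[1], hy$window[1])
  expect_gt(hy$fold_points[2], hy$window[2])
  # every reported point is a genuine fixed point of the driven cell
  for (k in sample(nrow(br), 20)) {
    res <- rhs_model3(unlist(br[k, c("N", "D", "R")]), pfli(),
                      meanD = br$d_ext[k], meanN = 0)
    expect_lt(sqrt(sum(res^2)), 1e-7)
  }
})

test_that("pair census finds the symmetric point and mirror-paired asymmetric points", {
  census <- pair_fixed_points(pfli())
  states <- lapply(census, function(s) s$state)
  is_sym <- vapply(states, function(st)
    max(abs(st[1, ] - st[2, ])) < 1e-6 * (1 + max(st)), logical(1))
  expect_gte(sum(is_sym), 1)
  asym <- states[!is_sym]
  for (st in asym) {
    swapped <- st[2:1, ]
    found <- any(vapply(asym, function(z)
      max(abs(z - swapped)) < 1e-5 * (1 + max(z)), logical(1)))
    expect_true(found)
  }
  # every reported point is a fixed point with tiny residual
  for (s in census) expect_lt(s$residual, 1e-8)
})

test_that("pair census stable set matches the brute-force integration oracle", {
  for (params in list(pfli(), li())) {
    census <- stable_states(pair_fixed_points(params))
    oracle <- pair_attractors_oracle(params)
    expect_equal(length(oracle), length(census))
    for (end in oracle) {
      hit <- any(vapply(census, function(s)
        max(abs(s$state - end)) < 1e-3 * (1 + max(end)), logical(1)))
      expect_true(hit)
    }
  }
})

test_that("stability classification matches analytic structure and finite differences", {
  p <- with_fields(li(), S_LI = 0)  # fully linear decoupled cell
  st <- matrix(c(p$beta_N / p$alpha_N, p$beta_D / p$alpha_D, 0), 1, 3)
  ss <- classify_stability(st, p, d_ext = 0)
  expect_equal(ss$stability, "STABLE")
  expect_setequal(round(Re(ss$eigenvalues), 8),
                  round(-c(p$alpha_N, p$alpha_D, p$alpha_R), 8))
  # analytic multicell Jacobian vs central differences at a generic state
  g <- pair_graph()
  set.seed(3)
  states <- matrix(runif(6, 0.5, 5), 2, 3)
  J_an <- notchcrypt:::jacobian_lattice3(states, pfli(), g$W)
  J_fd <- notchcrypt:::jacobian_fd(function(y)
    notchcrypt:::rhs_lattice3(y, pfli(), g$W, clamp = FALSE),
    as.vector(states))
  expect_lt(max(abs(J_an - J_fd)) / max(abs(J_an)), 1e-6)
  expect_error(classify_stability(states, pfli(), g), "not a fixed point")
})

test_that("in the bistable regime the symmetric pair state is not an attractor", {
  census <- pair_fixed_points(pfli())
  is_sym <- vapply(census, function(s)
    max(abs(s$state[1, ] - s$state[2, ])) < 1e-6 * (1 + max(s$state)), logical(1))
  sym_classes <- vapply(census[is_sym], function(s) s$stability, character(1))
  expect_true(any(sym_classes %in% c("UNSTABLE", "SADDLE")))
})

test_that("stability class predicts the fate of perturbed trajectories", {
  set.seed(41)
  g <- pair_graph()
  n_checked <- 0
  for (i in 1:20) {
    p <- with_fields(pfli(),
                     beta_N = runif(1, 6, 24), beta_D = runif(1, 6, 40),
                     h = sample(2:4, 1), S_PF = sample(c(0, 0.98), 1))
    census <- tryCatch(pair_fixed_points(p), error = function(e) list())
    for (s in census) {
      if (s$marginal) next
      y0 <- s$state * (1 + 0.01 * matrix(runif(6, -1, 1), 2, 3))
      tr <- integrate_circuit(p, y0, g, c(0, 60))
      drift <- max(abs(tr$species[2, , ] - s$state))
      start_off <- max(abs(y0 - s$state))
      if (s$stability == "STABLE") expect_lt(drift, start_off + 1e-4)
      else expect_gt(drift, 5 * start_off)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("pair bistability requires less cooperativity with the feedback", {
  map_li <- pair_bistability_map(li(), h_grid = 1:3)
  map_pf <- pair_bistability_map(pfli(), h_grid = 1:3)
  expect_false(map_li["1", 1])
  expect_true(map_li["2", 1])
  expect_true(map_pf["1", 1])
  expect_gt(min_h_bistable(map_li), min_h_bistable(map_pf))
  # bistability is monotone in h at these defaults
  for (m in list(map_li, map_pf)) {
    v <- m[, 1]
    expect_true(all(diff(as.integer(v)) >= 0))
  }
})

test_that("nullcline curves pass through the census fixed points and swap-map onto each other", {
  pp <- nullclines(pfli(), grid_n = 61)
  expect_s3_class(pp, "phase_portrait")
  expect_gt(nrow(pp$nullclines$dNi), 0)
  # exchange symmetry: the two rate grids are transposes
  expect_equal(pp$rate_grids$dNi, t(pp$rate_grids$dNj), tolerance = 1e-9)
  # every fixed point's (N_i, N_j) projection zeroes both reduced rates
  axis <- pp$axis
  for (s in pp$fixed_points) {
    Ni <- s$state[1, 1]; Nj <- s$state[2, 1]
    # reduced rates interpolated at the projection
    fi <- approx2 <- function(Z, x, y) {
      ix <- findInterval(x, axis); iy <- findInterval(y, axis)
      Z[ix, iy]
    }
    step <- diff(axis[1:2])
    scale <- max(abs(pp$rate_grids$dNi))
    expect_lt(abs(fi(pp$rate_grids$dNi, Ni, Nj)) / scale, 0.2)
  }
  # the grid rates change sign across the zero contour (sign-grid oracle)
  Z <- pp$rate_grids$dNi
  expect_true(any(Z > 0) && any(Z < 0))
})
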