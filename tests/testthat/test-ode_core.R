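test_that("Hill activation and repression match their closed forms", {
  expect_equal(hill_activation(1.7, 1.7, 3), 0.5)
  expect_equal(hill_activation(0, 1, 2), 0)
  expect_equal(hill_activation(2, 1, 4), 16 / 17)
  expect_equal(hill_repression(0, 2, 3), 1)
  expect_equal(hill_repression(0.4, 0.4, 5), 0.5)
  expect_equal(hill_repression(3, 1, 2), 0.1)
  expect_error(hill_activation(1, -1, 2), "positive")
  expect_error(hill_activation(1, 1, 0.5), ">= 1")
  expect_error(hill_repression(-1, 1, 2), "nonnegative")
})

test_that("activation and repression are complementary and monotone", {
  set.seed(11)
  x <- sort(runif(200, 0, 20))
  for (k in c(0.3, 1, 5)) for (e in c(1, 2, 4)) {
    expect_equal(hill_activation(x, k, e) + hill_repression(x, k, e),
                 rep(1, length(x)))
    expect_true(all(diff(hill_activation(x, k, e)) >= 0))
  }
})

test_that("five-species derivatives reduce to basal synthesis at the origin", {
  p2 <- fixture_params_model2("li_default")  # S_PF = 0
  d <- rhs_model2(rep(0, 5), p2, meanD = 0, meanN = 0)
  expect_equal(d, c(p2$beta_nm, 0, p2$beta_dm, 0, 0))
})

test_that("five-species derivatives match an independent term-by-term evaluation", {
  p2 <- fixture_params_model2("pfli_default")
  state <- c(Nm = 0.7, N = 2.1, Dm = 1.3, D = 0.4, R = 5.2)
  meanD <- 1.9; meanN <- 0.8
  x <- state[["N"]] * meanD
  sig <- x^p2$p / (p2$k_p^p2$p + x^p2$p)
  del <- p2$k_d^p2$h / (p2$k_d^p2$h + x^p2$h)
  oracle <- c(
    p2$beta_nm * ((1 - p2$S_PF) + p2$S_PF * sig) - p2$alpha_n * state[["Nm"]],
    p2$beta_N * state[["Nm"]] - p2$alpha_N * state[["N"]] - x,
    p2$beta_dm * ((1 - p2$S_LI) + p2$S_LI * del) - p2$alpha_d * state[["Dm"]],
    p2$beta_D * state[["Dm"]] - p2$alpha_D * state[["D"]] - meanN * state[["D"]],
    x - p2$alpha_R * state[["R"]])
  expect_equal(rhs_model2(state, p2, meanD, meanN), oracle)
  expect_error(rhs_model2(c(-0.1, 1, 1, 1, 1), p2, 0, 0), "negative")
})

test_that("any NICD fixed point satisfies R* = N <D> / alpha_R", {
  p2 <- fixture_params_model2("pfli_default")
  state <- c(1, 3, 1, 2, 3 * 1.5 / p2$alpha_R)  # R chosen to zero dR
  d <- rhs_model2(state, p2, meanD = 1.5, meanN = 0.2)
  expect_equal(d[5], 0)
})

test_that("protein-model derivatives match the printed equations and limits", {
  p <- pfli()
  # S_PF = 0, meanD = 0: receptor decays linearly toward beta_N / alpha_N
  pl <- li()
  st <- c(2, 1, 0.5)
  expect_equal(rhs_model3(st, pl, 0, 0)[1], pl$beta_N - pl$alpha_N * 2)
  # saturated repression: ligand production fully off, pure decay
  psat <- with_fields(p, S_LI = 1)
  d <- rhs_model3(c(50, 3, 1), psat, meanD = 50, meanN = 0)
  expect_equal(d[2], -psat$alpha_D * 3, tolerance = 1e-6)
  # independent term-by-term oracle at generic state
  st <- c(1.3, 0.8, 2.2); meanD <- 2.4; meanN <- 1.1
  x <- st[1] * meanD
  sig <- x^p$p / (p$k_p^p$p + x^p$p)
  del <- p$k_d^p$h / (p$k_d^p$h + x^p$h)
  oracle <- c(
    p$beta_N * ((1 - p$S_PF) + p$S_PF * sig) - p$alpha_N * st[1] - x,
    p$beta_D * ((1 - p$S_LI) + p$S_LI * del) - p$alpha_D * st[2] - meanN * st[2],
    x - p$alpha_R * st[3])
  expect_equal(rhs_model3(st, p, meanD, meanN), oracle)
})

test_that("pure-LI protein equations agree with an independently coded LI RHS", {
  p <- li()
  set.seed(7)
  for (i in 1:25) {
    st <- runif(3, 0, 10); mD <- runif(1, 0, 5); mN <- runif(1, 0, 5)
    expect_equal(rhs_model3(st, p, mD, mN), li_rhs_independent(st, p, mD, mN))
  }
})

test_that("quasi-steady-state reduction applies the printed substitution", {
  p2 <- circuit_params(beta_N = 1, beta_D = 3, alpha_N = 1, alpha_D = 1,
                       alpha_R = 1, alpha_n = 2, alpha_d = 3,
                       beta_nm = 2, beta_dm = 6, k_p = 1, k_d = 1,
                       S_PF = 0.5, S_LI = 1, p = 2, h = 2,
                       model_form = "MODEL2")
  p3 <- qssa_reduce(p2)
  expect_equal(p3$beta_N, 1 * 2 / 2)   # beta_N * beta_nm / alpha_n
  expect_equal(p3$beta_D, 3 * 6 / 3)
  expect_equal(p3$model_form, "MODEL3")
  expect_equal(p3$S_PF, p2$S_PF)
  # identity when beta_nm = alpha_n and beta_dm = alpha_d
  p2b <- fixture_params_model2("pfli_default", mrna_scale = 10)
  p3b <- qssa_reduce(p2b)
  m3 <- fixture_params("pfli_default")
  expect_equal(p3b$beta_N, m3$beta_N)
  expect_equal(p3b$beta_D, m3$beta_D)
  expect_error(qssa_reduce(m3), "MODEL2")
})

test_that("MODEL2 trajectories converge to the reduced MODEL3 as mRNA turnover grows", {
  m3 <- fixture_params("pfli_default")
  g <- pair_graph()
  times <- seq(0, 15, length.out = 61)
  init3 <- matrix(c(1, 0.5, 2, 3, 0.5, 0.2), 2, 3)
  tr3 <- integrate_circuit(m3, init3, g, times)
  errs <- sapply(c(10, 100, 1000), function(scale) {
    p2 <- fixture_params_model2("pfli_default", mrna_scale = scale)
    # mRNA initialized at its quasi-steady level for the starting proteins,
    # so the comparison is free of the fast relaxation boundary layer
    x0 <- init3[, 1] * rev(init3[, 2])   # pair: <D>_i = D_j
    f0 <- (1 - p2$S_PF) + p2$S_PF * hill_activation(x0, p2$k_p, p2$p)
    g0 <- (1 - p2$S_LI) + p2$S_LI * hill_repression(x0, p2$k_d, p2$h)
    init2 <- cbind(Nm = (p2$beta_nm / p2$alpha_n) * f0, init3[, 1, drop = FALSE],
                   Dm = (p2$beta_dm / p2$alpha_d) * g0, init3[, 2:3])
    tr2 <- integrate_circuit(p2, init2, g, times)
    max(abs(tr2$species[, , c("N", "D", "R")] - tr3$species))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("integration is deterministic and respects the linear closed form", {
  p <- with_fields(li(), S_LI = 0)  # fully unregulated: linear dynamics
  g1 <- neighbor_graph(list(integer(0)))  # single decoupled cell
  times <- seq(0, 10, length.out = 51)
  tr <- integrate_circuit(p, matrix(c(0, 0, 0), 1, 3), g1, times)
  closed <- p$beta_N / p$alpha_N * (1 - exp(-p$alpha_N * times))
  expect_equal(as.vector(tr$species[, 1, "N"]), closed, tolerance = 1e-6)
  tr2 <- integrate_circuit(p, matrix(c(0, 0, 0), 1, 3), g1, times)
  expect_identical(tr$species, tr2$species)
  # holding at the exact fixed point leaves the state unchanged
  fp <- matrix(c(p$beta_N / p$alpha_N, p$beta_D / p$alpha_D, 0), 1, 3)
  tr3 <- integrate_circuit(p, fp, g1, c(0, 50))
  expect_equal(tr3$species[2, , ], tr3$species[1, , ], tolerance = 1e-6)
})

test_that("species stay nonnegative from arbitrary nonnegative starts", {
  set.seed(23)
  g <- build_lattice(3, 3, "HEX_PERIODIC")
  for (i in 1:6) {
    p <- with_fields(pfli(),
                     beta_N = runif(1, 2, 30), beta_D = runif(1, 2, 30),
                     h = sample(1:4, 1), S_PF = runif(1))
    init <- matrix(runif(27, 0, 20), 9, 3)
    tr <- integrate_circuit(p, init, g, seq(0, 30, length.out = 31))
    expect_true(all(tr$species >= 0))
  }
})

test_that("trajectory long-format export is tidy and complete", {
  p <- li()
  g <- pair_graph()
  tr <- integrate_circuit(p, matrix(1, 2, 3), g, seq(0, 1, 0.5))
  long <- trajectory_long(tr)
  expect_equal(nrow(long), 3 * 2 * 3)
  expect_setequal(unique(long$species), c("N", "D", "R"))
  expect_equal(long$value[long$time == 0], rep(1, 6))
})

test_that("dimensional rates nondimensionalize consistently", {
  sc <- scaling_constants(t0 = 2, k_t = 0.5)
  expect_equal(sc$N0, 1); expect_equal(sc$D0, sc$R0)
  dimensional <- list(beta_n0 = 0.05, beta_n = 0.45, beta_N = 4,
                      beta_d0 = 0, beta_d = 1, beta_D = 8,
                      alpha_n = 0.5, alpha_N = 0.5, alpha_d = 0.5,
                      alpha_D = 1, alpha_R = 0.5,
                      k_p = 1.5, k_d = 0.5, p = 2, h = 2)
  p2 <- nondimensionalize(dimensional, sc)
  expect_s3_class(p2, "circuit_params")
  expect_equal(p2$model_form, "MODEL2")
  expect_equal(p2$S_PF, 0.9)
  expect_equal(p2$S_LI, 1)
  expect_equal(p2$alpha_N, 1)   # alpha_N * t0
  expect_equal(p2$k_d, 1)       # k_d / (k_t N0 D0)
})

test_that("parameter validation enforces the domain invariants", {
  expect_error(circuit_params(beta_N = -1, beta_D = 1, alpha_N = 1,
                              alpha_D = 1, alpha_R = 1, k_p = 1, k_d = 1,
                              S_PF = 0, S_LI = 1), "positive")
  expect_error(circuit_params(beta_N = 1, beta_D = 1, alpha_N = 1,
                              alpha_D = 1, alpha_R = 1, k_p = 1, k_d = 1,
                              S_PF = 1.2, S_LI = 1), "S_PF")
  expect_error(circuit_params(beta_N = 1, beta_D = 1, alpha_N = 1,
                              alpha_D = 1, alpha_R = 1, k_p = 1, k_d = 1,
                              S_PF = 0.5, S_LI = 1, h = 0.3), "h")
  p2 <- fixture_params_model2("pfli_default")
  expect_equal(p2$beta_nm, p2$beta_n0 + p2$beta_n)
  expect_equal(p2$beta_dm, p2$beta_d0 + p2$beta_d)
})
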