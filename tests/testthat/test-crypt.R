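# compact configuration used throughout: ~16 cells keeps single tests fast
small_config <- function(...) {
  crypt_config(lattice_nx = 100, lattice_ny = 26, n_cells = 16, ...)
}

test_that("initial worlds are reproducible and sit on the support at the uniform state", {
  cfg <- small_config()
  p <- pfli()
  set.seed(42); w1 <- init_crypt(cfg, p)
  set.seed(42); w2 <- init_crypt(cfg, p)
  expect_identical(w1$lattice, w2$lattice)
  expect_identical(w1$signaling, w2$signaling)
  contacts <- notchcrypt:::cpm_contacts(w1$lattice, length(w1$type_of_id))
  cells <- 3:length(w1$type_of_id)
  expect_true(all(contacts[cells, 2] > 0))   # every cell touches SUPPORT
  hom <- homogeneous_fixed_point(p)
  spread <- max(abs(w1$signaling[cells, 3] / hom$state[3] - 1))
  expect_lte(spread, cfg$init_noise + 1e-12)
})

test_that("zero-temperature dynamics never increase the effective energy", {
  cfg <- small_config(potts_temperature = 0)
  set.seed(1)
  w <- init_crypt(cfg, pfli())
  E0 <- notchcrypt:::cpm_total_energy(w$lattice, w$type_of_id, w$target_vol,
                                      w$lambda_vol, cfg$adhesion_J)
  for (i in 1:20) potts_step(w)
  E1 <- notchcrypt:::cpm_total_energy(w$lattice, w$type_of_id, w$target_vol,
                                      w$lambda_vol, cfg$adhesion_J)
  expect_lte(E1, E0 + 1e-9)
})

test_that("incremental energy bookkeeping matches recomputation from scratch", {
  cfg <- small_config()
  set.seed(2)
  w <- init_crypt(cfg, pfli())
  E <- notchcrypt:::cpm_total_energy(w$lattice, w$type_of_id, w$target_vol,
                                     w$lambda_vol, cfg$adhesion_J)
  for (i in 1:50) {
    potts_step(w)
    E <- E + w$last_energy_delta
  }
  E_scratch <- notchcrypt:::cpm_total_energy(w$lattice, w$type_of_id,
                                             w$target_vol, w$lambda_vol,
                                             cfg$adhesion_J)
  expect_lt(abs(E - E_scratch), 1e-9 * max(1, abs(E_scratch)))
})

test_that("an isolated cell relaxes to its target volume", {
  cfg <- small_config()
  set.seed(3)
  reldev <- replicate(3, {
    lattice <- matrix(0L, 26, 40)
    lattice[10:13, 18:21] <- 2L   # 16 px, target 25
    type_of_id <- c(0L, 1L, 2L)
    tv <- c(0, 0, 25); lv <- c(0, 0, cfg$lambda_volume)
    for (i in 1:500)
      res <- notchcrypt:::cpm_mcs(lattice, type_of_id, tv, lv,
                                  cfg$adhesion_J, cfg$potts_temperature, 1L)
    abs(res$volumes[3] - 25) / 25
  })
  expect_lt(median(reldev), 0.05)
})

test_that("pixel bookkeeping is conserved across the full update loop", {
  cfg <- small_config()
  run <- run_crypt(cfg, pfli(), n_mcs = 150, seed = 4)
  lat <- run$final_lattice
  ids <- sort(unique(as.vector(lat)))
  live <- which(run$final_alive) - 1L
  expect_true(all(ids %in% c(0L, 1L, live)))
  # support pixels are immutable
  expect_true(all(lat[seq_len(cfg$support_rows), ] == 1L))
})

test_that("the cell-count ledger balances at every step", {
  cfg <- small_config()
  run <- run_crypt(cfg, pfli(), n_mcs = 300, seed = 7)
  ev <- run$events
  n_prev <- c(cfg$n_cells, ev$n_cells[-nrow(ev)])
  expect_equal(ev$n_cells, n_prev + ev$divisions - ev$anoikis - ev$exits)
})

test_that("identical seeds give identical sample streams", {
  cfg <- small_config()
  r1 <- run_crypt(cfg, pfli(), n_mcs = 120, seed = 9)
  r2 <- run_crypt(cfg, pfli(), n_mcs = 120, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$final_lattice, r2$final_lattice)
  expect_identical(r1$events, r2$events)
})

test_that("signaling uses contact-weighted neighbors and spares isolated cells", {
  cfg <- small_config()
  set.seed(11)
  w <- init_crypt(cfg, pfli())
  # strand one cell away from the epithelium: no epithelial contact
  w$lattice[w$lattice == 2L] <- 0L
  w$lattice[20:22, 45:47] <- 2L
  R_before <- w$signaling[3, 3]
  D_before <- w$signaling[3, 2]
  signaling_step(w)
  # no trans flux: NICD decays, ligand rises toward its unrepressed level
  expect_lt(w$signaling[3, 3], R_before)
  expect_gt(w$signaling[3, 2], D_before)
})

test_that("a frozen-mechanics two-cell crypt reproduces the pair-cell ODE trajectory", {
  p <- pfli()
  cfg <- crypt_config(lattice_nx = 40, lattice_ny = 26, n_cells = 2,
                      potts_temperature = 0, lambda_volume = 0,
                      ode_dt = 0.02)
  set.seed(13)
  w <- init_crypt(cfg, p)
  y0 <- w$signaling[3:4, ]
  n_steps <- 100
  for (i in seq_len(n_steps)) signaling_step(w)   # no potts_step: frozen
  tr <- integrate_circuit(p, y0, pair_graph(),
                          seq(0, n_steps * cfg$ode_dt, length.out = n_steps + 1))
  expect_equal(w$signaling[3:4, ], tr$species[n_steps + 1, , ],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("fates follow the NICD threshold inclusively and only stem cells grow", {
  cfg <- small_config()
  set.seed(15)
  w <- init_crypt(cfg, pfli())
  cells <- 3:length(w$type_of_id)
  w$signaling[cells, 3] <- w$threshold          # exactly at threshold
  tv0 <- sum(w$target_vol[cells])
  fate_update(w)
  expect_true(all(w$type_of_id[cells] == 2L))   # boundary inclusive: STEM
  grow <- cfg$growth_rate * cfg$turnover_multiplier
  expect_equal(sum(w$target_vol[cells]) - tv0, length(cells) * grow)
  w$signaling[cells, 3] <- 0
  tv1 <- sum(w$target_vol[cells])
  fate_update(w)
  expect_true(all(w$type_of_id[cells] == 3L))   # all PANETH
  expect_equal(sum(w$target_vol[cells]), tv1)   # no growth
})

test_that("division splits a cell into two inheriting daughters", {
  cfg <- small_config()
  set.seed(17)
  w <- init_crypt(cfg, pfli())
  vols <- tabulate(w$lattice + 1L, nbins = length(w$type_of_id))
  mother <- which.max(vols)
  v_mother <- vols[mother]
  n_before <- sum(w$alive) - 2L
  daughter <- divide_cell(w, mother)
  expect_false(is.na(daughter))
  expect_equal(sum(w$alive) - 2L, n_before + 1L)
  vols2 <- tabulate(w$lattice + 1L, nbins = length(w$type_of_id))
  expect_equal(vols2[mother] + vols2[daughter], v_mother)
  expect_gt(min(vols2[c(mother, daughter)]), 0)
  expect_equal(w$signaling[daughter, ], w$signaling[mother, ],
               ignore_attr = TRUE)
})

test_that("detached cells die and cells pushed over the margin exit", {
  cfg <- small_config()
  set.seed(19)
  w <- init_crypt(cfg, pfli())
  # detach one cell into the medium, move another over the edge margin
  victim <- 3L; migrant <- 4L
  w$lattice[w$lattice == victim - 1L] <- 0L
  w$lattice[20:23, 10:13] <- victim - 1L       # floats in MEDIUM
  w$lattice[w$lattice == migrant - 1L] <- 0L
  w$lattice[4:7, 1:3] <- migrant - 1L          # on support, inside edge margin
  out <- anoikis_and_exit(w)
  expect_equal(out$anoikis, 1L)
  expect_equal(out$exits, 1L)
  expect_false(w$alive[victim])
  expect_false(w$alive[migrant])
  expect_true(all(w$lattice != victim - 1L))
  expect_true(all(w$lattice != migrant - 1L))
})

test_that("the niche maintains a mosaic and all event classes occur", {
  cfg <- small_config()
  cfg$turnover_multiplier <- 2
  run <- run_crypt(cfg, pfli(), n_mcs = 500, seed = 21)
  ev <- colSums(run$events[, c("divisions", "anoikis", "exits")])
  expect_gt(ev[["divisions"]], 0)
  late <- run$samples[run$samples$mcs > 250, ]
  expect_gt(as.numeric(bimodality(late$nicd)), 5 / 9)
  g <- crypt_contact_graph(run)
  expect_gt(checkerboard_score(attr(g, "labels"), g), 0.5)
})

test_that("Sarle's coefficient matches its benchmark distributions", {
  set.seed(31)
  bern <- rep(c(0, 1), 3000)
  expect_equal(bimodality(bern), 1.0, tolerance = 3e-3)
  expect_equal(bimodality(rnorm(20000)), 1 / 3, tolerance = 0.03)
  expect_equal(bimodality(runif(20000)), 1 / 1.8, tolerance = 0.02)
  zv <- bimodality(rep(1, 50))
  expect_true(is.na(zv))
  expect_true(attr(zv, "zero_variance"))
  expect_error(bimodality(1:5), "at least 10")
})

test_that("suppressing the feedback arm lowers the Notch-high population", {
  cfg <- small_config(ode_dt = 0.02)
  sweep <- pf_strength_sweep(cfg, pfli(), gamma_values = c(1, 0.5, 0),
                             seeds = 1:2, n_mcs = 400)
  med <- aggregate(high_fraction ~ gamma, sweep, median)
  med <- med[order(-med$gamma), ]
  expect_true(all(diff(med$high_fraction) <= 1e-9))
  expect_gt(med$high_fraction[1], 0.3)
  expect_lt(med$high_fraction[3], 0.05)
  # reproducible per seed
  sweep2 <- pf_strength_sweep(cfg, pfli(), gamma_values = c(1, 0.5, 0),
                              seeds = 1:2, n_mcs = 400)
  expect_identical(sweep, sweep2)
})
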