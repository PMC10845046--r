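test_that("pseudo-first-order displacement matches the closed form", {
  crn <- pseudo_first_order_crn(a0 = 1e-3, unit = 1e4)
  traj <- simulate(crn, t_end = 5, dt = 0.01, rtol = 1e-10, atol = 1e-14)
  out <- crn$species$name[crn$species$role == "output"]
  k <- crn$params$k_bind
  expected <- 1e-3 * (1 - exp(-k * 1e4 * traj$time))
  got <- as.numeric(traj$conc[, out])
  sel <- traj$time > 0.05
  expect_lt(max(abs(got[sel] - expected[sel]) / expected[sel]), 1e-6)
})

test_that("settle detector recovers the closed-form 95% time", {
  crn <- pseudo_first_order_crn(a0 = 1e-3, unit = 1e4)
  traj <- simulate(crn, t_end = 10, dt = 0.001, rtol = 1e-10, atol = 1e-14)
  out <- crn$species$name[crn$species$role == "output"]
  st <- settle_time(traj, outputs = out, epsilon = 0.05)
  r <- crn$params$k_bind * 1e4
  expect_equal(st$settle_time, -log(0.05) / r, tolerance = 0.02)
})

test_that("zero input produces zero fluorescence and a decoding error", {
  crn <- compile_netlist(not_chain(0))
  crn$species$init_conc_nM[crn$species$role == "input"] <- 0
  traj <- simulate(crn, t_end = 100, dt = 0.1)
  fl <- crn$species$name[crn$species$role == "fluorescence"]
  expect_true(all(abs(plateaus(traj, fl)) < 1e-6))
  expect_error(decode_word(traj), "no fluorescence")
  st <- settle_time(traj)
  expect_equal(st$settle_time, 0)
})

test_that("fluorescence is monotone nondecreasing", {
  crn <- compile_netlist(not_chain(0))
  traj <- simulate(crn, t_end = 400, dt = 0.1)
  fl <- crn$species$name[crn$species$role == "fluorescence"]
  for (f in fl) {
    expect_gte(min(diff(traj$conc[, f])), -1e-6)
  }
})

test_that("strand conservation holds along the whole trajectory", {
  crn <- compile_netlist(build_sqrt4_netlist(9))
  traj <- simulate(crn, t_end = 50, dt = 0.5)
  C <- conservation_vectors(crn)
  totals <- traj$conc %*% t(C)
  drift <- apply(totals, 2, function(x) max(abs(x - x[1])))
  scale <- pmax(totals[1, ], 1)
  expect_lt(max(drift / scale), 1e-6)
  expect_gte(min(traj$conc), -traj$atol)
})

test_that("plateaus are insensitive to solver tolerances", {
  crn <- compile_netlist(build_sqrt4_netlist(9))
  fl <- crn$species$name[crn$species$role == "fluorescence"]
  p1 <- plateaus(simulate(crn, 200, dt = 0.5), fl)
  p2 <- plateaus(simulate(crn, 200, dt = 0.5, rtol = 0.5e-8, atol = 0.5e-6), fl)
  ref <- pmax(abs(p1), 1)
  expect_lt(max(abs(p1 - p2) / ref), 1e-3)
})

test_that("the implicit solver agrees with a fixed-step RK4 oracle", {
  # amplifier sub-network: 6 dynamical species
  crn <- compile_netlist(amplifier_only(0, unit = 1e3))
  times <- seq(0, 40, by = 2)
  ora <- oracle_rk4(crn, times, substeps = 400)
  traj <- simulate(crn, t_end = 40, dt = 2, rtol = 1e-10, atol = 1e-10)
  scale <- max(ora)
  expect_lt(max(abs(traj$conc - ora)) / scale, 1e-4)
})

test_that("fan-out and amplifier regenerate their input catalytically", {
  for (nl in list(fanout_only(0), amplifier_only(1))) {
    crn <- compile_netlist(nl)
    traj <- simulate(crn, t_end = 1000, dt = 1)
    input <- crn$species$name[crn$species$role == "input"]
    expect_gte(as.numeric(plateaus(traj, input)), 0.99 * 1e4)
  }
})

test_that("the amplifier plateau approaches its duplex concentration", {
  crn <- compile_netlist(amplifier_only(1))
  # attenuate the input to a quarter of the stage concentration
  crn$species$init_conc_nM[crn$species$role == "input"] <- 2500
  traj <- simulate(crn, t_end = 2000, dt = 1)
  out <- crn$species$name[crn$species$role == "output" &
                            crn$species$value == 1L]
  expect_equal(as.numeric(plateaus(traj, out)), 1e4, tolerance = 0.01)
})

test_that("doubling k_bind never slows a single-pathway circuit", {
  st <- function(kb) {
    nl <- build_module_demo_netlist(1, c(1, 0), 0,
                                    params = kinetic_params(k_bind = kb))
    traj <- simulate(compile_netlist(nl), t_end = 200, dt = 0.05)
    settle_time(traj)$settle_time
  }
  t1 <- st(3e-4)
  t2 <- st(6e-4)
  expect_lte(t2, t1)
})

test_that("ambiguous plateau ratios raise a decoding error", {
  crn <- compile_netlist(not_chain(0))
  traj <- simulate(crn, t_end = 100, dt = 0.1)
  # force equal plateaus on both fluorophores of the reporter
  traj$conc[, traj$reporters[[1]]$fluor0] <-
    traj$conc[, traj$reporters[[1]]$fluor1]
  expect_error(decode_word(traj), "ambiguous")
})

test_that("solver failures are reported with context, not truncated", {
  crn <- compile_netlist(not_chain(0))
  expect_error(simulate(crn, t_end = -1), "t_end")
  expect_error(settle_time(simulate(crn, 10, dt = 0.1), outputs = "nope"),
               "absent")
})
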