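test_that("classical codings give the classical one-input functions", {
  not <- make_mapping_module(1, c(1, 0), "A", "Y")
  expect_equal(module_function(not), c(1L, 0L))
  yes <- make_mapping_module(1, c(0, 1), "A", "Y")
  expect_equal(module_function(yes), c(0L, 1L))
  expect_equal(module_function(make_mapping_module(1, c(0, 0), "A", "Y")),
               c(0L, 0L))  # SET0
  expect_equal(module_function(make_mapping_module(1, c(1, 1), "A", "Y")),
               c(1L, 1L))  # SET1
})

test_that("three-input AND coding is the 0..01 vector and OR responds to 01", {
  and3 <- make_mapping_module(3, c(0, 0, 0, 0, 0, 0, 0, 1),
                              c("A", "B", "C"), "Y")
  f <- module_function(and3)
  expect_equal(f, as.integer(0:7 == 7))
  or2 <- make_mapping_module(2, c(0, 1, 1, 1), c("A0", "A1"), "Y")
  expect_equal(module_function(or2)[bits_to_index(c(1, 0)) + 1L], 1L)
})

test_that("coding <-> function is a bijection for every module of arity <= 3", {
  for (n in 1:3) {
    for (c_idx in seq_len(2^(2^n)) - 1L) {
      k <- as.integer(bitwAnd(bitwShiftR(c_idx, seq_len(2^n) - 1L), 1L))
      m <- make_mapping_module(n, k, paste0("I", seq_len(n) - 1L), "O")
      expect_identical(module_function(m), k)
      expect_identical(codes_for_function(module_function(m)), m$k_codes)
    }
  }
})

test_that("codes_for_function validates its table", {
  expect_error(codes_for_function(c(0, 1, 1)), "power of two")
  expect_error(codes_for_function(c(0, 2)), "bits")
  expect_identical(codes_for_function(c(0, 1)), c(0L, 1L))
})

test_that("realizable-function counts are 2^(2^n)", {
  e1 <- enumerate_realizable_functions(1)
  expect_equal(e1$count, 4L)
  expect_setequal(e1$names, c("SET0", "SET1", "YES", "NOT"))
  expect_equal(enumerate_realizable_functions(2)$count, 16L)
  e3 <- enumerate_realizable_functions(3)
  expect_equal(e3$count, 256L)
  expect_equal(nrow(unique(e3$tables)), 256L)
  expect_error(enumerate_realizable_functions(5), "cap")
})

test_that("mapping modules always hold 2^n duplexes, one per combination", {
  for (n in 1:3) {
    k <- rep(c(0L, 1L), length.out = 2^n)
    m <- make_mapping_module(n, k, paste0("I", seq_len(n) - 1L), "O")
    expect_length(m$duplexes, 2^n)
    combos <- matrix(unlist(lapply(m$duplexes, `[[`, "match_codes")),
                     ncol = n, byrow = TRUE)
    expect_equal(nrow(unique(combos)), 2^n)
  }
  expect_error(make_mapping_module(2, c(0, 1), c("A", "B"), "Y"), "k_codes")
  expect_error(make_mapping_module(0, integer(0), character(0), "Y"),
               "positive")
})

test_that("auxiliary gate inventories match their templates", {
  # fan-out-two: 4 duplexes + 2 fuels; fuel at 2x the same-path duplex sum
  crn <- compile_netlist(fanout_only(bit = 0, m = 2))
  sp <- crn$species
  expect_equal(sum(sp$role == "gate"), 4L)
  expect_equal(sum(sp$role == "fuel"), 2L)
  expect_equal(unique(sp$init_conc_nM[sp$role == "fuel"]), 2 * 2 * 1e4)
  # the gate (duplexes + fuels) holds 10 distinct component strands
  gate_strands <- unique(unlist(sp$strands[sp$role %in% c("gate", "fuel")]))
  expect_length(gate_strands, 10L)
  # amplifier alone: Amp0, Amp1, H0, H1 initially present (plus its input)
  amp <- compile_netlist(amplifier_only(0))
  expect_equal(sum(amp$species$init_conc_nM > 0 &
                     amp$species$gate %in% "AMP.B"), 4L)
  expect_equal(count_initial_species(amp), 5L)
  # fan-out-three: 6 duplexes + 2 fuels
  crn3 <- compile_netlist(fanout_only(bit = 1, m = 3))
  expect_equal(sum(crn3$species$role == "gate"), 6L)
  expect_equal(sum(crn3$species$role == "fuel"), 2L)
  expect_error(make_fanout_gate("A", 1), "m >= 2")
})

test_that("a triple fan-out emits three equal copies and recycles its input", {
  crn <- compile_netlist(fanout_only(bit = 1, m = 3))
  traj <- simulate(crn, t_end = 500, dt = 0.5)
  outs <- crn$species$name[crn$species$role == "output"]
  expect_length(outs, 3L)
  p <- plateaus(traj, outs)
  expect_true(all(abs(p - 1e4) / 1e4 < 0.01))
  input <- crn$species$name[crn$species$role == "input"]
  expect_gte(as.numeric(plateaus(traj, input)), 0.99 * 1e4)
})
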