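test_that("compilation is deterministic", {
  a <- compile_netlist(build_sqrt4_netlist(9))
  b <- compile_netlist(build_sqrt4_netlist(9))
  expect_identical(a$species$name, b$species$name)
  expect_identical(a$species$structure, b$species$structure)
  expect_identical(a$reactions, b$reactions)
})

test_that("netlist wiring violations are compile errors", {
  p <- kinetic_params()
  # a wire consumed by two gates without a fan-out
  nl <- netlist(list(make_mapping_module(1, c(0, 1), "A", "Y1"),
                     make_mapping_module(1, c(1, 0), "A", "Y2")),
                c(A = 1), params = p)
  expect_error(compile_netlist(nl), "fan-out")
  # the same netlist compiles once the shared wire is declared a bus
  nl$shared_wires <- "A"
  expect_s3_class(compile_netlist(nl), "dsd_crn")
  # unwired input
  expect_error(compile_netlist(netlist(
    list(make_mapping_module(1, c(0, 1), "Q", "Y")), c(A = 1), params = p)),
    "unwired")
  # doubly driven wire
  expect_error(compile_netlist(netlist(
    list(make_mapping_module(1, c(0, 1), "A", "Y", id = "Ma"),
         make_mapping_module(1, c(0, 1), "B", "Y", id = "Mb")),
    c(A = 1, B = 0), params = p)), "driven")
})

test_that("mapping-module expansion follows the sequential-displacement chain", {
  # 1-input module, input logic 0: only the matching duplex reacts
  crn1 <- compile_netlist(netlist(
    list(make_mapping_module(1, c(1, 0), "A", "Y", id = "M")),
    c(A = 0)))
  expect_length(crn1$reactions, 1L)
  expect_equal(sum(crn1$species$role == "gate"), 2L)
  out <- crn1$species[crn1$species$role == "output", ]
  expect_equal(out$value, 1L)  # NOT of 0
  # 2-input module, inputs (A1,A0) = (1,0): two prefix-matching rows bind the
  # first input, one completes -> 3 reactions, one output of logic 1 (OR)
  crn2 <- compile_netlist(netlist(
    list(make_mapping_module(2, c(0, 1, 1, 1), c("A0", "A1"), "Y", id = "M")),
    c(A0 = 0, A1 = 1)))
  expect_length(crn2$reactions, 3L)
  expect_equal(sum(crn2$species$role == "gate"), 4L)
  expect_equal(crn2$species$value[crn2$species$role == "output"], 1L)
  expect_equal(sum(crn2$species$role == "intermediate"), 2L)
})

test_that("empty netlists compile to empty networks", {
  crn <- compile_netlist(empty_netlist())
  expect_equal(nrow(crn$species), 0L)
  expect_length(crn$reactions, 0L)
  expect_equal(count_initial_species(crn), 0L)
})

test_that("expand_gate compiles a lone gate in context", {
  crn <- expand_gate(make_mapping_module(1, c(1, 0), "A", "Y"), c(A = 1))
  expect_s3_class(crn, "dsd_crn")
  expect_equal(crn$species$value[crn$species$role == "output"], 0L)
})

test_that("species-counting conventions separate inventory from involvement", {
  crn <- compile_netlist(build_exponentiation_netlist(3))
  expect_equal(count_initial_species(crn), 139L)
  expect_equal(count_initial_species(crn, involved_only = TRUE), 71L)
  # involvement is input-independent for this circuit
  crn2 <- compile_netlist(build_exponentiation_netlist(6))
  expect_equal(count_initial_species(crn2, involved_only = TRUE), 71L)
})

test_that("component-strand counting covers the computational core", {
  crn <- compile_netlist(build_sqrt4_netlist(0))
  expect_equal(count_component_strands(crn, "core"), 64L)
  expect_gt(count_component_strands(crn, "full"),
            count_component_strands(crn, "core"))
  # a single duplex contributes two strands
  one <- compile_netlist(netlist(
    list(make_mapping_module(1, c(0, 1), "A", "Y")), c(A = 0)))
  gate_sp <- one$species[one$species$role == "gate", ]
  expect_length(unique(unlist(gate_sp$strands[1])), 2L)
})

test_that("exponentiation netlist has the published gate composition", {
  nl <- build_exponentiation_netlist(0)
  types <- vapply(nl$gates, `[[`, "", "type")
  mods <- nl$gates[types == "module"]
  arities <- vapply(mods, `[[`, 0L, "n")
  expect_equal(sum(arities == 1L), 3L)   # three NOT modules
  expect_equal(sum(arities == 3L), 8L)   # eight AND modules
  expect_equal(sum(types == "amplifier"), 8L)
  expect_equal(sum(types == "reporter"), 8L)
  for (m in mods[arities == 1L]) expect_equal(m$k_codes, c(1L, 0L))
  for (m in mods[arities == 3L])
    expect_equal(m$k_codes, c(rep(0L, 7), 1L))
})

test_that("two-step mode adds explicit encounter complexes and still works", {
  nl <- not_chain(0)
  one <- compile_netlist(nl)
  two <- compile_netlist(nl, two_step = TRUE)
  expect_gt(nrow(two$species), nrow(one$species))
  expect_gt(length(two$reactions), length(one$reactions))
  expect_true(check_strand_conservation(two)$conserved)
  traj <- simulate(two, t_end = 400, dt = 0.2)
  expect_equal(decode_word(traj)$word, "1")
})

test_that("reaction counts equal matched prefixes; duplex count is coding-independent", {
  for (k_idx in c(0, 5, 15)) {
    k <- as.integer(bitwAnd(bitwShiftR(as.integer(k_idx), 0:3), 1L))
    crn <- compile_netlist(netlist(
      list(make_mapping_module(2, k, c("A0", "A1"), "Y")), c(A0 = 1, A1 = 0)))
    expect_equal(sum(crn$species$role == "gate"), 4L)
    # rows with x0 = 1: two stage-1 bindings; one completes stage 2
    expect_length(crn$reactions, 3L)
  }
})
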