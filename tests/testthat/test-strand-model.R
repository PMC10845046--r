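test_that("signal strands carry the four code variants with logic = right code", {
  variants <- expand.grid(l = 0:1, r = 0:1)
  strands <- Map(function(l, r) make_signal_strand("w", l, r),
                 variants$l, variants$r)
  expect_equal(vapply(strands, `[[`, "", "variant"),
               paste0("A", 2 * variants$l + variants$r))
  expect_equal(vapply(strands, `[[`, 0L, "value"), as.integer(variants$r))
  # exactly 4 distinct structures per wire
  expect_length(unique(vapply(strands, `[[`, "", "id")), 4L)
  for (s in strands) {
    expect_length(s$domains, 7L)
    expect_equal(s$domains[[2]]$code_bit, s$left_code)
    expect_equal(s$domains[[6]]$code_bit, s$right_code)
    expect_equal(s$domains[[4]]$kind, "toehold")
  }
})

test_that("non-bit codes are rejected", {
  expect_error(make_signal_strand("w", 2, 0), "0 or 1")
  expect_error(make_signal_strand("w", 0, -1), "0 or 1")
  expect_error(make_signal_strand("w", 0.5, 1), "0 or 1")
})

test_that("canonical names are deterministic and order-insensitive", {
  a <- make_signal_strand("X0", 0, 0)
  expect_identical(canonical_name(a$id), canonical_name(a$id))
  # same strands, different construction order -> same name
  expect_identical(canonical_name(c("B[g]", a$id)),
                   canonical_name(c(a$id, "B[g]")))
  # duplexes differing in one code bit -> different names (all 4 code pairs)
  keys <- apply(expand.grid(l = 0:1, r = 0:1), 1, function(v)
    canonical_name(c("B[g]", make_signal_strand("X0", v[1], v[2])$id)))
  expect_length(unique(keys), 4L)
})

test_that("canonical structure keys are injective on full compiled circuits", {
  for (crn in list(compile_netlist(build_sqrt4_netlist(9)),
                   compile_netlist(build_exponentiation_netlist(5)))) {
    expect_false(anyDuplicated(crn$species$structure) > 0)
    expect_false(anyDuplicated(crn$species$name) > 0)
  }
})

test_that("kinetic parameter defaults match the displacement model", {
  p <- kinetic_params()
  expect_equal(p$k_bind, 3.0e-4)
  expect_equal(p$k_unbind, 0.1126)
  expect_equal(p$unit_conc, 1e4)
  expect_error(kinetic_params(k_bind = -1))
  expect_error(kinetic_params(unit_conc = 0))
})

test_that("conservation vectors balance every reaction of both circuits", {
  for (crn in list(compile_netlist(build_sqrt4_netlist(3)),
                   compile_netlist(build_exponentiation_netlist(6)))) {
    C <- conservation_vectors(crn)
    expect_equal(dim(C), c(length(crn$strands), nrow(crn$species)))
    chk <- check_strand_conservation(crn)
    expect_true(chk$conserved)
    expect_equal(chk$max_imbalance, 0)
  }
})

test_that("an empty network has an empty conservation matrix", {
  crn <- compile_netlist(empty_netlist())
  expect_equal(nrow(crn$species), 0L)
  expect_equal(dim(conservation_vectors(crn)), c(0L, 0L))
  expect_true(check_strand_conservation(crn)$conserved)
})
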