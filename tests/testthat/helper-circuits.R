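# Shared fixture builders (all constructed in code; nothing on disk).

not_chain <- function(x = 0) build_module_demo_netlist(1, c(1, 0), x)

or_chain <- function(x) build_module_demo_netlist(2, c(0, 1, 1, 1), x)

amplifier_only <- function(bit = 0, unit = 1e4) {
  netlist(list(make_amplifier("B")),
          stats::setNames(as.integer(bit), "B"),
          params = kinetic_params(unit_conc = unit), name = "amp-only")
}

fanout_only <- function(bit = 0, m = 2, unit = 1e4) {
  netlist(list(make_fanout_gate("A", m)),
          stats::setNames(as.integer(bit), "A"),
          params = kinetic_params(unit_conc = unit), name = "fanout-only")
}

empty_netlist <- function() {
  netlist(list(), stats::setNames(integer(0), character(0)), name = "empty")
}

# Single irreversible displacement A + G -> O + W in the pseudo-first-order
# regime: a one-input YES module whose input is diluted far below the gate.
pseudo_first_order_crn <- function(a0 = 1e-3, unit = 1e4) {
  nl <- build_module_demo_netlist(1, c(0, 1), 0,
                                  params = kinetic_params(unit_conc = unit))
  nl$gates <- nl$gates[1]  # module only, no amplifier/reporter
  crn <- compile_netlist(nl)
  crn$species$init_conc_nM[crn$species$role == "input"] <- a0
  crn
}
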