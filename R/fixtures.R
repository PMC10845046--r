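# Deterministic fixture generator: random mapping modules and small random
# netlists used by property-style tests.

#' Generate deterministic test fixtures
#'
#' Produces, from a single seed, a family of random mapping modules
#' (arity 1..3, random codings) and small random netlists (a random module
#' wired to a reporter, optionally through an amplifier, plus two-level
#' module/fan-out compositions), each bundled with its expected logic
#' outcome so generated circuits can be verified against their own defining
#' tables.
#'
#' @param seed Integer seed.
#' @param n_modules Number of random modules.
#' @param n_netlists Number of random single-module netlists.
#' @param n_two_level Number of random two-level netlists (module feeding a
#'   fan-out feeding a second module).
#' @param unit_conc Circuit concentration unit, nM.
#' @return A list with `modules` and `netlists`; each netlist entry carries
#'   the `dsd_netlist` and its `expected` bit per reporter label.
#' @export
generate_fixtures <- function(seed, n_modules = 6, n_netlists = 4,
                              n_two_level = 2, unit_conc = 1e4) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  params <- kinetic_params(unit_conc = unit_conc)
  modules <- lapply(seq_len(n_modules), function(i) {
    n <- sample(1:3, 1)
    make_mapping_module(n, sample(0:1, 2^n, replace = TRUE),
                        paste0("I", seq_len(n) - 1L), "O",
                        id = paste0("RM", i))
  })
  netlists <- list()
  for (i in seq_len(n_netlists)) {
    n <- sample(1:3, 1)
    k <- sample(0:1, 2^n, replace = TRUE)
    x <- sample(0:(2^n - 1), 1)
    with_amp <- sample(c(TRUE, FALSE), 1)
    mod <- make_mapping_module(n, k, paste0("X", seq_len(n) - 1L), "O")
    gates <- list(mod)
    rep_wire <- "O"
    if (with_amp) {
      gates <- c(gates, list(make_amplifier("O")))
      rep_wire <- "O.amp"
    }
    gates <- c(gates, list(make_reporter(rep_wire, label = "Q")))
    nl <- netlist(gates, input_bits(x, n), params = params,
                  name = sprintf("fix%d", i))
    expected <- module_function(mod)[x + 1L]
    netlists[[length(netlists) + 1L]] <-
      list(nl = nl, expected = c(Q = expected), input = x)
  }
  for (i in seq_len(n_two_level)) {
    n1 <- sample(1:2, 1)
    k1 <- sample(0:1, 2^n1, replace = TRUE)
    k2 <- sample(0:1, 4, replace = TRUE)
    x <- sample(0:(2^(n1 + 1) - 1), 1)
    bits <- index_to_bits(x, n1 + 1L)
    m1 <- make_mapping_module(n1, k1, paste0("X", seq_len(n1) - 1L), "M")
    fo <- make_fanout_gate("M", 2, out_wires = c("M.a", "M.b"))
    m2 <- make_mapping_module(2, k2, c("M.a", paste0("X", n1)), "O")
    gates <- list(m1, fo, m2,
                  make_reporter("O", label = "Q"),
                  make_reporter("M.b", label = "P"))
    inputs <- stats::setNames(bits, paste0("X", seq_len(n1 + 1L) - 1L))
    nl <- netlist(gates, inputs, params = params,
                  name = sprintf("fix2l%d", i))
    v1 <- module_function(m1)[bits_to_index(bits[seq_len(n1)]) + 1L]
    v2 <- module_function(m2)[bits_to_index(c(v1, bits[n1 + 1L])) + 1L]
    netlists[[length(netlists) + 1L]] <-
      list(nl = nl, expected = c(Q = v2, P = v1), input = x)
  }
  list(modules = modules, netlists = netlists, seed = seed)
}
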