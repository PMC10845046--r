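# Prebuilt circuits: the four-bit square-root circuit and the 2^x
# exponentiation circuit, their truth tables, and a truth-table verification
# harness.

#' Construct a truth table
#'
#' @param n_in,n_out Number of input / output bits.
#' @param outputs Integer matrix (`2^n_in` rows, `n_out` columns of bits);
#'   row r+1 is the output word for input value r, columns MSB first.
#' @param labels Optional output-bit labels (MSB first).
#' @return A `dsd_truth_table`.
#' @export
truth_table <- function(n_in, n_out, outputs, labels = NULL) {
  outputs <- as.matrix(outputs)
  stopifnot(nrow(outputs) == 2^n_in, ncol(outputs) == n_out,
            all(outputs %in% c(0, 1)))
  if (is.null(labels)) labels <- paste0("Y", rev(seq_len(n_out)) - 1L)
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 outputs = outputs, labels = labels),
            class = "dsd_truth_table")
}

#' @export
print.dsd_truth_table <- function(x, ...) {
  cat(sprintf("truth table: %d inputs -> %d outputs (%s)\n", x$n_in, x$n_out,
              paste(x$labels, collapse = "")))
  invisible(x)
}

word_bits <- function(value, width) {
  # MSB-first bit vector of an integer
  rev(as.integer(bitwAnd(bitwShiftR(as.integer(value), seq_len(width) - 1L), 1L)))
}

#' Truth table of the four-bit square-root circuit
#'
#' `Y1Y0 = floor(sqrt(X3X2X1X0))` for inputs 0..15.
#' @return A `dsd_truth_table` (16 rows, outputs Y1 Y0).
#' @export
sqrt4_table <- function() {
  out <- t(vapply(0:15, function(x) word_bits(floor(sqrt(x)), 2L), integer(2)))
  truth_table(4L, 2L, out, labels = c("Y1", "Y0"))
}

#' Truth table of the exponentiation circuit
#'
#' For input `x = X2X1X0`, the 8-bit output word `Y7..Y0` is the binary
#' (one-hot) representation of `2^x`.
#' @return A `dsd_truth_table` (8 rows, outputs Y7..Y0).
#' @export
exponentiation_table <- function() {
  out <- t(vapply(0:7, function(x) word_bits(2^x, 8L), integer(8)))
  truth_table(3L, 8L, out, labels = paste0("Y", 7:0))
}

input_bits <- function(x, width) {
  if (is.character(x)) {
    stopifnot(nchar(x) == width, grepl("^[01]+$", x))
    x <- strtoi(x, base = 2L)
  }
  x <- as.integer(x)
  stopifnot(length(x) == 1, x >= 0, x < 2^width)
  # named LSB-first: X0, X1, ...
  stats::setNames(as.integer(bitwAnd(bitwShiftR(x, seq_len(width) - 1L), 1L)),
                  paste0("X", seq_len(width) - 1L))
}

#' Build the four-bit square-root netlist
#'
#' Minimal mapping-module realization: `Y1 = OR(X2, X3)` as a two-input
#' module, `Y0` as a four-input module coded from the floor-square-root
#' truth table; `X2` and `X3`, each consumed by both modules, are driven
#' through fan-out-two gates.  Both outputs end in fluorescence reporters.
#' All species at 1X = 10,000 nM.
#'
#' @param x Input value 0..15, or a 4-character bit word `"X3X2X1X0"`.
#' @param params Kinetic parameters (default: 1X = 1e4 nM).
#' @return A `dsd_netlist`.
#' @export
build_sqrt4_netlist <- function(x, params = kinetic_params(unit_conc = 1e4)) {
  inputs <- input_bits(x, 4L)
  tbl <- sqrt4_table()
  # k codes indexed by input value; Y0 is the last column, Y1 the first
  k_y0 <- tbl$outputs[, 2]
  gates <- list(
    make_fanout_gate("X2", 2, out_wires = c("X2.a", "X2.b")),
    make_fanout_gate("X3", 2, out_wires = c("X3.a", "X3.b")),
    # consumption order X2 then X3; X3 is the MSB of the row index
    make_mapping_module(2, c(0, 1, 1, 1), c("X2.a", "X3.a"), "Y1"),
    make_mapping_module(4, k_y0, c("X0", "X1", "X2.b", "X3.b"), "Y0"),
    make_reporter("Y1", label = "1"),
    make_reporter("Y0", label = "0"))
  netlist(gates, inputs, params = params, name = "sqrt4")
}

#' Build the exponentiation (2^x) netlist
#'
#' Decoder structure: three one-input NOT mapping modules, eight
#' three-input AND mapping modules (one per output bit), a fan-out-two gate
#' on every input (one branch feeds the inverter, the other the shared
#' positive-literal bus of the AND array; the inverter output is likewise a
#' shared negative-literal bus), eight catalytic amplifiers restoring the
#' AND outputs to full concentration, and eight fluorescence reporters.
#' Species at 1X = 1,000 nM; fan-out fuels at twice the sum of the same-path
#' fan-out duplexes, amplifier fuels at twice the amplifier duplexes.
#'
#' @param x Input value 0..7, or a 3-character bit word `"X2X1X0"`.
#' @param params Kinetic parameters (default: 1X = 1e3 nM).
#' @return A `dsd_netlist`.
#' @export
build_exponentiation_netlist <- function(x,
                                         params = kinetic_params(unit_conc = 1e3)) {
  inputs <- input_bits(x, 3L)
  gates <- list()
  for (i in 0:2) {
    xi <- paste0("X", i)
    gates <- c(gates, list(
      make_fanout_gate(xi, 2, out_wires = paste0(xi, c(".not", ".bus"))),
      make_mapping_module(1, c(1, 0), paste0(xi, ".not"), paste0("N", i),
                          id = paste0("NOT.X", i))))
  }
  for (j in 0:7) {
    bits <- index_to_bits(j, 3L)  # (b0, b1, b2)
    lits <- ifelse(bits == 1L, paste0("X", 0:2, ".bus"), paste0("N", 0:2))
    gates <- c(gates, list(
      make_mapping_module(3, c(0, 0, 0, 0, 0, 0, 0, 1), lits,
                          paste0("Z", j), id = paste0("AND.", j)),
      make_amplifier(paste0("Z", j))))
  }
  # reporters MSB first so the decoded word reads Y7..Y0
  for (j in 7:0)
    gates <- c(gates, list(make_reporter(paste0("Z", j, ".amp"),
                                         label = as.character(j),
                                         id = paste0("REP.", j))))
  netlist(gates, inputs, params = params,
          shared_wires = c(paste0("X", 0:2, ".bus"), paste0("N", 0:2)),
          name = "exponentiation")
}

#' Build a single-module demonstration chain
#'
#' One n-input mapping module followed by an amplifier and a fluorescence
#' reporter -- the stage layout used to read out a lone gate.  Input wires
#' are `X0..X(n-1)`; the reporter label is `"Q"`.
#'
#' @param n Module arity.
#' @param k_codes Coding bits (length `2^n`), e.g. `c(1, 0)` for NOT.
#' @param x Input value (0..2^n-1) or bit word (`"X(n-1)..X0"`).
#' @param params Kinetic parameters (default 1X = 1e4 nM).
#' @return A `dsd_netlist`.
#' @examples
#' nl <- build_module_demo_netlist(1, c(1, 0), 0)  # NOT gate, input logic 0
#' @export
build_module_demo_netlist <- function(n, k_codes, x,
                                      params = kinetic_params(unit_conc = 1e4)) {
  inputs <- input_bits(x, n)
  gates <- list(
    make_mapping_module(n, k_codes, names(inputs), "O"),
    make_amplifier("O"),
    make_reporter("O.amp", label = "Q"))
  netlist(gates, inputs, params = params,
          name = sprintf("module%d-demo", n))
}

#' Default simulation horizons for the builtin circuits
#'
#' The horizon is chosen an order of magnitude beyond the expected settle
#' scale so the plateau used by the settle detector is a genuine steady
#' state: 300 s (grid 0.1 s) for the square-root circuit, 3,000 s (grid 1 s)
#' for the exponentiation circuit.
#'
#' @param circuit `"sqrt4"` or `"exponentiation"`.
#' @return List with `t_end` and `dt` (seconds).
#' @export
circuit_sim_defaults <- function(circuit = c("sqrt4", "exponentiation")) {
  switch(match.arg(circuit),
         sqrt4 = list(t_end = 300, dt = 0.1),
         exponentiation = list(t_end = 3000, dt = 1))
}

builtin_circuit <- function(circuit = c("sqrt4", "exponentiation")) {
  circuit <- match.arg(circuit)
  list(builder = switch(circuit, sqrt4 = build_sqrt4_netlist,
                        exponentiation = build_exponentiation_netlist),
       table = switch(circuit, sqrt4 = sqrt4_table(),
                      exponentiation = exponentiation_table()),
       defaults = circuit_sim_defaults(circuit))
}

#' Verify a circuit against its truth table
#'
#' Compiles and simulates the circuit once per input row (one input
#' assignment per run), decodes the reporter plateaus, and compares against
#' the table.  A decoding ambiguity marks the row failed with its
#' diagnostic.
#'
#' @param builder Function mapping an input value to a [netlist()] (e.g.
#'   [build_sqrt4_netlist()]).
#' @param table A [truth_table()] with matching output width.
#' @param t_end,dt Simulation horizon and grid (seconds).
#' @param epsilon Settle-band fraction.
#' @param ratio_threshold,floor_nM Decoding thresholds, see [decode_word()].
#' @param rows Input values to verify (default: all `2^n_in` rows).
#' @param two_step Use the two-step reaction mode.
#' @return A data.frame with one row per input: expected and decoded words,
#'   pass flag, settle time and the minimum plateau separation ratio.
#' @examples
#' \donttest{
#' rep <- verify_truth_table(build_sqrt4_netlist, sqrt4_table(),
#'                           t_end = 120, rows = c(0, 9))
#' }
#' @export
verify_truth_table <- function(builder, table, t_end, dt = 0.1,
                               epsilon = 0.05, ratio_threshold = 10,
                               floor_nM = 1, rows = NULL, two_step = FALSE) {
  stopifnot(is.function(builder), inherits(table, "dsd_truth_table"))
  if (is.null(rows)) rows <- seq_len(2^table$n_in) - 1L
  res <- lapply(rows, function(x) {
    expected <- paste(table$outputs[x + 1L, ], collapse = "")
    nl <- builder(x)
    crn <- compile_netlist(nl, two_step = two_step)
    traj <- simulate(crn, t_end = t_end, dt = dt)
    st <- settle_time(traj, epsilon = epsilon)
    dec <- tryCatch(decode_word(traj, ratio_threshold = ratio_threshold,
                                floor_nM = floor_nM),
                    error = function(e) e)
    if (inherits(dec, "error")) {
      data.frame(input = x, expected = expected, decoded = NA_character_,
                 decimal = NA_integer_, pass = FALSE,
                 settle_s = st$settle_time, min_ratio = NA_real_,
                 note = conditionMessage(dec))
    } else {
      ratios <- pmax(dec$table$Y_low, dec$table$Y_high) /
        pmax(pmin(dec$table$Y_low, dec$table$Y_high), traj$atol)
      data.frame(input = x, expected = expected, decoded = dec$word,
                 decimal = dec$decimal, pass = identical(dec$word, expected),
                 settle_s = st$settle_time, min_ratio = min(ratios),
                 note = "")
    }
  })
  do.call(rbind, res)
}

#' Flip one coding bit of a mapping module in a netlist
#'
#' Fault-injection helper: returns a netlist identical to `nl` except that
#' coding bit `row` (1-based) of module `gate_id` is flipped.
#'
#' @param nl A `dsd_netlist`.
#' @param gate_id Id of a mapping-module gate in the netlist.
#' @param row Index into the module's `k_codes`.
#' @return The modified netlist.
#' @export
inject_fault <- function(nl, gate_id, row) {
  stopifnot(inherits(nl, "dsd_netlist"))
  ids <- vapply(nl$gates, `[[`, "", "id")
  i <- match(gate_id, ids)
  if (is.na(i) || nl$gates[[i]]$type != "module")
    stop("gate_id must name a mapping module in the netlist", call. = FALSE)
  g <- nl$gates[[i]]
  stopifnot(row >= 1, row <= length(g$k_codes))
  k <- g$k_codes
  k[row] <- 1L - k[row]
  nl$gates[[i]] <- make_mapping_module(g$n, k, g$in_wires, g$out_wire,
                                       id = g$id)
  nl
}
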