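# Gate library: n-input mapping modules, fan-out gates, amplifiers and
# fluorescence reporters, plus the coding <-> Boolean-function correspondence.
#
# A mapping module with n inputs is a set of 2^n gate duplexes, one per input
# combination.  The duplex for combination x releases an output strand whose
# logic value is the module's coding bit k_[index(x)+1]; the vector
# k_1..k_{2^n} therefore IS the truth table, so a single module family
# realizes all 2^(2^n) n-input Boolean functions.

bits_to_index <- function(bits) {
  # bits given LSB-first (x0, x1, ...); index = sum x_i 2^i
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

index_to_bits <- function(idx, n) {
  as.integer(bitwAnd(bitwShiftR(as.integer(idx), seq_len(n) - 1L), 1L))
}

new_gate <- function(type, id, fields) {
  structure(c(list(type = type, id = id), fields), class = "dsd_gate")
}

#' @export
print.dsd_gate <- function(x, ...) {
  hdr <- switch(x$type,
    module = sprintf("%d-input mapping module '%s': (%s) -> %s, k = (%s)",
                     x$n, x$id, paste(x$in_wires, collapse = ","), x$out_wire,
                     paste(x$k_codes, collapse = ",")),
    fanout = sprintf("fan-out-%d gate '%s': %s -> (%s)", x$m, x$id, x$wire,
                     paste(x$out_wires, collapse = ",")),
    amplifier = sprintf("amplifier '%s': %s -> %s", x$id, x$wire, x$out_wire),
    reporter = sprintf("reporter '%s' on %s (label %s)", x$id, x$wire, x$label))
  cat(hdr, "\n")
  invisible(x)
}

#' Construct an n-input mapping module
#'
#' Builds the gate module made of `2^n` domain-coded duplexes, one per input
#' combination.  The duplex for combination `x` (bits consumed in wire order,
#' `in_wires[1]` first) accepts input strands whose logic values spell `x` and
#' releases an output strand of logic value `k_codes[index(x) + 1]`, where
#' `index(x)` treats the last input wire as the most significant bit.
#'
#' @param n Module arity (number of input wires), a positive integer.
#' @param k_codes Vector of `2^n` output code bits (the truth table).
#' @param in_wires Character vector of `n` distinct input wire ids, in
#'   toehold-exposure (consumption) order: the first wire is bound first.
#' @param out_wire Output wire id.
#' @param id Gate identifier (defaults to a name derived from the out wire).
#' @return A `dsd_gate` of type `"module"` whose `duplexes` list holds, per
#'   row, the `match_codes` (input combination) and `out_code`.
#' @examples
#' notg <- make_mapping_module(1, c(1, 0), "X0", "Y")   # NOT gate
#' and3 <- make_mapping_module(3, c(0,0,0,0,0,0,0,1), c("A","B","C"), "Y")
#' @export
make_mapping_module <- function(n, k_codes, in_wires, out_wire,
                                id = paste0("M.", out_wire)) {
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("module arity n must be a positive integer", call. = FALSE)
  if (length(k_codes) != 2^n || !is_bit(k_codes))
    stop(sprintf("k_codes must be %d bits for a %d-input module", 2^n, n),
         call. = FALSE)
  stopifnot(is.character(in_wires), length(in_wires) == n,
            is.character(out_wire), length(out_wire) == 1)
  if (anyDuplicated(c(in_wires, out_wire)))
    stop("module wires must be distinct", call. = FALSE)
  k_codes <- as.integer(k_codes)
  duplexes <- lapply(seq_len(2^n) - 1L, function(r) {
    list(row = r,
         match_codes = index_to_bits(r, n),
         out_code = k_codes[r + 1L])
  })
  new_gate("module", id,
           list(n = n, k_codes = k_codes, in_wires = in_wires,
                out_wire = out_wire, duplexes = duplexes))
}

#' Truth table computed by a mapping module
#'
#' Reads the function off the module's duplexes: the duplex matching input
#' combination `x` releases an output of value `out_code`, so
#' `f(x) = out_code(duplex(x))`.  This is the inverse of
#' [codes_for_function()].
#'
#' @param module A gate from [make_mapping_module()].
#' @return Integer vector of `2^n` output bits, indexed by input combination
#'   (row 1 is input 0...0; the last input wire is the most significant bit).
#' @export
module_function <- function(module) {
  stopifnot(inherits(module, "dsd_gate"), module$type == "module")
  f <- integer(2^module$n)
  for (d in module$duplexes)
    f[bits_to_index(d$match_codes) + 1L] <- d$out_code
  f
}

#' Coding bits realizing a Boolean function
#'
#' Inverse of [module_function()]: the coding domains of an n-input mapping
#' module are exactly the function's truth-table column, so any n-input
#' Boolean function is realizable by one module.
#'
#' @param truth_table Vector of output bits whose length is a power of two.
#' @return Integer vector `k_codes` usable with [make_mapping_module()].
#' @export
codes_for_function <- function(truth_table) {
  len <- length(truth_table)
  if (len < 2 || bitwAnd(len, len - 1L) != 0)
    stop("truth table length must be a power of two (>= 2)", call. = FALSE)
  if (!is_bit(truth_table))
    stop("truth table entries must be bits", call. = FALSE)
  as.integer(truth_table)
}

ONE_INPUT_FUNCTION_NAMES <- c("SET0" = "00", "YES" = "01",
                              "NOT" = "10", "SET1" = "11")

#' Enumerate the Boolean functions realizable by an n-input mapping module
#'
#' Constructs a module for every coding of the `2^n` output domains, derives
#' each truth table from the duplexes, and collects the distinct functions.
#' The count is `2^(2^n)`: 4 one-input functions (SET0, SET1, YES, NOT),
#' 16 two-input functions, 256 three-input functions.
#'
#' @param n Module arity.
#' @param cap Safety cap on `n` (the enumeration is exponential in `2^n`).
#' @return A list with `count`, the matrix `tables` (one row per distinct
#'   function), and for `n = 1` the classical function `names`.
#' @examples
#' enumerate_realizable_functions(1)$count  # 4
#' enumerate_realizable_functions(2)$count  # 16
#' @export
enumerate_realizable_functions <- function(n, cap = 4) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (n > cap)
    stop(sprintf("n = %d exceeds the enumeration cap (%d)", n, cap),
         call. = FALSE)
  wires <- paste0("I", seq_len(n) - 1L)
  n_codings <- 2^(2^n)
  tables <- matrix(NA_integer_, nrow = n_codings, ncol = 2^n)
  for (c_idx in seq_len(n_codings) - 1L) {
    k <- index_to_bits(c_idx, 2^n)
    m <- make_mapping_module(n, k, wires, "O")
    tables[c_idx + 1L, ] <- module_function(m)
  }
  keys <- apply(tables, 1, paste, collapse = "")
  distinct <- !duplicated(keys)
  out <- list(count = sum(distinct), tables = tables[distinct, , drop = FALSE])
  if (n == 1L) {
    nm <- names(ONE_INPUT_FUNCTION_NAMES)[match(keys[distinct],
                                                ONE_INPUT_FUNCTION_NAMES)]
    out$names <- nm
  }
  out
}

#' Construct a fan-out gate
#'
#' A fan-out gate copies one signal strand onto `m` downstream wires while
#' regenerating the input catalytically.  Per logic value it holds `m`
#' duplexes (F01..F0m for logic 0, F11..F1m for logic 1) plus one fuel strand
#' per logic value (H0, H1); the fuel displaces the input strand back out of
#' the post-displacement intermediate.  Fuel concentration defaults to twice
#' the summed concentration of the same-path duplexes.
#'
#' @param wire Input wire id.
#' @param m Number of copies (>= 2; for a single consumer use a YES module).
#' @param out_wires Optional character vector of `m` output wire ids.
#' @param id Gate identifier.
#' @return A `dsd_gate` of type `"fanout"`.
#' @export
make_fanout_gate <- function(wire, m = 2, out_wires = NULL,
                             id = paste0("FO.", wire)) {
  m <- as.integer(m)
  if (length(m) != 1 || is.na(m) || m < 2)
    stop("fan-out requires m >= 2 (use a YES mapping module for m = 1)",
         call. = FALSE)
  if (is.null(out_wires)) out_wires <- paste0(wire, ".c", seq_len(m))
  stopifnot(length(out_wires) == m, !anyDuplicated(c(wire, out_wires)))
  new_gate("fanout", id, list(wire = wire, m = m, out_wires = out_wires))
}

#' Construct an amplifier gate
#'
#' A catalytic amplification stage: two duplexes (Amp0, Amp1), one per logic
#' value, each paired with a fuel strand (H0, H1) at twice the duplex
#' concentration.  The incoming signal strand acts as a catalyst and the
#' output plateau approaches the duplex concentration, restoring a signal
#' attenuated by upstream competition back to full strength.
#'
#' @param wire Input wire id.
#' @param out_wire Output wire id.
#' @param id Gate identifier.
#' @return A `dsd_gate` of type `"amplifier"`.
#' @export
make_amplifier <- function(wire, out_wire = paste0(wire, ".amp"),
                           id = paste0("AMP.", wire)) {
  stopifnot(is.character(wire), length(wire) == 1,
            is.character(out_wire), length(out_wire) == 1, wire != out_wire)
  new_gate("amplifier", id, list(wire = wire, out_wire = out_wire))
}

#' Construct a fluorescence reporter gate
#'
#' Two fluorophore/quencher duplexes: Rep0 irreversibly consumes logic-0
#' signal strands on the wire and releases the fluorescence species
#' `Y_<label>1`; Rep1 consumes logic-1 strands and releases `Y_<label>2`.
#' Fluorescence accumulation is irreversible, hence monotone.
#'
#' @param wire Wire to report on.
#' @param label Output label used to name the fluorescence species
#'   (defaults to the wire id).
#' @param id Gate identifier.
#' @return A `dsd_gate` of type `"reporter"`.
#' @export
make_reporter <- function(wire, label = wire, id = paste0("REP.", wire)) {
  stopifnot(is.character(wire), length(wire) == 1)
  new_gate("reporter", id, list(wire = wire, label = label))
}
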