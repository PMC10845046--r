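# Core data model: domains, domain-coded signal strands, elementary strands,
# species identity, and kinetic parameters.
#
# A signal strand is a single DNA strand split by a central toehold "T" into a
# left and a right half of three domains each (flank, code, flank).  The middle
# (code) domain of each half carries one bit: the left code is used to
# hybridize with the upstream gate, the right code is the logic value of the
# strand.  The four variants per wire are conventionally called A0..A3 for
# codes (0,0), (0,1), (1,0), (1,1).

DEFAULT_TOEHOLD_NT <- 6L
DEFAULT_DOMAIN_NT <- 15L

#' Kinetic parameters for toehold-mediated strand displacement
#'
#' Bundles the two rate constants of the displacement model and the circuit
#' concentration unit.  Every productive displacement step is modelled as a
#' bimolecular reaction at `k_bind`; `k_unbind` is the toehold dissociation
#' rate used by the optional two-step reaction mode.
#'
#' @param k_bind Bimolecular binding rate constant, in 1/(nM s).
#' @param k_unbind Unimolecular toehold unbinding rate, in 1/s.
#' @param k_migrate Unimolecular branch-migration/resolution rate, in 1/s,
#'   used only in two-step mode.
#' @param unit_conc The circuit concentration unit "1X", in nM.
#' @return An object of class `dsd_params`.
#' @examples
#' kinetic_params()
#' kinetic_params(unit_conc = 1e3)
#' @export
kinetic_params <- function(k_bind = 3.0e-4, k_unbind = 0.1126,
                           k_migrate = 10, unit_conc = 1e4) {
  stopifnot(is.numeric(k_bind), k_bind > 0,
            is.numeric(k_unbind), k_unbind > 0,
            is.numeric(k_migrate), k_migrate > 0,
            is.numeric(unit_conc), unit_conc > 0)
  structure(list(k_bind = k_bind, k_unbind = k_unbind,
                 k_migrate = k_migrate, unit_conc = unit_conc),
            class = "dsd_params")
}

#' @export
print.dsd_params <- function(x, ...) {
  cat("DSD kinetic parameters\n")
  cat(sprintf("  k_bind    : %g /nM/s\n", x$k_bind))
  cat(sprintf("  k_unbind  : %g /s\n", x$k_unbind))
  cat(sprintf("  k_migrate : %g /s (two-step mode only)\n", x$k_migrate))
  cat(sprintf("  1X unit   : %g nM\n", x$unit_conc))
  invisible(x)
}

is_bit <- function(x) {
  length(x) > 0 && is.numeric(x) && all(x %in% c(0, 1))
}

#' Construct an abstract DNA domain
#'
#' @param name Domain identifier.  A trailing `"*"` denotes the Watson-Crick
#'   complement of the base domain.
#' @param kind One of `"toehold"`, `"flank"`, `"code"`, `"fluor"`.
#' @param code_bit The bit carried by a code domain (required iff
#'   `kind == "code"`).
#' @param length_nt Domain length in nucleotides; used only by the sequence
#'   designer.  Defaults to 6 nt for toeholds and 15 nt otherwise.
#' @return A list of class `dsd_domain`.
#' @export
domain <- function(name, kind = c("flank", "toehold", "code", "fluor"),
                   code_bit = NULL, length_nt = NULL) {
  kind <- match.arg(kind)
  if (kind == "code") {
    if (is.null(code_bit) || !is_bit(code_bit))
      stop("a code domain must carry a 0/1 code_bit", call. = FALSE)
  } else if (!is.null(code_bit) && !all(is.na(code_bit))) {
    stop("code_bit is only meaningful for code domains", call. = FALSE)
  }
  if (is.null(length_nt))
    length_nt <- if (kind == "toehold") DEFAULT_TOEHOLD_NT else DEFAULT_DOMAIN_NT
  stopifnot(length_nt >= 1)
  structure(list(name = name, kind = kind,
                 code_bit = if (kind == "code") as.integer(code_bit) else NA_integer_,
                 length_nt = as.integer(length_nt)),
            class = "dsd_domain")
}

toehold_domain <- function() domain("T", "toehold")

# Domain list for the 7-domain signal strand layout:
# flank, code(left), flank, T, flank, code(right), flank.
# Flank and code domains are wire-specific so that signals on different wires
# cannot cross-react.
signal_domains <- function(wire, left_code, right_code) {
  list(domain(paste0(wire, ".f1")),
       domain(paste0(wire, ".k", left_code), "code", code_bit = left_code),
       domain(paste0(wire, ".f2")),
       toehold_domain(),
       domain(paste0(wire, ".f3")),
       domain(paste0(wire, ".k", right_code), "code", code_bit = right_code),
       domain(paste0(wire, ".f4")))
}

new_strand <- function(id, kind, domains, wire = NA_character_,
                       value = NA_integer_) {
  structure(list(id = id, kind = kind, domains = domains,
                 wire = wire, value = value),
            class = "dsd_strand")
}

#' Construct a domain-coded signal strand
#'
#' Builds the unique 7-domain signal strand for a wire and a pair of code
#' bits.  The left code is the upstream-hybridization code, the right code is
#' the logic value of the strand.  The four code pairs (0,0), (0,1), (1,0),
#' (1,1) correspond to the strand variants A0, A1, A2 and A3.
#'
#' @param wire_id Wire identifier the strand travels on.
#' @param left_code,right_code Code bits (0 or 1).
#' @return A `dsd_strand` with fields `wire`, `value` (`= right_code`),
#'   `variant` (`"A0"`..`"A3"`) and the ordered list of 7 `domains`.
#' @examples
#' s <- make_signal_strand("X0", 0, 1)
#' s$variant  # "A1"
#' s$value    # logic 1
#' @export
make_signal_strand <- function(wire_id, left_code, right_code) {
  stopifnot(is.character(wire_id), length(wire_id) == 1, nzchar(wire_id))
  if (!is_bit(left_code) || !is_bit(right_code))
    stop("left_code and right_code must each be 0 or 1", call. = FALSE)
  left_code <- as.integer(left_code); right_code <- as.integer(right_code)
  s <- new_strand(id = sprintf("S[%s|%d%d]", wire_id, left_code, right_code),
                  kind = "signal",
                  domains = signal_domains(wire_id, left_code, right_code),
                  wire = wire_id, value = right_code)
  s$left_code <- left_code
  s$right_code <- right_code
  s$variant <- paste0("A", 2L * left_code + right_code)
  s
}

# Row-tagged output strand released by a gate duplex.  Its right half is the
# out-wire's standard (T, flank, code, flank) signal half -- this is what
# downstream gates recognise -- while its left half is specific to the duplex
# it was bound to, which is why duplexes of the same module with equal output
# codes still contribute structurally distinct top strands.
module_output_strand <- function(gate_id, row, out_wire, out_code) {
  tag <- sprintf("%s.r%d", gate_id, row)
  doms <- list(domain(paste0(tag, ".f1")),
               domain(paste0(tag, ".k", out_code), "code", code_bit = out_code),
               domain(paste0(tag, ".f2")),
               toehold_domain(),
               domain(paste0(out_wire, ".f3")),
               domain(paste0(out_wire, ".k", out_code), "code",
                      code_bit = out_code),
               domain(paste0(out_wire, ".f4")))
  new_strand(id = sprintf("S[%s|%s]", out_wire, tag), kind = "signal",
             domains = doms, wire = out_wire, value = as.integer(out_code))
}

comp_name <- function(name) {
  ifelse(endsWith(name, "*"), substr(name, 1, nchar(name) - 1),
         paste0(name, "*"))
}

comp_domain <- function(d) {
  domain(comp_name(d$name), d$kind, code_bit = d$code_bit, length_nt = d$length_nt)
}

# Template (bottom) strand of a gate duplex.  It exposes one toehold
# complement per expected input, each followed by the complement of the
# input's right signal half, and ends in the complement of the left half of
# the row's output strand.
gate_bottom_strand <- function(gate_id, row, in_wires, match_codes,
                               out_tag_domains) {
  doms <- list()
  for (i in seq_along(in_wires)) {
    w <- in_wires[[i]]; c_i <- match_codes[[i]]
    doms <- c(doms, list(
      domain("T*", "toehold"),
      domain(paste0(w, ".f3*")),
      domain(paste0(w, ".k", c_i, "*"), "code", code_bit = c_i),
      domain(paste0(w, ".f4*"))))
  }
  doms <- c(doms, lapply(out_tag_domains, comp_domain))
  new_strand(id = sprintf("B[%s.r%d]", gate_id, row), kind = "bottom",
             domains = doms)
}

fuel_strand <- function(gate_id, path_value) {
  id <- sprintf("H[%s|%d]", gate_id, path_value)
  doms <- list(domain(sprintf("%s.H%d.a", gate_id, path_value)),
               toehold_domain(),
               domain(sprintf("%s.H%d.b", gate_id, path_value)))
  new_strand(id = id, kind = "fuel", domains = doms, value = as.integer(path_value))
}

fluor_strand <- function(gate_id, path_value, label) {
  id <- sprintf("F[%s|%d]", gate_id, path_value)
  doms <- list(domain(sprintf("%s.Y%d.fluor", gate_id, path_value), "fluor"))
  s <- new_strand(id = id, kind = "fluor", domains = doms,
                  value = as.integer(path_value))
  s$label <- label
  s
}

#' Canonical structure key of a species
#'
#' Two species are the same chemical object iff they are built from the same
#' multiset of elementary strands; the canonical name is the sorted strand
#' list joined with `"+"`.  It is deterministic across runs and injective on
#' distinct structures, regardless of the order in which a complex was
#' assembled.
#'
#' @param species A species row/list with a `strands` character vector, or a
#'   bare character vector of strand ids.
#' @return A single string.
#' @export
canonical_name <- function(species) {
  strands <- if (is.character(species)) species else species$strands
  if (is.list(strands)) strands <- strands[[1]]
  stopifnot(is.character(strands), length(strands) >= 1)
  paste(sort(strands), collapse = "+")
}
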