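# Netlist -> chemical reaction network compiler.
#
# A netlist wires mapping modules, fan-out gates, amplifiers and reporters
# together and fixes one input assignment.  Compilation expands every gate by
# its reaction template into concrete species (with initial concentrations in
# nM) and irreversible mass-action displacement reactions, propagating which
# signal variants are producible on each wire so the network only contains
# reachable pathway species (all initially-present gate material is always
# included, reactive or not).

#' Assemble a circuit netlist
#'
#' @param gates List of gates from [make_mapping_module()],
#'   [make_fanout_gate()], [make_amplifier()], [make_reporter()].
#' @param inputs Named vector of input bits, one per primary input wire.
#'   Input wires carry the A0 (logic 0) or A1 (logic 1) signal variant at
#'   `unit_conc`.
#' @param params [kinetic_params()] for the circuit.
#' @param unit_conc The circuit's "1X" concentration in nM (defaults to the
#'   value in `params`).
#' @param shared_wires Wires deliberately consumed by several downstream
#'   gates from one common strand pool (a literal bus).  Any other wire with
#'   more than one consumer is a compile error: it must be driven through a
#'   fan-out gate.
#' @param reporter_conc Reporter duplex concentration; defaults to
#'   `unit_conc`.
#' @param name Circuit name (used in exports).
#' @return An object of class `dsd_netlist`.
#' @export
netlist <- function(gates, inputs, params = kinetic_params(),
                    unit_conc = params$unit_conc, shared_wires = character(),
                    reporter_conc = NULL, name = "circuit") {
  stopifnot(is.list(gates), all(vapply(gates, inherits, TRUE, "dsd_gate")))
  if (length(inputs) > 0) {
    stopifnot(!is.null(names(inputs)), all(nzchar(names(inputs))),
              !anyDuplicated(names(inputs)))
    if (!all(inputs %in% c(0, 1)))
      stop("input assignment must be bits", call. = FALSE)
  }
  stopifnot(inherits(params, "dsd_params"), unit_conc > 0)
  structure(list(gates = gates, inputs = inputs, params = params,
                 unit_conc = unit_conc, shared_wires = shared_wires,
                 reporter_conc = if (is.null(reporter_conc)) unit_conc else reporter_conc,
                 name = name),
            class = "dsd_netlist")
}

#' @export
print.dsd_netlist <- function(x, ...) {
  cat(sprintf("DSD netlist '%s': %d gates, inputs %s, 1X = %g nM\n",
              x$name, length(x$gates),
              paste0(names(x$inputs), "=", x$inputs, collapse = " "),
              x$unit_conc))
  invisible(x)
}

gate_in_wires <- function(g) {
  switch(g$type, module = g$in_wires, fanout = g$wire,
         amplifier = g$wire, reporter = g$wire)
}

gate_out_wires <- function(g) {
  switch(g$type, module = g$out_wire, fanout = g$out_wires,
         amplifier = g$out_wire, reporter = character())
}

validate_netlist <- function(nl) {
  ids <- vapply(nl$gates, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate gate ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  drivers <- c(names(nl$inputs), unlist(lapply(nl$gates, gate_out_wires)))
  dup <- drivers[duplicated(drivers)]
  if (length(dup))
    stop("wire driven more than once: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  consumed <- unlist(lapply(nl$gates, gate_in_wires))
  missing <- setdiff(consumed, drivers)
  if (length(missing))
    stop("unwired gate input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  multi <- unique(consumed[duplicated(consumed)])
  bad <- setdiff(multi, nl$shared_wires)
  if (length(bad))
    stop("wire(s) consumed by more than one gate without a fan-out gate ",
         "(or explicit shared-bus declaration): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# ---- builder ---------------------------------------------------------------

new_builder <- function(nl, two_step) {
  b <- new.env(parent = emptyenv())
  b$nl <- nl
  b$two_step <- two_step
  b$species <- list()
  b$index <- new.env(hash = TRUE, parent = emptyenv())
  b$strands <- list()
  b$reactions <- list()
  b$variants <- list()   # wire -> list(list(sp, value, strand))
  b$reporters <- list()
  b$sp_counter <- 0L
  b$w_counter <- 0L
  b
}

reg_strand <- function(b, strand) {
  if (is.null(b$strands[[strand$id]])) b$strands[[strand$id]] <- strand
  strand$id
}

species_key <- function(strands, state = NULL) {
  k <- paste(sort(strands), collapse = "+")
  if (!is.null(state)) k <- paste0(k, "#", state)
  k
}

add_species <- function(b, strands, name, role, init = 0, wire = NA_character_,
                        value = NA_integer_, gate = NA_character_,
                        state = NULL) {
  key <- species_key(strands, state)
  idx <- b$index[[key]]
  if (!is.null(idx)) {
    if (init > 0 && b$species[[idx]]$init == 0) b$species[[idx]]$init <- init
    return(idx)
  }
  idx <- length(b$species) + 1L
  b$species[[idx]] <- list(name = name, role = role, init = init,
                           strands = sort(strands), wire = wire,
                           value = value, gate = gate, key = key)
  b$index[[key]] <- idx
  idx
}

add_reaction <- function(b, reactants, products, rate, gate) {
  b$reactions[[length(b$reactions) + 1L]] <-
    list(reactants = as.integer(reactants), products = as.integer(products),
         rate = rate, gate = gate)
  invisible(NULL)
}

# One productive toehold-mediated displacement.  In one-step mode this is a
# single irreversible bimolecular reaction at k_bind; in two-step mode the
# toehold encounter is explicit (bind/unbind) followed by irreversible
# branch migration.
add_displacement <- function(b, r1, r2, products, gate) {
  p <- b$nl$params
  if (!b$two_step) {
    add_reaction(b, c(r1, r2), products, p$k_bind, gate)
  } else {
    strands <- c(b$species[[r1]]$strands, b$species[[r2]]$strands)
    enc <- add_species(b, strands, next_sp_name(b), "intermediate",
                       gate = gate, state = "enc")
    add_reaction(b, c(r1, r2), enc, p$k_bind, gate)
    add_reaction(b, enc, c(r1, r2), p$k_unbind, gate)
    add_reaction(b, enc, products, p$k_migrate, gate)
  }
}

next_sp_name <- function(b) {
  b$sp_counter <- b$sp_counter + 1L
  sprintf("sp%d", b$sp_counter)
}

next_w_name <- function(b) {
  b$w_counter <- b$w_counter + 1L
  sprintf("w%d", b$w_counter)
}

reg_variant <- function(b, wire, sp_idx, value, strand_id) {
  v <- b$variants[[wire]]
  if (is.null(v)) v <- list()
  v[[length(v) + 1L]] <- list(sp = sp_idx, value = value, strand = strand_id)
  b$variants[[wire]] <- v
}

wire_variants <- function(b, wire, value = NULL) {
  v <- b$variants[[wire]]
  if (is.null(v)) return(list())
  if (is.null(value)) v else Filter(function(x) x$value == value, v)
}

# ---- gate templates --------------------------------------------------------

expand_inputs <- function(b) {
  for (w in names(b$nl$inputs)) {
    bit <- as.integer(b$nl$inputs[[w]])
    s <- make_signal_strand(w, 0L, bit)
    reg_strand(b, s)
    idx <- add_species(b, s$id, paste0(w, ".", s$variant), "input",
                       init = b$nl$unit_conc, wire = w, value = bit)
    reg_variant(b, w, idx, bit, s$id)
  }
}

expand_module <- function(b, g) {
  conc <- b$nl$unit_conc
  for (d in g$duplexes) {
    top <- module_output_strand(g$id, d$row, g$out_wire, d$out_code)
    bottom <- gate_bottom_strand(g$id, d$row, g$in_wires, d$match_codes,
                                 top$domains[1:3])
    reg_strand(b, top); reg_strand(b, bottom)
    dup_idx <- add_species(b, c(bottom$id, top$id),
                           sprintf("%s.D%d", g$id, d$row + 1L), "gate",
                           init = conc, gate = g$id)
    expand_module_row(b, g, d, dup_idx, bottom, top)
  }
}

# Walk the sequential displacement chain of one duplex row: stage i exposes
# the toehold to the i-th input wire and only the signal variant whose logic
# value equals the row's i-th match code reacts; the final stage releases the
# row's output strand and leaves a fully bound waste duplex.
expand_module_row <- function(b, g, d, dup_idx, bottom, top) {
  n <- g$n
  recurse <- function(cur_idx, stage, bound) {
    want <- d$match_codes[stage]
    vars <- wire_variants(b, g$in_wires[stage], want)
    for (v in vars) {
      if (stage < n) {
        nxt <- add_species(b, c(bottom$id, top$id, bound, v$strand),
                           next_sp_name(b), "intermediate", gate = g$id)
        add_displacement(b, cur_idx, v$sp, nxt, g$id)
        recurse(nxt, stage + 1L, c(bound, v$strand))
      } else {
        out_idx <- add_species(b, top$id,
                               sprintf("%s.out%d", g$id, d$row + 1L),
                               "output", wire = g$out_wire,
                               value = d$out_code, gate = g$id)
        waste <- add_species(b, c(bottom$id, bound, v$strand),
                             next_w_name(b), "waste", gate = g$id)
        add_displacement(b, cur_idx, v$sp, c(out_idx, waste), g$id)
        reg_variant(b, g$out_wire, out_idx, d$out_code, top$id)
      }
    }
  }
  recurse(dup_idx, 1L, character())
}

expand_fanout <- function(b, g) {
  conc <- b$nl$unit_conc
  for (v in 0:1) {
    fuel <- fuel_strand(g$id, v)
    reg_strand(b, fuel)
    fuel_idx <- add_species(b, fuel$id, sprintf("%s.H%d", g$id, v), "fuel",
                            init = 2 * g$m * conc, value = v, gate = g$id)
    for (j in seq_len(g$m)) {
      top <- make_signal_strand(g$out_wires[j], v, v)
      bottom <- gate_bottom_strand(g$id, v * g$m + j, g$wire, v,
                                   top$domains[1:3])
      reg_strand(b, top); reg_strand(b, bottom)
      dup_idx <- add_species(b, c(bottom$id, top$id),
                             sprintf("%s.F%d%d", g$id, v, j), "gate",
                             init = conc, gate = g$id)
      for (s in wire_variants(b, g$wire, v)) {
        out_idx <- add_species(b, top$id,
                               sprintf("%s.out%d%d", g$id, v, j), "output",
                               wire = g$out_wires[j], value = v, gate = g$id)
        sp_idx <- add_species(b, c(bottom$id, s$strand), next_sp_name(b),
                              "intermediate", gate = g$id)
        add_displacement(b, s$sp, dup_idx, c(out_idx, sp_idx), g$id)
        waste <- add_species(b, c(bottom$id, fuel$id), next_w_name(b),
                             "waste", gate = g$id)
        add_displacement(b, sp_idx, fuel_idx, c(s$sp, waste), g$id)
        reg_variant(b, g$out_wires[j], out_idx, v, top$id)
      }
    }
  }
}

expand_amplifier <- function(b, g) {
  conc <- b$nl$unit_conc
  for (v in 0:1) {
    fuel <- fuel_strand(g$id, v)
    reg_strand(b, fuel)
    fuel_idx <- add_species(b, fuel$id, sprintf("%s.H%d", g$id, v), "fuel",
                            init = 2 * conc, value = v, gate = g$id)
    top <- make_signal_strand(g$out_wire, v, v)
    bottom <- gate_bottom_strand(g$id, v, g$wire, v, top$domains[1:3])
    reg_strand(b, top); reg_strand(b, bottom)
    dup_idx <- add_species(b, c(bottom$id, top$id),
                           sprintf("%s.Amp%d", g$id, v), "gate",
                           init = conc, value = v, gate = g$id)
    for (s in wire_variants(b, g$wire, v)) {
      out_idx <- add_species(b, top$id, sprintf("%s.out%d", g$id, v),
                             "output", wire = g$out_wire, value = v,
                             gate = g$id)
      sp_idx <- add_species(b, c(bottom$id, s$strand), next_sp_name(b),
                            "intermediate", gate = g$id)
      add_displacement(b, s$sp, dup_idx, c(out_idx, sp_idx), g$id)
      waste <- add_species(b, c(bottom$id, fuel$id), next_w_name(b),
                           "waste", gate = g$id)
      add_displacement(b, sp_idx, fuel_idx, c(s$sp, waste), g$id)
      reg_variant(b, g$out_wire, out_idx, v, top$id)
    }
  }
}

expand_reporter <- function(b, g) {
  conc <- b$nl$reporter_conc
  fl_names <- character(2)
  for (v in 0:1) {
    fl <- fluor_strand(g$id, v, g$label)
    qb <- new_strand(sprintf("B[%s.rep%d]", g$id, v), "bottom",
                     domains = list(domain("T*", "toehold"),
                                    domain(paste0(g$wire, ".f3*")),
                                    domain(paste0(g$wire, ".k", v, "*"),
                                           "code", code_bit = v),
                                    domain(paste0(g$wire, ".f4*")),
                                    domain(paste0(g$id, ".q", v))))
    reg_strand(b, fl); reg_strand(b, qb)
    dup_idx <- add_species(b, c(qb$id, fl$id),
                           sprintf("%s.Rep%d", g$id, v), "gate",
                           init = conc, value = v, gate = g$id)
    # The released fluorophore strand: named Y_<label>1 for logic 0,
    # Y_<label>2 for logic 1.  Always present in the network (at zero) so
    # decoding is uniform across input assignments.
    fl_name <- sprintf("Y_%s%d", g$label, v + 1L)
    fl_idx <- add_species(b, fl$id, fl_name, "fluorescence", value = v,
                          gate = g$id)
    fl_names[v + 1L] <- fl_name
    for (s in wire_variants(b, g$wire, v)) {
      waste <- add_species(b, c(qb$id, s$strand), next_w_name(b), "waste",
                           gate = g$id)
      add_displacement(b, s$sp, dup_idx, c(fl_idx, waste), g$id)
    }
  }
  b$reporters[[length(b$reporters) + 1L]] <-
    list(label = g$label, wire = g$wire, fluor0 = fl_names[1],
         fluor1 = fl_names[2], gate = g$id)
}

#' Expand one gate into its reaction template
#'
#' Mostly useful for inspection; [compile_netlist()] calls this for every
#' gate.  Returns the reactions contributed by the gate in a one-gate CRN
#' context (inputs taken from `input_values`).
#'
#' @param gate A `dsd_gate`.
#' @param input_values Named bits for the gate's input wires.
#' @param params,unit_conc Kinetics and concentration unit.
#' @return A compiled `dsd_crn` containing just this gate.
#' @export
expand_gate <- function(gate, input_values, params = kinetic_params(),
                        unit_conc = params$unit_conc) {
  nl <- netlist(list(gate), input_values, params = params,
                unit_conc = unit_conc, name = gate$id)
  compile_netlist(nl)
}

# ---- compilation -----------------------------------------------------------

#' Compile a netlist into a chemical reaction network
#'
#' Expands every gate by its displacement template, in wire-topological
#' order, propagating which signal variants are producible on each wire for
#' the given input assignment.  All initially-present material (inputs, all
#' gate duplexes, fuels, reporters) is included whether or not it can react;
#' intermediates and wastes are created only along reachable pathways.
#' Compilation is deterministic, and every emitted reaction conserves the
#' count of every elementary strand (checked before returning).
#'
#' @param nl A [netlist()].
#' @param two_step If `TRUE`, each productive displacement is expanded into
#'   an explicit reversible toehold encounter followed by irreversible branch
#'   migration; the default one-step mode uses a single irreversible
#'   bimolecular reaction at `k_bind`.
#' @return An object of class `dsd_crn` with elements `species`
#'   (data.frame: name, role, init_conc_nM, wire, value, gate, structure),
#'   `reactions`, `strands`, `reporters`, and the stoichiometry matrix.
#' @export
compile_netlist <- function(nl, two_step = FALSE) {
  stopifnot(inherits(nl, "dsd_netlist"))
  validate_netlist(nl)
  b <- new_builder(nl, two_step)
  expand_inputs(b)
  pending <- nl$gates
  while (length(pending)) {
    ready <- vapply(pending, function(g)
      all(gate_in_wires(g) %in% names(b$variants)), TRUE)
    if (!any(ready))
      stop("netlist contains a dependency cycle or a wire with no ",
           "producible signal", call. = FALSE)
    for (g in pending[ready]) {
      switch(g$type,
             module = expand_module(b, g),
             fanout = expand_fanout(b, g),
             amplifier = expand_amplifier(b, g),
             reporter = expand_reporter(b, g))
    }
    pending <- pending[!ready]
  }
  finalize_crn(b)
}

finalize_crn <- function(b) {
  sp <- b$species
  species <- data.frame(
    name = vapply(sp, `[[`, "", "name"),
    role = vapply(sp, `[[`, "", "role"),
    init_conc_nM = vapply(sp, `[[`, 0, "init"),
    wire = vapply(sp, `[[`, "", "wire"),
    value = vapply(sp, `[[`, 0L, "value"),
    gate = vapply(sp, `[[`, "", "gate"),
    structure = vapply(sp, `[[`, "", "key"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(species$name))
    stop("internal error: non-unique species names", call. = FALSE)
  species$strands <- I(lapply(sp, `[[`, "strands"))
  nr <- length(b$reactions)
  ns <- nrow(species)
  if (nr > 0) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_len(nr)) {
      r <- b$reactions[[j]]
      tab <- table(c(r$products, -r$reactants))
      idxs <- as.integer(names(tab))
      for (k in seq_along(idxs)) {
        i <- idxs[k]
        ii <- c(ii, abs(i)); jj <- c(jj, j)
        xx <- c(xx, if (i > 0) as.numeric(tab[k]) else -as.numeric(tab[k]))
      }
    }
    stoich <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, nr))
  } else {
    stoich <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(ns, 0L))
  }
  gate_types <- stats::setNames(vapply(b$nl$gates, `[[`, "", "type"),
                                vapply(b$nl$gates, `[[`, "", "id"))
  crn <- structure(list(
    species = species,
    reactions = b$reactions,
    stoich = stoich,
    strands = b$strands,
    reporters = b$reporters,
    gate_types = gate_types,
    inputs = b$nl$inputs,
    unit_conc = b$nl$unit_conc,
    params = b$nl$params,
    two_step = b$two_step,
    name = b$nl$name), class = "dsd_crn")
  chk <- check_strand_conservation(crn)
  if (!chk$conserved)
    stop("internal error: a compiled reaction does not conserve strand ",
         "counts (max imbalance ", chk$max_imbalance, ")", call. = FALSE)
  crn
}

#' @export
print.dsd_crn <- function(x, ...) {
  cat(sprintf("DSD reaction network '%s': %d species, %d reactions\n",
              x$name, nrow(x$species), length(x$reactions)))
  cat(sprintf("  initially present: %d species; inputs: %s\n",
              count_initial_species(x),
              paste0(names(x$inputs), "=", x$inputs, collapse = " ")))
  invisible(x)
}

# ---- conservation ----------------------------------------------------------

#' Elementary-strand composition of every species
#'
#' Returns the matrix C with one row per elementary strand and one column
#' per species, giving the count of that strand in the species.  Because a
#' displacement reaction only re-partitions strands between complexes, every
#' reaction conserves each row: `t(C) %*% stoich == 0`.
#'
#' @param crn A compiled `dsd_crn`.
#' @return Integer matrix (strands x species), dimnames set.
#' @export
conservation_vectors <- function(crn) {
  stopifnot(inherits(crn, "dsd_crn"))
  strand_ids <- names(crn$strands)
  ns <- nrow(crn$species)
  C <- matrix(0L, nrow = length(strand_ids), ncol = ns,
              dimnames = list(strand_ids, crn$species$name))
  for (j in seq_len(ns)) {
    tab <- table(crn$species$strands[[j]])
    C[names(tab), j] <- as.integer(tab)
  }
  C
}

#' Check strand-count conservation of every reaction
#'
#' @param crn A compiled `dsd_crn`.
#' @return List with `conserved` (logical) and `max_imbalance`.
#' @export
check_strand_conservation <- function(crn) {
  C <- conservation_vectors(crn)
  if (length(crn$reactions) == 0)
    return(list(conserved = TRUE, max_imbalance = 0))
  imbalance <- C %*% crn$stoich
  m <- max(abs(imbalance))
  list(conserved = m == 0, max_imbalance = m)
}

# ---- counting conventions --------------------------------------------------

#' Count initially-present species
#'
#' With `involved_only = FALSE` (default) counts every distinct species with
#' nonzero initial concentration: inputs, all gate duplexes, fuels and
#' reporter duplexes, reactive or not.  With `involved_only = TRUE` counts
#' only the initially-present species that take part in at least one
#' reaction for the compiled input assignment -- the species actually
#' involved in the calculation.
#'
#' @param crn A compiled `dsd_crn`.
#' @param involved_only Restrict to species participating in a reaction.
#' @return Integer count.
#' @export
count_initial_species <- function(crn, involved_only = FALSE) {
  stopifnot(inherits(crn, "dsd_crn"))
  present <- crn$species$init_conc_nM > 0
  if (!involved_only) return(sum(present))
  touched <- unique(unlist(lapply(crn$reactions, function(r)
    c(r$reactants, r$products))))
  sum(present & seq_len(nrow(crn$species)) %in% touched)
}

#' Count distinct component strands of a compiled circuit
#'
#' Counts the distinct elementary strands making up the initially-present
#' species of the selected stages, each duplex contributing its component
#' strands.  `"core"` selects the computational core: input strands,
#' mapping-module duplexes and fan-out gates (duplexes plus fuels);
#' `"full"` additionally includes amplifier and reporter material.
#'
#' @param crn A compiled `dsd_crn`.
#' @param stages `"core"` or `"full"`.
#' @return Integer count of distinct elementary strands.
#' @export
count_component_strands <- function(crn, stages = c("core", "full")) {
  stopifnot(inherits(crn, "dsd_crn"))
  stages <- match.arg(stages)
  sp <- crn$species
  keep <- sp$init_conc_nM > 0
  if (stages == "core") {
    fam <- crn$gate_types[sp$gate]
    keep <- keep & (sp$role == "input" |
                      (!is.na(fam) & fam %in% c("module", "fanout")))
  }
  length(unique(unlist(sp$strands[keep])))
}
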