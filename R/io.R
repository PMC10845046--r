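# Tabular and SBML export of compiled circuits and trajectories.

#' Write the species table of a circuit as CSV
#'
#' Columns: name, role, init_conc_nM, wire, value, structure (canonical
#' strand composition).
#'
#' @param crn A compiled `dsd_crn`.
#' @param path Output CSV path.
#' @return Invisibly, the table written.
#' @export
write_species_table <- function(crn, path) {
  stopifnot(inherits(crn, "dsd_crn"))
  tab <- crn$species[, c("name", "role", "init_conc_nM", "wire", "value",
                         "gate", "structure")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Write the gate-duplex table of a netlist as CSV
#'
#' One row per mapping-module duplex: module id, match codes (input
#' combination), output code, initial concentration.
#'
#' @param nl A `dsd_netlist`.
#' @param path Output CSV path.
#' @return Invisibly, the table written.
#' @export
write_gate_table <- function(nl, path) {
  stopifnot(inherits(nl, "dsd_netlist"))
  rows <- list()
  for (g in nl$gates) {
    if (g$type != "module") next
    for (d in g$duplexes)
      rows[[length(rows) + 1L]] <- data.frame(
        module = g$id,
        match_codes = paste(d$match_codes, collapse = ""),
        out_code = d$out_code,
        init_conc_nM = nl$unit_conc)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), match_codes = character(),
               out_code = integer(), init_conc_nM = numeric())
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Write a trajectory as CSV
#'
#' First column `time_s`, then one column per tracked species (nM).
#'
#' @param traj A `dsd_trajectory`.
#' @param path Output CSV path.
#' @param species Optional subset of species columns.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path, species = NULL) {
  stopifnot(inherits(traj, "dsd_trajectory"))
  cc <- traj$conc
  if (!is.null(species)) cc <- cc[, species, drop = FALSE]
  tab <- data.frame(time_s = traj$time, cc, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# ---- SBML ------------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

sbml_id <- function(names) {
  ids <- paste0("s_", gsub("[^A-Za-z0-9_]", "_", names))
  make.unique(ids, sep = "_")
}

#' Export a compiled circuit as SBML Level 3
#'
#' Writes an SBML L3V2 core document with one compartment, every species
#' with its initial concentration, and every reaction with a mass-action
#' kinetic law (`k * reactant1 [* reactant2]`) carrying the rate constant as
#' a local parameter.
#'
#' @param crn A compiled `dsd_crn`.
#' @param path Output path (`.xml`/`.sbml`).
#' @return Invisibly, the path.
#' @export
export_sbml <- function(crn, path) {
  stopifnot(inherits(crn, "dsd_crn"))
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model",
                               id = sbml_id(crn$name),
                               name = crn$name)
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", constant = "true",
                      spatialDimensions = "3", size = "1")
  ids <- sbml_id(crn$species$name)
  if (nrow(crn$species) > 0) {
    ls <- xml2::xml_add_child(model, "listOfSpecies")
    for (i in seq_len(nrow(crn$species))) {
      xml2::xml_add_child(ls, "species", id = ids[i],
                          name = crn$species$name[i],
                          compartment = "cell",
                          initialConcentration =
                            format(crn$species$init_conc_nM[i], digits = 15),
                          hasOnlySubstanceUnits = "false",
                          boundaryCondition = "false", constant = "false")
    }
  }
  if (length(crn$reactions) > 0) {
    lr <- xml2::xml_add_child(model, "listOfReactions")
    for (j in seq_along(crn$reactions)) {
      r <- crn$reactions[[j]]
      rx <- xml2::xml_add_child(lr, "reaction", id = sprintf("r%d", j),
                                reversible = "false")
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (tab in list(table(r$reactants))) {
        for (k in seq_along(tab))
          xml2::xml_add_child(lre, "speciesReference",
                              species = ids[as.integer(names(tab)[k])],
                              stoichiometry = as.character(as.integer(tab[k])),
                              constant = "true")
      }
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (tab in list(table(r$products))) {
        for (k in seq_along(tab))
          xml2::xml_add_child(lpr, "speciesReference",
                              species = ids[as.integer(names(tab)[k])],
                              stoichiometry = as.character(as.integer(tab[k])),
                              constant = "true")
      }
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
      apply_node <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(apply_node, "times")
      xml2::xml_add_child(apply_node, "ci", "k")
      for (ri in r$reactants)
        xml2::xml_add_child(apply_node, "ci", ids[ri])
      llp <- xml2::xml_add_child(kl, "listOfLocalParameters")
      xml2::xml_add_child(llp, "localParameter", id = "k",
                          value = format(r$rate, digits = 15))
    }
  }
  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("SBML I/O failure writing '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Read back an SBML document written by [export_sbml()]
#'
#' Standards-level reader used for round-trip checks: returns the species
#' (with initial concentrations) and reactions of an SBML L3 core model.
#'
#' @param path SBML file path.
#' @return List with `model_id`, data.frame `species` (id, name,
#'   initial_concentration), and `reactions` (list with reactant/product id
#'   vectors and rate constant `k`).
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error"))
    stop("SBML I/O failure reading '", path, "': ", conditionMessage(doc),
         call. = FALSE)
  if (xml2::xml_name(doc) != "sbml")
    stop("not an SBML document: root element is <",
         xml2::xml_name(doc), ">", call. = FALSE)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    initial_concentration =
      as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
    stringsAsFactors = FALSE)
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(n) {
    expand_refs <- function(xp) {
      refs <- xml2::xml_find_all(n, xp)
      rep(xml2::xml_attr(refs, "species"),
          times = as.integer(xml2::xml_attr(refs, "stoichiometry")))
    }
    k_node <- xml2::xml_find_first(n, ".//localParameter[@id='k']")
    list(id = xml2::xml_attr(n, "id"),
         reactants = expand_refs(".//listOfReactants/speciesReference"),
         products = expand_refs(".//listOfProducts/speciesReference"),
         k = as.numeric(xml2::xml_attr(k_node, "value")))
  })
  model <- xml2::xml_find_first(doc, ".//model")
  list(model_id = xml2::xml_attr(model, "id"), species = species,
       reactions = reactions)
}
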