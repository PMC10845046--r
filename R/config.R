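# Netlist configuration files (YAML or JSON) and named standard functions.

STANDARD_FUNCTIONS <- c("AND", "OR", "NOT", "YES", "XOR", "NAND", "NOR",
                        "SET0", "SET1")

#' Coding bits of a named standard Boolean function
#'
#' @param name One of `r paste(STANDARD_FUNCTIONS, collapse = ", ")`.
#' @param n Module arity.
#' @return `k_codes` vector of length `2^n`.
#' @export
standard_codes <- function(name, n) {
  name <- toupper(name)
  n <- as.integer(n)
  stopifnot(n >= 1)
  xs <- seq_len(2^n) - 1L
  ones <- vapply(xs, function(x) sum(index_to_bits(x, n)), 0L)
  k <- switch(name,
    AND = as.integer(xs == 2^n - 1L),
    OR = as.integer(xs > 0L),
    NAND = as.integer(xs != 2^n - 1L),
    NOR = as.integer(xs == 0L),
    XOR = as.integer(ones %% 2L == 1L),
    NOT = { stopifnot(n == 1L); c(1L, 0L) },
    YES = { stopifnot(n == 1L); c(0L, 1L) },
    SET0 = rep(0L, 2^n),
    SET1 = rep(1L, 2^n),
    stop("unknown standard function: ", name, call. = FALSE))
  k
}

config_gate <- function(spec) {
  type <- spec$type
  if (is.null(type)) stop("gate entry without a type", call. = FALSE)
  id <- spec$id
  switch(type,
    module = {
      in_wires <- as.character(unlist(spec[["in"]]))
      n <- if (!is.null(spec$n)) as.integer(spec$n) else length(in_wires)
      k <- if (!is.null(spec$k)) as.integer(unlist(spec$k))
           else if (!is.null(spec[["function"]]))
             standard_codes(spec[["function"]], n)
           else stop("module gate needs 'k' codes or a 'function' name",
                     call. = FALSE)
      args <- list(n = n, k_codes = k, in_wires = in_wires,
                   out_wire = spec$out)
      if (!is.null(id)) args$id <- id
      do.call(make_mapping_module, args)
    },
    fanout = {
      args <- list(wire = spec$wire, m = if (is.null(spec$m)) 2 else spec$m,
                   out_wires = if (is.null(spec$out)) NULL
                               else as.character(unlist(spec$out)))
      if (!is.null(id)) args$id <- id
      do.call(make_fanout_gate, args)
    },
    amplifier = {
      args <- list(wire = spec$wire)
      if (!is.null(spec$out)) args$out_wire <- spec$out
      if (!is.null(id)) args$id <- id
      do.call(make_amplifier, args)
    },
    reporter = {
      args <- list(wire = spec$wire)
      if (!is.null(spec$label)) args$label <- as.character(spec$label)
      if (!is.null(id)) args$id <- id
      do.call(make_reporter, args)
    },
    stop("unknown gate type: ", type, call. = FALSE))
}

#' Read a netlist from a YAML or JSON configuration file
#'
#' The file has sections `inputs` (wire: bit), `gates` (list of entries with
#' `type` module/fanout/amplifier/reporter and the corresponding fields; a
#' module takes either explicit `k` codes or a standard `function` name),
#' and optional `unit_conc`, `params` (`k_bind`, `k_unbind`),
#' `shared_wires`, `reporter_conc`, `name`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `dsd_netlist`.
#' @export
read_netlist_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$gates) || is.null(cfg$inputs))
    stop("config must define 'gates' and 'inputs'", call. = FALSE)
  p <- cfg$params
  params <- kinetic_params(
    k_bind = if (is.null(p$k_bind)) 3.0e-4 else p$k_bind,
    k_unbind = if (is.null(p$k_unbind)) 0.1126 else p$k_unbind,
    unit_conc = if (is.null(cfg$unit_conc)) 1e4 else cfg$unit_conc)
  gates <- lapply(cfg$gates, config_gate)
  inputs <- unlist(cfg$inputs)
  netlist(gates, stats::setNames(as.integer(inputs), names(inputs)),
          params = params,
          shared_wires = as.character(unlist(cfg$shared_wires)),
          reporter_conc = cfg$reporter_conc,
          name = if (is.null(cfg$name)) "config-circuit" else cfg$name)
}
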