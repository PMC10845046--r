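# Mass-action ODE integration of compiled reaction networks, plateau/settle
# detection, and decoding of fluorescence into logic words.

#' Simulate a compiled reaction network
#'
#' Integrates the deterministic mass-action ODEs of the network with a
#' stiff-capable solver on a fixed output grid.  Rates are in nM/s
#' (bimolecular constants in 1/(nM s)), time in seconds.
#'
#' @param crn A compiled `dsd_crn`.
#' @param t_end Final time, seconds.
#' @param dt Output grid spacing, seconds (default 0.1 s).
#' @param rtol,atol Relative / absolute (nM) solver tolerances.
#' @param method deSolve integration method; `"lsodes"` exploits the
#'   sparsity of the stoichiometry.
#' @return A `dsd_trajectory`: `time` (seconds), `conc` (time x species
#'   matrix, nM), plus the reporter map and solver settings.
#' @examples
#' nl <- build_sqrt4_netlist(9)
#' crn <- compile_netlist(nl)
#' traj <- simulate(crn, t_end = 60)
#' @export
simulate <- function(crn, t_end, dt = 0.1, rtol = 1e-8, atol = 1e-6,
                     method = "lsodes") {
  stopifnot(inherits(crn, "dsd_crn"), t_end > 0, dt > 0)
  ns <- nrow(crn$species)
  y0 <- stats::setNames(crn$species$init_conc_nM, crn$species$name)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  if (length(crn$reactions) == 0) {
    conc <- matrix(rep(y0, each = length(times)), nrow = length(times),
                   dimnames = list(NULL, names(y0)))
    return(new_trajectory(times, conc, crn, rtol, atol))
  }
  k <- vapply(crn$reactions, `[[`, 0, "rate")
  i1 <- vapply(crn$reactions, function(r) r$reactants[1], 0L)
  i2 <- vapply(crn$reactions, function(r)
    if (length(r$reactants) > 1) r$reactants[2] else NA_integer_, 0L)
  bi <- !is.na(i2)
  i2b <- i2[bi]
  S <- crn$stoich
  deriv <- function(t, y, parms) {
    v <- k * y[i1]
    v[bi] <- v[bi] * y[i2b]
    list(as.vector(S %*% v))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("ODE solver failed on circuit '%s' (istate = %d) at t <= %g s; try tighter tolerances or a smaller dt",
                 crn$name, istate[1], t_end), call. = FALSE)
  if (nrow(sol) < length(times))
    stop(sprintf("ODE solution truncated at t = %g s (of %g s) on circuit '%s'",
                 sol[nrow(sol), 1], t_end, crn$name), call. = FALSE)
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- names(y0)
  new_trajectory(as.numeric(sol[, 1]), conc, crn, rtol, atol)
}

new_trajectory <- function(time, conc, crn, rtol, atol) {
  structure(list(time = time, conc = conc, species = crn$species,
                 reporters = crn$reporters, params = crn$params,
                 unit_conc = crn$unit_conc, circuit = crn$name,
                 rtol = rtol, atol = atol),
            class = "dsd_trajectory")
}

#' @export
print.dsd_trajectory <- function(x, ...) {
  cat(sprintf("DSD trajectory of '%s': %d species over [0, %g] s (%d points)\n",
              x$circuit, ncol(x$conc), max(x$time), length(x$time)))
  invisible(x)
}

#' Final (plateau) concentrations of selected species
#'
#' @param traj A `dsd_trajectory`.
#' @param species Species names (default: all fluorescence species).
#' @return Named numeric vector of concentrations at `t_end`, nM.
#' @export
plateaus <- function(traj, species = NULL) {
  stopifnot(inherits(traj, "dsd_trajectory"))
  if (is.null(species))
    species <- traj$species$name[traj$species$role == "fluorescence"]
  missing <- setdiff(species, colnames(traj$conc))
  if (length(missing))
    stop("species absent from trajectory: ", paste(missing, collapse = ", "),
         call. = FALSE)
  traj$conc[nrow(traj$conc), species]
}

#' Settle time of tracked outputs
#'
#' Earliest grid time t* such that every tracked output stays within a band
#' of `epsilon` (fraction) around its final value for all t >= t*.  The band
#' has a small absolute floor (the solver `atol`) so that species that are
#' identically zero settle at t = 0.
#'
#' @param traj A `dsd_trajectory`.
#' @param outputs Species names to track; defaults to all fluorescence
#'   species.
#' @param epsilon Band half-width as a fraction of the final value.
#' @return A `dsd_settle` list: `settle_time` (s), `epsilon`, `t_end`, and
#'   the per-output `plateaus` (nM).
#' @export
settle_time <- function(traj, outputs = NULL, epsilon = 0.05) {
  stopifnot(inherits(traj, "dsd_trajectory"), epsilon > 0)
  if (is.null(outputs))
    outputs <- traj$species$name[traj$species$role == "fluorescence"]
  missing <- setdiff(outputs, colnames(traj$conc))
  if (length(missing))
    stop("outputs absent from trajectory: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cc <- traj$conc[, outputs, drop = FALSE]
  fin <- cc[nrow(cc), ]
  band <- epsilon * abs(fin) + traj$atol
  dev <- abs(sweep(cc, 2, fin)) > rep(band, each = nrow(cc))
  violated <- rowSums(dev) > 0
  t_star <- if (!any(violated)) 0 else traj$time[max(which(violated)) + 1L]
  structure(list(settle_time = t_star, epsilon = epsilon,
                 t_end = max(traj$time),
                 plateaus = stats::setNames(as.numeric(fin), outputs)),
            class = "dsd_settle")
}

#' @export
print.dsd_settle <- function(x, ...) {
  cat(sprintf("settled at %g s (%.0f%% band, t_end = %g s)\n",
              x$settle_time, 100 * x$epsilon, x$t_end))
  invisible(x)
}

#' Decode reporter fluorescence into a logic word
#'
#' For each reported wire the plateau of the logic-1 fluorophore
#' (`Y_<label>2`) is compared with the logic-0 fluorophore (`Y_<label>1`):
#' the bit is 1 if the former exceeds the latter by `ratio_threshold`, 0 in
#' the symmetric case, and a decoding error otherwise (an ambiguous bit
#' signals circuit malfunction rather than guessing).  Ratios rather than
#' absolute thresholds are used because absolute fluorescence scales with
#' the circuit concentration unit.
#'
#' @param traj A `dsd_trajectory` of a circuit with reporters.
#' @param reporters Reporter map (defaults to the compiled one, in netlist
#'   order; the first reporter is the most significant bit).
#' @param ratio_threshold Minimum high/low plateau ratio for an unambiguous
#'   bit.
#' @param floor_nM Minimum plateau (nM) for the winning fluorophore; below
#'   this the wire carries no signal at all.
#' @return A `dsd_logic` list: `word` (string, MSB first), `bits` (named by
#'   label), `decimal`, and a per-bit `table` of plateaus and ratios.
#' @export
decode_word <- function(traj, reporters = NULL, ratio_threshold = 10,
                        floor_nM = 1) {
  stopifnot(inherits(traj, "dsd_trajectory"), ratio_threshold > 1)
  if (is.null(reporters)) reporters <- traj$reporters
  if (length(reporters) == 0)
    stop("trajectory has no reporters to decode", call. = FALSE)
  bits <- integer(length(reporters))
  labels <- character(length(reporters))
  lo <- hi <- numeric(length(reporters))
  for (i in seq_along(reporters)) {
    rp <- reporters[[i]]
    labels[i] <- rp$label
    y0 <- as.numeric(plateaus(traj, rp$fluor0))
    y1 <- as.numeric(plateaus(traj, rp$fluor1))
    lo[i] <- y0; hi[i] <- y1
    if (max(y0, y1) < floor_nM)
      stop(sprintf("decoding error on output '%s': no fluorescence signal (%.3g / %.3g nM)",
                   rp$label, y0, y1), call. = FALSE)
    if (y1 >= ratio_threshold * y0) bits[i] <- 1L
    else if (y0 >= ratio_threshold * y1) bits[i] <- 0L
    else stop(sprintf("decoding error on output '%s': ambiguous plateau ratio (Y1 = %.3g, Y2 = %.3g nM)",
                      rp$label, y0, y1), call. = FALSE)
  }
  word <- paste(bits, collapse = "")
  structure(list(word = word,
                 bits = stats::setNames(bits, labels),
                 decimal = strtoi(word, base = 2L),
                 table = data.frame(label = labels, Y_low = lo, Y_high = hi,
                                    bit = bits)),
            class = "dsd_logic")
}

#' @export
print.dsd_logic <- function(x, ...) {
  cat(sprintf("decoded word %s (decimal %d)\n", x$word, x$decimal))
  invisible(x)
}
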