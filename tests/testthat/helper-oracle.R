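# Independent fixed-step RK4 integrator used as a numerical oracle on small
# sub-networks.  Deliberately shares no code with simulate(): rates are
# evaluated reaction-by-reaction and the state advanced with classical RK4.

oracle_rk4 <- function(crn, times, substeps = 20) {
  y <- crn$species$init_conc_nM
  names(y) <- crn$species$name
  rxn <- crn$reactions
  deriv <- function(y) {
    dy <- numeric(length(y))
    for (r in rxn) {
      v <- r$rate
      for (i in r$reactants) v <- v * y[i]
      for (i in r$reactants) dy[i] <- dy[i] - v
      for (i in r$products) dy[i] <- dy[i] + v
    }
    dy
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y),
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  for (ti in seq_len(length(times) - 1)) {
    h <- (times[ti + 1] - times[ti]) / substeps
    for (s in seq_len(substeps)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[ti + 1, ] <- y
  }
  out
}
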