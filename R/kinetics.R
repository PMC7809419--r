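#' Clamp values into the closed unit interval
#' @param x numeric vector.
#' @return `pmin(pmax(x, 0), 1)`.
#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

.named_u <- function(network, u) {
  if (length(u) != length(network@inputNames))
    stop(sprintf("input vector must have length c=%d",
                 length(network@inputNames)))
  stats::setNames(as.numeric(u), network@inputNames)
}

.state_parts <- function(network, state) {
  k <- speciesCounts(network)
  p <- k[["p"]]; s <- k[["s"]]; m <- k[["m"]]
  if (length(state) < p + s + m)
    stop(sprintf("state vector must have length >= %d", p + s + m))
  list(x = stats::setNames(state[seq_len(p)], network@geneNames),
       y = stats::setNames(state[p + seq_len(s)], network@signalNames),
       z = stats::setNames(state[p + s + seq_len(m)], network@metaboliteNames))
}

.mod_product <- function(consts, levels, rule_id, strict = FALSE) {
  if (!length(consts)) return(1)
  v <- consts * levels[names(consts)]
  if (strict && any(v >= 1))
    stop(sprintf("modifier constraint violated in %s: F*level >= 1 for %s",
                 rule_id, paste(names(consts)[v >= 1], collapse = ", ")))
  v <- pmin(v, 1 - 1e-9)          # soft clamp; transient states may brush 1
  prod(1 + v)
}

#' Gene expression rate law
#'
#' Time derivative of one gene's expression level. With all required
#' transcription factors present the expression rate is the product of
#' binding-constant-weighted TF levels; if any required TF is absent
#' (level 0) the derivative is exactly `basal - decay`. Cofactor enhancers
#' multiply the expression rate; inhibitors divide expression plus basal
#' production. Decay is a constant rate.
#'
#' @param rule a [GeneRule-class].
#' @param network the owning [PathwayNetwork-class].
#' @param state numeric state vector (genes, signaling, metabolites in
#'   canonical order).
#' @param u named external-input vector.
#' @param strict error (rather than soft-clamp) when an inhibitor term
#'   `F * level` reaches 1.
#' @return scalar `dx_i/dt`.
#' @export
geneRate <- function(rule, network, state, u, strict = FALSE) {
  u <- .named_u(network, u)
  parts <- .state_parts(network, state)
  if (length(rule@activators)) {
    ylev <- parts$y[names(rule@activators)]
    if (any(ylev == 0) || prod(ylev) == 0) return(rule@basal - rule@decay)
    e <- prod(rule@activators * ylev)
  } else {
    return(rule@basal - rule@decay)   # no required TFs: basal turnover only
  }
  enh <- .mod_product(rule@enhMet, parts$z, rule@gene, strict) *
         .mod_product(rule@enhInput, u, rule@gene, strict)
  inh <- .mod_product(rule@inhMet, parts$z, rule@gene, strict) *
         .mod_product(rule@inhInput, u, rule@gene, strict) *
         .mod_product(rule@inhSig, parts$y, rule@gene, strict)
  (e * enh + rule@basal) / inh - rule@decay
}

#' Signaling interaction rates
#'
#' Rate vector of the signal-transduction network (length `q`): each rate
#' is the basal rate constant times the product of binding-constant-
#' weighted activator levels, multiplied by metabolite/input enhancer
#' factors and divided by metabolite/input/protein inhibitor factors. A
#' rate is exactly zero whenever any required activator level is zero.
#'
#' @inheritParams geneRate
#' @param network a [PathwayNetwork-class].
#' @return named numeric vector `r_s` of length `q`.
#' @export
signalingRates <- function(network, state, u, strict = FALSE) {
  u <- .named_u(network, u)
  parts <- .state_parts(network, state)
  vapply(network@interactionRules, function(r) {
    base <- r@rate
    if (length(r@activators)) {
      ylev <- parts$y[names(r@activators)]
      if (any(ylev == 0)) return(0)
      base <- base * prod(r@activators * ylev)
    }
    enh <- .mod_product(r@enhMet, parts$z, r@id, strict) *
           .mod_product(r@enhInput, u, r@id, strict)
    inh <- .mod_product(r@inhMet, parts$z, r@id, strict) *
           .mod_product(r@inhInput, u, r@id, strict) *
           .mod_product(r@inhSig, parts$y, r@id, strict)
    base * enh / inh
  }, numeric(1)) -> r
  stats::setNames(r, colnames(network@interactionMatrix))
}

#' Metabolic reaction fluxes
#'
#' Flux vector of the metabolic network (length `n`) under modified
#' Michaelis-Menten kinetics: `K * E * Z / (Km + Z)` with `Z` the product
#' of substrate concentrations and `E` the catalyzing gene's expression
#' level, times enhancer factors or divided by inhibitor factors. A flux
#' is exactly zero when its rate constant is zero (knockout) or any
#' substrate is absent.
#'
#' @inheritParams signalingRates
#' @return named numeric vector `r_m` of length `n`.
#' @export
metabolicRates <- function(network, state, u, strict = FALSE) {
  u <- .named_u(network, u)
  parts <- .state_parts(network, state)
  vapply(network@reactionRules, function(r) {
    if (r@K == 0) return(0)
    E <- parts$x[[r@catGene]]
    Z <- if (length(r@substrates)) prod(parts$z[r@substrates]) else 1
    base <- r@K * E * Z / (r@Km + Z)
    enh <- .mod_product(r@enhMet, parts$z, r@id, strict) *
           .mod_product(r@enhInput, u, r@id, strict)
    inh <- .mod_product(r@inhMet, parts$z, r@id, strict) *
           .mod_product(r@inhInput, u, r@id, strict)
    base * enh / inh
  }, numeric(1)) -> r
  stats::setNames(r, colnames(network@stoichMatrix))
}

#' Full three-timescale state derivative
#'
#' Assembles the complete derivative of the integrated pathway on the slow
#' timescale: gene rates per gene, `(1/omega1) * N_s %*% r_s` for
#' signaling, and `(1/(omega1*omega2)) * N_m %*% r_m` for metabolites.
#'
#' @inheritParams signalingRates
#' @param omega1,omega2 timescale ratios in (0, 1].
#' @return list with components `xdot`, `ydot`, `zdot` (named numerics).
#' @export
fullDerivative <- function(network, state, u, omega1 = 1 / 60,
                           omega2 = 1 / 60, strict = FALSE) {
  stopifnot(omega1 > 0, omega1 <= 1, omega2 > 0, omega2 <= 1)
  xdot <- vapply(network@geneRules, geneRate, numeric(1),
                 network = network, state = state, u = u, strict = strict)
  rs <- signalingRates(network, state, u, strict)
  rm <- metabolicRates(network, state, u, strict)
  ydot <- as.numeric(network@interactionMatrix %*% rs) / omega1
  zdot <- as.numeric(network@stoichMatrix %*% rm) / (omega1 * omega2)
  list(xdot = stats::setNames(xdot, network@geneNames),
       ydot = stats::setNames(ydot, network@signalNames),
       zdot = stats::setNames(zdot, network@metaboliteNames))
}
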