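#' @import methods
#' @importFrom stats runif optim median sd
#' @importFrom utils write.csv read.csv head tail
NULL

.chk_named_num <- function(x, what, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = TRUE) {
  if (length(x) == 0) return(character(0))
  msg <- character(0)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    msg <- c(msg, sprintf("%s must be a named numeric vector", what))
  bad <- (lo_open & x <= lo) | (!lo_open & x < lo) |
         (hi_open & x >= hi) | (!hi_open & x > hi)
  if (any(bad))
    msg <- c(msg, sprintf("%s constants out of range [%s%s, %s%s): %s",
                          what, if (lo_open) ">" else "", lo,
                          if (hi_open) "<" else "", hi,
                          paste(names(x)[bad], collapse = ", ")))
  msg
}

#' Gene-regulatory rule
#'
#' One transcription rule: the gene's basal production and decay rates, the
#' transcription factors whose binding drives the expression rate (a product
#' of binding-constant-weighted levels), and optional cofactor enhancers
#' (metabolites, external inputs) or inhibitors (metabolites, external
#' inputs, signaling molecules). Enhancers multiply the expression rate;
#' inhibitors divide expression plus basal production. All binding and
#' feedback constants lie in `[0, 1)`; zero means no binding.
#'
#' @slot gene gene identifier (character).
#' @slot basal basal mRNA production rate, in `(0, 1)`.
#' @slot decay constant decay rate, in `(0, 1)`.
#' @slot activators named numeric, transcription-factor binding constants
#'   keyed by signaling-species id.
#' @slot enhMet,enhInput named numerics, cofactor enhancer constants keyed
#'   by metabolite / input id.
#' @slot inhMet,inhInput,inhSig named numerics, inhibitor constants.
#' @slot mode one of `"plain"`, `"activated"`, `"inhibited"`, `"mixed"`;
#'   derived from which modifier sets are non-empty.
#' @export
setClass("GeneRule",
  representation(gene = "character", basal = "numeric", decay = "numeric",
                 activators = "numeric", enhMet = "numeric",
                 enhInput = "numeric", inhMet = "numeric",
                 inhInput = "numeric", inhSig = "numeric",
                 mode = "character"),
  prototype(activators = numeric(0), enhMet = numeric(0),
            enhInput = numeric(0), inhMet = numeric(0),
            inhInput = numeric(0), inhSig = numeric(0), mode = "plain"))

setValidity("GeneRule", function(object) {
  msg <- character(0)
  if (length(object@gene) != 1L) msg <- c(msg, "gene must be a single id")
  if (object@basal <= 0 || object@basal >= 1)
    msg <- c(msg, sprintf("gene %s: basal rate must lie in (0,1)", object@gene))
  if (object@decay <= 0 || object@decay >= 1)
    msg <- c(msg, sprintf("gene %s: decay rate must lie in (0,1)", object@gene))
  msg <- c(msg,
    .chk_named_num(object@activators, sprintf("gene %s activators", object@gene)),
    .chk_named_num(object@enhMet, sprintf("gene %s enhMet", object@gene)),
    .chk_named_num(object@enhInput, sprintf("gene %s enhInput", object@gene)),
    .chk_named_num(object@inhMet, sprintf("gene %s inhMet", object@gene)),
    .chk_named_num(object@inhInput, sprintf("gene %s inhInput", object@gene)),
    .chk_named_num(object@inhSig, sprintf("gene %s inhSig", object@gene)))
  if (length(intersect(names(object@enhMet), names(object@inhMet))) ||
      length(intersect(names(object@enhInput), names(object@inhInput))))
    msg <- c(msg, sprintf("gene %s: enhancer and inhibitor sets overlap",
                          object@gene))
  if (length(msg)) msg else TRUE
})

#' Signaling interaction rule
#'
#' One interaction of the signal-transduction network: a mass-action-style
#' rate, the product of binding-constant-weighted activator levels times a
#' basal rate constant, enhanced or inhibited by `(1 + F * level)` factors.
#' The target species receives `+1` in the interaction matrix; species in
#' `consumes` receive `-1`. Activation interactions are catalytic (empty
#' `consumes`); first-order deactivation/decay interactions consume their
#' own species and have no target.
#'
#' @slot id interaction label.
#' @slot target activated species id, or `NA` for pure consumption.
#' @slot rate basal rate constant in `(0, 1]`.
#' @slot consumes character vector of consumed signaling species.
#' @slot activators named numeric binding constants over signaling ids.
#' @slot enhMet,enhInput enhancer constants (metabolites, inputs).
#' @slot inhMet,inhInput,inhSig inhibitor constants.
#' @export
setClass("InteractionRule",
  representation(id = "character", target = "character", rate = "numeric",
                 consumes = "character", activators = "numeric",
                 enhMet = "numeric", enhInput = "numeric",
                 inhMet = "numeric", inhInput = "numeric",
                 inhSig = "numeric"),
  prototype(target = NA_character_, rate = 1, consumes = character(0),
            activators = numeric(0), enhMet = numeric(0),
            enhInput = numeric(0), inhMet = numeric(0),
            inhInput = numeric(0), inhSig = numeric(0)))

setValidity("InteractionRule", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single label")
  if (object@rate <= 0 || object@rate > 1)
    msg <- c(msg, sprintf("interaction %s: rate constant must lie in (0,1]",
                          object@id))
  msg <- c(msg,
    .chk_named_num(object@activators, sprintf("interaction %s activators", object@id)),
    .chk_named_num(object@enhMet, sprintf("interaction %s enhMet", object@id)),
    .chk_named_num(object@enhInput, sprintf("interaction %s enhInput", object@id)),
    .chk_named_num(object@inhMet, sprintf("interaction %s inhMet", object@id)),
    .chk_named_num(object@inhInput, sprintf("interaction %s inhInput", object@id)),
    .chk_named_num(object@inhSig, sprintf("interaction %s inhSig", object@id)))
  if (length(msg)) msg else TRUE
})

#' Metabolic reaction rule
#'
#' One enzyme-catalyzed reaction with modified Michaelis-Menten kinetics:
#' `flux = K * E * Z / (Km + Z)` with `Z` the product of substrate
#' concentrations and `E` the expression level of the catalyzing gene,
#' multiplied by noncompetitive/allosteric enhancer factors or divided by
#' inhibitor factors. Setting `K = 0` knocks the reaction out
#' (zero flux).
#'
#' @slot id reaction label.
#' @slot substrates consumed metabolite ids (`-1` stoichiometry).
#' @slot products produced metabolite ids (`+1` stoichiometry).
#' @slot catGene id of the single catalyzing gene supplying the enzyme.
#' @slot K kinetic rate constant, in `[0, 1]` (`0` only after knockout).
#' @slot Km Michaelis constant, in `(0, 1]`.
#' @slot enhMet,enhInput enhancer feedback constants.
#' @slot inhMet,inhInput inhibitor feedback constants.
#' @export
setClass("ReactionRule",
  representation(id = "character", substrates = "character",
                 products = "character", catGene = "character",
                 K = "numeric", Km = "numeric", enhMet = "numeric",
                 enhInput = "numeric", inhMet = "numeric",
                 inhInput = "numeric"),
  prototype(substrates = character(0), products = character(0),
            enhMet = numeric(0), enhInput = numeric(0),
            inhMet = numeric(0), inhInput = numeric(0)))

setValidity("ReactionRule", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single label")
  if (length(object@catGene) != 1L)
    msg <- c(msg, sprintf("reaction %s: exactly one catalyzing gene required",
                          object@id))
  if (object@K < 0 || object@K > 1)
    msg <- c(msg, sprintf("reaction %s: rate constant K must lie in [0,1]",
                          object@id))
  if (object@Km <= 0 || object@Km > 1)
    msg <- c(msg, sprintf("reaction %s: Michaelis constant must lie in (0,1]",
                          object@id))
  msg <- c(msg,
    .chk_named_num(object@enhMet, sprintf("reaction %s enhMet", object@id)),
    .chk_named_num(object@enhInput, sprintf("reaction %s enhInput", object@id)),
    .chk_named_num(object@inhMet, sprintf("reaction %s inhMet", object@id)),
    .chk_named_num(object@inhInput, sprintf("reaction %s inhInput", object@id)))
  if (length(msg)) msg else TRUE
})

#' Integrated-pathway network specification
#'
#' The full definition of an integrated gene-regulatory / signaling /
#' metabolic network: species name vectors (`p` genes, `s` signaling
#' species, `m` metabolites, `c` external inputs), the `s x q` interaction
#' matrix and `m x n` stoichiometric matrix (entries in `{-1, 0, +1}`), and
#' the per-gene, per-interaction and per-reaction kinetic rules. Build one
#' with [pathwayNetwork()]; the matrices are derived from the rules and
#' cross-checked by the validity method.
#'
#' @slot geneNames,signalNames,metaboliteNames,inputNames species ids.
#' @slot interactionMatrix integer `s x q` matrix.
#' @slot stoichMatrix integer `m x n` matrix.
#' @slot geneRules,interactionRules,reactionRules lists of rule objects.
#' @slot displayNames optional map from canonical id to display name.
#' @slot meta free-form list (name, version, generation seed).
#' @export
setClass("PathwayNetwork",
  representation(geneNames = "character", signalNames = "character",
                 metaboliteNames = "character", inputNames = "character",
                 interactionMatrix = "matrix", stoichMatrix = "matrix",
                 geneRules = "list", interactionRules = "list",
                 reactionRules = "list", displayNames = "character",
                 meta = "list"),
  prototype(displayNames = character(0), meta = list()))

setValidity("PathwayNetwork", function(object) {
  msg <- character(0)
  gn <- object@geneNames; sn <- object@signalNames
  mn <- object@metaboliteNames; un <- object@inputNames
  all_ids <- c(gn, sn, mn, un)
  if (anyDuplicated(all_ids))
    msg <- c(msg, paste("duplicate species ids:",
                        paste(unique(all_ids[duplicated(all_ids)]),
                              collapse = ", ")))
  Ns <- object@interactionMatrix; Nm <- object@stoichMatrix
  if (nrow(Ns) != length(sn))
    msg <- c(msg, sprintf("interaction_matrix must have s=%d rows, has %d",
                          length(sn), nrow(Ns)))
  if (ncol(Ns) != length(object@interactionRules))
    msg <- c(msg, sprintf("interaction_matrix must have q=%d columns, has %d",
                          length(object@interactionRules), ncol(Ns)))
  if (nrow(Nm) != length(mn))
    msg <- c(msg, sprintf("stoich_matrix must have m=%d rows, has %d",
                          length(mn), nrow(Nm)))
  if (ncol(Nm) != length(object@reactionRules))
    msg <- c(msg, sprintf("stoich_matrix must have n=%d columns, has %d",
                          length(object@reactionRules), ncol(Nm)))
  if (length(Ns) && !all(Ns %in% c(-1, 0, 1)))
    msg <- c(msg, "interaction_matrix entries must be -1, 0 or +1")
  if (length(Nm) && !all(Nm %in% c(-1, 0, 1)))
    msg <- c(msg, "stoich_matrix entries must be -1, 0 or +1")
  if (length(object@geneRules) != length(gn))
    msg <- c(msg, "one gene rule required per gene")
  chk_ref <- function(ids, pool, what)
    if (!all(ids %in% pool))
      sprintf("%s references unknown id(s): %s", what,
              paste(setdiff(ids, pool), collapse = ", ")) else character(0)
  for (i in seq_along(object@geneRules)) {
    r <- object@geneRules[[i]]
    v <- validObject(r, test = TRUE)
    if (is.character(v)) { msg <- c(msg, v); next }
    msg <- c(msg,
      chk_ref(r@gene, gn, "gene rule"),
      chk_ref(names(r@activators), sn, sprintf("gene %s activators", r@gene)),
      chk_ref(names(r@enhMet), mn, sprintf("gene %s enhMet", r@gene)),
      chk_ref(names(r@enhInput), un, sprintf("gene %s enhInput", r@gene)),
      chk_ref(names(r@inhMet), mn, sprintf("gene %s inhMet", r@gene)),
      chk_ref(names(r@inhInput), un, sprintf("gene %s inhInput", r@gene)),
      chk_ref(names(r@inhSig), sn, sprintf("gene %s inhSig", r@gene)))
  }
  # column consistency: +1 of N_s column == target, -1 entries == consumes
  for (k in seq_along(object@interactionRules)) {
    r <- object@interactionRules[[k]]
    v <- validObject(r, test = TRUE)
    if (is.character(v)) { msg <- c(msg, v); next }
    msg <- c(msg,
      chk_ref(names(r@activators), sn, sprintf("interaction %s activators", r@id)),
      chk_ref(r@consumes, sn, sprintf("interaction %s consumes", r@id)),
      chk_ref(names(r@enhMet), mn, sprintf("interaction %s enhMet", r@id)),
      chk_ref(names(r@enhInput), un, sprintf("interaction %s enhInput", r@id)),
      chk_ref(names(r@inhMet), mn, sprintf("interaction %s inhMet", r@id)),
      chk_ref(names(r@inhInput), un, sprintf("interaction %s inhInput", r@id)),
      chk_ref(names(r@inhSig), sn, sprintf("interaction %s inhSig", r@id)))
    if (ncol(Ns) >= k && nrow(Ns) == length(sn)) {
      plus <- sn[Ns[, k] == 1]; minus <- sn[Ns[, k] == -1]
      want <- if (is.na(r@target)) character(0) else r@target
      if (!setequal(plus, want))
        msg <- c(msg, sprintf(
          "interaction_matrix column %d (+1 rows) inconsistent with target of %s",
          k, r@id))
      if (!setequal(minus, r@consumes))
        msg <- c(msg, sprintf(
          "interaction_matrix column %d (-1 rows) inconsistent with consumes of %s",
          k, r@id))
    }
  }
  for (k in seq_along(object@reactionRules)) {
    r <- object@reactionRules[[k]]
    v <- validObject(r, test = TRUE)
    if (is.character(v)) { msg <- c(msg, v); next }
    msg <- c(msg,
      chk_ref(r@substrates, mn, sprintf("reaction %s substrates", r@id)),
      chk_ref(r@products, mn, sprintf("reaction %s products", r@id)),
      chk_ref(r@catGene, gn, sprintf("reaction %s catalyzing gene", r@id)),
      chk_ref(names(r@enhMet), mn, sprintf("reaction %s enhMet", r@id)),
      chk_ref(names(r@enhInput), un, sprintf("reaction %s enhInput", r@id)),
      chk_ref(names(r@inhMet), mn, sprintf("reaction %s inhMet", r@id)),
      chk_ref(names(r@inhInput), un, sprintf("reaction %s inhInput", r@id)))
    if (ncol(Nm) >= k && nrow(Nm) == length(mn)) {
      if (!setequal(mn[Nm[, k] == -1], r@substrates))
        msg <- c(msg, sprintf(
          "stoich_matrix column %d (-1 rows) inconsistent with substrates of %s",
          k, r@id))
      if (!setequal(mn[Nm[, k] == 1], r@products))
        msg <- c(msg, sprintf(
          "stoich_matrix column %d (+1 rows) inconsistent with products of %s",
          k, r@id))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory of an integrated pathway
#'
#' Time-indexed states of a [PathwayNetwork-class] simulation on the slow
#' timescale: a `length(times) x (p+s+m)` state matrix (columns in
#' canonical species order: genes, signaling, metabolites) plus the applied
#' external inputs.
#'
#' @slot times numeric vector of slow-timescale sample times.
#' @slot states numeric matrix, one row per time, states clamped to [0,1].
#' @slot inputs numeric matrix of external inputs, one row per time.
#' @slot meta list: species counts, config, clamp counts, spec hash.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", inputs = "matrix",
                 meta = "list"),
  prototype(meta = list()))

setValidity("Trajectory", function(object) {
  msg <- character(0)
  if (nrow(object@states) != length(object@times))
    msg <- c(msg, "states must have one row per time point")
  if (nrow(object@inputs) != length(object@times))
    msg <- c(msg, "inputs must have one row per time point")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' MIMO plant wrapping an integrated-pathway simulator
#'
#' A frozen, reproducible simulator: the network with its (possibly tuned
#' or perturbed) constants, the timescale ratios, the per-step integration
#' horizon, and any active perturbation (reaction knockouts, pinned
#' enzyme/protein signals). `plantStep()` is a pure function of its input
#' instance, which is what the sliding-window dataset and the controller
#' consume.
#'
#' @slot network the [PathwayNetwork-class] (knockouts already applied).
#' @slot omega1,omega2 slow:fast and fast:ultrafast timescale ratios.
#' @slot stepHorizon slow-time integrated per plant step.
#' @slot knockouts integer indices of zero-rate reactions.
#' @slot signalOverrides named numeric of pinned species levels in (0,1).
#' @slot initState named initial state drawn uniformly in (0,1).
#' @slot config list of seeds, tolerances and solver options.
#' @export
setClass("Plant",
  representation(network = "PathwayNetwork", omega1 = "numeric",
                 omega2 = "numeric", stepHorizon = "numeric",
                 knockouts = "integer", signalOverrides = "numeric",
                 initState = "numeric", config = "list"),
  prototype(omega1 = 1 / 60, omega2 = 1 / 60, stepHorizon = 1,
            knockouts = integer(0), signalOverrides = numeric(0),
            config = list()))

setValidity("Plant", function(object) {
  msg <- character(0)
  if (object@omega1 <= 0 || object@omega1 > 1)
    msg <- c(msg, "omega1 must lie in (0, 1]")
  if (object@omega2 <= 0 || object@omega2 > 1)
    msg <- c(msg, "omega2 must lie in (0, 1]")
  if (object@stepHorizon <= 0) msg <- c(msg, "stepHorizon must be positive")
  if (length(object@signalOverrides) &&
      (any(object@signalOverrides <= 0) || any(object@signalOverrides >= 1)))
    msg <- c(msg, "signal overrides must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Sliding-window supervised dataset
#'
#' Regressor/target pairs for surrogate training: row `a` of `V` is the
#' window vector built from `tau` past input/output instance pairs plus the
#' current input instance, and row `a` of `Y` is the current output
#' instance (the supervised signal).
#'
#' @slot V numeric matrix `phi x d` of window regressors.
#' @slot Y numeric matrix `phi x (p+s+m)` of supervised outputs.
#' @slot tau number of past input/output pairs per window.
#' @slot dims named integer vector with `p`, `s`, `m`, `c`.
#' @slot meta list (seed, jitter amplitude, plant config).
#' @export
setClass("WindowDataset",
  representation(V = "matrix", Y = "matrix", tau = "integer",
                 dims = "integer", meta = "list"),
  prototype(meta = list()))

setValidity("WindowDataset", function(object) {
  msg <- character(0)
  d <- windowDimension(object@tau, object@dims[["p"]], object@dims[["s"]],
                       object@dims[["m"]], object@dims[["c"]])
  if (ncol(object@V) != d)
    msg <- c(msg, sprintf("V must have d=%d columns, has %d", d, ncol(object@V)))
  nout <- object@dims[["p"]] + object@dims[["s"]] + object@dims[["m"]]
  if (ncol(object@Y) != nout)
    msg <- c(msg, sprintf("Y must have %d columns, has %d", nout, ncol(object@Y)))
  if (nrow(object@V) != nrow(object@Y))
    msg <- c(msg, "V and Y must have the same number of samples")
  if (length(msg)) msg else TRUE
})

#' MISO-ensemble epsilon-SVR surrogate
#'
#' The multi-output surrogate of the plant: one epsilon-insensitive support
#' vector regressor per output component, all sharing one radial-basis
#' kernel over the window regressor. Stored in primal-free dual form: the
#' union of support vectors, a dual-coefficient matrix (column `mu` holds
#' `alpha_b = zeta_b - zeta_b*` for output `mu`, zero where the point is
#' not a support vector of that output) and per-output biases. Prediction
#' is the kernel expansion `sum_b alpha_b k(v, v_b) + beta_mu`, clamped to
#' [0, 1] for plant compatibility.
#'
#' @slot SV numeric matrix `nSV x d`, union of support vectors.
#' @slot alpha numeric matrix `nSV x (p+s+m)` of dual coefficients.
#' @slot bias numeric vector of per-output biases.
#' @slot gamma radial-basis kernel coefficient.
#' @slot cost box constraint of the dual (the regularization parameter C).
#' @slot epsilon insensitive-tube half width.
#' @slot outputNames output component ids.
#' @slot meta list (training sizes, seeds, spec hash).
#' @export
setClass("SurrogateModel",
  representation(SV = "matrix", alpha = "matrix", bias = "numeric",
                 gamma = "numeric", cost = "numeric", epsilon = "numeric",
                 outputNames = "character", meta = "list"),
  prototype(meta = list()))

setValidity("SurrogateModel", function(object) {
  msg <- character(0)
  if (nrow(object@alpha) != nrow(object@SV))
    msg <- c(msg, "alpha must have one row per support vector")
  if (ncol(object@alpha) != length(object@bias))
    msg <- c(msg, "one bias required per output model")
  if (length(object@alpha) && max(abs(object@alpha)) > object@cost + 1e-6)
    msg <- c(msg, "dual coefficients must satisfy |alpha| <= C")
  if (object@gamma <= 0 || object@cost <= 0 || object@epsilon < 0)
    msg <- c(msg, "hyperparameters must satisfy gamma>0, C>0, epsilon>=0")
  if (length(msg)) msg else TRUE
})
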