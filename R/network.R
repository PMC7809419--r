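#' Construct a gene-regulatory rule
#'
#' @param gene gene id.
#' @param basal,decay basal production and decay rates in (0,1).
#' @param activators named numeric of transcription-factor binding
#'   constants in [0,1), keyed by signaling id.
#' @param enhMet,enhInput cofactor enhancer constants.
#' @param inhMet,inhInput,inhSig inhibitor constants.
#' @return a validated [GeneRule-class].
#' @export
geneRule <- function(gene, basal, decay, activators = numeric(0),
                     enhMet = numeric(0), enhInput = numeric(0),
                     inhMet = numeric(0), inhInput = numeric(0),
                     inhSig = numeric(0)) {
  has_enh <- length(enhMet) + length(enhInput) > 0
  has_inh <- length(inhMet) + length(inhInput) + length(inhSig) > 0
  mode <- if (has_enh && has_inh) "mixed" else if (has_enh) "activated"
          else if (has_inh) "inhibited" else "plain"
  new("GeneRule", gene = gene, basal = basal, decay = decay,
      activators = activators, enhMet = enhMet, enhInput = enhInput,
      inhMet = inhMet, inhInput = inhInput, inhSig = inhSig, mode = mode)
}

#' Construct a signaling interaction rule
#'
#' @param id interaction label.
#' @param target activated species id (`NA` for a pure
#'   consumption/deactivation interaction).
#' @param activators named numeric of binding constants over signaling ids.
#' @param rate basal rate constant in (0,1].
#' @param consumes signaling species carrying `-1` stoichiometry.
#' @param enhMet,enhInput,inhMet,inhInput,inhSig modifier constants.
#' @return a validated [InteractionRule-class].
#' @export
interactionRule <- function(id, target = NA_character_,
                            activators = numeric(0), rate = 1,
                            consumes = character(0), enhMet = numeric(0),
                            enhInput = numeric(0), inhMet = numeric(0),
                            inhInput = numeric(0), inhSig = numeric(0)) {
  new("InteractionRule", id = id, target = target, rate = rate,
      consumes = consumes, activators = activators, enhMet = enhMet,
      enhInput = enhInput, inhMet = inhMet, inhInput = inhInput,
      inhSig = inhSig)
}

#' Construct a metabolic reaction rule
#'
#' @param id reaction label.
#' @param substrates,products metabolite ids.
#' @param catGene id of the catalyzing gene (its expression level is the
#'   enzyme level).
#' @param K,Km kinetic rate constant and Michaelis constant in (0,1].
#' @param enhMet,enhInput,inhMet,inhInput feedback constants.
#' @return a validated [ReactionRule-class].
#' @export
reactionRule <- function(id, substrates, products, catGene, K, Km,
                         enhMet = numeric(0), enhInput = numeric(0),
                         inhMet = numeric(0), inhInput = numeric(0)) {
  new("ReactionRule", id = id, substrates = substrates, products = products,
      catGene = catGene, K = K, Km = Km, enhMet = enhMet,
      enhInput = enhInput, inhMet = inhMet, inhInput = inhInput)
}

#' Assemble a pathway network from rules
#'
#' Builds the `s x q` interaction matrix and `m x n` stoichiometric matrix
#' from the rule lists and returns a validated [PathwayNetwork-class].
#'
#' @param geneNames,signalNames,metaboliteNames,inputNames species ids.
#' @param geneRules,interactionRules,reactionRules rule lists.
#' @param displayNames optional named character map id -> display name.
#' @param meta free-form metadata list.
#' @return a validated [PathwayNetwork-class].
#' @export
pathwayNetwork <- function(geneNames, signalNames, metaboliteNames,
                           inputNames, geneRules, interactionRules,
                           reactionRules, displayNames = character(0),
                           meta = list()) {
  s <- length(signalNames); m <- length(metaboliteNames)
  q <- length(interactionRules); n <- length(reactionRules)
  Ns <- matrix(0L, s, q, dimnames = list(
    signalNames, vapply(interactionRules, function(r) r@id, character(1))))
  for (k in seq_len(q)) {
    r <- interactionRules[[k]]
    if (!is.na(r@target)) Ns[r@target, k] <- 1L
    Ns[r@consumes, k] <- -1L
  }
  Nm <- matrix(0L, m, n, dimnames = list(
    metaboliteNames, vapply(reactionRules, function(r) r@id, character(1))))
  for (k in seq_len(n)) {
    r <- reactionRules[[k]]
    Nm[r@substrates, k] <- -1L
    Nm[r@products, k] <- 1L
  }
  ord <- vapply(geneRules, function(r) r@gene, character(1))
  if (!setequal(ord, geneNames) || length(ord) != length(geneNames))
    stop("gene rules must cover each gene exactly once")
  geneRules <- geneRules[match(geneNames, ord)]
  new("PathwayNetwork", geneNames = geneNames, signalNames = signalNames,
      metaboliteNames = metaboliteNames, inputNames = inputNames,
      interactionMatrix = Ns, stoichMatrix = Nm, geneRules = geneRules,
      interactionRules = interactionRules, reactionRules = reactionRules,
      displayNames = displayNames, meta = meta)
}

#' Species counts of a network
#'
#' @param object a [PathwayNetwork-class].
#' @return named integer vector with `p`, `s`, `m`, `c` (species counts)
#'   and `q`, `n` (interaction and reaction counts).
#' @export
#' @rdname speciesCounts
setMethod("speciesCounts", "PathwayNetwork", function(object) {
  c(p = length(object@geneNames), s = length(object@signalNames),
    m = length(object@metaboliteNames), c = length(object@inputNames),
    q = ncol(object@interactionMatrix), n = ncol(object@stoichMatrix))
})

#' Species names of a network
#'
#' @param object a [PathwayNetwork-class].
#' @param role one of `"all"` (canonical state order: genes, signaling,
#'   metabolites), `"genes"`, `"signals"`, `"metabolites"`, `"inputs"`.
#' @param ... unused.
#' @return character vector of ids.
#' @export
#' @rdname speciesNames
setMethod("speciesNames", "PathwayNetwork", function(object, role = "all", ...) {
  switch(match.arg(role, c("all", "genes", "signals", "metabolites", "inputs")),
         all = c(object@geneNames, object@signalNames, object@metaboliteNames),
         genes = object@geneNames, signals = object@signalNames,
         metabolites = object@metaboliteNames, inputs = object@inputNames)
})

setMethod("show", "PathwayNetwork", function(object) {
  k <- speciesCounts(object)
  cat(sprintf("PathwayNetwork '%s'\n",
              if (!is.null(object@meta$name)) object@meta$name else "unnamed"))
  cat(sprintf("  genes: %d, signaling: %d, metabolites: %d, inputs: %d\n",
              k["p"], k["s"], k["m"], k["c"]))
  cat(sprintf("  interactions (q): %d, reactions (n): %d\n", k["q"], k["n"]))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g], %d state variables\n",
              length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA,
              ncol(object@states)))
})

setMethod("show", "Plant", function(object) {
  k <- speciesCounts(object@network)
  cat(sprintf("MIMO plant: %d inputs -> %d outputs (omega1=%.4g, omega2=%.4g)\n",
              sum(k[c("p", "s", "m", "c")]), sum(k[c("p", "s", "m")]),
              object@omega1, object@omega2))
  if (length(object@knockouts))
    cat("  knockouts:", paste(colnames(object@network@stoichMatrix)[object@knockouts],
                              collapse = ", "), "\n")
  if (length(object@signalOverrides))
    cat("  pinned species:", paste(names(object@signalOverrides), collapse = ", "), "\n")
})

setMethod("show", "WindowDataset", function(object) {
  cat(sprintf("WindowDataset: %d samples, tau=%d, d=%d, outputs=%d\n",
              nrow(object@V), object@tau, ncol(object@V), ncol(object@Y)))
})

setMethod("show", "SurrogateModel", function(object) {
  cat(sprintf(
    "SurrogateModel: %d MISO eps-SVR models, %d support vectors (union), d=%d\n",
    length(object@bias), nrow(object@SV), ncol(object@SV)))
  cat(sprintf("  rbf gamma=%g, C=%g, epsilon=%g\n",
              object@gamma, object@cost, object@epsilon))
})

#' Accessors for Trajectory objects
#'
#' @param object a [Trajectory-class].
#' @return `stateMatrix`: the time-by-species state matrix; `inputMatrix`:
#'   the external inputs; `trajectoryTimes`: the sample times.
#' @export
#' @rdname stateMatrix
setMethod("stateMatrix", "Trajectory", function(object) object@states)

#' @export
#' @rdname stateMatrix
setMethod("inputMatrix", "Trajectory", function(object) object@inputs)

#' @export
#' @rdname stateMatrix
setMethod("trajectoryTimes", "Trajectory", function(object) object@times)

#' Compare two network specifications field by field
#'
#' Numeric constants are compared to within `tol`; structure (species,
#' matrices, rule topology) must match exactly.
#'
#' @param a,b [PathwayNetwork-class] objects.
#' @param tol numeric tolerance for constants.
#' @return `TRUE` or a character vector describing the first differences.
#' @export
networkEquals <- function(a, b, tol = 1e-12) {
  diffs <- character(0)
  for (slot in c("geneNames", "signalNames", "metaboliteNames", "inputNames"))
    if (!identical(methods::slot(a, slot), methods::slot(b, slot)))
      diffs <- c(diffs, paste0(slot, " differ"))
  if (!isTRUE(all.equal(unname(a@interactionMatrix),
                        unname(b@interactionMatrix), tolerance = 0)))
    diffs <- c(diffs, "interaction_matrix differ")
  if (!isTRUE(all.equal(unname(a@stoichMatrix), unname(b@stoichMatrix),
                        tolerance = 0)))
    diffs <- c(diffs, "stoich_matrix differ")
  cmp_num <- function(x, y, what) {
    if (!identical(names(x), names(y))) return(paste0(what, " keys differ"))
    if (length(x) && max(abs(x - y)) > tol) return(paste0(what, " values differ"))
    character(0)
  }
  cmp_rules <- function(ra, rb, what, slots) {
    if (length(ra) != length(rb)) return(paste0(what, " counts differ"))
    out <- character(0)
    for (i in seq_along(ra)) for (sl in slots) {
      x <- methods::slot(ra[[i]], sl); y <- methods::slot(rb[[i]], sl)
      lab <- sprintf("%s[%d]@%s", what, i, sl)
      if (is.numeric(x)) out <- c(out, cmp_num(x, y, lab))
      else if (!identical(x, y)) out <- c(out, paste0(lab, " differ"))
    }
    out
  }
  diffs <- c(diffs,
    cmp_rules(a@geneRules, b@geneRules, "gene_rules",
              c("gene", "basal", "decay", "activators", "enhMet", "enhInput",
                "inhMet", "inhInput", "inhSig", "mode")),
    cmp_rules(a@interactionRules, b@interactionRules, "interaction_rules",
              c("id", "target", "rate", "consumes", "activators", "enhMet",
                "enhInput", "inhMet", "inhInput", "inhSig")),
    cmp_rules(a@reactionRules, b@reactionRules, "reaction_rules",
              c("id", "substrates", "products", "catGene", "K", "Km",
                "enhMet", "enhInput", "inhMet", "inhInput")))
  if (length(diffs)) diffs else TRUE
}
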