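#' Read and write network specification files
#'
#' The on-disk format is a single human-readable JSON document
#' (conventional extension `.net.json`): species id lists, the rule
#' sections with their named constants, and the two dense integer matrices
#' stored row-major with explicit dimensions. Numeric constants are
#' written at full precision so that `loadNetwork(saveNetwork(x))`
#' round-trips exactly.
#'
#' @param path file path.
#' @return `loadNetwork`: a validated [PathwayNetwork-class];
#'   `saveNetwork`: the path, invisibly.
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(doc$format) || !identical(doc$format, "pathway-network/1"))
    stop("not a pathway-network/1 document: ", path)
  num <- function(x) {
    if (is.null(x) || !length(x)) return(numeric(0))
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  chr <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))
  sp <- doc$species
  readMat <- function(node, what, nrow_want, ncol_want, rows, cols) {
    dm <- as.integer(unlist(node$dim))
    vals <- as.integer(unlist(node$values))
    if (length(vals) != prod(dm))
      stop(sprintf("%s: %d values do not fill declared %dx%d shape",
                   what, length(vals), dm[1], dm[2]))
    if (dm[1] != nrow_want || dm[2] != ncol_want)
      stop(sprintf("%s: expected shape %dx%d, file declares %dx%d",
                   what, nrow_want, ncol_want, dm[1], dm[2]))
    matrix(vals, nrow = dm[1], ncol = dm[2], byrow = TRUE,
           dimnames = list(rows, cols))
  }
  grules <- lapply(doc$gene_rules, function(g) geneRule(
    gene = g$gene, basal = g$basal, decay = g$decay,
    activators = num(g$activators), enhMet = num(g$enh_met),
    enhInput = num(g$enh_input), inhMet = num(g$inh_met),
    inhInput = num(g$inh_input), inhSig = num(g$inh_sig)))
  irules <- lapply(doc$interaction_rules, function(g) interactionRule(
    id = g$id, target = if (is.null(g$target)) NA_character_ else g$target,
    activators = num(g$activators), rate = g$rate, consumes = chr(g$consumes),
    enhMet = num(g$enh_met), enhInput = num(g$enh_input),
    inhMet = num(g$inh_met), inhInput = num(g$inh_input),
    inhSig = num(g$inh_sig)))
  rrules <- lapply(doc$reaction_rules, function(g) reactionRule(
    id = g$id, substrates = chr(g$substrates), products = chr(g$products),
    catGene = g$cat_gene, K = g$K, Km = g$Km,
    enhMet = num(g$enh_met), enhInput = num(g$enh_input),
    inhMet = num(g$inh_met), inhInput = num(g$inh_input)))
  iid <- vapply(irules, function(r) r@id, character(1))
  rid <- vapply(rrules, function(r) r@id, character(1))
  Ns <- readMat(doc$interaction_matrix, "interaction_matrix",
                length(chr(sp$signals)), length(irules), chr(sp$signals), iid)
  Nm <- readMat(doc$stoich_matrix, "stoich_matrix",
                length(chr(sp$metabolites)), length(rrules),
                chr(sp$metabolites), rid)
  if (!all(Ns %in% c(-1L, 0L, 1L)))
    stop("interaction_matrix entries must be -1, 0 or +1")
  if (!all(Nm %in% c(-1L, 0L, 1L)))
    stop("stoich_matrix entries must be -1, 0 or +1")
  net <- new("PathwayNetwork",
             geneNames = chr(sp$genes), signalNames = chr(sp$signals),
             metaboliteNames = chr(sp$metabolites), inputNames = chr(sp$inputs),
             interactionMatrix = Ns, stoichMatrix = Nm,
             geneRules = grules, interactionRules = irules,
             reactionRules = rrules,
             displayNames = if (is.null(doc$display_names))
               character(0) else unlist(doc$display_names),
             meta = if (is.null(doc$meta)) list() else doc$meta)
  validObject(net)
  net
}

#' @param network a validated [PathwayNetwork-class].
#' @rdname loadNetwork
#' @export
saveNetwork <- function(network, path) {
  validObject(network)
  nmap <- function(x) if (!length(x)) NULL else as.list(x)
  doc <- list(
    format = "pathway-network/1",
    species = list(genes = network@geneNames, signals = network@signalNames,
                   metabolites = network@metaboliteNames,
                   inputs = network@inputNames),
    display_names = nmap(network@displayNames),
    gene_rules = lapply(network@geneRules, function(g) list(
      gene = g@gene, basal = g@basal, decay = g@decay,
      activators = nmap(g@activators), enh_met = nmap(g@enhMet),
      enh_input = nmap(g@enhInput), inh_met = nmap(g@inhMet),
      inh_input = nmap(g@inhInput), inh_sig = nmap(g@inhSig))),
    interaction_rules = lapply(network@interactionRules, function(g) list(
      id = g@id, target = if (is.na(g@target)) NULL else g@target,
      rate = g@rate, consumes = g@consumes, activators = nmap(g@activators),
      enh_met = nmap(g@enhMet), enh_input = nmap(g@enhInput),
      inh_met = nmap(g@inhMet), inh_input = nmap(g@inhInput),
      inh_sig = nmap(g@inhSig))),
    reaction_rules = lapply(network@reactionRules, function(g) list(
      id = g@id, substrates = g@substrates, products = g@products,
      cat_gene = g@catGene, K = g@K, Km = g@Km,
      enh_met = nmap(g@enhMet), enh_input = nmap(g@enhInput),
      inh_met = nmap(g@inhMet), inh_input = nmap(g@inhInput))),
    interaction_matrix = list(
      dim = dim(network@interactionMatrix),
      values = as.integer(t(network@interactionMatrix))),
    stoich_matrix = list(
      dim = dim(network@stoichMatrix),
      values = as.integer(t(network@stoichMatrix))),
    meta = network@meta)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
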