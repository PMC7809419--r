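#' @useDynLib pathMPC, .registration = TRUE
#' @importFrom Rcpp sourceCpp evalCpp
NULL

# Pack a PathwayNetwork into the flat index structure consumed by the
# compiled evaluator. All indices are 0-based; activator/substrate/modifier
# references are absolute positions in the (x, y, z) state vector, input
# references index the u vector.
.packModel <- function(network) {
  k <- speciesCounts(network)
  p <- k[["p"]]; s <- k[["s"]]; m <- k[["m"]]
  gpos <- stats::setNames(seq_len(p) - 1L, network@geneNames)
  ypos <- stats::setNames(p + seq_len(s) - 1L, network@signalNames)
  zpos <- stats::setNames(p + s + seq_len(m) - 1L, network@metaboliteNames)
  upos <- stats::setNames(seq_len(k[["c"]]) - 1L, network@inputNames)
  mod <- function(consts, pos) {
    list(idx = as.integer(unname(pos[names(consts)])),
         F = as.numeric(unname(consts)))
  }
  genes <- lapply(network@geneRules, function(r) list(
    act = as.integer(unname(ypos[names(r@activators)])),
    K = as.numeric(unname(r@activators)),
    enhz = mod(r@enhMet, zpos), enhu = mod(r@enhInput, upos),
    inhz = mod(r@inhMet, zpos), inhu = mod(r@inhInput, upos),
    inhy = mod(r@inhSig, ypos), b = r@basal, d = r@decay))
  inters <- lapply(network@interactionRules, function(r) list(
    act = as.integer(unname(ypos[names(r@activators)])),
    K = as.numeric(unname(r@activators)),
    enhz = mod(r@enhMet, zpos), enhu = mod(r@enhInput, upos),
    inhz = mod(r@inhMet, zpos), inhu = mod(r@inhInput, upos),
    inhy = mod(r@inhSig, ypos), rate = r@rate))
  reacts <- lapply(network@reactionRules, function(r) list(
    sub = as.integer(unname(zpos[r@substrates])),
    enhz = mod(r@enhMet, zpos), enhu = mod(r@enhInput, upos),
    inhz = mod(r@inhMet, zpos), inhu = mod(r@inhInput, upos),
    K = r@K, Km = r@Km, cat = as.integer(unname(gpos[r@catGene]))))
  list(p = p, s = s, m = m, c = k[["c"]],
       genes = genes, inters = inters, reacts = reacts,
       Ns = matrix(as.integer(network@interactionMatrix), nrow(network@interactionMatrix)),
       Nm = matrix(as.integer(network@stoichMatrix), nrow(network@stoichMatrix)))
}

.model_cache <- new.env(parent = emptyenv())

# Compiled-model handle, cached per network identity within a session.
.compiledModel <- function(network) {
  key <- networkHash(network)
  hit <- .model_cache[[key]]
  if (!is.null(hit)) return(hit)
  ptr <- .model_build(.packModel(network))
  .model_cache[[key]] <- ptr
  ptr
}

#' Cheap content hash of a network specification
#'
#' Used to stamp trajectories, datasets and surrogate models with the
#' identity of the network that produced them.
#'
#' @param network a [PathwayNetwork-class].
#' @return a short character hash.
#' @export
networkHash <- function(network) {
  raw <- serialize(list(network@geneNames, network@signalNames,
                        network@metaboliteNames, network@inputNames,
                        network@interactionMatrix, network@stoichMatrix,
                        lapply(network@geneRules, function(r)
                          list(r@basal, r@decay, r@activators, r@enhMet,
                               r@enhInput, r@inhMet, r@inhInput, r@inhSig)),
                        lapply(network@interactionRules, function(r)
                          list(r@rate, r@activators, r@enhMet, r@enhInput,
                               r@inhMet, r@inhInput, r@inhSig)),
                        lapply(network@reactionRules, function(r)
                          list(r@K, r@Km, r@enhMet, r@enhInput, r@inhMet,
                               r@inhInput))),
                   NULL)
  v <- as.integer(raw)
  mix <- cumsum((v + 7L) * (seq_along(v) %% 97L + 1L)) %% 2147483647L
  sprintf("%08x%08x", mix[length(mix)], sum(v) %% 2147483647L)
}
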