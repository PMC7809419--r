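#' Generate a small random but connected test network
#'
#' Builds a valid integrated-pathway specification of arbitrary (small)
#' size for tests and examples: a signaling cascade driven by the first
#' external input (activation plus first-order decay per species), one
#' transcription rule per gene wired to the cascade, and a metabolite
#' chain (inflow, conversions, outflow) catalyzed by the genes in round
#' robin, with occasional metabolite/input modifiers so every rate-law
#' branch is exercised. All constants are drawn uniformly from the unit
#' interval ranges used throughout the model; generation is deterministic
#' for a fixed seed.
#'
#' @param nGenes,nSignals,nMetabolites,nInputs species counts, all >= 1.
#' @param seed integer seed.
#' @return a validated [PathwayNetwork-class].
#' @export
buildToyNetwork <- function(nGenes, nSignals, nMetabolites, nInputs, seed = 1L) {
  if (any(c(nGenes, nSignals, nMetabolites, nInputs) < 1))
    stop("all species counts must be >= 1")
  withSeed(seed, {
    gn <- paste0("g", seq_len(nGenes))
    sn <- paste0("y", seq_len(nSignals))
    mn <- paste0("z", seq_len(nMetabolites))
    un <- paste0("u", seq_len(nInputs))
    rk <- function(n = 1) runif(n, 0.05, 0.95)   # constants in (0, 1)

    irules <- list()
    for (j in seq_len(nSignals)) {
      if (j == 1) {
        act <- numeric(0)
        enhInput <- stats::setNames(rk(), un[1])
        r <- rk() * 0.5
      } else {
        act <- stats::setNames(rk(), sn[j - 1])
        enhInput <- numeric(0)
        r <- 1
      }
      irules <- c(irules, interactionRule(
        id = paste0("act_", sn[j]), target = sn[j], activators = act,
        rate = r, enhInput = enhInput))
      irules <- c(irules, interactionRule(
        id = paste0("dec_", sn[j]), target = NA_character_,
        activators = stats::setNames(rk() * 0.6 + 0.2, sn[j]),
        consumes = sn[j]))
    }

    grules <- lapply(seq_len(nGenes), function(i) {
      tf <- sn[(i - 1) %% nSignals + 1]
      enhMet <- if (i %% 3 == 0)
        stats::setNames(rk(), mn[(i - 1) %% nMetabolites + 1]) else numeric(0)
      inhSig <- if (i %% 4 == 0 && nSignals > 1)
        stats::setNames(rk(), sn[i %% nSignals + 1]) else numeric(0)
      inhSig <- inhSig[setdiff(names(inhSig), tf)]
      geneRule(gn[i], basal = runif(1, 0.05, 0.3),
               decay = runif(1, 0.05, 0.3),
               activators = stats::setNames(rk(), tf),
               enhMet = enhMet, inhSig = inhSig)
    })

    rrules <- list(reactionRule(
      id = "inflow", substrates = character(0), products = mn[1],
      catGene = gn[1], K = rk(), Km = runif(1, 0.1, 1),
      enhInput = stats::setNames(rk(), un[nInputs])))
    if (nMetabolites > 1) {
      for (k in seq_len(nMetabolites - 1)) {
        cat <- gn[(k - 1) %% nGenes + 1]
        enh <- if (k %% 2 == 0)
          stats::setNames(rk(), mn[1]) else numeric(0)
        enh <- enh[setdiff(names(enh), c(mn[k], mn[k + 1]))]
        rrules <- c(rrules, reactionRule(
          id = paste0("r", k), substrates = mn[k], products = mn[k + 1],
          catGene = cat, K = rk(), Km = runif(1, 0.1, 1), enhMet = enh))
      }
    }
    rrules <- c(rrules, reactionRule(
      id = "outflow", substrates = mn[nMetabolites], products = character(0),
      catGene = gn[nGenes], K = rk(), Km = runif(1, 0.1, 1)))

    pathwayNetwork(gn, sn, mn, un, grules, irules, rrules,
                   meta = list(name = sprintf("toy_%d_%d_%d_%d", nGenes,
                                              nSignals, nMetabolites, nInputs),
                               seed = seed))
  })
}
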