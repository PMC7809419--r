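#' Curated central-carbon-metabolism network
#'
#' The packaged integrated-pathway specification covering glycolysis and
#' gluconeogenesis, the TCA cycle, the pentose phosphate pathway and
#' fatty-acid synthesis/consumption, the PI3K/AKT/mTOR, HIF-1alpha, MYC,
#' RAS/ERK, JAK/STAT3, NF-kB, p53/MDM2, AMPK and PHD signaling axes, and
#' one transcription rule per enzyme gene, with 27 micro-environmental
#' inputs. Species counts are (p, s, m, c) = (37, 29, 41, 27).
#'
#' The wiring is a curated reconstruction assembled from the canonical
#' pathway structure of these routes (KEGG-style topology) and standard
#' regulatory relationships (for example HIF-1alpha and MYC driving
#' glycolytic enzymes, p53 repressing glucose transport and the oxidative
#' pentose phosphate branch, AKT activating MDM2 and lipogenic genes,
#' oxygen-dependent PHD destabilizing HIF-1alpha, lactate stabilizing
#' HIF-1alpha and inhibiting PHD). Kinetic and binding constants are
#' versioned package defaults in the unit-interval ranges of the rate
#' laws, calibrated once against the qualitative normal-behavior
#' checklist (see `ccmScenario("normal")`); they are not measured values.
#' The non-oxidative pentose phosphate branch is oriented toward
#' ribose-5-phosphate synthesis and sink reactions are assigned to a
#' representative pathway gene, both documented in the methods vignette.
#'
#' @return a validated [PathwayNetwork-class] with the canonical id ->
#'   display-name map in `displayNames`.
#' @export
ccmNetwork <- function() {
  genes <- c("glut1", "hk", "gpi", "pfk1", "pfk2", "aldo", "tpi", "gapdh",
             "pgk", "pgam", "eno", "pk", "ldh", "pdh", "pc", "cs", "aco",
             "idh", "ogdh", "scs", "sdh", "fh", "mdh", "pepck1", "fbpase",
             "g6pase", "g6pd", "pgd", "rpi", "rpe", "tkt", "taldo", "acly",
             "acc", "fasn", "acsl", "etc")
  signals <- c("rtk", "irs1", "pi3k", "pip3", "pdk1", "akt", "pten", "tsc",
               "rheb", "mtor", "s6k", "hif1a", "phd", "vhl", "myc", "ras",
               "raf", "mek", "erk", "jak", "stat3", "ikk", "nfkb", "p53",
               "mdm2", "ampk", "lkb1", "foxo", "redd1")
  mets <- c("glc_ext", "glc", "g6p", "f6p", "f16bp", "f26bp", "dhap",
            "ga3p", "bpg13", "pg3", "pg2", "pep", "pyr", "lac", "accoa",
            "cit", "icit", "akg", "succoa", "succ", "fum", "mal", "oaa",
            "pg6", "ru5p", "r5p", "x5p", "s7p", "e4p", "nadph", "nadp",
            "nadh", "nad", "atp", "adp", "amp", "ffa", "malcoa", "acylcoa",
            "fadh2", "fad")
  inputs <- c("glc_s", "o2", "insulin", "gf", "egf", "igf1", "il6", "tnfa",
              "aa", "gln", "stress", "ros", "glucagon", "epinephrine",
              "cortisol", "leptin", "adiponectin", "lac_ext", "pyr_ext",
              "serine", "glycine", "lipid", "fgf", "pdgf", "vegf", "tgfb",
              "wnt")

  nv <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }

  # -- signaling layer: one catalytic activation + one decay per species --
  act <- function(sp, activators = numeric(0), rate = 1, enhMet = numeric(0),
                  enhInput = numeric(0), inhMet = numeric(0),
                  inhSig = numeric(0))
    interactionRule(paste0("act_", sp), target = sp, activators = activators,
                    rate = rate, enhMet = enhMet, enhInput = enhInput,
                    inhMet = inhMet, inhSig = inhSig)
  dec <- function(sp, k = 0.5)
    interactionRule(paste0("dec_", sp), target = NA_character_,
                    activators = nv(stats::setNames(k, sp)), consumes = sp)

  irules <- list(
    act("rtk", rate = 0.18,
        enhInput = nv(gf = 0.8, egf = 0.5, igf1 = 0.5, fgf = 0.3,
                      pdgf = 0.3, vegf = 0.3)),                  dec("rtk", 0.85),
    act("irs1", nv(rtk = 0.8), enhInput = nv(insulin = 0.9)),    dec("irs1", 0.9),
    act("pi3k", nv(irs1 = 0.6), enhMet = nv(g6p = 0.6, glc = 0.25)),
                                                                 dec("pi3k", 0.85),
    act("pip3", nv(pi3k = 0.9), inhSig = nv(pten = 0.85)),       dec("pip3", 0.8),
    act("pdk1", nv(pip3 = 0.9)),                                 dec("pdk1", 0.8),
    act("akt", nv(pdk1 = 0.95)),                                 dec("akt", 0.8),
    act("pten", rate = 0.3, enhInput = nv(stress = 0.4)),        dec("pten", 0.85),
    act("tsc", rate = 0.55, inhSig = nv(akt = 0.9)),             dec("tsc", 0.85),
    act("rheb", rate = 0.6, inhSig = nv(tsc = 0.9)),             dec("rheb", 0.85),
    act("mtor", nv(rheb = 0.95), enhInput = nv(aa = 0.5, gln = 0.3),
        inhSig = nv(redd1 = 0.5)),                               dec("mtor", 0.8),
    act("s6k", nv(mtor = 0.9)),                                  dec("s6k", 0.85),
    act("hif1a", nv(mtor = 0.6), enhMet = nv(lac = 0.85),
        inhSig = nv(phd = 0.9)),                                 dec("hif1a", 0.75),
    act("phd", nv(vhl = 0.55), enhInput = nv(o2 = 0.9),
        inhMet = nv(lac = 0.85)),                                dec("phd", 0.8),
    act("vhl", rate = 0.5),                                      dec("vhl", 0.85),
    act("myc", nv(erk = 0.65), enhInput = nv(wnt = 0.4),
        enhMet = nv(glc = 0.3)),                                 dec("myc", 0.8),
    act("ras", nv(rtk = 0.8)),                                   dec("ras", 0.9),
    act("raf", nv(ras = 0.8), enhMet = nv(lac = 0.15)),          dec("raf", 0.9),
    act("mek", nv(raf = 0.8)),                                   dec("mek", 0.9),
    act("erk", nv(mek = 0.8)),                                   dec("erk", 0.9),
    act("jak", rate = 0.3, enhInput = nv(il6 = 0.8)),            dec("jak", 0.85),
    act("stat3", nv(jak = 0.9)),                                 dec("stat3", 0.8),
    act("ikk", rate = 0.3, enhInput = nv(tnfa = 0.8, tgfb = 0.3)),
                                                                 dec("ikk", 0.85),
    act("nfkb", nv(ikk = 0.9), enhMet = nv(lac = 0.5)),          dec("nfkb", 0.8),
    act("p53", rate = 0.45, enhInput = nv(ros = 0.6, stress = 0.4),
        enhMet = nv(lac = 0.85), inhMet = nv(nadph = 0.8),
        inhSig = nv(mdm2 = 0.95, akt = 0.9)),
                                                                 dec("p53", 0.8),
    act("mdm2", nv(akt = 0.75)),                                 dec("mdm2", 0.85),
    act("ampk", nv(lkb1 = 0.85), enhMet = nv(amp = 0.8),
        enhInput = nv(leptin = 0.3, adiponectin = 0.3)),         dec("ampk", 0.8),
    act("lkb1", rate = 0.35, enhInput = nv(stress = 0.5)),       dec("lkb1", 0.85),
    act("foxo", rate = 0.6,
        enhInput = nv(glucagon = 0.5, cortisol = 0.4, epinephrine = 0.3),
        inhSig = nv(akt = 0.9)),                                 dec("foxo", 0.8),
    act("redd1", nv(hif1a = 0.8)),                               dec("redd1", 0.85))

  # -- transcription layer ------------------------------------------------
  g <- function(gene, activators, b = 0.03, d = 0.07, enhMet = numeric(0),
                enhInput = numeric(0), inhSig = numeric(0))
    geneRule(gene, basal = b, decay = d, activators = activators,
             enhMet = enhMet, enhInput = enhInput, inhSig = inhSig)

  grules <- list(
    g("glut1", nv(hif1a = 0.8, myc = 0.65), d = 0.05, inhSig = nv(p53 = 0.9)),
    g("hk", nv(hif1a = 0.85, myc = 0.7), enhMet = nv(glc = 0.3)),
    g("gpi", nv(myc = 0.4)),
    g("pfk1", nv(hif1a = 0.4), enhMet = nv(f26bp = 0.4)),
    g("pfk2", nv(hif1a = 0.35)),
    g("aldo", nv(hif1a = 0.38)),
    g("tpi", nv(myc = 0.4)),
    g("gapdh", nv(hif1a = 0.32)),
    g("pgk", nv(hif1a = 0.38)),
    g("pgam", nv(myc = 0.3)),
    g("eno", nv(myc = 0.3)),
    g("pk", nv(hif1a = 0.85, myc = 0.8)),
    g("ldh", nv(hif1a = 0.75, myc = 0.65)),
    g("pdh", nv(erk = 0.4), inhSig = nv(hif1a = 0.7)),
    g("pc", nv(erk = 0.4)),
    g("cs", nv(erk = 0.25)),
    g("aco", nv(erk = 0.28)),
    g("idh", nv(erk = 0.35)),
    g("ogdh", nv(erk = 0.35)),
    g("scs", nv(erk = 0.35)),
    g("sdh", nv(erk = 0.35)),
    g("fh", nv(erk = 0.35)),
    g("mdh", nv(erk = 0.35)),
    g("pepck1", nv(foxo = 0.35), inhSig = nv(akt = 0.9),
      enhInput = nv(glucagon = 0.4)),
    g("fbpase", nv(foxo = 0.32), inhSig = nv(akt = 0.9)),
    g("g6pase", nv(foxo = 0.35), inhSig = nv(akt = 0.9),
      enhInput = nv(glucagon = 0.4, cortisol = 0.3)),
    g("g6pd", nv(myc = 0.7, stat3 = 0.5), d = 0.05, inhSig = nv(p53 = 0.95)),
    g("pgd", nv(myc = 0.45), d = 0.06, inhSig = nv(p53 = 0.8)),
    g("rpi", nv(myc = 0.45), d = 0.06, inhSig = nv(p53 = 0.8)),
    g("rpe", nv(myc = 0.4)),
    g("tkt", nv(myc = 0.7, stat3 = 0.5), d = 0.05, inhSig = nv(p53 = 0.9)),
    g("taldo", nv(myc = 0.4)),
    g("acly", nv(akt = 0.4)),
    g("acc", nv(akt = 0.55, mtor = 0.5)),
    g("fasn", nv(akt = 0.55, mtor = 0.55)),
    g("acsl", nv(akt = 0.4), enhInput = nv(lipid = 0.4)),
    g("etc", nv(ampk = 0.45)))

  # -- metabolic layer ----------------------------------------------------
  rx <- function(id, sub, prod, cat, K, Km = 0.3, enhMet = numeric(0),
                 enhInput = numeric(0), inhMet = numeric(0),
                 inhInput = numeric(0))
    reactionRule(id, substrates = sub, products = prod, catGene = cat,
                 K = K, Km = Km, enhMet = enhMet, enhInput = enhInput,
                 inhMet = inhMet, inhInput = inhInput)

  rrules <- list(
    rx("glc_supply", character(0), "glc_ext", "glut1", 0.5, 0.5,
       enhInput = nv(glc_s = 0.9), inhMet = nv(lac = 0.9)),
    rx("glc_uptake", "glc_ext", "glc", "glut1", 0.6, 0.35,
       inhMet = nv(lac = 0.9)),
    rx("hk", "glc", "g6p", "hk", 0.8, 0.2,
       inhMet = nv(g6p = 0.4)),
    rx("gpi", "g6p", "f6p", "gpi", 0.6, 0.35),
    rx("pfk1", c("f6p", "atp"), c("f16bp", "adp"), "pfk1", 0.75, 0.15,
       enhMet = nv(f26bp = 0.6, amp = 0.6)),
    rx("pfk2", c("f6p", "atp"), c("f26bp", "adp"), "pfk2", 0.3, 0.4),
    rx("f26bpase", "f26bp", "f6p", "pfk2", 0.3, 0.4),
    rx("aldo", "f16bp", c("dhap", "ga3p"), "aldo", 0.7, 0.3),
    rx("tpi", "dhap", "ga3p", "tpi", 0.75, 0.3),
    rx("gapdh", c("ga3p", "nad"), c("bpg13", "nadh"), "gapdh", 0.85, 0.25),
    rx("pgk", "bpg13", "pg3", "pgk", 0.85, 0.25),
    rx("pgam", "pg3", "pg2", "pgam", 0.7, 0.3),
    rx("eno", "pg2", "pep", "eno", 0.5, 0.35),
    rx("pk", c("pep", "adp"), c("pyr", "atp"), "pk", 0.9, 0.2,
       enhMet = nv(f16bp = 0.5)),
    rx("ldh", c("pyr", "nadh"), c("lac", "nad"), "ldh", 0.55, 0.15,
       enhInput = nv(pyr_ext = 0.2)),
    rx("lac_clear", "lac", character(0), "ldh", 0.3, 0.4,
       enhInput = nv(lac_ext = 0.1)),
    rx("pdh", c("pyr", "fad"), c("accoa", "fadh2"), "pdh", 0.8, 0.25),
    rx("pc", c("pyr", "atp"), c("oaa", "adp"), "pc", 0.6, 0.2),
    rx("cs", c("accoa", "oaa"), "cit", "cs", 0.8, 0.3),
    rx("aco", "cit", "icit", "aco", 0.25, 0.5),
    rx("idh", c("icit", "fad"), c("akg", "fadh2"), "idh", 0.75, 0.3),
    rx("ogdh", c("akg", "fad"), c("succoa", "fadh2"), "ogdh", 0.75, 0.3),
    rx("scs", c("succoa", "adp"), c("succ", "atp"), "scs", 0.85, 0.2),
    rx("sdh", c("succ", "fad"), c("fum", "fadh2"), "sdh", 0.7, 0.3),
    rx("fh", "fum", "mal", "fh", 0.6, 0.35),
    rx("mdh", c("mal", "fad"), c("oaa", "fadh2"), "mdh", 0.7, 0.3),
    rx("pepck1", c("oaa", "atp"), c("pep", "adp"), "pepck1", 0.3, 0.4),
    rx("fbpase", "f16bp", "f6p", "fbpase", 0.35, 0.4),
    rx("g6pase", "g6p", "glc", "g6pase", 0.4, 0.4),
    rx("glc_export", "glc", character(0), "glut1", 0.3, 0.5),
    rx("g6pd", c("g6p", "nadp"), c("pg6", "nadph"), "g6pd", 0.7, 0.3,
       inhMet = nv(nadph = 0.5, lac = 0.9)),
    rx("pgd", c("pg6", "nadp"), c("ru5p", "nadph"), "pgd", 0.55, 0.3,
       inhMet = nv(lac = 0.9)),
    rx("rpi", "ru5p", "r5p", "rpi", 0.7, 0.3),
    rx("rpe", "x5p", "ru5p", "rpe", 0.6, 0.3),
    rx("tkt_a", c("f6p", "ga3p"), c("x5p", "e4p"), "tkt", 0.55, 0.3),
    rx("taldo", c("e4p", "f6p"), c("s7p", "ga3p"), "taldo", 0.55, 0.3),
    rx("tkt_b", c("s7p", "ga3p"), c("x5p", "r5p"), "tkt", 0.55, 0.3),
    rx("purine_syn", "r5p", "amp", "rpi", 0.55, 0.28),
    rx("nadph_use", "nadph", "nadp", "gapdh", 0.7, 0.4,
       enhMet = nv(lac = 0.95), enhInput = nv(ros = 0.4)),
    rx("acly", c("cit", "atp"), c("accoa", "oaa", "adp"), "acly", 0.4, 0.4),
    rx("acc", c("accoa", "atp"), c("malcoa", "adp"), "acc", 0.45, 0.4,
       inhMet = nv(acylcoa = 0.5)),
    rx("fasn", c("malcoa", "nadph"), c("ffa", "nadp"), "fasn", 0.2, 0.3),
    rx("acsl", c("ffa", "atp"), c("acylcoa", "amp"), "acsl", 0.35, 0.4,
       enhInput = nv(lipid = 0.3)),
    rx("acylcoa_use", "acylcoa", character(0), "acsl", 0.35, 0.6),
    rx("nadh_shuttle", c("nadh", "fad"), c("nad", "fadh2"), "mdh", 0.5, 0.45,
       inhMet = nv(lac = 0.9)),
    rx("oxphos", c("fadh2", "adp"), c("fad", "atp"), "etc", 0.95, 0.12,
       enhInput = nv(o2 = 0.9), inhMet = nv(lac = 0.6)),
    rx("atp_use", "atp", "adp", "etc", 0.4, 0.5),
    rx("ck_buffer", "adp", "atp", "etc", 0.2, 0.4),
    rx("ffa_ox", "ffa", character(0), "etc", 0.2, 0.5),
    rx("amp_salvage", "amp", "adp", "pgk", 0.4, 0.4),
    rx("ak_cycle", "adp", "amp", "pgk", 0.15, 0.5),
    rx("nucleotide_turnover", "amp", character(0), "acly", 0.12, 0.5))

  display <- c(glut1 = "GLUT1", hk = "Hexokinase", gpi = "Glucose-6-phosphate isomerase",
               pfk1 = "PFK1", pfk2 = "PFK2", aldo = "Aldolase",
               tpi = "Triose-phosphate isomerase", gapdh = "GAPDH",
               pgk = "Phosphoglycerate kinase", pgam = "Phosphoglycerate mutase",
               eno = "Enolase", pk = "Pyruvate kinase", ldh = "Lactate dehydrogenase",
               pdh = "Pyruvate dehydrogenase", pc = "Pyruvate carboxylase",
               cs = "Citrate synthase", aco = "Aconitase", idh = "Isocitrate dehydrogenase",
               ogdh = "alpha-KG dehydrogenase", scs = "Succinyl-CoA synthetase",
               sdh = "Succinate dehydrogenase", fh = "Fumarase",
               mdh = "Malate dehydrogenase", pepck1 = "PEPCK1",
               fbpase = "Fructose-1,6-bisphosphatase", g6pase = "Glucose-6-phosphatase",
               g6pd = "Glucose-6-phosphate dehydrogenase",
               pgd = "Phospho-gluco dehydrogenase", rpi = "Ribose-5P isomerase",
               rpe = "Ribulose-5P epimerase", tkt = "Transketolase",
               taldo = "Transaldolase", acly = "ATP-citrate lyase",
               acc = "Acetyl-CoA carboxylase", fasn = "Fatty acid synthase",
               acsl = "Acyl-CoA synthetase", etc = "Electron transport chain",
               hif1a = "HIF-1α", nfkb = "NF-κB", akt = "AKT",
               mtor = "mTOR", pi3k = "PI3K", erk = "ERK", stat3 = "STAT3",
               myc = "MYC", p53 = "p53", phd = "PHD",
               glc = "Glucose", g6p = "Glucose-6P", f6p = "Fructose-6P",
               f16bp = "Fructose-1,6-bisP", f26bp = "Fructose-2,6-bisP",
               ga3p = "Glyceraldehyde-3P", pep = "PEP", pyr = "Pyruvate",
               lac = "Lactate", r5p = "Ribose-5P", nadph = "NADPH",
               nadh = "NADH", atp = "ATP", oaa = "Oxaloacetate",
               cit = "Citrate", succ = "Succinate", ffa = "Free fatty acids")

  pathwayNetwork(genes, signals, mets, inputs, grules, irules, rrules,
                 displayNames = display,
                 meta = list(name = "ccm", version = "1.0", tuning_seed = 20260929))
}

#' Reference external-input vector for the packaged CCM network
#'
#' Baseline micro-environment: glucose and oxygen replete, moderate
#' insulin/growth-factor tone, low stress. Scenario definitions perturb
#' individual components of this vector.
#'
#' @return named numeric of length 27 with values in (0, 1).
#' @export
ccmBaselineInput <- function() {
  u <- c(glc_s = 0.8, o2 = 0.8, insulin = 0.6, gf = 0.6, egf = 0.4,
         igf1 = 0.4, il6 = 0.35, tnfa = 0.3, aa = 0.6, gln = 0.5,
         stress = 0.2, ros = 0.25, glucagon = 0.3, epinephrine = 0.25,
         cortisol = 0.3, leptin = 0.3, adiponectin = 0.3, lac_ext = 0.2,
         pyr_ext = 0.2, serine = 0.4, glycine = 0.4, lipid = 0.35,
         fgf = 0.3, pdgf = 0.3, vegf = 0.3, tgfb = 0.25, wnt = 0.3)
  u
}
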