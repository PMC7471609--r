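## Deterministic synthetic fixtures: toy core models with the
## ferredoxin/NAD(P)H redox structure of cellulolytic anaerobes,
## maintenance training datasets with known GAM/NGAM, and omics datasets
## with a planted consistent-reaction set. All generators are pure
## functions of their arguments and seed.

#' Generate a toy core metabolic model
#'
#' Two layouts share a substrate uptake chain that produces ATP
#' (\code{atpPerSubstrate} mol ATP per mol substrate) and a biomass
#' reaction in three variants (cellobiose / cellulose / no-cellulosome)
#' whose ATP coefficient plays the growth-associated-maintenance role:
#'
#' * the default chain/parallel layout: a linear conversion chain of
#'   \code{chainLength} gene-associated steps feeding \code{nRoutes}
#'   parallel routes into the biomass precursor, plus a secretion valve —
#'   small enough for hand-computed LP answers;
#' * with \code{includeRedox = TRUE}: a pyruvate-node topology with
#'   NADH/NADPH/ferredoxin pools, an ethanol and an acetate branch, a
#'   ferredoxin-dependent hydrogenase (own gene), a bifurcating and a
#'   bidirectional hydrogenase with distinct structural genes that share a
#'   maturase gene (so deleting the maturase silences both, mimicking
#'   \emph{hydG} genotypes), a ferredoxin:NADP oxidoreductase supplying
#'   NADPH, and a sulfate-reduction-style NADPH sink behind a
#'   closed-by-default sulfate uptake (an external electron acceptor for
#'   rescue screening).
#'
#' \code{includeCycle} adds a two-reaction internal loop disconnected from
#' any demand (thermodynamically infeasible; loopless FVA must zero it).
#' \code{includeCellulose} adds a glucose-equivalent cellodextrin
#' pseudo-reaction path for growth on cellulose.
#'
#' @param chainLength number of chain steps (chain layout), >= 1.
#' @param nRoutes parallel routes (chain layout), >= 1.
#' @param includeRedox use the redox/pyruvate-node layout.
#' @param includeCycle add the two-reaction internal loop.
#' @param includeCellulose add the cellodextrin pseudo-reactions.
#' @param atpPerSubstrate mol ATP formed per mol substrate taken up.
#' @param biomassAtp mol ATP hydrolysed per unit biomass (the GAM role).
#' @param seed retained for generator-signature uniformity; the layout is
#'   fully deterministic.
#' @return a [MetabolicModel].
#' @export
toyModel <- function(chainLength = 2, nRoutes = 2, includeRedox = FALSE,
                     includeCycle = FALSE, includeCellulose = FALSE,
                     atpPerSubstrate = 4, biomassAtp = 2, seed = 1L) {
  if (!includeRedox && nRoutes < 1)
    stop("contradictory spec: need at least one route")
  if (!includeRedox && chainLength < 1)
    stop("contradictory spec: need at least one chain step")
  met <- function(id, compartment, formula = "", charge = NA_integer_,
                  name = id)
    data.frame(id = id, name = name, formula = formula, charge = charge,
               compartment = compartment, stringsAsFactors = FALSE)
  rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "", name = id)
    list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
         gpr = gpr, subsystem = "")

  mets <- rbind(met("sub_e", "e"), met("sub_c", "c"),
                met("atp_c", "c"), met("adp_c", "c"), met("pi_c", "c"))
  A <- atpPerSubstrate
  B <- biomassAtp
  energy <- function(n) c(atp_c = n, adp_c = -n, pi_c = -n)
  reactions <- list(
    rxn("EX_sub_e", c(sub_e = -1), lb = -10, ub = 0),
    rxn("SUBt", c(sub_e = -1, sub_c = 1), gpr = "gT"))

  if (!includeRedox) {
    chain <- paste0("c", seq_len(chainLength))
    for (cm in chain) mets <- rbind(mets, met(paste0(cm, "_c"), "c"))
    mets <- rbind(mets, met("p_c", "c"), met("p_e", "e"))
    prev <- "sub_c"
    for (i in seq_len(chainLength)) {
      st <- stats::setNames(c(-1, 1), c(prev, paste0(chain[i], "_c")))
      if (i == 1) st <- c(st, energy(A))
      reactions <- c(reactions, list(
        rxn(paste0("CH", i), st, gpr = paste0("gC", i))))
      prev <- paste0(chain[i], "_c")
    }
    for (r in seq_len(nRoutes))
      reactions <- c(reactions, list(
        rxn(paste0("RT", r), stats::setNames(c(-1, 1), c(prev, "p_c")),
            gpr = paste0("gR", r))))
    reactions <- c(reactions, list(
      rxn("Pt", c(p_c = -1, p_e = 1)),
      rxn("EX_p_e", c(p_e = -1)),
      rxn("BIOMASS_CELLOBIOSE", c(p_c = -1, energy(-B))),
      rxn("BIOMASS_CELLULOSE", c(p_c = -1.2, energy(-B))),
      rxn("BIOMASS_NO_CELLULOSOME", c(p_c = -0.9, energy(-B)))))
  } else {
    for (id in c("pyr_c", "accoa_c", "nad_c", "nadh_c", "nadp_c",
                 "nadph_c", "fdxo_c", "fdxr_c", "etoh_c", "ac_c", "h2_c"))
      mets <- rbind(mets, met(id, "c"))
    for (id in c("etoh_e", "ac_e", "h2_e", "so4_e", "h2s_e"))
      mets <- rbind(mets, met(id, "e"))
    reactions <- c(reactions, list(
      rxn("GLY", c(sub_c = -1, pyr_c = 2, nad_c = -2, nadh_c = 2,
                   energy(2)), gpr = "gG"),
      rxn("POR", c(pyr_c = -1, fdxo_c = -1, accoa_c = 1, fdxr_c = 1),
          gpr = "gP"),
      rxn("ALCD", c(accoa_c = -1, nadh_c = -2, nad_c = 2, etoh_c = 1),
          gpr = "gE"),
      rxn("PTACK", c(accoa_c = -1, ac_c = 1, energy(1)), gpr = "gA"),
      rxn("BIF", c(fdxr_c = -1, nadh_c = -1, fdxo_c = 1, nad_c = 1,
                   h2_c = 2), gpr = "gBif and gMat"),
      rxn("H2ASE", c(nadph_c = -1, nadp_c = 1, h2_c = 1),
          gpr = "gH2 and gMat"),
      rxn("ECH", c(fdxr_c = -1, fdxo_c = 1, h2_c = 1), gpr = "gEch"),
      rxn("NFN", c(fdxr_c = -1, nadh_c = -1, nadp_c = -2, fdxo_c = 1,
                   nad_c = 1, nadph_c = 2), gpr = "gN"),
      rxn("RDX", c(so4_e = -1, nadph_c = -1, nadp_c = 1, h2s_e = 1),
          gpr = "gS"),
      rxn("EX_so4_e", c(so4_e = -1)),
      rxn("EX_h2s_e", c(h2s_e = -1)),
      rxn("ETOHt", c(etoh_c = -1, etoh_e = 1)),
      rxn("ACt", c(ac_c = -1, ac_e = 1)),
      rxn("H2t", c(h2_c = -1, h2_e = 1)),
      rxn("EX_etoh_e", c(etoh_e = -1)),
      rxn("EX_ac_e", c(ac_e = -1)),
      rxn("EX_h2_e", c(h2_e = -1)),
      rxn("BIOMASS_CELLOBIOSE",
          c(pyr_c = -2, nadph_c = -0.5, nadp_c = 0.5, energy(-B))),
      rxn("BIOMASS_CELLULOSE",
          c(pyr_c = -2.4, nadph_c = -0.5, nadp_c = 0.5, energy(-B))),
      rxn("BIOMASS_NO_CELLULOSOME",
          c(pyr_c = -1.8, nadph_c = -0.5, nadp_c = 0.5, energy(-B)))))
  }
  reactions <- c(reactions, list(
    rxn("ATPM", c(atp_c = -1, adp_c = 1, pi_c = 1))))
  if (includeCycle) {
    mets <- rbind(mets, met("cycA_c", "c"), met("cycB_c", "c"))
    reactions <- c(reactions, list(
      rxn("CYCA", c(cycA_c = -1, cycB_c = 1), gpr = "gCyA"),
      rxn("CYCB", c(cycB_c = -1, cycA_c = 1), gpr = "gCyB")))
  }
  if (includeCellulose) {
    mets <- rbind(mets, met("glceq_e", "e"), met("cell4_e", "e"))
    reactions <- c(reactions, list(
      rxn("EX_glceq_e", c(glceq_e = -1), lb = 0, ub = 0),
      rxn("CLDX4", c(glceq_e = -4, cell4_e = 1), lb = 0, ub = 0),
      rxn("CELL4t", c(cell4_e = -1, sub_c = 4), gpr = "gT")))
  }
  makeModel("toy_core",
            mets, reactions,
            biomassVariants = c(cellobiose = "BIOMASS_CELLOBIOSE",
                                cellulose = "BIOMASS_CELLULOSE",
                                no_cellulosome = "BIOMASS_NO_CELLULOSOME"),
            atpmReaction = "ATPM")
}

#' Default batch-cellobiose condition for the toy models
#'
#' @param model a toy model from [toyModel()].
#' @param uptake maximum substrate uptake magnitude.
#' @return a [GrowthCondition] with all toy secretions allowed.
#' @export
toyCondition <- function(model, uptake = 10) {
  secr <- intersect(c("EX_p_e", "EX_etoh_e", "EX_ac_e", "EX_h2_e", "EX_h2s_e"),
                    reactionIds(model))
  growthCondition("toy-batch-cellobiose",
                  reactorMode = "batch", carbonSource = "cellobiose",
                  biomassVariant = "cellobiose",
                  uptake = c(EX_sub_e = uptake), secretion = secr)
}

#' Generate a maintenance training dataset with known GAM/NGAM
#'
#' For each growth rate, computes the substrate uptake whose ATP yield
#' matches the planted demand \code{gam * mu + ngam} (plus seeded Gaussian
#' noise on the ATP scale) and emits a condition with the measured uptake
#' and growth rate at zero standard deviation. Feeding the conditions
#' through [maxATPYield()] and [fitMaintenance()] recovers \code{gam} and
#' \code{ngam} exactly at zero noise.
#'
#' @param model a chain-layout [toyModel()] (its first chain step defines
#'   the ATP yield per substrate).
#' @param gam,ngam planted maintenance parameters (>= 0).
#' @param growthRates measured growth rates (1/h), nonempty.
#' @param noiseSd Gaussian noise sd on the ATP demand.
#' @param seed RNG seed.
#' @return list of [GrowthCondition]s, one per growth rate.
#' @export
maintenanceDataset <- function(model, gam, ngam, growthRates,
                               noiseSd = 0, seed = 1L) {
  stopifnot(gam >= 0, ngam >= 0)
  if (!length(growthRates)) stop("empty growth rate list")
  atpYield <- -stoichiometry(model)["atp_c", "ATPM"] *
    sum(stoichiometry(model)["atp_c", grep("^CH1$", reactionIds(model))])
  if (length(atpYield) != 1 || atpYield <= 0)
    stop("model lacks the chain ATP-producing step")
  withSeed <- function(expr) { # localized RNG, restored afterwards
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  noise <- withSeed(stats::rnorm(length(growthRates), 0, noiseSd))
  biomassRxn <- biomassVariants(model)[["cellobiose"]]
  pCoef <- -stoichiometry(model)[, biomassRxn]
  pCoef <- pCoef[grep("^p_c$|^pyr_c$", names(pCoef))]
  lapply(seq_along(growthRates), function(i) {
    mu <- growthRates[i]
    uptake <- (gam * mu + ngam + noise[i]) / atpYield
    if (uptake < mu * sum(pCoef))
      stop("growth rate ", mu, " infeasible for the model at the planted ",
           "parameters (required uptake ", signif(uptake, 4), " too small)")
    growthCondition(
      name = sprintf("maint_%02d", i),
      reactorMode = "chemostat", carbonSource = "cellobiose",
      biomassVariant = "cellobiose",
      measured = data.frame(
        reaction = c("EX_sub_e", biomassRxn),
        mean = c(-uptake, mu), sd = c(0, 0),
        stringsAsFactors = FALSE),
      uptake = c(EX_sub_e = uptake * 2),
      secretion = intersect(c("EX_p_e", "EX_etoh_e", "EX_ac_e", "EX_h2_e", "EX_h2s_e"),
                            reactionIds(model)))
  })
}

#' Generate an omics dataset with a planted consistent set
#'
#' Builds wild-type and maturase-deletion conditions on the redox toy
#' model, runs the quadratic pFBA simulation, and assigns gene fold
#' changes that match the simulated reaction fold changes on a planted set
#' of reactions whose genes are private to them (so the GPR mean maps the
#' gene values back exactly). At zero noise the protocol must recover
#' exactly the planted set with a pFBA Pearson correlation of 1.
#'
#' @param model a redox [toyModel()].
#' @param deletions gene ids deleted in the mutant (default the shared
#'   hydrogenase maturase, mimicking a \emph{hydG}-style genotype).
#' @param planted reaction ids to plant; default: the reactions with a
#'   private single-gene GPR and a nonzero simulated fold change.
#' @param noiseSd Gaussian noise added to the planted gene fold changes.
#' @param fracUnmeasured fraction of the remaining (non-planted) genes
#'   masked as unmeasured.
#' @param seed RNG seed.
#' @return list with geneFC (data.frame gene/log2fc), conditionWt,
#'   conditionMut, deletions, config ([fcProtocolConfig()]), and
#'   expectedConsistent (the planted ground-truth reaction set).
#' @export
omicsDataset <- function(model, deletions = "gMat", planted = NULL,
                         noiseSd = 0, fracUnmeasured = 0, seed = 1L) {
  cond <- toyCondition(model)
  biomassRxn <- biomassVariants(model)[["cellobiose"]]
  mkCond <- function(m, name) {
    mm <- applyCondition(m, cond)
    mu <- fba(mm, biomassRxn)@objective
    c2 <- cond
    c2@name <- name
    c2@measured <- data.frame(
      reaction = c("EX_sub_e", biomassRxn),
      mean = c(-10, 0.9 * mu), sd = c(0, 0), stringsAsFactors = FALSE)
    c2
  }
  condWt <- mkCond(model, "wt")
  condMut <- mkCond(deleteGenes(model, deletions), "mut")
  config <- fcProtocolConfig(uptakeWt = "EX_sub_e", loopless = FALSE)

  solveFC <- function(cnd, m) {
    mm <- applyCondition(m, cnd)
    mm <- applyBounds(mm, buildMeasuredBounds(mm, cnd))
    pfba(mm)
  }
  pWt <- solveFC(condWt, model)
  pMut <- solveFC(condMut, deleteGenes(model, deletions))
  fcP <- simulatedFoldChange(fluxes(pMut), fluxes(pWt),
                             fluxes(pMut)[["EX_sub_e"]],
                             fluxes(pWt)[["EX_sub_e"]], config$epsilon)
  fcByRxn <- stats::setNames(fcP$fc, reactionIds(model))
  reversal <- grepl("sign_reversal", fcP$flag)

  ## candidate planted reactions: single private gene, clean nonzero FC
  geneCount <- table(unlist(lapply(model@gpr, gprGenes)))
  if (is.null(planted)) {
    planted <- Filter(function(j) {
      g <- gprGenes(model@gpr[[j]])
      length(g) == 1 && geneCount[[g]] == 1 &&
        abs(fcByRxn[[j]]) > 0.05 && !reversal[[match(j, reactionIds(model))]]
    }, reactionIds(model))
  }
  if (!length(planted)) stop("no plantable reactions with private GPR genes")
  bad <- Filter(function(j) is.null(model@gpr[[j]]), planted)
  if (length(bad))
    stop("planted reaction(s) without GPR: ", paste(bad, collapse = ", "))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  plantedGenes <- vapply(planted, function(j) gprGenes(model@gpr[[j]]),
                         character(1))
  fcGenes <- fcByRxn[planted] + stats::rnorm(length(planted), 0, noiseSd)
  others <- setdiff(geneIds(model), plantedGenes)
  keep <- others[stats::runif(length(others)) >= fracUnmeasured]
  geneFC <- data.frame(
    gene = c(plantedGenes, keep),
    log2fc = c(unname(fcGenes), rep(0, length(keep))),
    stringsAsFactors = FALSE)
  expected <- planted[sign(fcGenes) == sign(fcByRxn[planted]) &
                        fcGenes != 0]
  list(geneFC = geneFC, conditionWt = condWt, conditionMut = condMut,
       deletions = deletions, config = config,
       expectedConsistent = unname(expected))
}
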