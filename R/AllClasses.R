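#' @import methods
NULL

#' MetabolicModel: a genome-scale stoichiometric model
#'
#' Container for a constraint-based metabolic model: the stoichiometric
#' matrix (metabolites x reactions), flux bounds in mmol/gCDW/h,
#' gene-protein-reaction (GPR) boolean associations, metabolite chemistry
#' (formula, charge, compartment) and the bookkeeping the simulation layer
#' needs — which reactions are biomass variants (cellobiose / cellulose /
#' no-cellulosome) and which reaction is the ATP-hydrolysis pseudo-reaction
#' carrying non-growth-associated maintenance.
#'
#' @slot id model identifier.
#' @slot stoich dense numeric matrix, metabolites in rows, reactions in
#'   columns, with dimnames.
#' @slot lb,ub named numeric vectors of lower/upper flux bounds per reaction.
#' @slot gpr named list of parsed GPR boolean trees (see [parseGPR()]);
#'   entries may be \code{NULL} for reactions with no gene association.
#' @slot genes character vector of gene identifiers.
#' @slot mets data.frame with columns id, name, formula, charge, compartment.
#' @slot rxns data.frame with columns id, name, subsystem.
#' @slot biomassVariants named character; names are variant labels
#'   (\code{cellobiose}, \code{cellulose}, \code{no_cellulosome}), values are
#'   reaction ids.
#' @slot atpmReaction id of the ATP-hydrolysis (NGAM) pseudo-reaction, or
#'   \code{NA_character_}.
#' @slot compartments named character of compartment ids -> names.
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    id = "character",
    stoich = "matrix",
    lb = "numeric",
    ub = "numeric",
    gpr = "list",
    genes = "character",
    mets = "data.frame",
    rxns = "data.frame",
    biomassVariants = "character",
    atpmReaction = "character",
    compartments = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  S <- object@stoich
  rid <- colnames(S); mid <- rownames(S)
  if (is.null(rid) || is.null(mid))
    return("stoichiometric matrix must have dimnames")
  if (anyDuplicated(rid)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(mid)) msg <- c(msg, "duplicated metabolite ids")
  if (!identical(object@mets$id, mid))
    msg <- c(msg, "mets table does not match stoichiometry rows")
  if (!identical(object@rxns$id, rid))
    msg <- c(msg, "rxns table does not match stoichiometry columns")
  if (!identical(names(object@lb), rid) || !identical(names(object@ub), rid))
    msg <- c(msg, "bounds must be named by reaction id")
  if (any(object@lb > object@ub + 1e-12))
    msg <- c(msg, "lower bound exceeds upper bound")
  if (ncol(S) > 0 && any(colSums(S != 0) == 0))
    msg <- c(msg, "reaction with empty stoichiometry")
  if (!identical(names(object@gpr), rid))
    msg <- c(msg, "gpr list must be named by reaction id")
  leaves <- unique(unlist(lapply(object@gpr, gprGenes)))
  if (length(setdiff(leaves, object@genes)))
    msg <- c(msg, paste("GPR references unknown genes:",
                        paste(setdiff(leaves, object@genes), collapse = ", ")))
  if (!all(object@mets$compartment %in% names(object@compartments)))
    msg <- c(msg, "metabolite compartment not declared")
  bv <- object@biomassVariants
  if (length(bv) && length(setdiff(bv, rid)))
    msg <- c(msg, "biomass variant reaction absent from model")
  if (!is.na(object@atpmReaction) && !(object@atpmReaction %in% rid))
    msg <- c(msg, "ATP-hydrolysis reaction absent from model")
  if (length(msg)) msg else TRUE
})

#' GrowthCondition: a simulation condition
#'
#' A reactor/medium/parameter context under which a [MetabolicModel] is
#' simulated: reactor mode (batch or chemostat), carbon source, active
#' biomass variant, the fitted growth- and non-growth-associated ATP
#' maintenance values, the measured extracellular flux table (mean and sd
#' per exchange reaction plus optionally the growth rate), and the medium
#' (allowed uptakes with maximum magnitudes, allowed secretions).
#'
#' @slot name condition label.
#' @slot reactorMode \code{"batch"} or \code{"chemostat"}.
#' @slot carbonSource \code{"cellobiose"} or \code{"cellulose"}.
#' @slot biomassVariant biomass variant label.
#' @slot gam growth-associated maintenance, mmol ATP/gCDW.
#' @slot ngam non-growth-associated maintenance, mmol ATP/gCDW/h.
#' @slot measured data.frame with columns reaction, mean, sd
#'   (fluxes in mmol/gCDW/h; growth rate in 1/h).
#' @slot uptake named numeric: exchange id -> maximum uptake magnitude.
#' @slot secretion character vector of exchange ids allowed to secrete.
#' @exportClass GrowthCondition
setClass("GrowthCondition",
  representation(
    name = "character",
    reactorMode = "character",
    carbonSource = "character",
    biomassVariant = "character",
    gam = "numeric",
    ngam = "numeric",
    measured = "data.frame",
    uptake = "numeric",
    secretion = "character"
  )
)

setValidity("GrowthCondition", function(object) {
  msg <- character(0)
  if (!object@reactorMode %in% c("batch", "chemostat"))
    msg <- c(msg, "reactorMode must be 'batch' or 'chemostat'")
  if (!object@carbonSource %in% c("cellobiose", "cellulose"))
    msg <- c(msg, "carbonSource must be 'cellobiose' or 'cellulose'")
  if (!is.na(object@gam) && object@gam < 0) msg <- c(msg, "gam must be >= 0")
  if (!is.na(object@ngam) && object@ngam < 0) msg <- c(msg, "ngam must be >= 0")
  m <- object@measured
  if (nrow(m) && (!all(c("reaction", "mean", "sd") %in% names(m))))
    msg <- c(msg, "measured table needs columns reaction, mean, sd")
  if (nrow(m) && any(m$sd < 0)) msg <- c(msg, "measured sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FluxDistribution: one flux vector over a model
#'
#' @slot condition condition label the distribution was computed under.
#' @slot fluxes named numeric, flux per reaction (mmol/gCDW/h).
#' @slot objective objective value of the program that produced it.
#' @slot status solver status string.
#' @exportClass FluxDistribution
setClass("FluxDistribution",
  representation(condition = "character", fluxes = "numeric",
                 objective = "numeric", status = "character"))

#' FluxRange: per-reaction flux variability intervals
#'
#' @slot ranges data.frame with columns reaction, min, max, status.
#' @slot loopless logical; whether thermodynamically infeasible internal
#'   cycles were excluded.
#' @exportClass FluxRange
setClass("FluxRange",
  representation(ranges = "data.frame", loopless = "logical"))

setValidity("FluxRange", function(object) {
  r <- object@ranges
  if (!all(c("reaction", "min", "max", "status") %in% names(r)))
    return("ranges needs columns reaction, min, max, status")
  ok <- r$status != "ok" | r$min <= r$max + 1e-6
  if (!all(ok)) return("min exceeds max")
  TRUE
})

#' MaintenanceFit: fitted GAM/NGAM parameters
#'
#' Ordinary least squares of maximum ATP-hydrolysis flux on measured growth
#' rate; the slope is the growth-associated maintenance (GAM) and the
#' intercept the non-growth-associated maintenance (NGAM).
#'
#' @slot gam slope, mmol ATP/gCDW.
#' @slot ngam intercept, mmol ATP/gCDW/h.
#' @slot r2 coefficient of determination of the fit.
#' @slot n number of points used.
#' @slot excluded labels of outlier points excluded from the fit.
#' @slot points data.frame with columns label, growth, atp, outlier.
#' @exportClass MaintenanceFit
setClass("MaintenanceFit",
  representation(gam = "numeric", ngam = "numeric", r2 = "numeric",
                 n = "integer", excluded = "character", points = "data.frame"))

#' ConsistencyReport: result of the fold-change integration protocol
#'
#' Per-reaction measured and simulated log2 fold changes, the mapped and
#' consistent flags, and Pearson correlations over the consistent set.
#'
#' @slot records data.frame with one row per reaction (columns reaction,
#'   fc_meas, fc_pfba, fc_fva, mapped, consistent, n_genes, flags).
#' @slot counts named numeric: total, mapped, consistent.
#' @slot correlations named numeric: pearson_pfba, pearson_fva.
#' @exportClass ConsistencyReport
setClass("ConsistencyReport",
  representation(records = "data.frame", counts = "numeric",
                 correlations = "numeric"))

setValidity("ConsistencyReport", function(object) {
  ct <- object@counts
  if (!all(c("total", "mapped", "consistent") %in% names(ct)))
    return("counts needs total, mapped, consistent")
  if (!(ct["consistent"] <= ct["mapped"] && ct["mapped"] <= ct["total"]))
    return("counts must satisfy consistent <= mapped <= total")
  r <- object@correlations
  if (any(!is.na(r) & (r < -1 - 1e-9 | r > 1 + 1e-9)))
    return("correlations outside [-1, 1]")
  TRUE
})
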