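## Constructors, accessors and show methods for MetabolicModel.

#' Build a MetabolicModel from a reaction list
#'
#' Low-level constructor used by the SBML reader and the fixture
#' generators.
#'
#' @param id model identifier.
#' @param mets data.frame with columns id, name, formula, charge,
#'   compartment.
#' @param reactions list of lists, each with elements id, name, stoich
#'   (named numeric of metabolite coefficients, products positive), lb, ub,
#'   gpr (string, may be ""), subsystem.
#' @param biomassVariants named character (variant label -> reaction id).
#' @param atpmReaction id of the ATP-hydrolysis pseudo-reaction or NA.
#' @param compartments named character of compartment ids.
#' @return a validated [MetabolicModel].
#' @export
makeModel <- function(id, mets, reactions,
                      biomassVariants = character(0),
                      atpmReaction = NA_character_,
                      compartments = c(c = "cytosol", e = "extracellular")) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  for (col in c("name", "formula")) if (is.null(mets[[col]])) mets[[col]] <- ""
  if (is.null(mets$charge)) mets$charge <- NA_integer_
  rid <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rid)) stop("duplicated reaction ids")
  S <- matrix(0, nrow(mets), length(reactions),
              dimnames = list(mets$id, rid))
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoich
    bad <- setdiff(names(st), mets$id)
    if (length(bad))
      stop(sprintf("reaction '%s' references undeclared species: %s",
                   rid[k], paste(bad, collapse = ", ")))
    S[names(st), k] <- st
  }
  getf <- function(f, default) vapply(reactions, function(r)
    if (is.null(r[[f]])) default else r[[f]], default)
  lb <- getf("lb", -1000); ub <- getf("ub", 1000)
  names(lb) <- rid; names(ub) <- rid
  gprs <- lapply(reactions, function(r)
    parseGPR(if (is.null(r$gpr)) "" else r$gpr))
  names(gprs) <- rid
  rxns <- data.frame(id = rid,
                     name = getf("name", ""),
                     subsystem = getf("subsystem", ""),
                     stringsAsFactors = FALSE)
  genes <- sort(unique(unlist(lapply(gprs, gprGenes))))
  if (is.null(genes)) genes <- character(0)
  new("MetabolicModel", id = id, stoich = S, lb = lb, ub = ub,
      gpr = gprs, genes = genes, mets = mets, rxns = rxns,
      biomassVariants = biomassVariants, atpmReaction = atpmReaction,
      compartments = compartments)
}

#' @rdname modelAccessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' Model accessors
#'
#' Accessor functions for [MetabolicModel] slots: reaction, metabolite and
#' gene identifiers, flux bounds, the stoichiometric matrix, the exchange
#' reaction set, the biomass variant map and the ATP-hydrolysis reaction.
#'
#' @param object a [MetabolicModel].
#' @return the corresponding component.
#' @name modelAccessors
#' @aliases reactionIds metaboliteIds geneIds stoichiometry lowerBounds
#'   upperBounds exchangeReactions biomassVariants atpmReaction
NULL

#' @rdname modelAccessors
setMethod("reactionIds", "MetabolicModel", function(object)
  colnames(object@stoich))

#' @rdname modelAccessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname modelAccessors
setMethod("metaboliteIds", "MetabolicModel", function(object)
  rownames(object@stoich))

#' @rdname modelAccessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname modelAccessors
setMethod("geneIds", "MetabolicModel", function(object) object@genes)

#' @rdname modelAccessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname modelAccessors
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoich)

#' @rdname modelAccessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))
#' @rdname modelAccessors
setMethod("lowerBounds", "MetabolicModel", function(object) object@lb)

#' @rdname modelAccessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))
#' @rdname modelAccessors
setMethod("upperBounds", "MetabolicModel", function(object) object@ub)

#' @rdname modelAccessors
#' @export
setGeneric("biomassVariants", function(object)
  standardGeneric("biomassVariants"))
#' @rdname modelAccessors
setMethod("biomassVariants", "MetabolicModel", function(object)
  object@biomassVariants)

#' @rdname modelAccessors
#' @export
setGeneric("atpmReaction", function(object) standardGeneric("atpmReaction"))
#' @rdname modelAccessors
setMethod("atpmReaction", "MetabolicModel", function(object)
  object@atpmReaction)

#' @rdname modelAccessors
#' @export
setGeneric("exchangeReactions", function(object)
  standardGeneric("exchangeReactions"))
#' @rdname modelAccessors
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  S <- object@stoich
  extracellular <- object@mets$id[object@mets$compartment == "e"]
  one <- colSums(S != 0) == 1
  ids <- colnames(S)[one]
  ids[vapply(ids, function(j) {
    met <- rownames(S)[S[, j] != 0]
    met %in% extracellular
  }, logical(1))]
})

#' Set flux bounds on one or more reactions
#'
#' @param model a [MetabolicModel].
#' @param reactions reaction ids.
#' @param lb,ub new bounds, recycled along \code{reactions}; \code{NA}
#'   leaves the existing bound in place.
#' @return the modified model.
#' @export
setBounds <- function(model, reactions, lb = NA, ub = NA) {
  unknown <- setdiff(reactions, reactionIds(model))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  lb <- rep_len(lb, length(reactions))
  ub <- rep_len(ub, length(reactions))
  keep <- !is.na(lb); model@lb[reactions[keep]] <- lb[keep]
  keep <- !is.na(ub); model@ub[reactions[keep]] <- ub[keep]
  validObject(model)
  model
}

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel '%s'\n", object@id))
  cat(sprintf("  %d metabolites, %d reactions, %d genes\n",
              nrow(object@stoich), ncol(object@stoich),
              length(object@genes)))
  cat(sprintf("  %d exchange reactions\n",
              length(exchangeReactions(object))))
  if (length(object@biomassVariants))
    cat("  biomass variants:",
        paste(sprintf("%s=%s", names(object@biomassVariants),
                      object@biomassVariants), collapse = ", "), "\n")
  if (!is.na(object@atpmReaction))
    cat("  ATP hydrolysis (NGAM):", object@atpmReaction, "\n")
})

setMethod("show", "GrowthCondition", function(object) {
  cat(sprintf("GrowthCondition '%s' (%s, %s)\n", object@name,
              object@reactorMode, object@carbonSource))
  cat(sprintf("  biomass variant: %s; GAM = %g mmol ATP/gCDW; NGAM = %g mmol ATP/gCDW/h\n",
              object@biomassVariant, object@gam, object@ngam))
  cat(sprintf("  %d measured fluxes, %d allowed uptakes, %d allowed secretions\n",
              nrow(object@measured), length(object@uptake),
              length(object@secretion)))
})

setMethod("show", "FluxDistribution", function(object) {
  cat(sprintf("FluxDistribution (%s): %d reactions, objective %.6g, status %s\n",
              object@condition, length(object@fluxes), object@objective,
              object@status))
})

setMethod("show", "FluxRange", function(object) {
  cat(sprintf("FluxRange over %d reactions (%s)\n", nrow(object@ranges),
              if (object@loopless) "loopless" else "standard"))
})

setMethod("show", "MaintenanceFit", function(object) {
  cat(sprintf("MaintenanceFit: GAM = %.4g mmol ATP/gCDW, NGAM = %.4g mmol ATP/gCDW/h (r2 = %.4f, n = %d)\n",
              object@gam, object@ngam, object@r2, object@n))
  if (length(object@excluded))
    cat("  excluded outliers:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "ConsistencyReport", function(object) {
  ct <- object@counts; r <- object@correlations
  cat(sprintf("ConsistencyReport: %d reactions, %d mapped, %d consistent\n",
              ct["total"], ct["mapped"], ct["consistent"]))
  cat(sprintf("  Pearson r over consistent set: pFBA %.3f, FVA %.3f\n",
              r["pearson_pfba"], r["pearson_fva"]))
})

#' @rdname fluxAccessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' Result accessors
#'
#' @param object a result object.
#' @return \code{fluxes()} returns the named flux vector of a
#'   [FluxDistribution]; \code{ranges()} the data.frame of a [FluxRange];
#'   \code{records()} the per-reaction table of a [ConsistencyReport].
#' @name fluxAccessors
#' @aliases fluxes ranges records
NULL

#' @rdname fluxAccessors
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)

#' @rdname fluxAccessors
#' @export
setGeneric("ranges", function(object) standardGeneric("ranges"))
#' @rdname fluxAccessors
setMethod("ranges", "FluxRange", function(object) object@ranges)

#' @rdname fluxAccessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname fluxAccessors
setMethod("records", "ConsistencyReport", function(object) object@records)
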