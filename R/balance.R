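## Elemental mass and charge balance checking, and automatic correction by
## addition of protons and water.

#' Parse a chemical formula in Hill notation
#'
#' @param formula e.g. \code{"C6H12O6"}; \code{""}/\code{NA} parse to an
#'   empty element map.
#' @return named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  m <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(m) || sum(nchar(m)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", m)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", m))
  ct[is.na(ct)] <- 1
  agg <- tapply(ct, el, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Check the mass and charge balance of reactions
#'
#' For each requested reaction, computes the stoichiometry-weighted
#' per-element difference (products minus reactants) and the charge
#' difference. Exchange reactions are skipped by convention (status
#' \code{"exchange"}); reactions involving any metabolite without a formula
#' or charge are reported \code{"unscorable"} rather than failed, since
#' genome-scale models routinely carry generic biomass species.
#'
#' @param model a [MetabolicModel].
#' @param reactions reaction ids (default: all).
#' @return data.frame with columns reaction, status (\code{"balanced"},
#'   \code{"imbalanced"}, \code{"unscorable"}, \code{"exchange"}),
#'   charge_delta and element_deltas (list column of named numeric, the
#'   nonzero per-element deltas).
#' @export
checkMassBalance <- function(model, reactions = reactionIds(model)) {
  exch <- exchangeReactions(model)
  S <- model@stoich
  mets <- model@mets
  res <- lapply(reactions, function(j) {
    if (!j %in% colnames(S)) stop("unknown reaction id: ", j)
    if (j %in% exch)
      return(list(reaction = j, status = "exchange",
                  charge_delta = NA_real_, element_deltas = numeric(0)))
    st <- S[, j]; st <- st[st != 0]
    rows <- match(names(st), mets$id)
    if (any(!nzchar(mets$formula[rows]) | is.na(mets$charge[rows])))
      return(list(reaction = j, status = "unscorable",
                  charge_delta = NA_real_, element_deltas = numeric(0)))
    deltas <- numeric(0)
    for (i in seq_along(st)) {
      f <- parseFormula(mets$formula[rows[i]])
      for (e in names(f)) {
        deltas[e] <- (if (e %in% names(deltas)) deltas[e] else 0) +
          st[i] * f[[e]]
      }
    }
    deltas <- deltas[abs(deltas) > 1e-9]
    chg <- sum(st * mets$charge[rows])
    status <- if (length(deltas) == 0 && abs(chg) < 1e-9) "balanced" else "imbalanced"
    list(reaction = j, status = status, charge_delta = chg,
         element_deltas = deltas)
  })
  data.frame(
    reaction = vapply(res, `[[`, character(1), "reaction"),
    status = vapply(res, `[[`, character(1), "status"),
    charge_delta = vapply(res, `[[`, numeric(1), "charge_delta"),
    element_deltas = I(lapply(res, `[[`, "element_deltas")),
    stringsAsFactors = FALSE)
}

#' Balance a reaction by adding protons and water
#'
#' When a reaction's imbalance is confined to hydrogen, oxygen and charge,
#' unique coefficients of H+ (formula H, charge +1) and H2O exist that zero
#' all three deltas: the proton count cancels the charge delta, the water
#' count cancels the oxygen delta, and the hydrogen budget must then close
#' exactly. Positive solved coefficients are placed on the product side,
#' negative on the reactant side. Already balanced reactions are returned
#' unchanged.
#'
#' @param model a [MetabolicModel].
#' @param reaction reaction id to correct.
#' @return the model with corrected stoichiometry for that reaction.
#' @export
balanceWithWaterProtons <- function(model, reaction) {
  chk <- checkMassBalance(model, reaction)
  if (chk$status == "balanced") return(model)
  if (chk$status %in% c("exchange", "unscorable"))
    stop("reaction '", reaction, "' is ", chk$status,
         " and cannot be auto-balanced")
  deltas <- chk$element_deltas[[1]]
  other <- setdiff(names(deltas), c("H", "O"))
  if (length(other))
    stop(sprintf(
      "uncorrectable imbalance in reaction '%s': residual deltas in %s (%s)",
      reaction, paste(other, collapse = ", "),
      paste(sprintf("%s=%g", names(deltas), deltas), collapse = ", ")))
  dH <- if ("H" %in% names(deltas)) deltas[["H"]] else 0
  dO <- if ("O" %in% names(deltas)) deltas[["O"]] else 0
  dQ <- chk$charge_delta
  x <- -dQ          # protons to add on the product side
  y <- -dO          # waters to add on the product side
  if (abs(dH + x + 2 * y) > 1e-9)
    stop(sprintf(
      "uncorrectable imbalance in reaction '%s': no proton/water solution (residual H delta %g)",
      reaction, dH + x + 2 * y))
  mets <- model@mets
  findSpecies <- function(formula, charge) {
    hit <- which(mets$formula == formula & mets$charge == charge &
                   mets$compartment == "c")
    if (!length(hit))
      hit <- which(mets$formula == formula & mets$charge == charge)
    if (!length(hit))
      stop("model lacks a species with formula ", formula,
           " needed for balancing")
    mets$id[hit[1]]
  }
  if (abs(x) > 1e-9) {
    h <- findSpecies("H", 1L)
    model@stoich[h, reaction] <- model@stoich[h, reaction] + x
  }
  if (abs(y) > 1e-9) {
    w <- findSpecies("H2O", 0L)
    model@stoich[w, reaction] <- model@stoich[w, reaction] + y
  }
  validObject(model)
  model
}
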