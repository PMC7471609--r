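## Mutant growth, medium-supplement rescue and single-reaction-deletion
## lethality screening.

maxGrowth <- function(model, condition, applyMeasured = FALSE) {
  m <- applyCondition(model, condition)
  if (applyMeasured && nrow(condition@measured))
    m <- applyBounds(m, buildMeasuredBounds(m, condition))
  biomassRxn <- m@biomassVariants[[condition@biomassVariant]]
  sol <- tryCatch(fba(m, biomassRxn, condition = condition@name),
                  error = function(e) e)
  if (inherits(sol, "error")) return(NA_real_)
  sol@objective
}

#' Mutant growth as percent of wild type
#'
#' Maximum growth of the wild type and of a gene-deletion mutant under an
#' identical condition; a mutant below the lethality threshold (default
#' 20% of the wild-type rate) is called lethal.
#'
#' @param model a [MetabolicModel].
#' @param condition a [GrowthCondition] (medium caps; uptake left free
#'   within them).
#' @param deletedGenes gene ids deleted in the mutant.
#' @param threshold lethality threshold as a fraction of wild-type growth.
#' @param label mutant label for the report.
#' @return one-row data.frame: label, wt_growth, mut_growth, percent,
#'   lethal.
#' @export
mutantGrowthPercent <- function(model, condition, deletedGenes,
                                threshold = 0.20,
                                label = paste(deletedGenes, collapse = "-")) {
  wt <- maxGrowth(model, condition)
  if (is.na(wt) || wt <= feasTol)
    stop("wild-type growth is zero or infeasible under condition '",
         condition@name, "': percent of WT undefined")
  mutModel <- deleteGenes(model, deletedGenes)
  mg <- maxGrowth(mutModel, condition)
  if (is.na(mg)) mg <- 0
  pct <- 100 * mg / wt
  data.frame(label = if (nzchar(label)) label else "wild-type",
             wt_growth = wt, mut_growth = mg, percent = pct,
             lethal = pct < 100 * threshold, stringsAsFactors = FALSE)
}

#' Medium-supplement rescue screen
#'
#' For each supplement, opens its exchange uptake to the configured
#' magnitude on top of the mutant's condition and recomputes growth as a
#' percent of the *unsupplemented* wild type — so a supplement can push a
#' mutant above 100%.
#'
#' @param model a [MetabolicModel].
#' @param condition base [GrowthCondition].
#' @param deletedGenes gene ids deleted in the mutant.
#' @param supplements named numeric vector, exchange id -> maximum uptake
#'   magnitude (default 1000, effectively unconstrained), or a character
#'   vector of exchange ids.
#' @param threshold lethality threshold (fraction of WT).
#' @return data.frame with one row per supplement: supplement, wt_growth,
#'   mut_growth, percent, rescued.
#' @export
rescueScreen <- function(model, condition, deletedGenes, supplements,
                         threshold = 0.20) {
  if (is.character(supplements))
    supplements <- stats::setNames(rep(1000, length(supplements)),
                                   supplements)
  exch <- exchangeReactions(model)
  unknown <- setdiff(names(supplements), exch)
  if (length(unknown))
    stop("supplement exchange(s) absent from model: ",
         paste(unknown, collapse = ", "))
  wt <- maxGrowth(model, condition)
  if (is.na(wt) || wt <= feasTol)
    stop("wild-type growth is zero or infeasible: percent of WT undefined")
  mutModel <- deleteGenes(model, deletedGenes)
  rows <- lapply(names(supplements), function(s) {
    cond <- condition
    cond@uptake[s] <- supplements[[s]]
    mg <- maxGrowth(mutModel, cond)
    if (is.na(mg)) mg <- 0
    pct <- 100 * mg / wt
    data.frame(supplement = s, wt_growth = wt, mut_growth = mg,
               percent = pct, rescued = pct >= 100 * threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-reaction-deletion lethality scan
#'
#' On top of a base gene-deletion mutant, closes every not-yet-disabled
#' reaction one at a time and records the maximum growth rate. Reactions
#' pushing growth below the threshold fraction of the *wild-type* rate are
#' returned as lethal candidates, sorted by residual growth. Per-reaction
#' infeasibility is recorded as zero growth, never as a fatal error.
#'
#' @param model a [MetabolicModel].
#' @param condition a [GrowthCondition].
#' @param baseDeletedGenes gene ids of the base mutant.
#' @param threshold lethality threshold as a fraction of wild-type growth.
#' @return data.frame of candidates: reaction, growth, percent_wt.
#' @export
reactionDeletionScan <- function(model, condition,
                                 baseDeletedGenes = character(0),
                                 threshold = 0.20) {
  wt <- maxGrowth(model, condition)
  if (is.na(wt) || wt <= feasTol)
    stop("wild-type growth is zero or infeasible under condition '",
         condition@name, "'")
  base <- deleteGenes(model, baseDeletedGenes)
  base <- applyCondition(base, condition)
  biomassRxn <- base@biomassVariants[[condition@biomassVariant]]
  already <- reactionIds(base)[base@lb == 0 & base@ub == 0]
  targets <- setdiff(reactionIds(base), c(already, biomassRxn))
  growth <- vapply(targets, function(j) {
    m <- base
    m@lb[j] <- 0; m@ub[j] <- 0
    sol <- tryCatch(fba(m, biomassRxn), error = function(e) NULL)
    if (is.null(sol)) 0 else sol@objective
  }, numeric(1))
  cand <- data.frame(reaction = targets, growth = unname(growth),
                     percent_wt = 100 * unname(growth) / wt,
                     stringsAsFactors = FALSE)
  cand <- cand[cand$growth < threshold * wt, , drop = FALSE]
  cand[order(cand$growth, cand$reaction), , drop = FALSE]
}
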