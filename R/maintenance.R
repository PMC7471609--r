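## Training of growth- and non-growth-associated ATP maintenance.
##
## Each measured condition contributes one point: the experimentally
## measured growth rate on the x axis and the model's maximum
## ATP-hydrolysis flux (with measured exchange fluxes as bounds, GAM
## zeroed inside the biomass reaction and the NGAM bound released) on the
## y axis. Ordinary least squares across conditions then yields GAM as the
## slope and NGAM as the intercept.

#' Condition class used for maintenance-parameter bookkeeping
#'
#' @param condition a [GrowthCondition].
#' @return \code{"batch"}, \code{"chemostat-cellobiose"} or
#'   \code{"chemostat-cellulose"}.
#' @export
conditionClass <- function(condition) {
  if (condition@reactorMode == "batch") "batch"
  else paste0("chemostat-", condition@carbonSource)
}

#' Maximum ATP-hydrolysis flux under measured bounds
#'
#' Applies the condition and its measured flux bounds (including the
#' measured growth rate), zeroes the growth-associated ATP stoichiometry
#' inside the biomass reaction and the NGAM lower bound so that all spare
#' ATP can route to the hydrolysis pseudo-reaction, and maximises the
#' hydrolysis flux. The resulting (growth, ATP) pair is one training point
#' for [fitMaintenance()].
#'
#' @param model a [MetabolicModel] with an ATP-hydrolysis reaction.
#' @param condition a [GrowthCondition] whose measured table contains the
#'   exchange fluxes and the growth rate (a row for the biomass reaction).
#' @param zeroGAM zero the biomass ATP coefficient during training
#'   (default); set \code{FALSE} to leave the shipped coefficient in
#'   place.
#' @return one-row data.frame with columns label, growth, atp, outlier.
#' @export
maxATPYield <- function(model, condition, zeroGAM = TRUE) {
  if (is.na(model@atpmReaction))
    stop("model has no ATP-hydrolysis reaction")
  cond <- condition
  if (zeroGAM) cond@gam <- 0
  cond@ngam <- 0
  m <- applyCondition(model, cond)
  bounds <- buildMeasuredBounds(m, cond)
  m <- applyBounds(m, bounds)
  biomassRxn <- m@biomassVariants[[cond@biomassVariant]]
  growth <- if (biomassRxn %in% cond@measured$reaction)
    cond@measured$mean[cond@measured$reaction == biomassRxn][1]
  else NA_real_
  sol <- tryCatch(fba(m, m@atpmReaction, condition = condition@name),
                  error = function(e) e)
  if (inherits(sol, "error"))
    stop("measured bounds infeasible for condition '", condition@name,
         "': ", conditionMessage(sol))
  data.frame(label = condition@name, growth = growth,
             atp = sol@objective, outlier = FALSE,
             stringsAsFactors = FALSE)
}

#' Fit GAM and NGAM by linear regression
#'
#' Ordinary least squares of maximum ATP-hydrolysis flux on measured
#' growth rate over the non-outlier points: the slope is the
#' growth-associated maintenance (mmol ATP/gCDW) and the intercept the
#' non-growth-associated maintenance (mmol ATP/gCDW/h). Outliers are
#' caller-designated (no automatic criterion) and excluded from the fit.
#' The regression is unweighted; measurement uncertainty enters the
#' pipeline only through the flux bounds that produced the points.
#'
#' @param points data.frame with columns label, growth, atp and optionally
#'   outlier (logical).
#' @param outliers additional point labels to exclude.
#' @return a [MaintenanceFit]. A negative fitted NGAM is physically
#'   suspect and raises a warning, but the value is still returned.
#' @export
fitMaintenance <- function(points, outliers = character(0)) {
  pts <- as.data.frame(points, stringsAsFactors = FALSE)
  if (is.null(pts$outlier)) pts$outlier <- FALSE
  pts$outlier <- pts$outlier | pts$label %in% outliers
  use <- pts[!pts$outlier, ]
  if (nrow(use) < 2)
    stop("need at least 2 non-outlier points to fit GAM/NGAM (have ",
         nrow(use), ")")
  fit <- stats::lm(atp ~ growth, data = use)
  co <- stats::coef(fit)
  gam <- unname(co[["growth"]])
  ngam <- unname(co[["(Intercept)"]])
  r2 <- if (stats::sd(use$atp) > 0)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  if (ngam < 0)
    warning("fitted NGAM is negative (", signif(ngam, 4),
            " mmol ATP/gCDW/h): physically suspect")
  new("MaintenanceFit", gam = gam, ngam = ngam, r2 = r2,
      n = nrow(use), excluded = pts$label[pts$outlier], points = pts)
}

#' Validate growth predictions under fitted maintenance parameters
#'
#' For each condition, installs the GAM/NGAM of its condition class,
#' bounds the measured exchange fluxes (growth left free), and maximises
#' growth. Returns the paired measured/predicted table with the squared
#' Pearson correlation; a condition whose measured bounds are infeasible
#' is recorded as a failed row rather than aborting the run.
#'
#' @param model a [MetabolicModel].
#' @param conditions list of [GrowthCondition]s; each measured table must
#'   include the growth rate (a row for the biomass reaction).
#' @param parameters named list (by condition class) of
#'   \code{list(gam=, ngam=)} or [MaintenanceFit] objects.
#' @return list with \code{table} (condition, class, measured, predicted,
#'   status) and \code{r2} (NA with fewer than two successful rows).
#' @export
validateGrowth <- function(model, conditions, parameters) {
  rows <- lapply(conditions, function(cond) {
    cls <- conditionClass(cond)
    par <- parameters[[cls]]
    if (is.null(par))
      stop("no fitted parameters for condition class '", cls, "'")
    if (is(par, "MaintenanceFit")) par <- list(gam = par@gam, ngam = par@ngam)
    cond@gam <- max(0, par$gam)
    cond@ngam <- max(0, par$ngam)
    m <- applyCondition(model, cond)
    biomassRxn <- m@biomassVariants[[cond@biomassVariant]]
    meas <- cond@measured
    growthMeasured <- if (biomassRxn %in% meas$reaction)
      meas$mean[meas$reaction == biomassRxn][1] else NA_real_
    cond@measured <- meas[meas$reaction != biomassRxn, , drop = FALSE]
    out <- tryCatch({
      if (nrow(cond@measured))
        m <- applyBounds(m, buildMeasuredBounds(m, cond))
      sol <- fba(m, biomassRxn, condition = cond@name)
      list(pred = sol@objective, status = "ok")
    }, error = function(e) list(pred = NA_real_, status = "infeasible"))
    data.frame(condition = cond@name, class = cls,
               measured = growthMeasured, predicted = out$pred,
               status = out$status, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$status == "ok" & !is.na(tab$measured)
  r2 <- if (sum(ok) >= 2 && stats::sd(tab$measured[ok]) > 0 &&
            stats::sd(tab$predicted[ok]) > 0)
    stats::cor(tab$measured[ok], tab$predicted[ok])^2 else NA_real_
  list(table = tab, r2 = r2)
}
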