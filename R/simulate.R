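## Flux simulation over the feasible space
##   Omega = { v : S v = 0, lb <= v <= ub }.

feasTol <- 1e-6

clampBounds <- function(model) {
  model@lb[!is.finite(model@lb)] <- -1000
  model@ub[!is.finite(model@ub)] <- 1000
  model
}

#' Flux balance analysis
#'
#' Maximises a linear objective over the feasible flux space. Only the
#' objective *value* is contractual: at degenerate optima the flux vector
#' is solver-dependent, and downstream analyses that need a unique vector
#' should use [pfba()].
#'
#' @param model a [MetabolicModel] (bounds already configured).
#' @param objective either a single reaction id or a named numeric vector
#'   of objective coefficients.
#' @param maximize maximise (default) or minimise.
#' @param condition label recorded on the result.
#' @return a [FluxDistribution].
#' @export
fba <- function(model, objective, maximize = TRUE, condition = "") {
  model <- clampBounds(model)
  rid <- reactionIds(model)
  cvec <- stats::setNames(numeric(length(rid)), rid)
  if (is.character(objective)) {
    if (!all(objective %in% rid))
      stop("objective reaction(s) not in model: ",
           paste(setdiff(objective, rid), collapse = ", "))
    cvec[objective] <- 1
  } else {
    if (is.null(names(objective)) || !all(names(objective) %in% rid))
      stop("objective must be a reaction id or a named coefficient vector")
    cvec[names(objective)] <- objective
  }
  if (all(cvec == 0)) stop("objective has no nonzero coefficient")
  r <- lpSolve2(unname(cvec), model@stoich, rep(0, nrow(model@stoich)),
                unname(model@lb), unname(model@ub), maximize = maximize)
  if (r$status == "infeasible") {
    tight <- rid[model@ub - model@lb < feasTol]
    stop("FBA infeasible",
         if (length(tight)) paste0(" (tightly bounded reactions: ",
                                   paste(utils::head(tight, 8), collapse = ", "), ")")
         else "")
  }
  if (r$status == "unbounded")
    stop("FBA unbounded; unbounded direction involves reaction ",
         if (!is.na(r$unbounded_var)) rid[r$unbounded_var] else "<unknown>")
  new("FluxDistribution", condition = condition,
      fluxes = stats::setNames(r$x, rid),
      objective = r$objective, status = "optimal")
}

#' Parsimonious FBA by quadratic norm minimisation
#'
#' Returns the unique minimiser of the squared flux norm
#' \eqn{\sum_j v_j^2} over the feasible space. The quadratic program is the
#' entire formulation — no growth-maximisation pre-step is performed;
#' measured bounds are expected to pin the exchange fluxes beforehand. The
#' strictly convex objective makes the solution unique, and the active-set
#' solver is deterministic, so repeated solves agree to numerical
#' precision.
#'
#' @param model a [MetabolicModel] with bounds configured.
#' @param condition label recorded on the result.
#' @return a [FluxDistribution]; \code{objective} is the minimised squared
#'   norm.
#' @export
pfba <- function(model, condition = "") {
  model <- clampBounds(model)
  S <- model@stoich
  rid <- colnames(S)
  sol <- qpMinNorm(S, unname(model@lb), unname(model@ub))
  if (sol$status != "optimal")
    stop("pFBA infeasible: no flux distribution satisfies the bounds")
  v <- stats::setNames(sol$x, rid)
  v[abs(v) < 1e-10] <- 0
  new("FluxDistribution", condition = condition, fluxes = v,
      objective = sum(v^2), status = "optimal")
}

#' Flux variability analysis
#'
#' Minimises and maximises each requested flux over the feasible space.
#' With \code{loopless = TRUE}, thermodynamically infeasible internal
#' cycles are excluded through mixed-integer constraints: each internal
#' reaction gets a binary flux-direction variable and a sign-constrained
#' potential variable, and the potentials must be orthogonal to the null
#' space of the internal stoichiometric matrix (big-M = 1000). Exchange
#' reactions, biomass variants and the ATP-hydrolysis pseudo-reaction keep
#' unconstrained directionality.
#'
#' @param model a [MetabolicModel] with bounds configured.
#' @param reactions reaction ids to analyse (default: all).
#' @param loopless exclude internal cycles via the mixed-integer
#'   formulation.
#' @return a [FluxRange].
#' @export
fva <- function(model, reactions = reactionIds(model), loopless = FALSE) {
  model <- clampBounds(model)
  unknown <- setdiff(reactions, reactionIds(model))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  if (loopless) return(fvaLoopless(model, reactions))
  S <- model@stoich
  rid <- colnames(S)
  res <- lapply(reactions, function(j) {
    cvec <- numeric(length(rid)); cvec[match(j, rid)] <- 1
    lo <- lpSolve2(cvec, S, rep(0, nrow(S)), unname(model@lb),
                   unname(model@ub), maximize = FALSE)
    hi <- lpSolve2(cvec, S, rep(0, nrow(S)), unname(model@lb),
                   unname(model@ub), maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop("FVA infeasible")
    c(lo$objective, hi$objective)
  })
  new("FluxRange",
      ranges = data.frame(reaction = reactions,
                          min = vapply(res, `[`, numeric(1), 1),
                          max = vapply(res, `[`, numeric(1), 2),
                          status = "ok", stringsAsFactors = FALSE),
      loopless = FALSE)
}

#' Detect blocked reactions
#'
#' With every exchange reaction opened to (-1000, 1000) — the most general
#' boundary scenario, giving the smallest possible blocked set — a reaction
#' is blocked when its FVA minimum and maximum are both zero within the
#' feasibility tolerance.
#'
#' @param model a [MetabolicModel].
#' @param tol absolute flux tolerance.
#' @param mag exchange bound magnitude (the blocked set is invariant to
#'   it; exposed for that very check).
#' @return list with \code{blocked} (character vector of reaction ids) and
#'   \code{percent} (share of all reactions, in percent).
#' @export
findBlockedReactions <- function(model, tol = feasTol, mag = 1000) {
  exch <- exchangeReactions(model)
  model@lb[exch] <- -mag
  model@ub[exch] <- mag
  fr <- fva(model, loopless = FALSE)
  r <- fr@ranges
  blocked <- r$reaction[abs(r$min) < tol & abs(r$max) < tol]
  list(blocked = blocked,
       percent = 100 * length(blocked) / length(r$reaction))
}
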