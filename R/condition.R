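## Condition / medium configuration and application to a model.

#' Construct a growth condition
#'
#' @param name condition label.
#' @param reactorMode \code{"batch"} or \code{"chemostat"}.
#' @param carbonSource \code{"cellobiose"} or \code{"cellulose"}.
#' @param biomassVariant biomass variant label (must exist in the model the
#'   condition is applied to).
#' @param gam growth-associated maintenance (mmol ATP/gCDW); \code{NA}
#'   leaves the model's shipped biomass ATP coefficient untouched.
#' @param ngam non-growth-associated maintenance (mmol ATP/gCDW/h).
#' @param measured data.frame with columns reaction, mean, sd.
#' @param uptake named numeric: exchange id -> maximum uptake magnitude.
#' @param secretion character vector of exchange ids allowed to secrete.
#' @return a [GrowthCondition].
#' @export
growthCondition <- function(name, reactorMode = "batch",
                            carbonSource = "cellobiose",
                            biomassVariant = "cellobiose",
                            gam = NA_real_, ngam = 0,
                            measured = data.frame(reaction = character(0),
                                                  mean = numeric(0),
                                                  sd = numeric(0)),
                            uptake = numeric(0),
                            secretion = character(0)) {
  new("GrowthCondition", name = name, reactorMode = reactorMode,
      carbonSource = carbonSource, biomassVariant = biomassVariant,
      gam = if (is.na(gam)) NA_real_ else as.numeric(gam),
      ngam = as.numeric(ngam),
      measured = as.data.frame(measured, stringsAsFactors = FALSE),
      uptake = uptake, secretion = secretion)
}

#' Read a condition file (YAML or JSON)
#'
#' Expected keys: \code{reactor_mode}, \code{carbon_source},
#' \code{biomass_variant}, \code{gam}, \code{ngam}, \code{medium} (with
#' \code{uptake}: map of exchange id to maximum uptake magnitude, and
#' \code{secretion}: list of exchange ids) and \code{measured}: either an
#' inline map \code{reaction: [mean, sd]} or the path (relative to the
#' condition file) of a TSV with columns reaction_id, mean, sd.
#'
#' @param path condition file (\code{.yaml}/\code{.yml}/\code{.json}).
#' @param name condition label; defaults to the file base name.
#' @return a [GrowthCondition].
#' @export
readCondition <- function(path, name = sub("\\.[^.]+$", "", basename(path))) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  measured <- data.frame(reaction = character(0), mean = numeric(0),
                         sd = numeric(0))
  if (!is.null(cfg$measured)) {
    if (is.character(cfg$measured)) {
      tab <- utils::read.delim(file.path(dirname(path), cfg$measured),
                               stringsAsFactors = FALSE)
      names(tab)[names(tab) == "reaction_id"] <- "reaction"
      measured <- tab[, c("reaction", "mean", "sd")]
    } else {
      measured <- data.frame(
        reaction = names(cfg$measured),
        mean = vapply(cfg$measured, function(x) as.numeric(x[[1]]), numeric(1)),
        sd = vapply(cfg$measured, function(x) as.numeric(x[[2]]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  upt <- numeric(0)
  if (!is.null(cfg$medium$uptake))
    upt <- vapply(cfg$medium$uptake, as.numeric, numeric(1))
  growthCondition(
    name = name,
    reactorMode = cfg$reactor_mode %||% "batch",
    carbonSource = cfg$carbon_source %||% "cellobiose",
    biomassVariant = cfg$biomass_variant %||% "cellobiose",
    gam = if (is.null(cfg$gam)) NA_real_ else as.numeric(cfg$gam),
    ngam = cfg$ngam %||% 0,
    measured = measured,
    uptake = upt,
    secretion = as.character(unlist(cfg$medium$secretion)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a condition to YAML
#'
#' @param condition a [GrowthCondition].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCondition <- function(condition, path) {
  m <- condition@measured
  cfg <- list(
    reactor_mode = condition@reactorMode,
    carbon_source = condition@carbonSource,
    biomass_variant = condition@biomassVariant,
    gam = if (is.na(condition@gam)) NULL else condition@gam,
    ngam = condition@ngam,
    medium = list(
      uptake = as.list(condition@uptake),
      secretion = as.list(condition@secretion)),
    measured = stats::setNames(
      lapply(seq_len(nrow(m)), function(i) c(m$mean[i], m$sd[i])),
      m$reaction))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Configure a model for a growth condition
#'
#' Applies a [GrowthCondition] to a model: activates the condition's
#' biomass variant (all other variants bounded to zero), sets the
#' ATP-hydrolysis lower bound to NGAM, installs GAM as the ATP-hydrolysis
#' stoichiometry inside the active biomass reaction (replacing the shipped
#' coefficient), closes all exchange uptakes except the medium-allowed set,
#' closes secretion except the allowed set, and for growth on cellulose
#' opens the glucose-equivalent cellodextrin pseudo-reactions.
#'
#' Measured flux bounds are *not* applied here; see
#' [buildMeasuredBounds()].
#'
#' @param model a [MetabolicModel].
#' @param condition a [GrowthCondition].
#' @return the configured model.
#' @export
applyCondition <- function(model, condition) {
  validObject(condition)
  bv <- model@biomassVariants
  if (!condition@biomassVariant %in% names(bv))
    stop("biomass variant '", condition@biomassVariant,
         "' absent from model (has: ",
         paste(names(bv), collapse = ", "), ")")
  active <- bv[[condition@biomassVariant]]
  for (r in bv) {
    if (r == active) {
      model@lb[r] <- 0; model@ub[r] <- 1000
    } else {
      model@lb[r] <- 0; model@ub[r] <- 0
    }
  }
  ## NGAM
  if (!is.na(model@atpmReaction)) {
    model@lb[model@atpmReaction] <- condition@ngam
    model@ub[model@atpmReaction] <- 1000
  } else if (condition@ngam > 0) {
    stop("condition specifies NGAM but model has no ATP-hydrolysis reaction")
  }
  ## GAM: biomass ATP-hydrolysis stoichiometry scaled to the fitted value
  if (!is.na(condition@gam)) {
    if (is.na(model@atpmReaction))
      stop("cannot install GAM: model has no ATP-hydrolysis reaction")
    model <- installGAM(model, active, condition@gam)
  }
  ## medium
  exch <- exchangeReactions(model)
  unknown <- setdiff(c(names(condition@uptake), condition@secretion), exch)
  if (length(unknown))
    stop("medium references unknown exchange(s): ",
         paste(unknown, collapse = ", "))
  model@lb[exch] <- 0
  model@ub[exch] <- 0
  if (length(condition@uptake))
    model@lb[names(condition@uptake)] <- -abs(condition@uptake)
  if (length(condition@secretion))
    model@ub[condition@secretion] <- 1000
  ## cellulose: open cellodextrin glucose-equivalent pseudo-reactions
  if (condition@carbonSource == "cellulose") {
    cdx <- cellodextrinReactions(model)
    if (length(cdx)) {
      model@lb[cdx] <- 0
      model@ub[cdx] <- 1000
    }
  }
  validObject(model)
  model
}

## pseudo-reactions n glceq_e -> celln_e, detected structurally
cellodextrinReactions <- function(model) {
  S <- model@stoich
  if (!"glceq_e" %in% rownames(S)) return(character(0))
  hits <- vapply(colnames(S), function(j) {
    st <- S[, j]; st <- st[st != 0]
    length(st) == 2 && "glceq_e" %in% names(st) &&
      st[["glceq_e"]] < 0 &&
      any(grepl("^cell[0-9]+_e$", names(st)))
  }, logical(1))
  colnames(S)[hits]
}

## Replace the growth-associated maintenance contribution of a biomass
## reaction: the ATP-hydrolysis stoichiometry (taken from the model's NGAM
## pseudo-reaction) is rescaled so the biomass column consumes exactly
## `gam` mmol ATP per gCDW formed.
installGAM <- function(model, biomassReaction, gam) {
  atpm <- model@atpmReaction
  hyd <- model@stoich[, atpm]
  atpRow <- names(hyd)[hyd < 0][which.min(hyd[hyd < 0])]  # the ATP species
  current <- -model@stoich[atpRow, biomassReaction] /
    (-hyd[[atpRow]])                                      # shipped GAM
  delta <- gam - current
  model@stoich[, biomassReaction] <- model@stoich[, biomassReaction] +
    delta * hyd
  model
}

#' Bound overrides from measured fluxes
#'
#' For each measured reaction, the flux interval is the measured mean plus
#' or minus one standard deviation — for triplicate normally distributed
#' measurements this gives a confidence level above 90%. Returns the
#' overrides without touching the model.
#'
#' @param model a [MetabolicModel] (for id validation).
#' @param condition a [GrowthCondition] with a nonempty measured table.
#' @return data.frame with columns reaction, lb, ub.
#' @export
buildMeasuredBounds <- function(model, condition) {
  m <- condition@measured
  if (!nrow(m)) stop("condition '", condition@name, "' has no measured table")
  unknown <- setdiff(m$reaction, reactionIds(model))
  if (length(unknown))
    stop("measured reaction(s) absent from model: ",
         paste(unknown, collapse = ", "))
  data.frame(reaction = m$reaction, lb = m$mean - m$sd, ub = m$mean + m$sd,
             stringsAsFactors = FALSE)
}

#' Apply measured-bound overrides to a model
#'
#' @param model a [MetabolicModel].
#' @param bounds data.frame from [buildMeasuredBounds()].
#' @return the model with overridden bounds.
#' @export
applyBounds <- function(model, bounds) {
  setBounds(model, bounds$reaction, bounds$lb, bounds$ub)
}
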