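## Fold-change-based multi-omics integration protocol.
##
## Simulated fluxes (unique pFBA vectors and FVA interval centers) are
## normalised to the carbon-source uptake rate, floored away from zero,
## log2-transformed and differenced between case and control; measured
## gene-level log2 fold changes are mapped to reactions through the GPR
## as the plain mean over genes with nonzero measured FC; a reaction is
## "consistent" when its measured fold change shares a strict sign with at
## least one simulated fold change.

#' Protocol configuration
#'
#' @param epsilon flooring threshold for normalised fluxes (default 1e-4).
#' @param uptakeWt,uptakeMut id of the designated carbon-source exchange
#'   used for flux normalisation in each condition.
#' @param loopless use loopless FVA for the interval-based fold changes.
#' @return a list of class \code{fcProtocolConfig}.
#' @export
fcProtocolConfig <- function(epsilon = 1e-4, uptakeWt, uptakeMut = uptakeWt,
                             loopless = TRUE) {
  stopifnot(epsilon > 0)
  structure(list(epsilon = epsilon, uptakeWt = uptakeWt,
                 uptakeMut = uptakeMut, loopless = loopless),
            class = "fcProtocolConfig")
}

#' Floor a value away from zero
#'
#' Values in the open interval (0, epsilon) are pushed up by epsilon and
#' values in (-epsilon, 0) pushed down, so that subsequent log transforms
#' cannot blow up on vanishing fluxes; everything else passes through
#' unchanged, except exact zero which maps to +epsilon (the continuous
#' extension of the positive branch, making "zero in both conditions"
#' yield a fold change of zero).
#'
#' @param x numeric vector.
#' @param epsilon flooring threshold (> 0).
#' @return floored values.
#' @export
floorValue <- function(x, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  out <- x
  out[x == 0] <- epsilon
  sel <- x > 0 & x < epsilon
  out[sel] <- x[sel] + epsilon
  sel <- x < 0 & x > -epsilon
  out[sel] <- x[sel] - epsilon
  out
}

#' Simulated log2 fold change between two conditions
#'
#' Each flux is normalised to the magnitude of its condition's substrate
#' uptake rate, floored ([floorValue()]), and the fold change taken in
#' log2 space. Negative normalised fluxes are handled on the magnitude
#' scale: the value reported is \code{log2(|a|) - log2(|b|)}, and a sign
#' flip between conditions is flagged \code{"sign_reversal"} (such records
#' are excluded from consistency calls and correlations). Exact zeros that
#' were floored to +epsilon are flagged \code{"floored_zero"}.
#'
#' @param vMut,vWt fluxes (vectors) in the case and control conditions.
#' @param uptakeMut,uptakeWt substrate uptake fluxes (nonzero scalars).
#' @param epsilon flooring threshold.
#' @return data.frame with columns fc and flag.
#' @export
simulatedFoldChange <- function(vMut, vWt, uptakeMut, uptakeWt,
                                epsilon = 1e-4) {
  if (abs(uptakeMut) < .Machine$double.eps || abs(uptakeWt) < .Machine$double.eps)
    stop("zero substrate uptake: cannot normalise fluxes")
  nm <- vMut / abs(uptakeMut)
  nw <- vWt / abs(uptakeWt)
  a <- floorValue(nm, epsilon)
  b <- floorValue(nw, epsilon)
  fc <- log2(abs(a)) - log2(abs(b))
  flag <- character(length(fc))
  flag[nm == 0 | nw == 0] <- "floored_zero"
  rev <- sign(a) != sign(b)
  flag[rev] <- trimws(paste(flag[rev], "sign_reversal"))
  data.frame(fc = fc, flag = flag, stringsAsFactors = FALSE)
}

#' Center of a flux variability interval
#'
#' The midpoint \code{(min + max)/2}, a scalar summary used to compare
#' whether a reaction's feasible range shifts up or down between
#' conditions; it does not itself belong to a feasible flux distribution.
#'
#' @param vMin,vMax interval endpoints (vectors), \code{vMin <= vMax}.
#' @return midpoints.
#' @export
fvaCenter <- function(vMin, vMax) {
  stopifnot(all(vMin <= vMax + 1e-9))
  (vMin + vMax) / 2
}

#' Map gene-level fold changes onto reactions
#'
#' For each reaction, the contributing gene set is the subset of its GPR
#' genes with a nonzero measured fold change; the reaction's measured fold
#' change is the plain mean over that set regardless of AND/OR structure.
#' Reactions whose contributing set is empty are unmapped. Genes absent
#' from the table (unmeasured) and genes measured at exactly zero both
#' drop out of the mean; the report distinguishes them.
#'
#' @param model a [MetabolicModel].
#' @param geneFC data.frame with columns gene and log2fc, or a named
#'   numeric vector.
#' @return data.frame with columns reaction, fc_meas, mapped, n_genes
#'   (contributing genes), n_zero (genes measured at zero), n_unmeasured.
#' @export
mapGeneFoldChanges <- function(model, geneFC) {
  if (is.data.frame(geneFC)) {
    fcByGene <- stats::setNames(geneFC$log2fc, geneFC$gene)
  } else fcByGene <- geneFC
  if (any(!is.finite(fcByGene)))
    stop("gene fold changes must be finite")
  rows <- lapply(reactionIds(model), function(j) {
    genes <- gprGenes(model@gpr[[j]])
    measured <- genes[genes %in% names(fcByGene)]
    vals <- fcByGene[measured]
    contributing <- vals[vals != 0]
    data.frame(reaction = j,
               fc_meas = if (length(contributing)) mean(contributing) else NA_real_,
               mapped = length(contributing) > 0,
               n_genes = length(contributing),
               n_zero = sum(vals == 0),
               n_unmeasured = length(genes) - length(measured),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Identify consistent reactions
#'
#' A reaction is consistent when its measured fold change is strictly
#' nonzero and shares a sign with at least one of the simulated fold
#' changes (pFBA or FVA). Zero fold changes never qualify; simulated fold
#' changes flagged as sign reversals are not eligible sign witnesses.
#'
#' @param records data.frame with columns fc_meas, fc_pfba, fc_fva and
#'   optionally flag_pfba / flag_fva.
#' @return logical vector: membership in the consistent set.
#' @export
consistentReactions <- function(records) {
  fm <- records$fc_meas
  fp <- records$fc_pfba
  fv <- records$fc_fva
  okp <- if ("flag_pfba" %in% names(records))
    !grepl("sign_reversal", records$flag_pfba) else TRUE
  okv <- if ("flag_fva" %in% names(records))
    !grepl("sign_reversal", records$flag_fva) else TRUE
  pos <- !is.na(fm) & fm > 0 & ((okp & fp > 0) | (okv & fv > 0))
  neg <- !is.na(fm) & fm < 0 & ((okp & fp < 0) | (okv & fv < 0))
  pos | neg
}

#' Run the fold-change integration protocol
#'
#' Pipeline: (1) configure both conditions and apply measured flux bounds,
#' with the mutant's gene deletions applied to its model copy; (2) compute
#' the unique quadratic-pFBA flux vector and the (optionally loopless) FVA
#' ranges in both conditions; (3) convert to simulated fold changes
#' (pFBA fluxes, and FVA interval centers) normalised to the designated
#' substrate uptake; (4) map measured gene fold changes to reactions
#' through the GPRs; (5) call the consistent set; (6) report Pearson
#' correlations between measured and simulated fold changes over the
#' consistent set.
#'
#' @param model a [MetabolicModel].
#' @param conditionWt,conditionMut [GrowthCondition]s with measured tables.
#' @param deletionsMut gene ids deleted in the mutant.
#' @param geneFC measured gene log2 fold changes (data.frame gene/log2fc
#'   or named vector).
#' @param config a [fcProtocolConfig()].
#' @return a [ConsistencyReport].
#' @export
runFoldChangeProtocol <- function(model, conditionWt, conditionMut,
                                  deletionsMut, geneFC, config) {
  stopifnot(inherits(config, "fcProtocolConfig"))
  rid <- reactionIds(model)
  for (u in c(config$uptakeWt, config$uptakeMut))
    if (!u %in% rid) stop("uptake reaction absent from model: ", u)

  wt <- applyCondition(model, conditionWt)
  wt <- applyBounds(wt, buildMeasuredBounds(wt, conditionWt))
  mut <- deleteGenes(model, deletionsMut)
  mut <- applyCondition(mut, conditionMut)
  mut <- applyBounds(mut, buildMeasuredBounds(mut, conditionMut))

  pWt <- pfba(wt, condition = conditionWt@name)
  pMut <- pfba(mut, condition = conditionMut@name)
  rWt <- fva(wt, loopless = config$loopless)
  rMut <- fva(mut, loopless = config$loopless)
  cWt <- stats::setNames(fvaCenter(rWt@ranges$min, rWt@ranges$max),
                         rWt@ranges$reaction)
  cMut <- stats::setNames(fvaCenter(rMut@ranges$min, rMut@ranges$max),
                          rMut@ranges$reaction)

  upWtP <- fluxes(pWt)[[config$uptakeWt]]
  upMutP <- fluxes(pMut)[[config$uptakeMut]]
  upWtC <- cWt[[config$uptakeWt]]
  upMutC <- cMut[[config$uptakeMut]]

  fcP <- simulatedFoldChange(fluxes(pMut)[rid], fluxes(pWt)[rid],
                             upMutP, upWtP, config$epsilon)
  fcV <- simulatedFoldChange(cMut[rid], cWt[rid],
                             upMutC, upWtC, config$epsilon)
  meas <- mapGeneFoldChanges(model, geneFC)

  records <- data.frame(reaction = rid,
                        fc_meas = meas$fc_meas,
                        fc_pfba = fcP$fc,
                        fc_fva = fcV$fc,
                        mapped = meas$mapped,
                        n_genes = meas$n_genes,
                        n_zero = meas$n_zero,
                        n_unmeasured = meas$n_unmeasured,
                        flag_pfba = fcP$flag,
                        flag_fva = fcV$flag,
                        stringsAsFactors = FALSE)
  records$consistent <- consistentReactions(records)

  M <- records[records$consistent, ]
  pear <- function(x, y) {
    if (nrow(M) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_
  }
  new("ConsistencyReport",
      records = records,
      counts = c(total = length(rid), mapped = sum(records$mapped),
                 consistent = sum(records$consistent)),
      correlations = c(pearson_pfba = pear(M$fc_meas, M$fc_pfba),
                       pearson_fva = pear(M$fc_meas, M$fc_fva)))
}

#' Reaction fold-change table for map visualisation
#'
#' Two-column table (reaction id, measured log2 fold change) restricted to
#' the consistent set, in the layout metabolic-map viewers such as Escher
#' load as reaction data.
#'
#' @param report a [ConsistencyReport].
#' @param path optional TSV output path.
#' @return data.frame with columns reaction and fc.
#' @export
escherTable <- function(report, path = NULL) {
  r <- report@records
  out <- data.frame(reaction = r$reaction[r$consistent],
                    fc = r$fc_meas[r$consistent],
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
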