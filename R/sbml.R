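## Minimal SBML Level-3 + FBC v2 I/O.
##
## Follows the conventions of FBC-strict genome-scale models: bounds as
## global parameters referenced from fbc:lowerFluxBound/fbc:upperFluxBound,
## GPRs as fbc:geneProductAssociation trees, species charge and chemical
## formula as fbc attributes. Identifier prefixes R_/M_/G_ are added on
## write and stripped on read (the usual convention, matching cobrapy).
## Biomass-variant and ATP-hydrolysis bookkeeping is stored in a small
## custom annotation; models lacking it fall back to id heuristics.

FLUXKIT_NS <- "https://fluxkit.invalid/sbml-annotations"

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num <- function(x) sprintf("%.17g", x)

stripPrefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

#' Write a model as SBML Level 3 with FBC v2
#'
#' The emitted document re-reads with [readMetabolicModel()] to an
#' equivalent model (stoichiometry, bounds, GPRs, biomass-variant
#' annotations). Output is deterministic: identical models produce
#' byte-identical files.
#'
#' @param model a [MetabolicModel].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMetabolicModel <- function(model, path) {
  validObject(model)
  S <- model@stoich
  rid <- colnames(S)
  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- sprintf(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
             'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
             'level="3" version="1" fbc:required="false">'))
  add('  <model id="%s" fbc:strict="true">', xmlEscape(model@id))
  ## custom annotation: biomass variants + ATPM reaction
  if (length(model@biomassVariants) || !is.na(model@atpmReaction)) {
    add('    <annotation>')
    add('      <fk:info xmlns:fk="%s"%s>', FLUXKIT_NS,
        if (!is.na(model@atpmReaction))
          sprintf(' fk:atpHydrolysis="R_%s"', xmlEscape(model@atpmReaction))
        else "")
    for (lab in names(model@biomassVariants))
      add('        <fk:biomassVariant fk:label="%s" fk:reaction="R_%s"/>',
          xmlEscape(lab), xmlEscape(model@biomassVariants[[lab]]))
    add('      </fk:info>')
    add('    </annotation>')
  }
  add('    <listOfCompartments>')
  for (cid in names(model@compartments))
    add('      <compartment id="%s" name="%s" constant="true"/>',
        xmlEscape(cid), xmlEscape(model@compartments[[cid]]))
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model@mets))) {
    m <- model@mets[i, ]
    extra <- ""
    if (!is.na(m$charge))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    if (nzchar(m$formula) && !is.na(m$formula))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"',
                                     xmlEscape(m$formula)))
    add(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
               'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
               'constant="false"%s/>'),
        xmlEscape(m$id), xmlEscape(m$name), xmlEscape(m$compartment), extra)
  }
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (j in rid) {
    add('      <parameter id="bnd_lb_%s" value="%s" constant="true"/>',
        xmlEscape(j), num(model@lb[[j]]))
    add('      <parameter id="bnd_ub_%s" value="%s" constant="true"/>',
        xmlEscape(j), num(model@ub[[j]]))
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  writeGPRNode <- function(g, indent) {
    pad <- strrep(" ", indent)
    if (is.character(g)) {
      add('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', pad, xmlEscape(g))
    } else {
      tag <- if (g$op == "and") "fbc:and" else "fbc:or"
      add('%s<%s>', pad, tag)
      for (a in g$args) writeGPRNode(a, indent + 2L)
      add('%s</%s>', pad, tag)
    }
  }
  for (j in rid) {
    info <- model@rxns[model@rxns$id == j, ]
    add(paste0('      <reaction id="R_%s" name="%s" reversible="%s" ',
               'fast="false" fbc:lowerFluxBound="bnd_lb_%s" ',
               'fbc:upperFluxBound="bnd_ub_%s">'),
        xmlEscape(j), xmlEscape(info$name),
        if (model@lb[[j]] < 0) "true" else "false",
        xmlEscape(j), xmlEscape(j))
    st <- S[, j]
    reac <- names(st)[st < 0]; prod <- names(st)[st > 0]
    if (length(reac)) {
      add('        <listOfReactants>')
      for (m in reac)
        add('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
            xmlEscape(m), num(-st[[m]]))
      add('        </listOfReactants>')
    }
    if (length(prod)) {
      add('        <listOfProducts>')
      for (m in prod)
        add('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
            xmlEscape(m), num(st[[m]]))
      add('        </listOfProducts>')
    }
    g <- model@gpr[[j]]
    if (!is.null(g)) {
      add('        <fbc:geneProductAssociation>')
      writeGPRNode(g, 10L)
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  if (length(model@genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model@genes)
      add('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
          xmlEscape(g), xmlEscape(g))
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

## attribute lookup tolerant of namespace prefixes
attr2 <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- match(c(name, paste0("fbc:", name), paste0("fk:", name)), names(a))
  hit <- hit[!is.na(hit)]
  if (length(hit)) a[[hit[1]]] else NA_character_
}

readGPRNode <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- attr2(node, "geneProduct")
    return(stripPrefix(g, "G_"))
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, readGPRNode)
  if (length(args) == 1L) return(args[[1L]])
  list(op = if (nm == "and") "and" else "or", args = args)
}

#' Read an SBML Level-3 FBC model
#'
#' Parses an SBML Level-3 document carrying the FBC package (flux bounds as
#' parameters, GPRs as \code{fbc:geneProductAssociation}) into a
#' [MetabolicModel]. Reactions without explicit FBC bounds default to
#' (-1000, 1000) mmol/gCDW/h. Unresolvable species references raise a
#' structural error naming the offending reaction.
#'
#' @param path path to the SBML file.
#' @param verbose report model size after reading.
#' @return a validated [MetabolicModel].
#' @export
readMetabolicModel <- function(path, verbose = FALSE) {
  doc <- xml2::read_xml(path)
  ln <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  modelNode <- ln(doc, "model")[[1]]

  comp <- ln(modelNode, "compartment")
  compartments <- stats::setNames(
    vapply(comp, function(n) {
      nm <- attr2(n, "name"); if (is.na(nm)) attr2(n, "id") else nm
    }, character(1)),
    vapply(comp, function(n) attr2(n, "id"), character(1)))

  sp <- ln(modelNode, "species")
  boundary <- vapply(sp, function(n)
    identical(attr2(n, "boundaryCondition"), "true"), logical(1))
  sp <- sp[!boundary]
  mets <- data.frame(
    id = stripPrefix(vapply(sp, function(n) attr2(n, "id"), character(1)), "M_"),
    name = vapply(sp, function(n) {
      v <- attr2(n, "name"); if (is.na(v)) "" else v }, character(1)),
    formula = vapply(sp, function(n) {
      v <- attr2(n, "chemicalFormula"); if (is.na(v)) "" else v }, character(1)),
    charge = vapply(sp, function(n) {
      v <- attr2(n, "charge")
      if (is.na(v)) NA_integer_ else as.integer(v) }, integer(1)),
    compartment = vapply(sp, function(n) attr2(n, "compartment"), character(1)),
    stringsAsFactors = FALSE)

  pars <- ln(modelNode, "parameter")
  parVal <- stats::setNames(
    vapply(pars, function(n) as.numeric(attr2(n, "value")), numeric(1)),
    vapply(pars, function(n) attr2(n, "id"), character(1)))

  ## gene product labels: fbc:id -> label
  gps <- ln(modelNode, "geneProduct")
  gpLabel <- stats::setNames(
    vapply(gps, function(n) {
      v <- attr2(n, "label")
      if (is.na(v) || !nzchar(v)) stripPrefix(attr2(n, "id"), "G_") else v
    }, character(1)),
    vapply(gps, function(n) stripPrefix(attr2(n, "id"), "G_"), character(1)))
  relabel <- function(g) {
    if (is.null(g)) return(NULL)
    if (is.character(g)) {
      if (g %in% names(gpLabel)) return(unname(gpLabel[[g]])) else return(g)
    }
    g$args <- lapply(g$args, relabel)
    g
  }

  rxNodes <- ln(modelNode, "reaction")
  reactions <- lapply(rxNodes, function(n) {
    id <- stripPrefix(attr2(n, "id"), "R_")
    sref <- function(tag, sign) {
      lst <- xml2::xml_find_all(n, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(lst)) return(numeric(0))
      stats::setNames(
        sign * vapply(lst, function(x) {
          v <- attr2(x, "stoichiometry")
          if (is.na(v)) 1 else as.numeric(v) }, numeric(1)),
        stripPrefix(vapply(lst, function(x) attr2(x, "species"),
                           character(1)), "M_"))
    }
    st <- c(sref("listOfReactants", -1), sref("listOfProducts", 1))
    st <- tapply(st, names(st), sum)   # merge duplicated references
    st <- st[st != 0]
    lbp <- attr2(n, "lowerFluxBound"); ubp <- attr2(n, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parVal)) parVal[[lbp]] else -1000
    ub <- if (!is.na(ubp) && ubp %in% names(parVal)) parVal[[ubp]] else 1000
    gnode <- xml2::xml_find_first(
      n, ".//*[local-name()='geneProductAssociation']")
    g <- NULL
    if (!inherits(gnode, "xml_missing")) {
      kids <- xml2::xml_children(gnode)
      if (length(kids)) g <- relabel(readGPRNode(kids[[1]]))
    }
    nmv <- attr2(n, "name")
    list(id = id, name = if (is.na(nmv)) "" else nmv,
         stoich = stats::setNames(as.numeric(st), names(st)),
         lb = lb, ub = ub, gpr = deparseGPR(g), subsystem = "")
  })

  ## custom annotation (biomass variants, ATPM)
  bv <- character(0); atpm <- NA_character_
  info <- xml2::xml_find_first(modelNode, ".//*[local-name()='info']")
  if (!inherits(info, "xml_missing")) {
    a <- attr2(info, "atpHydrolysis")
    if (!is.na(a)) atpm <- stripPrefix(a, "R_")
    bvn <- xml2::xml_find_all(info, ".//*[local-name()='biomassVariant']")
    if (length(bvn))
      bv <- stats::setNames(
        stripPrefix(vapply(bvn, function(n) attr2(n, "reaction"),
                           character(1)), "R_"),
        vapply(bvn, function(n) attr2(n, "label"), character(1)))
  }
  rid <- vapply(reactions, `[[`, character(1), "id")
  if (!length(bv)) {   # heuristic fallback for external models
    guess <- c(cellobiose = "BIOMASS_CELLOBIOSE",
               cellulose = "BIOMASS_CELLULOSE",
               no_cellulosome = "BIOMASS_NO_CELLULOSOME")
    bv <- guess[guess %in% rid]
  }
  if (is.na(atpm) && "ATPM" %in% rid) atpm <- "ATPM"

  mid <- attr2(modelNode, "id")
  model <- makeModel(if (is.na(mid)) "model" else mid, mets, reactions,
                     biomassVariants = bv, atpmReaction = atpm,
                     compartments = compartments)
  if (verbose)
    message(sprintf("read model '%s': %d genes, %d metabolites, %d reactions",
                    model@id, length(model@genes), nrow(model@mets),
                    ncol(model@stoich)))
  model
}

#' Locate a user-supplied reference genome-scale model
#'
#' Looks for a deposited reference SBML model (for example a published
#' genome-scale reconstruction) first at \code{options(fluxkit.referenceModel=)}
#' and then under the package's \code{extdata/reference/} directory. The
#' package ships no such model; analyses that need one report its absence
#' gracefully.
#'
#' @param file file name to look for under \code{extdata/reference}.
#' @return path to the model file, or \code{NULL} when absent.
#' @export
locateReferenceModel <- function(file = "model.xml") {
  opt <- getOption("fluxkit.referenceModel", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", "reference", file, package = "fluxkit")
  if (nzchar(p) && file.exists(p)) p else NULL
}
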