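## Gene-protein-reaction boolean logic.
##
## A GPR tree is either NULL (no association), a character scalar (gene
## leaf), or list(op = "and"|"or", args = list(<trees>)).

#' Parse a gene-protein-reaction association string
#'
#' Accepts the conventional infix syntax with \code{and} / \code{or}
#' (case-insensitive; \code{&&}, \code{&}, \code{||}, \code{|} also
#' accepted) and parentheses, e.g. \code{"(g1 and g2) or g3"}. \code{or}
#' binds loosest. An empty or all-whitespace string yields \code{NULL},
#' meaning no gene association.
#'
#' @param text GPR string.
#' @return a GPR tree, or \code{NULL}.
#' @examples
#' parseGPR("(g1 and g2) or g3")
#' @export
parseGPR <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  take <- function() { pos <<- pos + 1L; toks[pos] }
  err <- function(what) stop(sprintf("GPR parse error at token %d ('%s'): %s",
                                     pos + 1L, peek(), what), call. = FALSE)
  parseAtom <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of expression")
    if (t == "(") {
      take()
      e <- parseOr()
      if (!identical(peek(), ")")) err("expected ')'")
      take()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) err("expected gene id")
    take()
  }
  parseAnd <- function() {
    args <- list(parseAtom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parseAtom()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  out <- parseOr()
  if (pos != length(toks)) err("trailing input")
  out
}

#' Deparse a GPR tree back to its string form
#'
#' @param gpr a GPR tree (see [parseGPR()]).
#' @return character scalar; \code{""} for \code{NULL}.
#' @export
deparseGPR <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- deparseGPR(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' Genes referenced by a GPR tree
#'
#' @param gpr a GPR tree.
#' @return character vector of gene ids (unique), possibly empty.
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gprGenes)))
}

#' Evaluate a GPR under a gene deletion set
#'
#' Deleted genes evaluate FALSE, all other genes TRUE. A reaction with no
#' gene association (\code{NULL} GPR) is always active: it cannot be
#' disabled by gene removal.
#'
#' @param gpr a GPR tree.
#' @param deletedGenes character vector of deleted gene ids.
#' @return logical: is the reaction still catalytically available?
#' @examples
#' evalGPR(parseGPR("(g1 and g2) or g3"), "g1")        # TRUE, g3 survives
#' evalGPR(parseGPR("(g1 and g2) or g3"), c("g1","g3")) # FALSE
#' @export
evalGPR <- function(gpr, deletedGenes = character(0)) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) return(!(gpr %in% deletedGenes))
  vals <- vapply(gpr$args, evalGPR, logical(1), deletedGenes = deletedGenes)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' Apply gene deletions to a model
#'
#' Every reaction whose GPR evaluates inactive under the deletion has both
#' flux bounds set to zero; all other reactions are untouched. Returns a
#' new model; the input is not modified.
#'
#' @param model a [MetabolicModel].
#' @param genes character vector of gene ids to delete (must exist).
#' @return a [MetabolicModel] with knocked-out reactions closed.
#' @export
deleteGenes <- function(model, genes) {
  if (length(genes) == 0) return(model)
  unknown <- setdiff(genes, model@genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  off <- disabledReactions(model, genes)
  model@lb[off] <- 0
  model@ub[off] <- 0
  model
}

#' Reactions disabled by a gene deletion set
#'
#' @param model a [MetabolicModel].
#' @param genes deleted gene ids.
#' @return character vector of reaction ids whose GPR evaluates inactive.
#' @export
disabledReactions <- function(model, genes) {
  hit <- vapply(model@gpr, function(g) !evalGPR(g, genes), logical(1))
  names(hit)[hit]
}
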