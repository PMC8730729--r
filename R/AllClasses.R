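#' DnsafExperiment: per-protein distributed spectral counts and dNSAF values
#'
#' A \linkS4class{SummarizedExperiment} holding the two quantities the BioID
#' enrichment chain works with: the distributed spectral count (\code{dSpC})
#' and the distributed normalized spectral abundance factor (\code{dNSAF}),
#' one row per protein and one column per replicate run. Protein lengths (in
#' amino acids) live in \code{rowData()$length_aa}; each column carries a
#' \code{condition} label (e.g. a bait name or \code{"control"}) and a
#' \code{replicate} index in \code{colData()}.
#'
#' The class guarantees the two algebraic invariants that make dNSAF a
#' relative abundance: within every replicate the dNSAF column sums to 1
#' whenever any counts were observed (and is all-zero otherwise), and
#' dNSAF is zero exactly where dSpC is zero.
#'
#' @seealso [dnsafExperiment()] to build one from peptide-level evidence,
#'   [enrichmentTest()] for bait-versus-control scoring.
#' @aliases DnsafExperiment-class
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass DnsafExperiment
setClass("DnsafExperiment", contains = "SummarizedExperiment")

setValidity("DnsafExperiment", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("dSpC", "dNSAF") %in% a))
    msg <- c(msg, "assays must include 'dSpC' and 'dNSAF'")
  if (!"length_aa" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'length_aa'")
  if (!all(c("condition", "replicate") %in%
           colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  if (length(msg) > 0) return(msg)
  L <- SummarizedExperiment::rowData(object)$length_aa
  if (any(!is.finite(L)) || any(L < 1))
    msg <- c(msg, "length_aa must be >= 1")
  ds <- SummarizedExperiment::assay(object, "dSpC")
  dn <- SummarizedExperiment::assay(object, "dNSAF")
  if (any(ds < 0)) msg <- c(msg, "dSpC must be non-negative")
  tot <- colSums(dn)
  live <- colSums(ds) > 0
  if (any(abs(tot[live] - 1) > 1e-6))
    msg <- c(msg, "dNSAF columns with counts must sum to 1")
  if (any(tot[!live] != 0))
    msg <- c(msg, "all-zero dSpC columns must have all-zero dNSAF")
  if (any((dn == 0) != (ds == 0)))
    msg <- c(msg, "dNSAF must be zero exactly where dSpC is zero")
  if (length(msg) > 0) msg else TRUE
})

#' Extract the distributed spectral count matrix
#'
#' @param x a \linkS4class{DnsafExperiment}.
#' @return numeric matrix, proteins by replicates.
#' @export
setGeneric("dSpC", function(x) standardGeneric("dSpC"))

#' @rdname dSpC
#' @export
setMethod("dSpC", "DnsafExperiment", function(x)
  SummarizedExperiment::assay(x, "dSpC"))

#' Extract the dNSAF matrix
#'
#' @param x a \linkS4class{DnsafExperiment}.
#' @return numeric matrix, proteins by replicates; each column sums to 1
#'   (or 0 for an empty run).
#' @export
setGeneric("dNSAF", function(x) standardGeneric("dNSAF"))

#' @rdname dNSAF
#' @export
setMethod("dNSAF", "DnsafExperiment", function(x)
  SummarizedExperiment::assay(x, "dNSAF"))

#' Condition labels of the replicate columns
#'
#' @param x a \linkS4class{DnsafExperiment}.
#' @return character vector of per-column condition labels.
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname conditionLabels
#' @export
setMethod("conditionLabels", "DnsafExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$condition))

#' @importMethodsFrom methods show
setMethod("show", "DnsafExperiment", function(object) {
  callNextMethod()
  cond <- table(conditionLabels(object))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(cond), as.integer(cond)),
            collapse = ", "), "\n")
})
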