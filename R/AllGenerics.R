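# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname AnnotatedSequence-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("seqId", function(object) standardGeneric("seqId"))
#' @rdname AnnotatedSequence-class
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))
#' @rdname AnnotatedSequence-class
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @rdname AnnotatedSequence-class
#' @export
setGeneric("introns", function(object) standardGeneric("introns"))
#' @rdname AnnotatedSequence-class
#' @export
setGeneric("primerMask", function(object) standardGeneric("primerMask"))

#' @rdname PairAlignment-class
#' @export
setGeneric("rowA", function(object) standardGeneric("rowA"))
#' @rdname PairAlignment-class
#' @export
setGeneric("rowB", function(object) standardGeneric("rowB"))
#' @rdname PairAlignment-class
#' @export
setGeneric("alignmentLength", function(object) standardGeneric("alignmentLength"))
#' @rdname PairAlignment-class
#' @export
setGeneric("maskColumns", function(object) standardGeneric("maskColumns"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("basePairs", function(object) standardGeneric("basePairs"))
#' @rdname SecondaryStructure-class
#' @export
setGeneric("helixLabels", function(object) standardGeneric("helixLabels"))

#' @rdname StructuredAlignment-class
#' @export
setGeneric("partnerColumns", function(object) standardGeneric("partnerColumns"))
#' @rdname StructuredAlignment-class
#' @export
setGeneric("helixColumns", function(object) standardGeneric("helixColumns"))

#' @rdname ComparisonReport-class
#' @export
setGeneric("siteChanges", function(object) standardGeneric("siteChanges"))
#' @rdname ComparisonReport-class
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

setMethod("seqId", "AnnotatedSequence", function(object) object@id)
setMethod("residues", "AnnotatedSequence", function(object) object@residues)
setMethod("regions", "AnnotatedSequence", function(object) object@regions)
setMethod("introns", "AnnotatedSequence", function(object) object@introns)
setMethod("primerMask", "AnnotatedSequence", function(object) object@primerMask)

#' @rdname AnnotatedSequence-class
#' @export
setMethod("length", "AnnotatedSequence", function(x) nchar(x@residues))

setMethod("rowA", "PairAlignment", function(object) object@rowA)
setMethod("rowB", "PairAlignment", function(object) object@rowB)
setMethod("alignmentLength", "PairAlignment", function(object) nchar(object@rowA))
setMethod("maskColumns", "PairAlignment", function(object) object@maskColumns)

setMethod("basePairs", "SecondaryStructure", function(object) object@pairs)
setMethod("helixLabels", "SecondaryStructure", function(object) object@helixLabels)
#' @rdname SecondaryStructure-class
#' @export
setMethod("length", "SecondaryStructure", function(x) nrow(x@pairs))

setMethod("partnerColumns", "StructuredAlignment", function(object) object@partner)
setMethod("helixColumns", "StructuredAlignment", function(object) object@helix)
setMethod("rowA", "StructuredAlignment", function(object) object@alignment@rowA)
setMethod("rowB", "StructuredAlignment", function(object) object@alignment@rowB)
setMethod("alignmentLength", "StructuredAlignment",
          function(object) nchar(object@alignment@rowA))

setMethod("siteChanges", "ComparisonReport", function(object) object@siteChanges)
setMethod("classCounts", "ComparisonReport", function(object) object@classCounts)

setMethod("show", "AnnotatedSequence", function(object) {
  cat(sprintf("AnnotatedSequence '%s': %d nt\n", object@id, nchar(object@residues)))
  if (length(object@regions))
    cat("  regions:", paste(sprintf("%s=[%d,%d]", names(object@regions),
        start(object@regions), end(object@regions)), collapse = " "), "\n")
  if (length(object@introns))
    cat(sprintf("  introns: %d\n", length(object@introns)))
  if (length(object@primerMask))
    cat(sprintf("  primer-masked positions: %d\n", sum(width(object@primerMask))))
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment %s/%s: %d columns\n",
              object@idA, object@idB, nchar(object@rowA)))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure '%s': %d pairs", object@seqId, nrow(object@pairs)))
  if (length(object@helixLabels))
    cat(sprintf(", %d helix labels (%s)", length(unique(object@helixLabels)),
        paste(utils::head(unique(object@helixLabels), 4L), collapse = ",")))
  cat("\n")
})

setMethod("show", "StructuredAlignment", function(object) {
  cat(sprintf("StructuredAlignment: %d columns, %d paired (reference row %s)\n",
              nchar(object@alignment@rowA),
              sum(!is.na(object@partner)), object@referenceRow))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  cat(sprintf("  variable sites: %d (gaps counted), %d (gaps excluded)\n",
              object@variableSitesWithGaps, object@variableSitesNoGaps))
  cc <- object@classCounts
  cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  cat(sprintf("  p-distance: %.4f (gaps counted), %.4f (gaps excluded)\n",
              object@distanceWithGaps, object@distanceNoGaps))
})

setMethod("show", "MotifReport", function(object) {
  cat("MotifReport\n")
  cat(sprintf("  helices: %d\n", object@helixCount))
  cat(sprintf("  U-U mismatch in helix II: %s\n", object@uuMismatch))
  cat(sprintf("  A-rich region II..III:    %s\n", object@aRich))
  cat(sprintf("  GGU on 5' side helix III: %s\n", object@gguMotif))
  cat(sprintf("  branched helix I:         %s\n", object@branchedHelixI))
  if (length(object@warnings)) cat("  warnings:", object@warnings, "\n")
})
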