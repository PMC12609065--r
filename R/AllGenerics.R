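#' @include AllClasses.R
NULL

#' Accessors for MitoGenome
#'
#' \code{genomeSequence} returns the reference \code{DNAString};
#' \code{genomeLength} its length in bases; \code{geneFeatures} the feature
#' \code{GRanges}.
#'
#' @param x A [MitoGenome-class].
#' @return See description.
#' @name genome-accessors
#' @aliases genomeSequence genomeLength geneFeatures
#' @export genomeSequence genomeLength geneFeatures
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname genome-accessors
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname genome-accessors
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

setMethod("genomeSequence", "MitoGenome", function(x) x@sequence)
setMethod("genomeLength", "MitoGenome", function(x) length(x@sequence))
setMethod("geneFeatures", "MitoGenome", function(x) x@features)

#' Accessors for MitoCohort
#'
#' \code{cohortCalls} returns the call table; \code{cohortAnimals} the animal
#' roster (including zero-call animals); \code{groupLabels} the ordered group
#' labels; \code{controlGroup} (and its replacement form) the control-group
#' label; \code{nAnimals} the roster size.
#'
#' @param x A [MitoCohort-class].
#' @param value Replacement control-group label (must be an existing group).
#' @return See description.
#' @name cohort-accessors
#' @aliases cohortCalls cohortAnimals groupLabels controlGroup controlGroup<-
#'   nAnimals
#' @export cohortCalls cohortAnimals groupLabels controlGroup nAnimals
#' @exportMethod controlGroup<-
setGeneric("cohortCalls", function(x) standardGeneric("cohortCalls"))

#' @rdname cohort-accessors
setGeneric("cohortAnimals", function(x) standardGeneric("cohortAnimals"))

#' @rdname cohort-accessors
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname cohort-accessors
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))

#' @rdname cohort-accessors
#' @export controlGroup<-
setGeneric("controlGroup<-", function(x, value)
  standardGeneric("controlGroup<-"))

#' @rdname cohort-accessors
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

setMethod("cohortCalls", "MitoCohort", function(x) x@calls)
setMethod("cohortAnimals", "MitoCohort", function(x) x@animals)
setMethod("groupLabels", "MitoCohort", function(x) x@groups)
setMethod("controlGroup", "MitoCohort", function(x) x@control)
setReplaceMethod("controlGroup", "MitoCohort", function(x, value) {
  x@control <- as.character(value)
  validObject(x)
  x
})
setMethod("nAnimals", "MitoCohort", function(x) nrow(x@animals))

#' Accessors for SiteCounts
#'
#' @param x A [SiteCounts-class].
#' @return \code{possibleSynonymous} / \code{possibleNonsynonymous}: the
#'   genome-wide opportunity counts; \code{perGeneSites}: the per-gene
#'   breakdown data.frame.
#' @name sitecounts-accessors
#' @aliases possibleSynonymous possibleNonsynonymous perGeneSites
#' @export possibleSynonymous possibleNonsynonymous perGeneSites
setGeneric("possibleSynonymous", function(x)
  standardGeneric("possibleSynonymous"))

#' @rdname sitecounts-accessors
setGeneric("possibleNonsynonymous", function(x)
  standardGeneric("possibleNonsynonymous"))

#' @rdname sitecounts-accessors
setGeneric("perGeneSites", function(x) standardGeneric("perGeneSites"))

setMethod("possibleSynonymous", "SiteCounts",
          function(x) x@possibleSynonymous)
setMethod("possibleNonsynonymous", "SiteCounts",
          function(x) x@possibleNonsynonymous)
setMethod("perGeneSites", "SiteCounts", function(x) x@perGene)
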