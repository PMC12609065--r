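#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand width seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths isCircular
#' @importFrom Biostrings DNAString DNAStringSet
NULL

GENE_CATEGORIES <- c("protein", "tRNA", "rRNA", "noncoding")

FUNCTIONAL_CLASSES <- c("nonsynonymous", "synonymous", "tRNA", "rRNA",
                        "noncoding")

#' MitoGenome: a circular mitochondrial reference genome with gene features
#'
#' Container for a single circular mitochondrial contig and its gene
#' annotation. The sequence is a \link[Biostrings]{DNAString}; features are a
#' \link[GenomicRanges]{GRanges} whose metadata columns \code{gene} and
#' \code{category} give the gene name and its functional category
#' (\code{"protein"}, \code{"tRNA"}, \code{"rRNA"} or \code{"noncoding"}).
#' Features may overlap (as Atp8/Atp6 do in real mtDNA); bases covered by no
#' feature are treated as noncoding. Features must not wrap the origin;
#' circularity is honoured where it matters analytically (coldspot
#' detection).
#'
#' @slot sequence A \code{DNAString} over \{A,C,G,T\}.
#' @slot features A \code{GRanges} with metadata columns \code{gene}
#'   (character) and \code{category} (character, one of the categories
#'   above), 1-based inclusive coordinates on the \code{+} reference strand;
#'   \code{strand()} gives the coding strand of each gene.
#'
#' @seealso [MitoGenome()], [buildFixtureGenome()], [readReferenceGenome()]
#' @export
setClass("MitoGenome",
  representation(sequence = "DNAString", features = "GRanges"))

setValidity("MitoGenome", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L < 1L)
    msg <- c(msg, "genome sequence must be non-empty")
  if (!all(strsplit(as.character(object@sequence), "")[[1]] %in%
           c("A", "C", "G", "T")))
    msg <- c(msg, "genome sequence must contain only A, C, G, T")
  ft <- object@features
  if (length(ft)) {
    if (is.null(mcols(ft)$gene) || is.null(mcols(ft)$category))
      msg <- c(msg, "features need metadata columns 'gene' and 'category'")
    else {
      if (!all(mcols(ft)$category %in% GENE_CATEGORIES))
        msg <- c(msg, sprintf("feature categories must be in {%s}",
                              paste(GENE_CATEGORIES, collapse = ", ")))
      if (any(start(ft) < 1L) || any(end(ft) > L))
        msg <- c(msg, "features must lie within [1, genome length]")
      isprot <- mcols(ft)$category == "protein"
      if (any(isprot & width(ft) < 3L))
        msg <- c(msg, "protein features must span at least one codon")
      if (any(isprot & !as.character(strand(ft)) %in% c("+", "-")))
        msg <- c(msg, "protein features must have strand '+' or '-'")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MitoGenome
#'
#' @param sequence Character string or \code{DNAString}: the circular
#'   reference sequence.
#' @param features A \code{GRanges} (metadata columns \code{gene},
#'   \code{category}) or a data.frame with columns \code{gene},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand},
#'   \code{category}.
#' @param name Contig name used in the \code{GRanges} seqinfo.
#' @return A validated [MitoGenome-class] object.
#' @examples
#' gn <- MitoGenome("ATGAAATTTTAA",
#'   data.frame(gene = "g1", start = 1, end = 12, strand = "+",
#'              category = "protein"))
#' genomeLength(gn)
#' @export
MitoGenome <- function(sequence, features = NULL, name = "chrM") {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  L <- length(sequence)
  si <- Seqinfo(seqnames = name, seqlengths = L, isCircular = TRUE)
  if (is.null(features)) {
    gr <- GRanges(seqinfo = si)
    mcols(gr)$gene <- character(0)
    mcols(gr)$category <- character(0)
  } else if (is.data.frame(features)) {
    gr <- GRanges(name, IRanges(features$start, features$end),
                  strand = features$strand, seqinfo = si)
    mcols(gr)$gene <- as.character(features$gene)
    mcols(gr)$category <- as.character(features$category)
  } else {
    gr <- features
    GenomeInfoDb::seqlevels(gr) <- name
    GenomeInfoDb::seqinfo(gr) <- si
  }
  new("MitoGenome", sequence = sequence, features = gr)
}

#' MitoCohort: variant calls for a cohort of animals
#'
#' The pipeline's central table: every detected mtDNA variant call across a
#' cohort, with the heteroplasmic fraction (HF) of each call, plus the full
#' animal roster. Animals with zero calls stay on the roster because a
#' mutational burden of zero is meaningful.
#'
#' @slot calls A data.frame with columns \code{animal_id}, \code{group},
#'   \code{position} (1-based), \code{ref}, \code{alt} (single bases),
#'   \code{hf} (heteroplasmic fraction in (0, 1]) and, once annotated,
#'   \code{functional_class} and \code{genes}.
#' @slot animals A data.frame with columns \code{animal_id}, \code{group};
#'   one row per animal, including animals without calls.
#' @slot groups Ordered character vector of group labels.
#' @slot control The label of the control group.
#' @slot metadata Free-form list; readers, filters and the simulator record
#'   row/exclusion counts and provenance here.
#'
#' @seealso [MitoCohort()], [readVariantTable()], [simulateCohort()]
#' @export
setClass("MitoCohort",
  representation(calls = "data.frame", animals = "data.frame",
                 groups = "character", control = "character",
                 metadata = "list"))

CALL_COLUMNS <- c("animal_id", "group", "position", "ref", "alt", "hf")

setValidity("MitoCohort", function(object) {
  msg <- character()
  calls <- object@calls
  animals <- object@animals
  if (!all(CALL_COLUMNS %in% names(calls)))
    msg <- c(msg, sprintf("calls must have columns: %s",
                          paste(CALL_COLUMNS, collapse = ", ")))
  if (!all(c("animal_id", "group") %in% names(animals)))
    msg <- c(msg, "animals must have columns animal_id, group")
  if (length(msg)) return(msg)
  if (nrow(calls)) {
    if (any(calls$hf <= 0 | calls$hf > 1))
      msg <- c(msg, "hf must lie in (0, 1]")
    key <- paste(calls$animal_id, calls$position, calls$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (animal_id, position, alt) call")
    if (!all(calls$animal_id %in% animals$animal_id))
      msg <- c(msg, "calls reference animals missing from the roster")
  }
  if (anyDuplicated(animals$animal_id))
    msg <- c(msg, "duplicate animal_id in roster")
  if (!all(animals$group %in% object@groups))
    msg <- c(msg, "animal group labels missing from groups")
  if (length(object@control) == 1L && !object@control %in% object@groups)
    msg <- c(msg, "control label is not one of the groups")
  if (length(msg)) msg else TRUE
})

#' Construct a MitoCohort
#'
#' @param calls data.frame of variant calls (columns \code{animal_id},
#'   \code{group}, \code{position}, \code{ref}, \code{alt}, \code{hf}).
#' @param animals data.frame roster (\code{animal_id}, \code{group});
#'   derived from \code{calls} when omitted, in which case zero-call animals
#'   are unknown.
#' @param groups Ordered group labels; derived from \code{animals} when
#'   omitted.
#' @param control Label of the control group; defaults to the first group.
#' @param metadata Optional provenance list.
#' @return A validated [MitoCohort-class] object.
#' @export
MitoCohort <- function(calls, animals = NULL, groups = NULL,
                       control = NULL, metadata = list()) {
  calls <- as.data.frame(calls)
  if (is.null(animals)) {
    animals <- unique(calls[, c("animal_id", "group"), drop = FALSE])
    rownames(animals) <- NULL
  }
  animals <- as.data.frame(animals)
  animals$animal_id <- as.character(animals$animal_id)
  animals$group <- as.character(animals$group)
  if (nrow(calls)) {
    calls$animal_id <- as.character(calls$animal_id)
    calls$group <- as.character(calls$group)
    calls$position <- as.integer(calls$position)
  }
  if (is.null(groups)) groups <- unique(animals$group)
  if (is.null(control)) control <- groups[1L]
  new("MitoCohort", calls = calls, animals = animals,
      groups = as.character(groups), control = as.character(control),
      metadata = metadata)
}

#' SiteCounts: possible synonymous / nonsynonymous substitution sites
#'
#' Result of [countPossibleSites()]: for every complete codon of every
#' protein-coding gene, each of the three alternative bases is classified as
#' synonymous (amino-acid preserving) or nonsynonymous (anything else,
#' including stop gain/loss). Per gene,
#' \code{possible_synonymous + possible_nonsynonymous = 3 * coding bases}.
#'
#' @slot possibleSynonymous Genome-wide count of synonymous substitution
#'   opportunities (sum over genes; overlapping genes tallied per gene).
#' @slot possibleNonsynonymous Genome-wide nonsynonymous count.
#' @slot perGene data.frame with columns \code{gene}, \code{coding_bases},
#'   \code{possible_synonymous}, \code{possible_nonsynonymous}.
#' @export
setClass("SiteCounts",
  representation(possibleSynonymous = "numeric",
                 possibleNonsynonymous = "numeric",
                 perGene = "data.frame"))

setValidity("SiteCounts", function(object) {
  msg <- character()
  if (object@possibleSynonymous < 0 || object@possibleNonsynonymous < 0)
    msg <- c(msg, "site counts must be non-negative")
  pg <- object@perGene
  if (nrow(pg)) {
    ok <- pg$possible_synonymous + pg$possible_nonsynonymous ==
      3 * pg$coding_bases
    if (!all(ok))
      msg <- c(msg, "per gene, S + N opportunities must equal 3 x coding bases")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MitoGenome", function(object) {
  ft <- object@features
  cat(sprintf("MitoGenome: %d bp circular contig, %d features\n",
              length(object@sequence), length(ft)))
  if (length(ft)) {
    tab <- table(factor(mcols(ft)$category, levels = GENE_CATEGORIES))
    cat("  features:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
})

setMethod("show", "MitoCohort", function(object) {
  cat(sprintf("MitoCohort: %d calls, %d animals, %d groups (control: %s)\n",
              nrow(object@calls), nrow(object@animals),
              length(object@groups), object@control))
  tab <- table(factor(object@animals$group, levels = object@groups))
  cat("  animals/group:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "SiteCounts", function(object) {
  cat(sprintf(
    "SiteCounts: %d possible synonymous, %d possible nonsynonymous (%d genes)\n",
    object@possibleSynonymous, object@possibleNonsynonymous,
    nrow(object@perGene)))
})
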