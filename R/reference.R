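#' @include AllClasses.R AllGenerics.R
NULL

# NCBI translation table 2 (vertebrate mitochondrial): ATA=Met, TGA=Trp,
# AGA/AGG=STOP, unlike the standard code.
MITO_CODE <- Biostrings::getGeneticCode("2")

MITO_STOPS <- names(MITO_CODE)[MITO_CODE == "*"]
MITO_SENSE_CODONS <- names(MITO_CODE)[MITO_CODE != "*"]

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# precedence for genome-level classification of a variant hitting
# overlapping features: lower rank wins
CLASS_RANK <- c(nonsynonymous = 1, synonymous = 2, tRNA = 3, rRNA = 4,
                noncoding = 5)

#' Translate one codon under the vertebrate mitochondrial genetic code
#'
#' Uses NCBI translation table 2, in which ATA encodes Met, TGA encodes Trp
#' and AGA/AGG are stop codons (all unlike the standard code).
#'
#' @param codon A 3-character string over \{A,C,G,T\}, read on the coding
#'   strand.
#' @return Single-letter amino-acid symbol, or \code{"*"} for a stop codon.
#' @examples
#' translateCodon("ATA")  # "M" under the mitochondrial code
#' translateCodon("AGA")  # "*"
#' @export
translateCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop("invalid codon: need a 3-base string over {A,C,G,T}, got '",
         paste(codon, collapse = ","), "'")
  unname(MITO_CODE[[codon]])
}

# vectorised codon lookup (no validation)
.translate <- function(codons) unname(MITO_CODE[codons])

.seq_chars <- function(genome) {
  strsplit(as.character(genomeSequence(genome)), "")[[1]]
}

# Classify a substitution with respect to ONE protein feature.
# Returns "synonymous", "nonsynonymous", or NA_character_ when the position
# falls in the trailing partial codon (no complete codon on the genome).
.classify_in_protein <- function(chars, s, e, str, pos, alt) {
  w <- e - s + 1L
  cl <- 3L * (w %/% 3L)
  if (str == "+") {
    off <- pos - s
    if (off >= cl) return(NA_character_)
    cstart <- s + 3L * (off %/% 3L)
    codon <- chars[cstart:(cstart + 2L)]
    mut <- codon
    mut[off %% 3L + 1L] <- alt
  } else {
    off <- e - pos          # offset along the coding strand
    if (off >= cl) return(NA_character_)
    gpos <- e - 3L * (off %/% 3L) - (0:2)          # genomic coords of codon
    codon <- unname(COMPLEMENT[chars[gpos]])        # coding-strand codon
    mut <- codon
    mut[off %% 3L + 1L] <- unname(COMPLEMENT[alt])
  }
  aa0 <- MITO_CODE[[paste(codon, collapse = "")]]
  aa1 <- MITO_CODE[[paste(mut, collapse = "")]]
  if (aa0 == aa1) "synonymous" else "nonsynonymous"
}

#' Classify a single-nucleotide substitution
#'
#' Classifies a substitution at a genome position against every overlapping
#' gene feature, and resolves a genome-level functional class by the
#' precedence nonsynonymous > synonymous > tRNA > rRNA > noncoding.
#' For protein genes the codon containing the position is rebuilt on the
#' coding strand (reverse-complementing for minus-strand genes), mutated and
#' re-translated under the vertebrate mitochondrial code; amino-acid
#' preserving changes are synonymous, everything else (including stop
#' gain/loss) nonsynonymous. Positions in a trailing partial codon of a
#' protein feature carry no protein-level class.
#'
#' @param genome A [MitoGenome-class].
#' @param position 1-based position.
#' @param ref Reference base at \code{position} (checked against the genome).
#' @param alt Alternate base, different from \code{ref}.
#' @return A list with \code{class} (genome-level functional class),
#'   \code{genes} (names of overlapping features) and \code{geneClasses}
#'   (named character: per-gene class; \code{NA} for a protein gene when the
#'   position lies in its incomplete terminal codon).
#' @examples
#' gn <- MitoGenome("ATGCTATAA",
#'   data.frame(gene = "g", start = 1, end = 9, strand = "+",
#'              category = "protein"))
#' classifySubstitution(gn, 6, "A", "G")$class  # CTA->CTG, both Leu
#' @export
classifySubstitution <- function(genome, position, ref, alt) {
  L <- genomeLength(genome)
  position <- as.integer(position)
  if (position < 1L || position > L)
    stop("position ", position, " out of range [1, ", L, "]")
  chars <- .seq_chars(genome)
  if (chars[position] != ref)
    stop("reference inconsistency at position ", position, ": genome has ",
         chars[position], ", call says ", ref)
  if (!alt %in% c("A", "C", "G", "T") || alt == ref)
    stop("alt must be a base different from ref")
  ft <- geneFeatures(genome)
  hit <- which(start(ft) <= position & end(ft) >= position)
  geneClasses <- character(0)
  if (length(hit)) {
    geneClasses <- vapply(hit, function(i) {
      cat_i <- mcols(ft)$category[i]
      if (cat_i == "protein")
        .classify_in_protein(chars, start(ft)[i], end(ft)[i],
                             as.character(strand(ft)[i]), position, alt)
      else cat_i
    }, character(1))
    names(geneClasses) <- mcols(ft)$gene[hit]
  }
  eff <- geneClasses[!is.na(geneClasses)]
  cls <- if (length(eff)) names(CLASS_RANK)[min(CLASS_RANK[eff])]
         else "noncoding"
  list(class = cls, genes = unname(mcols(ft)$gene[hit]),
       geneClasses = geneClasses)
}

# Per-gene classification of every substitution opportunity in the complete
# codons of one protein feature. Returns a data.frame
# (position, alt, class) with 3 rows per coding base.
.protein_gene_sites <- function(chars, s, e, str) {
  w <- e - s + 1L
  cl <- 3L * (w %/% 3L)
  if (cl == 0L) {
    return(data.frame(position = integer(0), alt = character(0),
                      class = character(0)))
  }
  if (str == "+") {
    gpos <- s:(s + cl - 1L)
    coding <- chars[gpos]
  } else {
    gpos <- e:(e - cl + 1L)
    coding <- unname(COMPLEMENT[chars[gpos]])
  }
  n_codon <- cl %/% 3L
  codon_mat <- matrix(coding, nrow = 3L)                 # 3 x n_codon
  codons <- apply(codon_mat, 2L, paste, collapse = "")
  aa0 <- .translate(codons)
  pos_out <- integer(0); alt_out <- character(0); cls_out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (k in 1:3) {                       # within-codon position
    cur <- codon_mat[k, ]
    for (b in bases) {
      sel <- cur != b
      if (!any(sel)) next
      mut <- codon_mat[, sel, drop = FALSE]
      mut[k, ] <- b
      aa1 <- .translate(apply(mut, 2L, paste, collapse = ""))
      syn <- aa1 == aa0[sel]
      coding_idx <- 3L * (which(sel) - 1L) + k
      pos_out <- c(pos_out, gpos[coding_idx])
      alt_b <- if (str == "+") b else unname(COMPLEMENT[b])
      alt_out <- c(alt_out, rep(alt_b, sum(sel)))
      cls_out <- c(cls_out,
                   ifelse(syn, "synonymous", "nonsynonymous"))
    }
  }
  data.frame(position = pos_out, alt = alt_out, class = cls_out,
             stringsAsFactors = FALSE)
}

#' Count possible synonymous and nonsynonymous substitution sites
#'
#' Enumerates, for every complete codon of every protein-coding feature, all
#' three alternative bases at each of its positions and classifies each as
#' synonymous or nonsynonymous under the vertebrate mitochondrial code.
#' Overlapping genes are tallied independently per gene, so the genome-wide
#' totals sum the per-gene counts.
#'
#' @param genome A [MitoGenome-class]; a genome without protein features
#'   yields zero counts.
#' @return A [SiteCounts-class] object.
#' @examples
#' gn <- MitoGenome("TTT", data.frame(gene = "g", start = 1, end = 3,
#'   strand = "+", category = "protein"))
#' countPossibleSites(gn)  # S = 1 (TTT->TTC), N = 8
#' @export
countPossibleSites <- function(genome) {
  ft <- geneFeatures(genome)
  prot <- which(mcols(ft)$category == "protein")
  if (!length(prot))
    return(new("SiteCounts", possibleSynonymous = 0,
               possibleNonsynonymous = 0,
               perGene = data.frame(gene = character(0),
                                    coding_bases = integer(0),
                                    possible_synonymous = integer(0),
                                    possible_nonsynonymous = integer(0))))
  chars <- .seq_chars(genome)
  pg <- lapply(prot, function(i) {
    sites <- .protein_gene_sites(chars, start(ft)[i], end(ft)[i],
                                 as.character(strand(ft)[i]))
    data.frame(gene = mcols(ft)$gene[i],
               coding_bases = nrow(sites) %/% 3L,
               possible_synonymous = sum(sites$class == "synonymous"),
               possible_nonsynonymous = sum(sites$class == "nonsynonymous"),
               stringsAsFactors = FALSE)
  })
  pg <- do.call(rbind, pg)
  new("SiteCounts",
      possibleSynonymous = sum(pg$possible_synonymous),
      possibleNonsynonymous = sum(pg$possible_nonsynonymous),
      perGene = pg)
}

# Precompute the genome-level functional class of every possible
# substitution: an L x 4 character matrix, columns A/C/G/T (alt base), with
# NA where alt equals the reference base. Used by the simulator and the
# annotation step so per-variant classification is a table lookup.
classificationTable <- function(genome) {
  L <- genomeLength(genome)
  chars <- .seq_chars(genome)
  bases <- c("A", "C", "G", "T")
  rank <- matrix(CLASS_RANK[["noncoding"]], nrow = L, ncol = 4L,
                 dimnames = list(NULL, bases))
  ft <- geneFeatures(genome)
  if (length(ft)) {
    ord <- order(match(mcols(ft)$category,
                       c("noncoding", "rRNA", "tRNA")))  # protein last (NA)
    for (i in ord) {
      cat_i <- mcols(ft)$category[i]
      idx <- start(ft)[i]:end(ft)[i]
      if (cat_i %in% c("tRNA", "rRNA")) {
        rank[idx, ] <- pmin(rank[idx, ], CLASS_RANK[[cat_i]])
      } else if (cat_i == "protein") {
        sites <- .protein_gene_sites(chars, start(ft)[i], end(ft)[i],
                                     as.character(strand(ft)[i]))
        r <- CLASS_RANK[sites$class]
        ij <- cbind(sites$position, match(sites$alt, bases))
        rank[ij] <- pmin(rank[ij], r)
      }
    }
  }
  out <- matrix(names(CLASS_RANK)[rank], nrow = L,
                dimnames = list(NULL, bases))
  out[cbind(seq_len(L), match(chars, bases))] <- NA_character_
  out
}

#' Annotate cohort calls with functional classes
#'
#' Adds/overwrites the \code{functional_class} column of a cohort's call
#' table using the genome-level precedence classification (nonsynonymous >
#' synonymous > tRNA > rRNA > noncoding across overlapping genes).
#'
#' @param cohort A [MitoCohort-class].
#' @param genome The [MitoGenome-class] the calls refer to.
#' @return The annotated [MitoCohort-class].
#' @export
annotateCohort <- function(cohort, genome) {
  calls <- cohortCalls(cohort)
  if (nrow(calls)) {
    chars <- .seq_chars(genome)
    bad <- which(chars[calls$position] != calls$ref)
    if (length(bad))
      stop("reference inconsistency at call row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    tab <- classificationTable(genome)
    calls$functional_class <-
      tab[cbind(calls$position, match(calls$alt, c("A", "C", "G", "T")))]
  } else {
    calls$functional_class <- character(0)
  }
  initialize(cohort, calls = calls)
}

#' Build a deterministic fixture mitochondrial genome
#'
#' Generates a random circular genome with the requested feature layout.
#' Features are placed in layout order, separated by randomly sized
#' noncoding gaps that absorb the sequence length not claimed by features.
#' Protein genes are built codon-wise on their coding strand with no
#' in-frame internal stop codon (an ATG start and a TAA stop when the gene
#' has at least three codons).
#'
#' @param seed Integer seed; the genome is a pure function of the arguments.
#' @param length Total genome length in bases.
#' @param layout data.frame with columns \code{category}, \code{length} and
#'   \code{strand} (and optionally \code{gene} names); protein lengths must
#'   be multiples of 3; see [mouseLikeLayout()] for a realistic default.
#' @return A validated [MitoGenome-class].
#' @examples
#' gn <- buildFixtureGenome(1, 200,
#'   data.frame(category = "protein", length = 150, strand = "+"))
#' @export
buildFixtureGenome <- function(seed, length, layout = mouseLikeLayout()) {
  layout <- as.data.frame(layout)
  total <- sum(layout$length)
  if (total > length)
    stop("layout lengths (", total, ") exceed genome length (", length, ")")
  if (any(layout$category == "protein" & layout$length %% 3L != 0L))
    stop("protein feature lengths must be multiples of 3")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, length, replace = TRUE)
  n <- nrow(layout)
  # distribute the unclaimed length over n+1 gaps
  spare <- length - total
  gaps <- if (spare > 0L && n > 0L)
    as.vector(stats::rmultinom(1L, spare, rep(1, n + 1L)))
  else rep(0L, n + 1L)
  starts <- integer(n); ends <- integer(n)
  cursor <- 1L
  for (i in seq_len(n)) {
    cursor <- cursor + gaps[i]
    starts[i] <- cursor
    ends[i] <- cursor + layout$length[i] - 1L
    cursor <- ends[i] + 1L
    if (layout$category[i] == "protein") {
      ncod <- layout$length[i] %/% 3L
      cod <- sample(MITO_SENSE_CODONS, ncod, replace = TRUE)
      if (ncod >= 3L) {
        cod[1L] <- "ATG"
        cod[ncod] <- "TAA"
      }
      coding <- strsplit(paste(cod, collapse = ""), "")[[1]]
      if (identical(layout$strand[i], "-"))
        coding <- rev(unname(COMPLEMENT[coding]))
      chars[starts[i]:ends[i]] <- coding
    }
  }
  gene <- if (!is.null(layout$gene)) as.character(layout$gene)
          else sprintf("%s%02d", substr(layout$category, 1, 1), seq_len(n))
  MitoGenome(paste(chars, collapse = ""),
             if (n) data.frame(gene = gene, start = starts, end = ends,
                               strand = layout$strand,
                               category = layout$category)
             else NULL)
}

#' A mouse-like mitochondrial gene layout
#'
#' Feature layout approximating the mouse mitochondrial genome: 2 rRNAs,
#' 22 tRNAs (8 on the minus strand), 13 protein-coding genes (one, an
#' Nd6-like gene, on the minus strand) and a control-region-like noncoding
#' block, about 16.3 kb in total. Gene lengths are rounded to codon
#' multiples; the layout feeds [buildFixtureGenome()].
#'
#' @return data.frame with columns \code{gene}, \code{category},
#'   \code{length}, \code{strand}.
#' @export
mouseLikeLayout <- function() {
  prot <- data.frame(
    gene = c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6", "Co3", "Nd3",
             "Nd4l", "Nd4", "Nd5", "Nd6", "Cytb"),
    category = "protein",
    length = c(957, 1038, 1545, 684, 204, 681, 783, 348, 297, 1377, 1824,
               528, 1143),
    strand = c(rep("+", 11), "-", "+"))
  trna <- data.frame(
    gene = sprintf("Trn%02d", 1:22), category = "tRNA",
    length = rep(c(69, 70, 72, 68, 75, 71, 66, 73, 70, 69, 74), 2),
    strand = rep(c("+", "+", "-", "+", "+", "-", "+", "+", "-", "+", "-"), 2))
  rrna <- data.frame(gene = c("Rnr1", "Rnr2"), category = "rRNA",
                     length = c(956, 1582), strand = "+")
  ncr <- data.frame(gene = "CR", category = "noncoding", length = 780,
                    strand = "+")
  rbind(rrna[1, ], trna[1:2, ], rrna[2, ], prot[1:9, ], trna[3:14, ],
        prot[10:11, ], trna[15:18, ], prot[12, ], trna[19:20, ],
        prot[13, ], trna[21:22, ], ncr)
}

#' Read a reference genome from FASTA plus BED-like annotation
#'
#' @param fasta Path to a single-contig FASTA file.
#' @param bed Path to a 6-column BED-like file: contig, start (0-based
#'   half-open), end, gene name, category (protein/tRNA/rRNA/noncoding),
#'   strand. Coordinates are converted to 1-based inclusive internally.
#' @return A [MitoGenome-class].
#' @export
readReferenceGenome <- function(fasta, bed) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop("expected a single circular contig, found ", length(seqs))
  tab <- utils::read.table(bed, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "gene",
                                         "category", "strand"))
  MitoGenome(as.character(seqs[[1L]]),
             data.frame(gene = tab$gene, start = tab$start + 1L,
                        end = tab$end, strand = tab$strand,
                        category = tab$category),
             name = names(seqs)[1L])
}
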