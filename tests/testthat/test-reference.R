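test_that("codon translation follows the vertebrate mitochondrial code", {
  expect_equal(translateCodon("ATA"), "M")  # Ile in the standard code
  expect_equal(translateCodon("AGA"), "*")  # Arg in the standard code
  expect_equal(translateCodon("CTA"), "L")
  expect_equal(translateCodon("TGA"), "W")
  expect_error(translateCodon("ATN"), "invalid codon")
  expect_error(translateCodon("AT"), "invalid codon")
})

test_that("substitutions are classified per gene with precedence", {
  gn <- MitoGenome("ATGCTATAA",
                   data.frame(gene = "g", start = 1, end = 9, strand = "+",
                              category = "protein"))
  # CTA -> CTG: Leu is 4-fold degenerate at the third position
  expect_equal(classifySubstitution(gn, 6, "A", "G")$class, "synonymous")
  # CGA -> AGA is a stop gain (AGA is a mito stop codon): nonsynonymous
  gn2 <- MitoGenome("ATGCGATAA",
                    data.frame(gene = "g", start = 1, end = 9, strand = "+",
                               category = "protein"))
  expect_equal(classifySubstitution(gn2, 4, "C", "A")$class, "nonsynonymous")
  # tRNA / rRNA / noncoding classes
  gn3 <- MitoGenome("ACGTACGTAC",
                    data.frame(gene = c("t", "r"), start = c(1, 4),
                               end = c(3, 6), strand = "+",
                               category = c("tRNA", "rRNA")))
  expect_equal(classifySubstitution(gn3, 2, "C", "T")$class, "tRNA")
  expect_equal(classifySubstitution(gn3, 5, "A", "G")$class, "rRNA")
  expect_equal(classifySubstitution(gn3, 8, "T", "A")$class, "noncoding")
  # errors
  expect_error(classifySubstitution(gn, 6, "C", "G"),
               "reference inconsistency")
  expect_error(classifySubstitution(gn, 10, "A", "G"), "out of range")
  expect_error(classifySubstitution(gn, 6, "A", "A"), "different from ref")
})

test_that("overlapping genes resolve by nonsyn > syn > tRNA > rRNA", {
  # protein gene overlapping a tRNA: protein class wins at shared positions
  gn <- MitoGenome("ATGCTATAA",
                   data.frame(gene = c("p", "t"), start = c(1, 4),
                              end = c(9, 9), strand = "+",
                              category = c("protein", "tRNA")))
  res <- classifySubstitution(gn, 6, "A", "G")
  expect_equal(res$class, "synonymous")
  expect_setequal(res$genes, c("p", "t"))
  expect_equal(unname(res$geneClasses["p"]), "synonymous")
  expect_equal(unname(res$geneClasses["t"]), "tRNA")
  res2 <- classifySubstitution(gn, 5, "T", "A")  # CTA -> CAA, Leu -> Gln
  expect_equal(res2$class, "nonsynonymous")
})

test_that("classification agrees with a full-protein translation oracle", {
  gn <- test_genome(42)
  ft <- geneFeatures(gn)
  prot <- which(S4Vectors::mcols(ft)$category == "protein")
  chars <- strsplit(as.character(genomeSequence(gn)), "")[[1]]
  set.seed(7)
  for (rep in 1:1000) {
    gi <- sample(prot, 1)
    pos <- sample(GenomicRanges::start(ft)[gi]:GenomicRanges::end(ft)[gi], 1)
    ref <- chars[pos]
    alt <- sample(setdiff(BASES, ref), 1)
    got <- classifySubstitution(gn, pos, ref, alt)
    gene <- S4Vectors::mcols(ft)$gene[gi]
    expect_equal(unname(got$geneClasses[gene]),
                 protein_oracle(gn, gi, pos, alt),
                 info = sprintf("gene %s pos %d %s>%s", gene, pos, ref, alt))
  }
})

test_that("minus-strand classification equals the reverse-complement copy", {
  # build a - strand gene, then the same gene reverse-complemented on +
  set.seed(11)
  gm <- buildFixtureGenome(5, 140, data.frame(
    category = "protein", length = 120, strand = "-"))
  ft <- geneFeatures(gm)
  s <- GenomicRanges::start(ft)[1]; e <- GenomicRanges::end(ft)[1]
  chars <- strsplit(as.character(genomeSequence(gm)), "")[[1]]
  rc <- rev(unname(COMP[chars[s:e]]))
  gp <- MitoGenome(paste(rc, collapse = ""),
                   data.frame(gene = "g", start = 1, end = e - s + 1,
                              strand = "+", category = "protein"))
  for (rep in 1:100) {
    pos <- sample(s:e, 1)
    ref <- chars[pos]
    alt <- sample(setdiff(BASES, ref), 1)
    minus_class <- classifySubstitution(gm, pos, ref, alt)$class
    # complementary substitution at the mirrored position of the + copy
    pos_plus <- e - pos + 1
    plus_class <- classifySubstitution(gp, pos_plus, unname(COMP[ref]),
                                       unname(COMP[alt]))$class
    expect_equal(minus_class, plus_class)
  }
})

test_that("possible-site counts match per-codon enumeration exactly", {
  # single-codon genes with known counts
  for (fix in list(list(seq = "TTT", S = 1, N = 8),
                   list(seq = "ATG", S = 1, N = 8))) {
    gn <- MitoGenome(fix$seq, data.frame(gene = "g", start = 1, end = 3,
                                         strand = "+",
                                         category = "protein"))
    sc <- countPossibleSites(gn)
    expect_equal(possibleSynonymous(sc), fix$S)
    expect_equal(possibleNonsynonymous(sc), fix$N)
  }
  # mixed fixture genome incl. a minus-strand gene
  gn <- test_genome(42)
  sc <- countPossibleSites(gn)
  pg <- perGeneSites(sc)
  ft <- geneFeatures(gn)
  prot <- which(S4Vectors::mcols(ft)$category == "protein")
  for (k in seq_along(prot)) {
    oracle <- site_oracle_gene(gn, prot[k])
    row <- pg[pg$gene == S4Vectors::mcols(ft)$gene[prot[k]], ]
    expect_equal(row$possible_synonymous, unname(oracle["synonymous"]))
    expect_equal(row$possible_nonsynonymous,
                 unname(oracle["nonsynonymous"]))
  }
  # partition identity: S + N = 3 x coding bases, genome-wide
  expect_equal(possibleSynonymous(sc) + possibleNonsynonymous(sc),
               3 * sum(pg$coding_bases))
  # no protein features -> zero counts
  empty <- buildFixtureGenome(1, 50, data.frame(category = character(0),
                                                length = numeric(0),
                                                strand = character(0)))
  sc0 <- countPossibleSites(empty)
  expect_equal(possibleSynonymous(sc0), 0)
  expect_equal(possibleNonsynonymous(sc0), 0)
})

test_that("trailing partial codons are excluded from sites and classes", {
  # 8-base protein feature: 2 complete codons + 2 trailing bases
  gn <- MitoGenome("ATGCTATACC",
                   data.frame(gene = "g", start = 1, end = 8, strand = "+",
                              category = "protein"))
  sc <- countPossibleSites(gn)
  pg <- perGeneSites(sc)
  expect_equal(pg$coding_bases, 6)
  # position 7 is in the partial codon: falls through to noncoding
  expect_equal(classifySubstitution(gn, 7, "T", "G")$class, "noncoding")
  expect_true(is.na(classifySubstitution(gn, 7, "T", "G")$geneClasses["g"]))
})

test_that("classificationTable matches classifySubstitution", {
  gn <- test_genome(3)
  tab <- mitoHet:::classificationTable(gn)
  chars <- strsplit(as.character(genomeSequence(gn)), "")[[1]]
  set.seed(21)
  pos <- sample(genomeLength(gn), 200, replace = TRUE)
  for (p in pos) {
    ref <- chars[p]
    expect_true(is.na(tab[p, ref]))
    for (alt in setdiff(BASES, ref)) {
      expect_equal(unname(tab[p, alt]),
                   classifySubstitution(gn, p, ref, alt)$class,
                   info = sprintf("pos %d alt %s", p, alt))
    }
  }
})

test_that("fixture genomes are deterministic and stop-free", {
  layout <- data.frame(category = c("protein", "tRNA"),
                       length = c(300, 70), strand = c("+", "+"))
  g1 <- buildFixtureGenome(9, 500, layout)
  g2 <- buildFixtureGenome(9, 500, layout)
  expect_equal(as.character(genomeSequence(g1)),
               as.character(genomeSequence(g2)))
  expect_equal(as.data.frame(geneFeatures(g1)),
               as.data.frame(geneFeatures(g2)))
  # the protein gene translates with no internal stop
  ft <- geneFeatures(g1)
  s <- GenomicRanges::start(ft)[1]; e <- GenomicRanges::end(ft)[1]
  chars <- strsplit(as.character(genomeSequence(g1)), "")[[1]]
  codons <- apply(matrix(chars[s:e], nrow = 3), 2, paste, collapse = "")
  aa <- unname(MITO_CODE_TEST[codons])
  expect_false(any(aa[-length(aa)] == "*"))
  # unsatisfiable layout errors
  expect_error(buildFixtureGenome(1, 100, data.frame(
    category = "protein", length = 300, strand = "+")), "exceed")
  expect_error(buildFixtureGenome(1, 100, data.frame(
    category = "protein", length = 100, strand = "+")), "multiples of 3")
})

test_that("FASTA + BED round trip preserves the genome model", {
  gn <- test_genome(8)
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(genomeSequence(gn)),
                                      "chrM")), fa)
  ft <- geneFeatures(gn)
  write.table(data.frame("chrM", GenomicRanges::start(ft) - 1L,
                         GenomicRanges::end(ft),
                         S4Vectors::mcols(ft)$gene,
                         S4Vectors::mcols(ft)$category,
                         as.character(GenomicRanges::strand(ft))),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- readReferenceGenome(fa, bed)
  expect_equal(as.character(genomeSequence(back)),
               as.character(genomeSequence(gn)))
  expect_equal(GenomicRanges::start(geneFeatures(back)),
               GenomicRanges::start(ft))
  expect_equal(S4Vectors::mcols(geneFeatures(back))$category,
               S4Vectors::mcols(ft)$category)
})
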