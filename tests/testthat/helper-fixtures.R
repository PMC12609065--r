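# Shared fixtures and independent oracles for the test suite.

MITO_CODE_TEST <- Biostrings::getGeneticCode("2")
BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# small mixed-feature genome used across tests: two + strand protein genes,
# one - strand protein gene, tRNA, rRNA, and uncovered (noncoding) sequence
test_genome <- function(seed = 42) {
  buildFixtureGenome(seed, 700, data.frame(
    category = c("protein", "tRNA", "protein", "rRNA", "protein"),
    length = c(90, 70, 120, 100, 150),
    strand = c("+", "+", "-", "+", "+")))
}

make_cohort <- function(calls, ...) MitoCohort(calls, ...)

# quick call-table builder: one row per (animal, position); alt chosen
# against the genome reference when supplied
call_rows <- function(animal_id, group, position, hf, genome = NULL,
                      alt = NULL, ref = NULL) {
  if (!is.null(genome)) {
    chars <- strsplit(as.character(genomeSequence(genome)), "")[[1]]
    ref <- chars[position]
    if (is.null(alt))
      alt <- vapply(ref, function(r) setdiff(BASES, r)[1], character(1))
  } else {
    if (is.null(ref)) ref <- "A"
    if (is.null(alt)) alt <- "G"
  }
  data.frame(animal_id = animal_id, group = group,
             position = as.integer(position), ref = ref, alt = alt,
             hf = hf, stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# EMD oracle: numeric integration of |F_a - F_b|, evaluating the ECDFs at
# midpoints of a partition refined below every CDF breakpoint (exact for
# step functions, unlike a naive fixed grid)
emd_oracle <- function(a, b) {
  Fa <- stats::ecdf(a); Fb <- stats::ecdf(b)
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1L) return(0)
  grid <- unlist(lapply(seq_len(length(xs) - 1L), function(i)
    seq(xs[i], xs[i + 1L], length.out = 9L)))
  mid <- (grid[-1L] + grid[-length(grid)]) / 2
  sum(abs(Fa(mid) - Fb(mid)) * diff(grid))
}

# full-protein translation oracle: classify a substitution inside one
# protein gene by translating the entire (possibly reverse-complemented)
# mutated coding sequence and comparing protein strings
protein_oracle <- function(genome, gene_idx, position, alt) {
  ft <- geneFeatures(genome)
  s <- GenomicRanges::start(ft)[gene_idx]
  e <- GenomicRanges::end(ft)[gene_idx]
  str <- as.character(GenomicRanges::strand(ft)[gene_idx])
  chars <- strsplit(as.character(genomeSequence(genome)), "")[[1]]
  mutated <- chars
  mutated[position] <- alt
  coding <- function(ch) {
    sub <- ch[s:e]
    if (str == "-") sub <- rev(unname(COMP[sub]))
    sub <- sub[seq_len(3 * (length(sub) %/% 3))]
    codons <- apply(matrix(sub, nrow = 3), 2, paste, collapse = "")
    paste(MITO_CODE_TEST[codons], collapse = "")
  }
  p0 <- coding(chars); p1 <- coding(mutated)
  if (p0 == p1) "synonymous" else "nonsynonymous"
}

# brute-force per-codon site enumeration oracle for one protein gene
site_oracle_gene <- function(genome, gene_idx) {
  ft <- geneFeatures(genome)
  s <- GenomicRanges::start(ft)[gene_idx]
  e <- GenomicRanges::end(ft)[gene_idx]
  str <- as.character(GenomicRanges::strand(ft)[gene_idx])
  chars <- strsplit(as.character(genomeSequence(genome)), "")[[1]]
  sub <- chars[s:e]
  if (str == "-") sub <- rev(unname(COMP[sub]))
  sub <- sub[seq_len(3 * (length(sub) %/% 3))]
  syn <- 0L; non <- 0L
  for (ci in seq_len(length(sub) / 3)) {
    cod <- sub[(3 * ci - 2):(3 * ci)]
    aa0 <- MITO_CODE_TEST[[paste(cod, collapse = "")]]
    for (k in 1:3) for (b in setdiff(BASES, cod[k])) {
      mut <- cod; mut[k] <- b
      if (MITO_CODE_TEST[[paste(mut, collapse = "")]] == aa0)
        syn <- syn + 1L
      else non <- non + 1L
    }
  }
  c(synonymous = syn, nonsynonymous = non)
}

# brute-force circular coldspot scan over an explicit position mask: walk
# the genome in circular order starting at a variant position, so every
# collected zero-run is maximal (flanked by variants on both sides)
coldspot_oracle <- function(variant_pos, L, min_run, circular = TRUE) {
  hit <- logical(L); hit[variant_pos] <- TRUE
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (!any(hit)) {
    return(if (L >= min_run) data.frame(start = 1L, end = L, length = L)
           else empty)
  }
  ord <- if (circular) {
    first <- which(hit)[1L]
    (first:(first + L - 1L) - 1L) %% L + 1L
  } else seq_len(L)
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (!hit[ord[i]]) {
      j <- i
      while (j < L && !hit[ord[j + 1L]]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = ord[i], end = ord[j],
                                     length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- if (length(runs)) as.data.frame(do.call(rbind, runs)) else empty
  out <- out[out$length >= min_run, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
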