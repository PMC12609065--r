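test_that("per-animal mean HF averages each animal's variants", {
  calls <- call_rows(c("m1", "m1", "m1", "m2"), "g", c(1, 2, 3, 4),
                     hf = c(0.1, 0.2, 0.3, 0.14))
  co <- MitoCohort(calls)
  m <- suppressMessages(meanHfPerAnimal(co))
  expect_equal(unname(m["m1"]), 0.2)
  expect_equal(unname(m["m2"]), 0.14)
  # order invariance
  co2 <- MitoCohort(calls[sample(nrow(calls)), ])
  expect_equal(suppressMessages(meanHfPerAnimal(co2))[names(m)], m)
  # zero-call animals excluded from HF but present in burden
  roster <- data.frame(animal_id = c("m1", "m2", "m3"), group = "g")
  co3 <- MitoCohort(calls, animals = roster)
  expect_message(m3 <- meanHfPerAnimal(co3), "zero calls")
  expect_false("m3" %in% names(m3))
  b <- mutationalBurden(co3)
  expect_equal(unname(b[c("m1", "m2", "m3")]), c(3, 1, 0))
  expect_equal(sum(b), nrow(calls))
})

test_that("emd1d matches closed forms and behaves as a metric", {
  expect_equal(emd1d(0.3, 0.7), 0.4)            # two point masses
  expect_equal(emd1d(c(0.1, 0.3), c(0.2, 0.4)), 0.1)  # sorted-gap mean
  x <- c(0.05, 0.2, 0.9)
  expect_equal(emd1d(x, x), 0)
  expect_error(emd1d(numeric(0), 1), "empty")
  set.seed(12)
  for (rep in 1:200) {
    a <- runif(sample(1:8, 1)); b <- runif(sample(1:8, 1))
    c_ <- runif(sample(1:8, 1))
    dab <- emd1d(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, emd1d(b, a))
    expect_lte(dab, emd1d(a, c_) + emd1d(c_, b) + 1e-12)
    # equal-size closed form: mean |sorted a - sorted b|
    m <- sample(1:8, 1)
    a2 <- runif(m); b2 <- runif(m)
    expect_equal(emd1d(a2, b2), mean(abs(sort(a2) - sort(b2))))
  }
})

test_that("pairwise EMD covers all unordered animal pairs", {
  calls <- call_rows(rep(c("m1", "m2", "m3"), each = 2), "g",
                     position = 1:6, hf = c(.1, .2, .1, .2, .3, .5))
  co <- MitoCohort(calls)
  v <- pairwiseEmd(co, "g")
  expect_length(v, 3)  # 3 animals -> 3 pairs
  # identical HF multisets -> all zeros
  same <- call_rows(rep(c("m1", "m2", "m3"), each = 2), "g",
                    position = 1:6, hf = rep(c(.1, .2), 3))
  expect_equal(pairwiseEmd(MitoCohort(same), "g"), rep(0, 3))
  # 5-animal random fixture vs numeric-integration oracle
  set.seed(4)
  rnd <- do.call(rbind, lapply(1:5, function(i)
    call_rows(paste0("a", i), "g", position = 100 * i + 1:6,
              hf = runif(6))))
  rc <- MitoCohort(rnd)
  got <- pairwiseEmd(rc, "g")
  hfs <- split(rnd$hf, rnd$animal_id)
  pairs <- combn(5, 2)
  oracle <- apply(pairs, 2, function(ij)
    emd_oracle(hfs[[ij[1]]], hfs[[ij[2]]]))
  expect_equal(got, oracle, tolerance = 1e-12)
  # fewer than two eligible animals errors
  one <- MitoCohort(call_rows("m1", "g", 1, hf = 0.2))
  expect_error(pairwiseEmd(one, "g"), "fewer than 2")
})

test_that("KDE mode follows the Silverman-bandwidth grid argmax", {
  expect_equal(kdeMode(0.5), 0.5)                 # degenerate
  expect_equal(kdeMode(rep(0.3, 4)), 0.3)         # zero spread
  # symmetric sample: peak at the centre, up to grid resolution
  x <- c(0.1, 0.2, 0.3)
  h <- stats::bw.nrd0(x)
  grid_step <- (diff(range(x)) + 6 * h) / 511
  expect_lt(abs(kdeMode(x) - 0.2), grid_step)
  # dense-grid oracle agreement on a random sample
  set.seed(9)
  y <- rnorm(60, 0.4, 0.05)
  dense <- stats::density(y, bw = stats::bw.nrd0(y), n = 2^14, cut = 3)
  step_y <- (diff(range(y)) + 6 * stats::bw.nrd0(y)) / 511
  expect_lt(abs(kdeMode(y) - dense$x[which.max(dense$y)]), step_y)
  # bimodal: mode tracks the heavier component
  set.seed(10)
  z <- c(rnorm(100, 0.1, 0.01), rnorm(50, 0.5, 0.01))
  expect_lt(abs(kdeMode(z) - 0.1), 0.03)
  expect_error(kdeMode(numeric(0)), "empty")
})

test_that("site-normalised N/S ratio handles zero counts", {
  sc <- new("SiteCounts", possibleSynonymous = 50,
            possibleNonsynonymous = 100,
            perGene = data.frame(gene = "g", coding_bases = 50,
                                 possible_synonymous = 50,
                                 possible_nonsynonymous = 100))
  mk <- function(classes, id = "m1") {
    calls <- call_rows(id, "g", seq_along(classes), hf = 0.2)
    calls$functional_class <- classes
    MitoCohort(calls)
  }
  # 2 nonsyn, 4 syn, N=100, S=50 -> (2/100)/(4/50) = 0.25
  co <- mk(rep(c("nonsynonymous", "synonymous"), c(2, 4)))
  expect_equal(unname(nsRatio(co, sc)), 0.25)
  # equal observed with equal possible -> 1
  sc_eq <- new("SiteCounts", possibleSynonymous = 80,
               possibleNonsynonymous = 80,
               perGene = data.frame(gene = "g", coding_bases = 160 / 3,
                                    possible_synonymous = 80,
                                    possible_nonsynonymous = 80))
  validObject(sc_eq, complete = FALSE)
  co_eq <- mk(rep(c("nonsynonymous", "synonymous"), each = 3))
  expect_equal(unname(nsRatio(co_eq, sc_eq)), 1)
  # zero nonsynonymous -> 0; zero synonymous -> NA (undefined)
  expect_equal(unname(nsRatio(mk(rep("synonymous", 3)), sc)), 0)
  expect_true(is.na(suppressMessages(
    nsRatio(mk(rep("nonsynonymous", 3)), sc))))
})

test_that("neutral placement over coding opportunities gives N/S near 1", {
  gn <- test_genome(6)
  sc <- countPossibleSites(gn)
  # enumerate every coding substitution opportunity (per-gene classes)
  ft <- geneFeatures(gn)
  chars <- strsplit(as.character(genomeSequence(gn)), "")[[1]]
  prot <- which(S4Vectors::mcols(ft)$category == "protein")
  sites <- do.call(rbind, lapply(prot, function(i)
    mitoHet:::.protein_gene_sites(chars, GenomicRanges::start(ft)[i],
                                  GenomicRanges::end(ft)[i],
                                  as.character(GenomicRanges::strand(ft)[i]))))
  set.seed(14)
  draw <- sites[sample(nrow(sites), 1e4, replace = TRUE), ]
  nN <- sum(draw$class == "nonsynonymous")
  nS <- sum(draw$class == "synonymous")
  ratio <- (nN / possibleNonsynonymous(sc)) / (nS / possibleSynonymous(sc))
  se <- ratio * sqrt(1 / nN + 1 / nS)   # delta-method Monte-Carlo SE
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("rank tests match exact enumeration and tie behaviour", {
  expect_equal(compareToControl(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compareToControl(c(4, 5, 6), c(1, 2, 3)), 0.1)  # symmetry
  expect_equal(compareToControl(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(compareToControl(numeric(0), 1), "non-empty")
})

test_that("normality gate flags non-normal samples", {
  set.seed(20)
  expo <- rexp(50)
  expect_lt(checkNormality(expo)$p.value, 0.05)
  hits <- sum(vapply(1:100, function(s) {
    set.seed(s)
    checkNormality(rnorm(50))$p.value > 0.05
  }, logical(1)))
  expect_gte(hits, 90)
  expect_error(checkNormality(rep(1, 10)), "zero-variance")
  expect_error(checkNormality(c(1, 2)), "3 <= n")
})

test_that("coldspots are maximal variant-free runs on the circle", {
  gn30 <- MitoGenome(paste(rep("A", 30), collapse = ""))
  co <- MitoCohort(call_rows(c("m1", "m1"), "g", c(5, 20), hf = 0.2,
                             ref = "A", alt = "G"))
  cs <- findColdspots(co, gn30, 9)
  expect_equal(cs$length, c(14, 14))
  expect_equal(cs$start, c(6, 21))
  expect_equal(cs$end, c(19, 4))  # second interval wraps the origin
  # no variants: one full-genome interval
  none <- MitoCohort(call_rows("m1", "g", 1, hf = .2)[0, ],
                     animals = data.frame(animal_id = "m1", group = "g"))
  expect_equal(findColdspots(none, gn30, 9),
               data.frame(start = 1L, end = 30L, length = 30L))
  # every position hit: no coldspot
  all_pos <- MitoCohort(call_rows("m1", "g", 1:30, hf = .2,
                                  ref = "A", alt = "G"))
  expect_equal(nrow(findColdspots(all_pos, gn30, 1)), 0)
  # brute-force oracle on random fixtures, circular and linear
  set.seed(25)
  for (rep in 1:60) {
    L <- sample(20:120, 1)
    npos <- sample(0:min(L, 15), 1)
    pos <- sort(sample(L, npos))
    gnL <- MitoGenome(paste(rep("A", L), collapse = ""))
    coL <- if (npos) MitoCohort(call_rows("m1", "g", pos, hf = .2,
                                          ref = "A", alt = "G"))
           else none
    min_run <- sample(1:9, 1)
    for (circ in c(TRUE, FALSE)) {
      got <- findColdspots(coL, gnL, min_run, circular = circ)
      got <- got[order(got$start), , drop = FALSE]
      rownames(got) <- NULL
      expect_equal(got, coldspot_oracle(pos, L, min_run, circ),
                   info = sprintf("L=%d npos=%d run=%d circ=%s",
                                  L, npos, min_run, circ))
    }
  }
})

test_that("per-gene densities count distinct alleles, split by class", {
  # two overlapping genes: variant in the overlap counts in both
  gn <- MitoGenome(paste(rep("ATGCTATAA", 20), collapse = ""),
                   data.frame(gene = c("p1", "t1"),
                              start = c(1, 82), end = c(90, 151),
                              strand = "+",
                              category = c("protein", "tRNA")))
  calls <- call_rows(c("m1", "m2", "m1"), "g", c(6, 6, 85),
                     hf = .2, genome = gn, alt = "G")
  co <- MitoCohort(calls)
  d <- variantDensityPerGene(co, gn)
  p1 <- d[d$gene == "p1", ]; t1 <- d[d$gene == "t1", ]
  # positions 6 and 85 hit p1; the (6,G) allele is shared by two animals
  # but counts once
  expect_equal(p1$n_variants, 2)
  expect_equal(p1$density, 2 / 90)
  expect_equal(t1$n_variants, 1)     # 85 in the overlap counts in t1 too
  expect_equal(t1$density, 1 / 70)
  # class split: pos 6 CTA->CTG synonymous; pos 85 in codon 29 (85,86,87)
  expect_equal(p1$density_synonymous * 90 +
                 p1$density_nonsynonymous * 90, 2)
  # gene with no variants has density 0
  gn2 <- MitoGenome("ACGTACGTAC",
                    data.frame(gene = "t", start = 1, end = 5,
                               strand = "+", category = "tRNA"))
  co2 <- MitoCohort(call_rows("m1", "g", 8, hf = .1, genome = gn2))
  expect_equal(variantDensityPerGene(co2, gn2)$density, 0)
})

test_that("group summaries report median, mode and p versus control", {
  vals <- setNames(c(1, 2, 3, 4, 1, 2, 3, 4, 11, 12, 13),
                   paste0("m", 1:11))
  roster <- data.frame(animal_id = paste0("m", 1:11),
                       group = rep(c("control", "same", "high"),
                                   c(4, 4, 3)))
  co <- MitoCohort(call_rows(roster$animal_id, roster$group, 1:11, hf = .2),
                   animals = roster, control = "control")
  gs <- groupSummary(vals, co)
  expect_equal(gs$median[gs$group == "control"], 2.5)
  expect_true(is.na(gs$p_vs_control[gs$group == "control"]))
  # identical to control -> tie-corrected p = 1
  expect_equal(gs$p_vs_control[gs$group == "same"], 1)
  # clearly separated n=3 vs n=4: exact p = 2/C(7,3)
  expect_equal(gs$p_vs_control[gs$group == "high"], 2 / choose(7, 3))
  expect_equal(attr(gs, "n_comparisons"), 2)
  # ordering invariance
  perm <- sample(length(vals))
  gs2 <- groupSummary(vals[perm], co)
  expect_equal(gs2, gs, ignore_attr = TRUE)
  expect_error(groupSummary(vals, `controlGroup<-`(co, "nope")))
})
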