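#' @include AllClasses.R AllGenerics.R
#' @importFrom stats density ecdf median rbinom rmultinom rpois sd
#'   shapiro.test wilcox.test setNames
NULL

#' One-dimensional Earth Mover's Distance (Wasserstein-1)
#'
#' Distance between the empirical distributions of two samples, with equal
#' mass on every point of a sample: the integral over the real line of the
#' absolute difference of the two empirical CDFs. For equal sample sizes
#' this reduces to the mean absolute difference of the sorted samples.
#'
#' @param a,b Non-empty numeric vectors (here: the heteroplasmic fractions
#'   of two animals' variants).
#' @return Non-negative scalar distance.
#' @examples
#' emd1d(c(0.1, 0.3), c(0.2, 0.4))  # 0.1
#' @export
emd1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("emd1d: empty sample")
  if (anyNA(a) || anyNA(b)) stop("emd1d: NA in sample")
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1L) return(0)
  # CDFs are step functions constant on [xs_i, xs_{i+1});
  # integrate |Fa - Fb| exactly over each piece
  Fa <- cumsum(tabulate(match(a, xs), length(xs))) / length(a)
  Fb <- cumsum(tabulate(match(b, xs), length(xs))) / length(b)
  k <- length(xs)
  sum(abs(Fa[-k] - Fb[-k]) * diff(xs))
}

#' Mean heteroplasmic fraction per animal
#'
#' Arithmetic mean of the HF over each animal's detected variants. Animals
#' with zero calls carry no HF information and are excluded (their count is
#' reported via \code{message()}).
#'
#' @param cohort A (filtered) [MitoCohort-class].
#' @return Named numeric vector, one mean HF per animal with >= 1 call.
#' @export
meanHfPerAnimal <- function(cohort) {
  calls <- cohortCalls(cohort)
  roster <- cohortAnimals(cohort)
  n_zero <- sum(!roster$animal_id %in% calls$animal_id)
  if (n_zero)
    message(n_zero, " animal(s) with zero calls excluded from HF summaries")
  if (!nrow(calls)) return(setNames(numeric(0), character(0)))
  out <- tapply(calls$hf, calls$animal_id, mean)
  setNames(as.numeric(out), names(out))
}

#' Mutational burden per animal
#'
#' Number of detected variants per animal; zero-call animals are included
#' with burden 0.
#'
#' @param cohort A (filtered) [MitoCohort-class].
#' @return Named integer vector over the full roster.
#' @export
mutationalBurden <- function(cohort) {
  roster <- cohortAnimals(cohort)
  calls <- cohortCalls(cohort)
  counts <- table(factor(calls$animal_id, levels = roster$animal_id))
  setNames(as.integer(counts), roster$animal_id)
}

#' Site-normalised nonsynonymous-to-synonymous ratio per animal
#'
#' For each animal, the number of nonsynonymous variants normalised to the
#' genome's possible nonsynonymous substitution sites, divided by the number
#' of synonymous variants normalised to the possible synonymous sites.
#' Ratios below 1 indicate purifying selection. Animals with zero synonymous
#' variants have an undefined ratio and are returned as \code{NA} (their
#' count is reported); animals with zero nonsynonymous but >= 1 synonymous
#' variants get ratio 0.
#'
#' @param cohort An annotated, filtered [MitoCohort-class] (see
#'   [annotateCohort()]).
#' @param site_counts A [SiteCounts-class] from the same genome.
#' @return Named numeric vector over the full roster (NA = undefined).
#' @export
nsRatio <- function(cohort, site_counts) {
  pN <- possibleNonsynonymous(site_counts)
  pS <- possibleSynonymous(site_counts)
  if (pN <= 0 || pS <= 0)
    stop("site counts must have positive possible N and S sites")
  calls <- cohortCalls(cohort)
  if (is.null(calls$functional_class))
    stop("cohort is not annotated; run annotateCohort() first")
  roster <- cohortAnimals(cohort)
  ids <- roster$animal_id
  nN <- table(factor(calls$animal_id[calls$functional_class ==
                                       "nonsynonymous"], levels = ids))
  nS <- table(factor(calls$animal_id[calls$functional_class ==
                                       "synonymous"], levels = ids))
  ratio <- ifelse(as.integer(nS) == 0L, NA_real_,
                  (as.integer(nN) / pN) / (as.integer(nS) / pS))
  n_undef <- sum(is.na(ratio))
  if (n_undef)
    message(n_undef, " animal(s) with undefined N/S ratio (0 synonymous ",
            "variants) excluded from group summaries")
  setNames(ratio, ids)
}

#' Modal value by Gaussian kernel density estimation
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth (unless overridden),
#' evaluated on a 512-point grid spanning [min - 3h, max + 3h]; returns the
#' grid argmax (first, i.e. smallest, on ties). Samples with a single value
#' or zero spread return that value.
#'
#' @param values Non-empty numeric vector.
#' @param bandwidth Numeric bandwidth, or \code{"silverman"} for the
#'   rule-of-thumb default.
#' @return The modal value.
#' @export
kdeMode <- function(values, bandwidth = "silverman") {
  if (!length(values)) stop("kdeMode: empty input")
  if (length(unique(values)) == 1L) return(values[[1L]])
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else as.numeric(bandwidth)
  d <- density(values, bw = bw, kernel = "gaussian", n = 512, cut = 3)
  d$x[which.max(d$y)]
}

#' Pairwise Earth Mover's Distances within a group
#'
#' [emd1d()] over every unordered pair of per-animal HF multisets in a
#' group. Animals with zero calls are excluded (and counted). The
#' alternative \code{mode = "pooled"} compares each animal against the
#' pooled HF distribution of the rest of the group instead.
#'
#' @param cohort A (filtered) [MitoCohort-class].
#' @param group Group label.
#' @param mode \code{"pairwise"} (default) or \code{"pooled"}.
#' @return Numeric vector of EMD values (length \code{n(n-1)/2} for
#'   \code{"pairwise"}, \code{n} for \code{"pooled"}).
#' @export
pairwiseEmd <- function(cohort, group, mode = c("pairwise", "pooled")) {
  mode <- match.arg(mode)
  calls <- cohortCalls(cohort)
  calls <- calls[calls$group == group, , drop = FALSE]
  hfs <- split(calls$hf, calls$animal_id)
  roster <- cohortAnimals(cohort)
  n_zero <- sum(roster$group == group) - length(hfs)
  if (n_zero)
    message(n_zero, " zero-call animal(s) in group '", group,
            "' excluded from EMD")
  n <- length(hfs)
  if (n < 2L)
    stop("group '", group, "' has fewer than 2 animals with calls")
  if (mode == "pairwise") {
    pairs <- utils::combn(n, 2L)
    apply(pairs, 2L, function(ij) emd1d(hfs[[ij[1L]]], hfs[[ij[2L]]]))
  } else {
    vapply(seq_len(n),
           function(i) emd1d(hfs[[i]], unlist(hfs[-i], use.names = FALSE)),
           numeric(1))
  }
}

#' Two-sided Wilcoxon rank-sum comparison against the control group
#'
#' Exact enumeration when both samples have at most 12 values and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction (the regime relevant for groups of ~30 animals).
#'
#' @param values_group,values_control Non-empty numeric vectors of a
#'   per-animal statistic.
#' @return Two-sided p-value.
#' @examples
#' compareToControl(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compareToControl <- function(values_group, values_control) {
  if (!length(values_group) || !length(values_control))
    stop("both samples must be non-empty")
  pooled <- c(values_group, values_control)
  if (all(pooled == pooled[1L])) return(1)  # fully tied: no shift detectable
  ties <- anyDuplicated(pooled) > 0L
  ex <- !ties && length(values_group) <= 12L && length(values_control) <= 12L
  suppressWarnings(
    wilcox.test(values_group, values_control, exact = ex,
                correct = TRUE)$p.value)
}

#' Shapiro-Wilk normality check
#'
#' Used to justify the choice of rank tests over parametric t tests in the
#' report narrative; zero-variance samples are degenerate and rejected.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with \code{statistic} and \code{p.value}.
#' @export
checkNormality <- function(values) {
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0)
    stop("zero-variance sample: normality test undefined")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}

#' Variant coldspots on the circular genome
#'
#' Maximal runs of consecutive positions carrying no variant in the whole
#' cohort, of length at least \code{min_run}. On the circular genome a run
#' may wrap the origin, in which case \code{end < start}.
#'
#' @param cohort A [MitoCohort-class].
#' @param genome The [MitoGenome-class].
#' @param min_run Minimum run length (default 9 positions).
#' @param circular Wrap runs across the origin (default TRUE).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive) and \code{length}.
#' @export
findColdspots <- function(cohort, genome, min_run = 9L, circular = TRUE) {
  L <- genomeLength(genome)
  pos <- sort(unique(cohortCalls(cohort)$position))
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (!length(pos)) {
    out <- data.frame(start = 1L, end = L, length = L)
    return(if (L >= min_run) out else empty)
  }
  k <- length(pos)
  if (circular) {
    nxt <- c(pos[-1L], pos[1L] + L)
    len <- nxt - pos - 1L
    out <- data.frame(start = (pos %% L) + 1L,
                      end = ((nxt - 2L) %% L) + 1L,
                      length = len)
  } else {
    starts <- c(1L, pos + 1L)
    ends <- c(pos - 1L, L)
    out <- data.frame(start = starts, end = ends,
                      length = ends - starts + 1L)
  }
  out <- out[out$length >= min_run, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant density per gene
#'
#' Distinct variant alleles (position, alt) overlapping each gene feature,
#' divided by the feature length in bases. A variant in a region where genes
#' overlap counts towards every overlapping gene. Protein-coding genes are
#' additionally split into synonymous and nonsynonymous densities (per-gene
#' classification, not the genome-level precedence class).
#'
#' @param cohort A (filtered) [MitoCohort-class].
#' @param genome The [MitoGenome-class].
#' @return data.frame with columns \code{gene}, \code{category},
#'   \code{length}, \code{n_variants}, \code{density} and, for protein
#'   genes, \code{density_synonymous} / \code{density_nonsynonymous}.
#' @export
variantDensityPerGene <- function(cohort, genome) {
  calls <- cohortCalls(cohort)
  uv <- unique(calls[, c("position", "alt"), drop = FALSE])
  ft <- geneFeatures(genome)
  chars <- .seq_chars(genome)
  rows <- lapply(seq_along(ft), function(i) {
    s <- start(ft)[i]; e <- end(ft)[i]
    w <- e - s + 1L
    inside <- uv[uv$position >= s & uv$position <= e, , drop = FALSE]
    cat_i <- mcols(ft)$category[i]
    row <- data.frame(gene = mcols(ft)$gene[i], category = cat_i,
                      length = w, n_variants = nrow(inside),
                      density = nrow(inside) / w,
                      density_synonymous = NA_real_,
                      density_nonsynonymous = NA_real_,
                      stringsAsFactors = FALSE)
    if (cat_i == "protein") {
      cls <- vapply(seq_len(nrow(inside)), function(j)
        .classify_in_protein(chars, s, e, as.character(strand(ft)[i]),
                             inside$position[j], inside$alt[j]),
        character(1))
      row$density_synonymous <- sum(cls == "synonymous", na.rm = TRUE) / w
      row$density_nonsynonymous <-
        sum(cls == "nonsynonymous", na.rm = TRUE) / w
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), category = character(0),
                      length = integer(0), n_variants = integer(0),
                      density = numeric(0),
                      density_synonymous = numeric(0),
                      density_nonsynonymous = numeric(0))
  rownames(out) <- NULL
  out
}

#' Per-group median, mode and rank-test p-value of a per-animal statistic
#'
#' For each group: the median, the KDE mode ([kdeMode()]) and, for
#' non-control groups, the two-sided Wilcoxon rank-sum p-value against the
#' control group ([compareToControl()]). No multiple-testing correction is
#' applied; the number of comparisons is returned so the report can state
#' it.
#'
#' @param values Named numeric vector of a per-animal statistic (names =
#'   animal ids); \code{NA} values (e.g. undefined N/S ratios) are dropped.
#' @param cohort The [MitoCohort-class] supplying group membership and the
#'   control label.
#' @param bandwidth Passed to [kdeMode()].
#' @return data.frame with columns \code{group}, \code{n}, \code{median},
#'   \code{mode}, \code{p_vs_control} (NA for the control group); attribute
#'   \code{n_comparisons} gives the number of uncorrected tests.
#' @export
groupSummary <- function(values, cohort, bandwidth = "silverman") {
  roster <- cohortAnimals(cohort)
  control <- controlGroup(cohort)
  groups <- groupLabels(cohort)
  if (!control %in% groups) stop("unknown control group '", control, "'")
  grp <- roster$group[match(names(values), roster$animal_id)]
  keep <- !is.na(values) & !is.na(grp)
  values <- values[keep]; grp <- grp[keep]
  ctrl_vals <- values[grp == control]
  rows <- lapply(groups, function(g) {
    v <- values[grp == g]
    if (!length(v))
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        mode = NA_real_, p_vs_control = NA_real_))
    p <- if (g == control || !length(ctrl_vals)) NA_real_
         else compareToControl(v, ctrl_vals)
    data.frame(group = g, n = length(v), median = median(v),
               mode = kdeMode(v, bandwidth), p_vs_control = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- sum(!is.na(out$p_vs_control))
  out
}

#' All per-animal and per-group statistics for a cohort
#'
#' One call computing everything the report needs: per-animal mean HF,
#' burden and N/S ratio; per-group summaries (median / KDE mode / Wilcoxon p
#' versus control) of mean HF, pairwise EMD, burden and N/S ratio; coldspot
#' intervals; per-gene variant densities.
#'
#' @param cohort A filtered [MitoCohort-class] (annotated, or it will be
#'   annotated here).
#' @param genome The [MitoGenome-class].
#' @param bandwidth KDE bandwidth for modes (default Silverman).
#' @param min_run Coldspot minimum run length (default 9).
#' @param emd_mode \code{"pairwise"} or \code{"pooled"}, see
#'   [pairwiseEmd()].
#' @return List with elements \code{per_animal} (data.frame),
#'   \code{group_summary} (data.frame, column \code{statistic} in
#'   \{mean_hf, emd, burden, ns_ratio\}), \code{emd} (named list of
#'   per-group EMD vectors), \code{coldspots}, \code{gene_density},
#'   \code{site_counts}, \code{n_comparisons}.
#' @export
cohortStatistics <- function(cohort, genome, bandwidth = "silverman",
                             min_run = 9L,
                             emd_mode = c("pairwise", "pooled")) {
  emd_mode <- match.arg(emd_mode)
  calls <- cohortCalls(cohort)
  if (is.null(calls$functional_class))
    cohort <- annotateCohort(cohort, genome)
  site_counts <- countPossibleSites(genome)
  mean_hf <- meanHfPerAnimal(cohort)
  burden <- mutationalBurden(cohort)
  nsr <- nsRatio(cohort, site_counts)
  roster <- cohortAnimals(cohort)
  per_animal <- data.frame(
    animal_id = roster$animal_id, group = roster$group,
    mean_hf = as.numeric(mean_hf[roster$animal_id]),
    burden = as.integer(burden[roster$animal_id]),
    ns_ratio = as.numeric(nsr[roster$animal_id]))
  emd <- lapply(setNames(groupLabels(cohort), groupLabels(cohort)),
                function(g) {
                  tryCatch(pairwiseEmd(cohort, g, emd_mode),
                           error = function(e) {
                             message("EMD skipped for group '", g, "': ",
                                     conditionMessage(e))
                             numeric(0)
                           })
                })
  # EMD values are per pair, not per animal; summarise per group directly
  control <- controlGroup(cohort)
  emd_rows <- lapply(groupLabels(cohort), function(g) {
    v <- emd[[g]]
    if (!length(v))
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        mode = NA_real_, p_vs_control = NA_real_))
    p <- if (g == control || !length(emd[[control]])) NA_real_
         else compareToControl(v, emd[[control]])
    data.frame(group = g, n = length(v), median = median(v),
               mode = kdeMode(v, bandwidth), p_vs_control = p)
  })
  emd_summary <- do.call(rbind, emd_rows)
  summaries <- rbind(
    cbind(statistic = "mean_hf", groupSummary(mean_hf, cohort, bandwidth)),
    cbind(statistic = "emd", emd_summary),
    cbind(statistic = "burden",
          groupSummary(setNames(as.numeric(burden), names(burden)),
                       cohort, bandwidth)),
    cbind(statistic = "ns_ratio", groupSummary(nsr, cohort, bandwidth)))
  rownames(summaries) <- NULL
  n_comp <- sum(!is.na(summaries$p_vs_control))
  list(per_animal = per_animal, group_summary = summaries, emd = emd,
       coldspots = findColdspots(cohort, genome, min_run),
       gene_density = variantDensityPerGene(cohort, genome),
       site_counts = site_counts, n_comparisons = n_comp)
}
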