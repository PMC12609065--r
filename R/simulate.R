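#' @include AllClasses.R AllGenerics.R reference.R
NULL

#' SimulationConfig: parameters of the germline transmission simulator
#'
#' Bottleneck, selection, turnover and mutation parameters for
#' [simulateCohort()]. The simulator models de novo mtDNA mutation in a
#' mutator founder generation followed by maternal transmission through an
#' effective Wright-Fisher bottleneck with class-dependent purifying
#' selection and autophagy-like turnover.
#'
#' @slot bottleneckSize Effective number of segregating mtDNA units sampled
#'   per binomial resampling round (the bottleneck size N_b).
#' @slot segregationRounds Binomial resampling rounds per generation (g).
#' @slot turnover Multiplier tau on g modelling bulk autophagic turnover;
#'   effective rounds per generation are \code{round(g * tau)} and selection
#'   coefficients are scaled by tau (impaired bulk turnover both limits
#'   segregation and compromises selection).
#' @slot selection Named numeric: per-class removal coefficient s in [0, 1);
#'   synonymous and noncoding variants are neutral (s = 0) by model
#'   structure.
#' @slot selectionThreshold HF above which selective removal acts (theta);
#'   below it a deleterious variant drifts neutrally.
#' @slot founderCopyNumber mtDNA copies at mutation time (C0); each de novo
#'   variant starts at HF = 1/C0.
#' @slot mutationRate Expected de novo variants per founder lineage
#'   (Poisson lambda).
#' @slot generations Transmission depth (default 3: F0 -> N1 -> N2 -> N3).
#' @slot detectionThreshold Final-HF reporting floor (default 0.01).
#' @slot litterSize Pups per litter; littermates share their dam's lineage
#'   state, reproducing the within-litter correlation of real cohorts.
#' @slot includeFixed Report fixed (HF = 1) variants, capped at 1? Default
#'   FALSE: a fixed variant is indistinguishable from the reference in
#'   resequencing.
#' @slot cohortSizes Named numeric: animals per group (defaults
#'   32/32/31/34/32 over the five preset groups).
#' @slot groupPresets Named list of per-group parameter overrides, see
#'   [presetGroups()].
#' @slot seed Integer seed; the cohort is a pure function of (config,
#'   genome, seed).
#' @export
setClass("SimulationConfig",
  representation(bottleneckSize = "numeric", segregationRounds = "numeric",
                 turnover = "numeric", selection = "numeric",
                 selectionThreshold = "numeric",
                 founderCopyNumber = "numeric", mutationRate = "numeric",
                 generations = "numeric", detectionThreshold = "numeric",
                 litterSize = "numeric", includeFixed = "logical",
                 cohortSizes = "numeric", groupPresets = "list",
                 seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@bottleneckSize < 1) msg <- c(msg, "bottleneckSize must be >= 1")
  if (object@segregationRounds < 1)
    msg <- c(msg, "segregationRounds must be >= 1")
  if (object@turnover <= 0) msg <- c(msg, "turnover must be > 0")
  if (!all(FUNCTIONAL_CLASSES %in% names(object@selection)))
    msg <- c(msg, sprintf("selection needs coefficients for all classes: %s",
                          paste(FUNCTIONAL_CLASSES, collapse = ", ")))
  else {
    if (any(object@selection < 0 | object@selection >= 1))
      msg <- c(msg, "selection coefficients must lie in [0, 1)")
    if (any(object@selection[c("synonymous", "noncoding")] != 0))
      msg <- c(msg, "synonymous and noncoding variants are neutral (s = 0)")
  }
  if (object@selectionThreshold <= 0 || object@selectionThreshold >= 1)
    msg <- c(msg, "selectionThreshold must lie in (0, 1)")
  if (object@founderCopyNumber < 1)
    msg <- c(msg, "founderCopyNumber must be >= 1")
  if (object@mutationRate < 0) msg <- c(msg, "mutationRate must be >= 0")
  if (object@generations < 1) msg <- c(msg, "generations must be >= 1")
  if (object@detectionThreshold < 0 || object@detectionThreshold > 1)
    msg <- c(msg, "detectionThreshold must lie in [0, 1]")
  if (object@litterSize < 1) msg <- c(msg, "litterSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Preset parameter overrides for the five study-design group archetypes
#'
#' Named list of per-group overrides applied on top of the base
#' [SimulationConfig()]:
#' \describe{
#'   \item{control}{baseline bottleneck, turnover and selection.}
#'   \item{tfam_het}{reduced mtDNA copy number: a more stringent bottleneck
#'     (\code{bottleneckSize} halved).}
#'   \item{tfam_oe}{increased copy number: a wider bottleneck
#'     (\code{bottleneckSize} doubled).}
#'   \item{bcl2l13_ko}{selective mitophagy disabled: all selection
#'     coefficients 0.}
#'   \item{ulk2_ko}{bulk autophagy impaired: \code{turnover} < 1, which both
#'     reduces the effective resampling rounds and scales the selection
#'     coefficients down.}
#' }
#' The numeric values are package defaults chosen to give clearly separated
#' regimes; they are not measurements of any real genotype.
#'
#' @param base_bottleneck Control-group bottleneck size the Tfam presets
#'   scale from.
#' @return Named list of override lists.
#' @export
presetGroups <- function(base_bottleneck = 50) {
  list(
    control = list(),
    tfam_het = list(bottleneckSize = base_bottleneck / 2),
    tfam_oe = list(bottleneckSize = base_bottleneck * 2),
    bcl2l13_ko = list(selection = c(synonymous = 0, nonsynonymous = 0,
                                    tRNA = 0, rRNA = 0, noncoding = 0)),
    ulk2_ko = list(turnover = 0.5))
}

#' Construct a SimulationConfig
#'
#' Defaults emulate an N3 mutator-mouse cohort: five groups of
#' 32/32/31/34/32 animals, three transmission generations, founder variants
#' at HF 1/64, a 50-unit control bottleneck with 10 resampling rounds per
#' generation, and purifying selection on nonsynonymous and tRNA (and, more
#' weakly, rRNA) variants once they exceed 25\% HF. See the package
#' vignette for the rationale behind each default.
#'
#' @param bottleneckSize,segregationRounds,turnover,selection,
#'   selectionThreshold,founderCopyNumber,mutationRate,generations,
#'   detectionThreshold,litterSize,includeFixed,cohortSizes,groupPresets,
#'   seed See [SimulationConfig-class].
#' @return A validated [SimulationConfig-class].
#' @export
SimulationConfig <- function(bottleneckSize = 50,
                             segregationRounds = 10,
                             turnover = 1,
                             selection = c(synonymous = 0,
                                           nonsynonymous = 0.6,
                                           tRNA = 0.6, rRNA = 0.2,
                                           noncoding = 0),
                             selectionThreshold = 0.25,
                             founderCopyNumber = 64,
                             mutationRate = 900,
                             generations = 3,
                             detectionThreshold = 0.01,
                             litterSize = 4,
                             includeFixed = FALSE,
                             cohortSizes = c(control = 32, tfam_het = 32,
                                             tfam_oe = 31, bcl2l13_ko = 34,
                                             ulk2_ko = 32),
                             groupPresets = presetGroups(bottleneckSize),
                             seed = 1) {
  new("SimulationConfig", bottleneckSize = bottleneckSize,
      segregationRounds = segregationRounds, turnover = turnover,
      selection = selection, selectionThreshold = selectionThreshold,
      founderCopyNumber = founderCopyNumber, mutationRate = mutationRate,
      generations = generations, detectionThreshold = detectionThreshold,
      litterSize = litterSize, includeFixed = includeFixed,
      cohortSizes = cohortSizes, groupPresets = groupPresets, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: N_b=%g, g=%g, tau=%g, theta=%g, C0=%g, lambda=%g,\n",
    "  %g generations, detection > %g, litter size %g, seed %g\n"),
    object@bottleneckSize, object@segregationRounds, object@turnover,
    object@selectionThreshold, object@founderCopyNumber,
    object@mutationRate, object@generations, object@detectionThreshold,
    object@litterSize, object@seed))
  cat("  selection:",
      paste(sprintf("%s=%g", names(object@selection), object@selection),
            collapse = ", "), "\n")
  cat("  cohort:",
      paste(sprintf("%s=%g", names(object@cohortSizes), object@cohortSizes),
            collapse = ", "), "\n")
})

# Merge the base config with a group's preset overrides and fold the
# turnover factor into effective rounds and selection strength.
resolveGroupConfig <- function(config, group) {
  preset <- config@groupPresets[[group]]
  if (is.null(preset))
    stop("no preset for group '", group, "'")
  g <- list(bottleneckSize = config@bottleneckSize,
            segregationRounds = config@segregationRounds,
            turnover = config@turnover,
            selection = config@selection,
            selectionThreshold = config@selectionThreshold,
            founderCopyNumber = config@founderCopyNumber,
            mutationRate = config@mutationRate,
            generations = config@generations,
            detectionThreshold = config@detectionThreshold)
  g[names(preset)] <- preset
  g$rounds <- max(1L, as.integer(round(g$segregationRounds * g$turnover)))
  g$selection_eff <- g$selection * g$turnover
  g
}

#' Wright-Fisher segregation of a heteroplasmic variant
#'
#' Iterates binomial resampling of the variant allele among \code{N}
#' segregating units for \code{rounds} rounds. When \code{s > 0} and the
#' current frequency exceeds \code{theta}, the sampling probability is
#' deflated to \code{p(1-s) / (1 - p s)} before the draw (selective-removal
#' step); below the threshold the variant drifts neutrally. Vectorised over
#' variants: \code{p0} and \code{s} may be vectors.
#'
#' Uses R's global random number generator; call \code{set.seed()} first for
#' reproducibility.
#'
#' @param p0 Initial frequency (vector allowed), in [0, 1].
#' @param N Number of segregating units (bottleneck size), >= 1.
#' @param rounds Number of binomial resampling rounds.
#' @param s Selection (removal) coefficient in [0, 1), recycled over
#'   \code{p0}.
#' @param theta HF threshold above which selection acts.
#' @return Vector of final frequencies in \{0, 1/N, ..., 1\}.
#' @examples
#' set.seed(1)
#' mean(segregateWrightFisher(rep(0.2, 1000), N = 100, rounds = 10))
#' @export
segregateWrightFisher <- function(p0, N, rounds, s = 0, theta = 0.25) {
  stopifnot(all(p0 >= 0 & p0 <= 1), N >= 1, rounds >= 0)
  p <- p0
  s <- rep_len(s, length(p))
  sel <- s > 0
  for (r in seq_len(rounds)) {
    psel <- p
    act <- sel & p > theta
    if (any(act))
      psel[act] <- p[act] * (1 - s[act]) / (1 - p[act] * s[act])
    p <- stats::rbinom(length(p), N, psel) / N
  }
  p
}

#' Draw de novo founder variants
#'
#' Poisson(\code{lambda}) variants at positions uniform over the genome
#' (unique within the lineage), alternate allele uniform over the three
#' non-reference bases, each classified via the genome's substitution table
#' and starting at HF = 1 / \code{founder_copy_number} (one mutant molecule
#' among C0 copies).
#'
#' @param genome A [MitoGenome-class].
#' @param lambda Expected number of de novo variants.
#' @param founder_copy_number C0, mtDNA copies at mutation time.
#' @param class_table Optional precomputed classification table (internal
#'   speed-up for repeated calls).
#' @return data.frame with columns \code{position}, \code{ref}, \code{alt},
#'   \code{hf}, \code{functional_class}.
#' @export
drawDeNovoVariants <- function(genome, lambda, founder_copy_number,
                               class_table = NULL) {
  L <- genomeLength(genome)
  n <- stats::rpois(1L, lambda)
  n <- min(n, L)
  if (n == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), hf = numeric(0),
                      functional_class = character(0)))
  if (is.null(class_table)) class_table <- classificationTable(genome)
  chars <- .seq_chars(genome)
  pos <- sort(sample.int(L, n))
  ref <- chars[pos]
  bases <- c("A", "C", "G", "T")
  # uniform over the 3 non-reference bases
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  data.frame(position = pos, ref = ref, alt = alt,
             hf = 1 / founder_copy_number,
             functional_class = class_table[cbind(pos, match(alt, bases))],
             stringsAsFactors = FALSE)
}

# Evolve founder variants through n_gen generations for one lineage.
.evolve <- function(hf, classes, params, n_gen) {
  if (!length(hf) || n_gen == 0L) return(hf)
  s <- unname(params$selection_eff[classes])
  for (gen in seq_len(n_gen))
    hf <- segregateWrightFisher(hf, params$bottleneckSize, params$rounds,
                                s, params$selectionThreshold)
  hf
}

.report_calls <- function(variants, hf, animal_id, group, params,
                          include_fixed, report_all = FALSE) {
  if (report_all) {
    keep <- rep(TRUE, length(hf))
  } else {
    keep <- hf > params$detectionThreshold &
      (if (include_fixed) TRUE else hf < 1)
  }
  out <- variants[keep, , drop = FALSE]
  out$hf <- pmin(hf[keep], 1)
  if (nrow(out)) {
    out <- cbind(animal_id = animal_id, group = group, out,
                 stringsAsFactors = FALSE)
  } else {
    out <- data.frame(animal_id = character(0), group = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), hf = numeric(0),
                      functional_class = character(0))
  }
  rownames(out) <- NULL
  out[, c("animal_id", "group", "position", "ref", "alt", "hf",
          "functional_class")]
}

#' Simulate one animal's variant calls
#'
#' Draws de novo founder variants for one maternal lineage and evolves each
#' variant's HF independently through the configured number of generations,
#' each generation applying [segregateWrightFisher()] with the group's
#' effective rounds and class-specific selection. Variants with final HF
#' above the detection threshold (and below 1, unless \code{includeFixed})
#' are reported as calls. Uses the global RNG; seed externally.
#'
#' @param config A [SimulationConfig-class].
#' @param genome A [MitoGenome-class].
#' @param group Group label (must have a preset); default \code{"control"}.
#' @param animal_id Identifier for the call rows.
#' @param class_table Optional precomputed classification table.
#' @param report \code{"detected"} (default) applies the detection window;
#'   \code{"all"} returns every founder variant with its uncensored final
#'   HF, including lost (0) and fixed (1) ones.
#' @return data.frame of calls (columns as in [MitoCohort-class] plus
#'   \code{functional_class}).
#' @export
simulateAnimal <- function(config, genome, group = "control",
                           animal_id = "sim1", class_table = NULL,
                           report = c("detected", "all")) {
  report <- match.arg(report)
  params <- resolveGroupConfig(config, group)
  vars <- drawDeNovoVariants(genome, params$mutationRate,
                             params$founderCopyNumber, class_table)
  hf <- .evolve(vars$hf, vars$functional_class, params,
                as.integer(params$generations))
  .report_calls(vars, hf, animal_id, group, params, config@includeFixed,
                report_all = report == "all")
}

#' Simulate a full cohort
#'
#' Generates the configured number of animals per group. Animals are
#' organised into litters of \code{litterSize}; littermates share one
#' maternal lineage: the founder's de novo variants are segregated through
#' \code{generations - 1} shared generations to their dam's state, and each
#' pup then receives one further, independent transmission. This reproduces
#' the within-litter correlation (non-independence of pups) that rank tests
#' on such cohorts do not account for.
#'
#' @param config A [SimulationConfig-class]; \code{config@seed} makes the
#'   cohort a pure function of (config, genome).
#' @param genome A [MitoGenome-class].
#' @return An annotated [MitoCohort-class] with
#'   \code{cohortMetadata(x)$config} recording the resolved configuration.
#' @examples
#' gn <- buildFixtureGenome(7, 2000, data.frame(
#'   category = c("protein", "tRNA"), length = c(900, 70),
#'   strand = "+"))
#' cfg <- SimulationConfig(cohortSizes = c(control = 4, ulk2_ko = 4),
#'   mutationRate = 50, seed = 11)
#' simulateCohort(cfg, gn)
#' @export
simulateCohort <- function(config, genome) {
  validObject(config)
  set.seed(as.integer(config@seed))
  class_table <- classificationTable(genome)
  groups <- names(config@cohortSizes)
  missing_presets <- setdiff(groups, names(config@groupPresets))
  if (length(missing_presets))
    stop("no preset for group(s): ",
         paste(missing_presets, collapse = ", "))
  all_calls <- list()
  roster <- list()
  for (grp in groups) {
    params <- resolveGroupConfig(config, grp)
    n <- as.integer(config@cohortSizes[[grp]])
    litter <- ceiling(seq_len(n) / config@litterSize)
    ids <- sprintf("%s_%03d", grp, seq_len(n))
    roster[[grp]] <- data.frame(animal_id = ids, group = grp,
                                litter = paste0(grp, "_L", litter),
                                stringsAsFactors = FALSE)
    shared_gens <- as.integer(params$generations) - 1L
    for (lt in unique(litter)) {
      vars <- drawDeNovoVariants(genome, params$mutationRate,
                                 params$founderCopyNumber, class_table)
      dam_hf <- .evolve(vars$hf, vars$functional_class, params, shared_gens)
      for (i in which(litter == lt)) {
        hf <- .evolve(dam_hf, vars$functional_class, params, 1L)
        all_calls[[length(all_calls) + 1L]] <-
          .report_calls(vars, hf, ids[i], grp, params, config@includeFixed)
      }
    }
  }
  calls <- do.call(rbind, all_calls)
  roster <- do.call(rbind, roster)
  cohort <- MitoCohort(calls, animals = roster[, c("animal_id", "group")],
                       groups = groups, control = groups[1L],
                       metadata = list(config = config,
                                       litters = roster$litter))
  message("simulated ", nrow(calls), " calls for ", nAnimals(cohort),
          " animals in ", length(groups), " groups")
  cohort
}
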