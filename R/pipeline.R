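#' @include AllClasses.R AllGenerics.R reference.R io.R filters.R stats.R
#'   simulate.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full heteroplasmy analysis pipeline
#'
#' simulate/read -> annotate -> filter -> statistics -> report, as one
#' reproducible run. Writes the report TSVs ([writeReport()]) plus a
#' \code{provenance.yaml} recording every option and the seed; on error,
#' partial outputs are removed.
#'
#' @param out_dir Output directory for the report bundle.
#' @param input \code{"simulate"} (default), \code{"tsv"} or \code{"vcf"}.
#' @param genome A [MitoGenome-class]; default a mouse-like fixture genome
#'   built with \code{genome_seed}.
#' @param genome_seed Seed for the fixture genome (ignored when
#'   \code{genome} is supplied).
#' @param sim_config [SimulationConfig-class] for \code{input = "simulate"};
#'   default \code{SimulationConfig(seed = seed)}.
#' @param variant_table TSV path for \code{input = "tsv"}.
#' @param hf_unit HF unit of the TSV, see [readVariantTable()].
#' @param vcf_paths,vcf_ids,vcf_groups,af_field Inputs for
#'   \code{input = "vcf"}, see [readVcfCohort()].
#' @param control Control-group label (default: the cohort's).
#' @param hf_min,recurrence_max,filter_order Filter options, see
#'   [filterVariants()].
#' @param bandwidth,min_run,emd_mode Statistics options, see
#'   [cohortStatistics()].
#' @param seed Master seed; seeds the simulator when \code{sim_config} is
#'   not supplied, and is recorded in the provenance file.
#' @return Invisibly, a list with the filtered \code{cohort}, the
#'   \code{genome}, the [cohortStatistics()] result and the report
#'   \code{files}.
#' @export
runPipeline <- function(out_dir,
                        input = c("simulate", "tsv", "vcf"),
                        genome = NULL, genome_seed = 101,
                        sim_config = NULL,
                        variant_table = NULL,
                        hf_unit = "fraction",
                        vcf_paths = NULL, vcf_ids = NULL, vcf_groups = NULL,
                        af_field = "AF",
                        control = NULL,
                        hf_min = 0.01, recurrence_max = 26,
                        filter_order = "hf_first",
                        bandwidth = "silverman", min_run = 9L,
                        emd_mode = "pairwise",
                        seed = 1) {
  input <- match.arg(input)
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) {
    unlink(file.path(out_dir, c("per_animal.tsv", "group_summary.tsv",
                                "coldspots.tsv", "gene_density.tsv",
                                "provenance.yaml")))
    if (created) unlink(out_dir, recursive = TRUE)
  })
  if (is.null(genome))
    genome <- .stage("genome", buildFixtureGenome(genome_seed, 16299))
  cohort <- switch(input,
    simulate = .stage("simulate", {
      if (is.null(sim_config)) sim_config <- SimulationConfig(seed = seed)
      simulateCohort(sim_config, genome)
    }),
    tsv = .stage("read", readVariantTable(variant_table, hf_unit)),
    vcf = .stage("read", readVcfCohort(vcf_paths, vcf_ids, vcf_groups,
                                       af_field)))
  if (!is.null(control)) controlGroup(cohort) <- control
  cohort <- .stage("annotate", annotateCohort(cohort, genome))
  cohort <- .stage("filter",
                   filterVariants(cohort, hf_min, recurrence_max,
                                  order = filter_order))
  stats <- .stage("stats",
                  cohortStatistics(cohort, genome, bandwidth, min_run,
                                   emd_mode))
  files <- .stage("report", writeReport(stats, out_dir))
  prov <- list(
    input = input, seed = seed, genome_length = genomeLength(genome),
    control = controlGroup(cohort),
    filters = list(hf_min = hf_min, recurrence_max = recurrence_max,
                   order = filter_order),
    stats = list(bandwidth = as.character(bandwidth),
                 min_run = as.integer(min_run), emd_mode = emd_mode,
                 n_uncorrected_comparisons = stats$n_comparisons),
    counts = list(calls = nrow(cohortCalls(cohort)),
                  animals = nAnimals(cohort)))
  if (input == "simulate")
    prov$simulation <- list(
      bottleneckSize = sim_config@bottleneckSize,
      segregationRounds = sim_config@segregationRounds,
      turnover = sim_config@turnover,
      selection = as.list(sim_config@selection),
      selectionThreshold = sim_config@selectionThreshold,
      founderCopyNumber = sim_config@founderCopyNumber,
      mutationRate = sim_config@mutationRate,
      generations = sim_config@generations,
      detectionThreshold = sim_config@detectionThreshold,
      litterSize = sim_config@litterSize,
      cohortSizes = as.list(sim_config@cohortSizes),
      seed = sim_config@seed)
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  ok <- TRUE
  invisible(list(cohort = cohort, genome = genome, stats = stats,
                 files = c(files,
                           provenance = file.path(out_dir,
                                                  "provenance.yaml"))))
}
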