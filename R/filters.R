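#' @include AllClasses.R AllGenerics.R
NULL

#' Heteroplasmic-fraction threshold filter
#'
#' Retains calls whose heteroplasmic fraction is strictly greater than
#' \code{hf_min}. The animal roster is unchanged: an animal whose calls are
#' all removed stays in the cohort with burden 0.
#'
#' @param cohort A [MitoCohort-class].
#' @param hf_min Threshold on the fraction scale (default 0.01, i.e.
#'   "HF > 1%"; comparison is strict).
#' @return The filtered [MitoCohort-class]; the removal count is appended to
#'   the metadata and reported via \code{message()}.
#' @export
applyHfThreshold <- function(cohort, hf_min = 0.01) {
  stopifnot(hf_min >= 0, hf_min < 1)
  calls <- cohortCalls(cohort)
  keep <- calls$hf > hf_min
  message("HF filter (> ", hf_min, "): removed ", sum(!keep), " of ",
          nrow(calls), " calls")
  md <- cohort@metadata
  md$hf_filter <- list(hf_min = hf_min, removed = sum(!keep),
                       kept = sum(keep))
  initialize(cohort, calls = calls[keep, , drop = FALSE], metadata = md)
}

#' Recurrence filter for inherited (non-de-novo) variants
#'
#' For each distinct variant allele (position, alt), counts the distinct
#' animals carrying it; alleles carried by \code{recurrence_max} or more
#' animals are removed entirely ("observed in fewer than
#' \code{recurrence_max} animals" is the keep rule), on the rationale that
#' such shared variants were inherited from a subline rather than generated
#' de novo.
#'
#' @param cohort A [MitoCohort-class].
#' @param recurrence_max Carrier-count cutoff (default 26; keep alleles with
#'   at most 25 carriers).
#' @param recurrence_frac Optional alternative: cutoff as a fraction of the
#'   roster size (overrides \code{recurrence_max} with
#'   \code{ceiling(frac * nAnimals)}).
#' @return The filtered [MitoCohort-class].
#' @export
applyRecurrenceFilter <- function(cohort, recurrence_max = 26,
                                  recurrence_frac = NULL) {
  if (!is.null(recurrence_frac))
    recurrence_max <- ceiling(recurrence_frac * nAnimals(cohort))
  stopifnot(recurrence_max >= 1)
  calls <- cohortCalls(cohort)
  if (nrow(calls)) {
    allele <- paste(calls$position, calls$alt)
    carriers <- tapply(calls$animal_id, allele,
                       function(a) length(unique(a)))
    keep <- carriers[allele] < recurrence_max
  } else keep <- logical(0)
  message("recurrence filter (< ", recurrence_max, " carriers): removed ",
          sum(!keep), " of ", nrow(calls), " calls")
  md <- cohort@metadata
  md$recurrence_filter <- list(recurrence_max = recurrence_max,
                               removed = sum(!keep), kept = sum(keep))
  initialize(cohort, calls = calls[keep, , drop = FALSE], metadata = md)
}

#' Apply the cohort variant inclusion rules
#'
#' Composition of [applyHfThreshold()] and [applyRecurrenceFilter()]. By
#' default the HF threshold is applied first, so recurrence is counted on
#' the analysed (HF-passing) calls; the order can be swapped.
#'
#' @param cohort A [MitoCohort-class].
#' @param hf_min HF threshold (strict \code{>}), default 0.01.
#' @param recurrence_max Carrier cutoff (strict \code{<}), default 26.
#' @param recurrence_frac Optional fractional cutoff, see
#'   [applyRecurrenceFilter()].
#' @param order \code{"hf_first"} (default) or \code{"recurrence_first"}.
#' @return The filtered [MitoCohort-class].
#' @examples
#' calls <- data.frame(animal_id = c("m1", "m1"), group = "control",
#'   position = c(10L, 20L), ref = "A", alt = "G", hf = c(0.011, 0.010))
#' filterVariants(MitoCohort(calls))  # keeps only the hf = 0.011 call
#' @export
filterVariants <- function(cohort, hf_min = 0.01, recurrence_max = 26,
                           recurrence_frac = NULL,
                           order = c("hf_first", "recurrence_first")) {
  order <- match.arg(order)
  if (order == "hf_first") {
    cohort <- applyHfThreshold(cohort, hf_min)
    applyRecurrenceFilter(cohort, recurrence_max, recurrence_frac)
  } else {
    cohort <- applyRecurrenceFilter(cohort, recurrence_max, recurrence_frac)
    applyHfThreshold(cohort, hf_min)
  }
}
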