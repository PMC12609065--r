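#' @include AllClasses.R AllGenerics.R
#' @importFrom utils read.table write.table head
NULL

#' Read a cohort variant table (TSV)
#'
#' Reads the tab-separated variant-call dialect with header columns
#' \code{animal_id}, \code{group}, \code{position}, \code{ref}, \code{alt},
#' \code{hf}. Heteroplasmic fractions are stored internally on the (0, 1]
#' fraction scale; tables recorded in percent are converted with
#' \code{hf_unit = "percent"}.
#'
#' @param path Path to the TSV file.
#' @param hf_unit \code{"fraction"} (default) or \code{"percent"}.
#' @param animals Optional roster data.frame (\code{animal_id},
#'   \code{group}) listing zero-call animals as well; defaults to the
#'   animals seen in the calls.
#' @param groups,control Passed to [MitoCohort()].
#' @return A [MitoCohort-class]; \code{metadata(x)$rows_read} records the
#'   row count.
#' @export
readVariantTable <- function(path, hf_unit = c("fraction", "percent"),
                             animals = NULL, groups = NULL, control = NULL) {
  hf_unit <- match.arg(hf_unit)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(CALL_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("variant table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$position <- as.integer(tab$position)
  tab$hf <- as.numeric(tab$hf)
  if (hf_unit == "percent") tab$hf <- tab$hf / 100
  bad <- which(!is.finite(tab$hf) | tab$hf <= 0 | tab$hf > 1)
  if (length(bad))
    stop("hf outside (0, 1] (after unit conversion) at row(s) ",
         paste(head(bad, 5L), collapse = ", "), " of ", path)
  dup <- which(duplicated(paste(tab$animal_id, tab$position, tab$alt)))
  if (length(dup))
    stop("duplicate (animal_id, position, alt) at row(s) ",
         paste(head(dup, 5L), collapse = ", "), " of ", path)
  cohort <- MitoCohort(tab, animals = animals, groups = groups,
                       control = control,
                       metadata = list(rows_read = nrow(tab), source = path))
  message("read ", nrow(tab), " calls for ", nAnimals(cohort),
          " animals from ", path)
  cohort
}

#' Write a cohort variant table (TSV)
#'
#' Inverse of [readVariantTable()]: hf is written with 17 significant digits
#' so a write/read round trip reproduces the numeric values exactly.
#'
#' @param cohort A [MitoCohort-class].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(cohort, path) {
  calls <- cohortCalls(cohort)[, CALL_COLUMNS, drop = FALSE]
  calls$hf <- formatC(calls$hf, digits = 17, format = "g")
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from per-animal VCF files
#'
#' Each VCF holds the calls of one animal (single sample). Only
#' single-nucleotide substitutions are kept; multi-allelic records are split
#' into one call per alternate allele; indel records are skipped and
#' counted. The heteroplasmic fraction is taken from \code{af_field} in the
#' INFO or FORMAT section.
#'
#' @param paths Character vector of VCF paths, one per animal.
#' @param animal_ids Animal identifiers, parallel to \code{paths}.
#' @param group Group labels, parallel to \code{paths} (recycled).
#' @param af_field Name of the allele-frequency field (default \code{"AF"}).
#' @param groups,control Passed to [MitoCohort()].
#' @return A [MitoCohort-class]; \code{metadata(x)$skipped_non_snv} counts
#'   skipped records per file.
#' @export
readVcfCohort <- function(paths, animal_ids, group, af_field = "AF",
                          groups = NULL, control = NULL) {
  stopifnot(length(paths) == length(animal_ids))
  group <- rep_len(group, length(paths))
  skipped <- integer(length(paths))
  calls <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    vcf <- VariantAnnotation::readVcf(paths[i])
    vcf <- VariantAnnotation::expand(vcf)
    snv <- VariantAnnotation::isSNV(vcf)
    skipped[i] <- sum(!snv)
    vcf <- vcf[snv]
    n <- length(vcf)
    if (n == 0L) {
      calls[[i]] <- NULL
      next
    }
    info_tab <- VariantAnnotation::info(vcf)
    if (af_field %in% names(info_tab)) {
      hf <- as.numeric(info_tab[[af_field]])
    } else if (af_field %in% rownames(VariantAnnotation::geno(
                 VariantAnnotation::header(vcf)))) {
      g <- VariantAnnotation::geno(vcf)[[af_field]]
      hf <- as.numeric(unlist(g[, 1L]))
    } else {
      stop("allele-frequency field '", af_field, "' not found in ",
           paths[i])
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    calls[[i]] <- data.frame(
      animal_id = animal_ids[i], group = group[i],
      position = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = as.character(rr$ALT),
      hf = hf, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls))
    calls <- data.frame(animal_id = character(0), group = character(0),
                        position = integer(0), ref = character(0),
                        alt = character(0), hf = numeric(0))
  roster <- data.frame(animal_id = as.character(animal_ids),
                       group = group, stringsAsFactors = FALSE)
  message("read ", nrow(calls), " SNV calls from ", length(paths),
          " VCF file(s); skipped ", sum(skipped), " non-SNV record(s)")
  MitoCohort(calls, animals = roster, groups = groups, control = control,
             metadata = list(skipped_non_snv = skipped, source = paths))
}

#' Access cohort metadata
#'
#' @param cohort A [MitoCohort-class].
#' @return The metadata list (reader/filter/simulator provenance).
#' @export
cohortMetadata <- function(cohort) cohort@metadata

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write the statistics report bundle
#'
#' Writes the tables produced by [cohortStatistics()] as TSV files with a
#' fixed column order and floating-point values at 6 significant digits:
#' \code{per_animal.tsv}, \code{group_summary.tsv}, \code{coldspots.tsv},
#' \code{gene_density.tsv}. An empty cohort yields headers-only files.
#'
#' @param stats Result of [cohortStatistics()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
writeReport <- function(stats, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(per_animal = file.path(dir, "per_animal.tsv"),
           group_summary = file.path(dir, "group_summary.tsv"),
           coldspots = file.path(dir, "coldspots.tsv"),
           gene_density = file.path(dir, "gene_density.tsv"))
  pa <- stats$per_animal
  for (col in c("mean_hf", "ns_ratio"))
    pa[[col]] <- .fmt_num(pa[[col]])
  write.table(pa, out["per_animal"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gs <- stats$group_summary
  for (col in c("median", "mode", "p_vs_control"))
    gs[[col]] <- .fmt_num(gs[[col]])
  write.table(gs, out["group_summary"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(stats$coldspots, out["coldspots"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gd <- stats$gene_density
  for (col in intersect(c("density", "density_synonymous",
                          "density_nonsynonymous"), names(gd)))
    gd[[col]] <- .fmt_num(gd[[col]])
  write.table(gd, out["gene_density"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out)
}

#' Read a flat YAML run configuration
#'
#' @param path YAML file of key-value pairs mirroring the pipeline options.
#' @return Named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)
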