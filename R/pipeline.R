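#' Genotype a recruited read set
#'
#' The core pipeline after read recruitment: all-map reads against the
#' padded allele database, build and solve the read-assignment ILP, extract
#' calls, and (optionally) score each call's prefix consistency over
#' near-optimal solution bands.
#'
#' @param reads A `read_set` tibble (`read_id`, `sequence`).
#' @param db A padded [allele_db].
#' @param depth A [depth_profile] on the per-copy (haploid) scale.
#' @param params [model_params()].
#' @param max_distance Candidate mapping edit-distance cutoff.
#' @param confidence Compute near-optimal bands and prefix consistency.
#' @param deltas Solution-band fractions.
#' @return A list of class `vg_genotype`: `calls` (a `vg_calls` tibble),
#'   `solution`, `candidates`, `bands` (or NULL), `depth`, `params`.
#' @export
genotype_reads <- function(reads, db, depth, params = model_params(),
                           max_distance = 25L, confidence = TRUE,
                           deltas = c(0.02, 0.04, 0.06, 0.08)) {
  cands <- map_reads_to_alleles(reads, db, max_distance = max_distance)
  if (nrow(cands) == 0L) {
    calls <- tibble(gene_id = character(0), allele_id = character(0),
                    copy_number = integer(0), n_assigned_reads = integer(0),
                    mean_edit_distance = numeric(0),
                    prefix_consistency = integer(0))
    class(calls) <- c("vg_calls", class(calls))
    return(structure(list(calls = calls, solution = NULL, candidates = cands,
                          bands = NULL, depth = depth, params = params),
                     class = "vg_genotype"))
  }
  model <- build_model(cands, db, depth, params)
  solution <- solve_assignment(model)
  calls <- calls_from_solution(solution, db, table = cands)
  bands <- NULL
  if (confidence && nrow(calls) > 0L) {
    bands <- near_optimal_solutions(model, solution, deltas)
    calls <- add_prefix_consistency(calls, bands)
  }
  structure(list(calls = calls, solution = solution, candidates = cands,
                 bands = bands, depth = depth, params = params),
            class = "vg_genotype")
}

#' @export
print.vg_genotype <- function(x, ...) {
  cat(sprintf("<vg_genotype> %d allele calls over %d genes\n",
              nrow(x$calls), dplyr::n_distinct(x$calls$gene_id)))
  if (!is.null(x$solution)) print(x$solution)
  invisible(x)
}

#' Genotype a sample from an alignment file
#'
#' Full pipeline: recruit reads over the target locus and orphon regions,
#' estimate (or accept) the depth profile, rescale it to the per-copy
#' scale, and run [genotype_reads()].
#'
#' @param bam_path Indexed BAM file of WGS reads mapped to a reference.
#' @param db A padded [allele_db].
#' @param target_regions,orphon_regions Region data frames (`chrom`,
#'   `start`, `end`, 0-based half-open); see [read_bed()].
#' @param depth Either a [depth_profile] (raw scale) or a background region
#'   data frame to estimate one from.
#' @param ploidy Background ploidy used to rescale the depth profile.
#' @param n_depth_positions,depth_seed Passed to [estimate_depth()].
#' @inheritParams genotype_reads
#' @return A `vg_genotype`.
#' @export
genotype_bam <- function(bam_path, db, target_regions, orphon_regions = NULL,
                         depth, ploidy = 2, params = model_params(),
                         max_distance = 25L, confidence = TRUE,
                         n_depth_positions = 10000L, depth_seed = 42L) {
  reads <- recruit_reads(bam_path, target_regions, orphon_regions)
  prof <- if (inherits(depth, "depth_profile")) depth
          else estimate_depth(bam_path, depth, n_depth_positions, depth_seed)
  genotype_reads(reads, db, haploid_depth(prof, ploidy), params = params,
                 max_distance = max_distance, confidence = confidence)
}

#' Presence/absence genotype matrix across samples
#'
#' Builds the samples x alleles 0/1 matrix consumed by downstream
#' association analyses.  Optionally filters alleles to those whose
#' presence AND absence each occur in at least `min_prevalence` of samples
#' (uninformative near-constant alleles carry no association signal).
#'
#' @param calls A data frame with columns `sample_id` and `allele_id`
#'   (e.g. row-bound `vg_calls` with a `sample_id` column added).
#' @param min_prevalence Minimum fraction for both presence and absence;
#'   `NULL` disables filtering.
#' @return A tibble with `sample_id` and one 0/1 column per allele.
#' @export
genotype_matrix <- function(calls, min_prevalence = 0.05) {
  stopifnot(all(c("sample_id", "allele_id") %in% names(calls)))
  samples <- unique(calls$sample_id)
  wide <- calls |>
    dplyr::distinct(.data$sample_id, .data$allele_id) |>
    dplyr::mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "allele_id", values_from = "present",
                       values_fill = 0L) |>
    dplyr::right_join(tibble(sample_id = samples), by = "sample_id") |>
    dplyr::mutate(dplyr::across(-"sample_id", ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::arrange(.data$sample_id)
  if (!is.null(min_prevalence)) {
    n <- nrow(wide)
    keep <- vapply(wide[-1], function(col) {
      p <- sum(col) / n
      p >= min_prevalence && (1 - p) >= min_prevalence
    }, logical(1))
    wide <- wide[, c(TRUE, keep), drop = FALSE]
  }
  wide
}

# ---- output files ------------------------------------------------------

output_header <- function(seed = NA, config = list()) {
  hash <- substr(rlang::hash(config), 1, 12)
  c(sprintf("# vgenotyper %s", as.character(packageVersion("vgenotyper"))),
    sprintf("# seed=%s config_hash=%s", format(seed), hash))
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline outputs carry `#`-prefixed header lines recording the tool
#' version, a hash of the configuration, and the seed.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed,config Recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, seed = NA, config = list()) {
  writeLines(output_header(seed, config), path)
  suppressWarnings(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Read a result TSV (skipping provenance headers)
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  out <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(paste0("malformed TSV ", path, ": ", conditionMessage(e))))
  if (nrow(out) > 0L && any(vapply(out, function(col) all(is.na(col)), logical(1)))) {
    bad <- names(out)[vapply(out, function(col) all(is.na(col)), logical(1))]
    warn(paste0("column(s) entirely NA in ", path, ": ", paste(bad, collapse = ", ")))
  }
  out
}

#' Read a BED file into a region tibble
#'
#' @param path BED path (0-based half-open, first three columns used).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(bed) < 3L) abort(paste0("BED file needs >= 3 columns: ", path))
  tibble(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
         end = as.integer(bed[[3]]))
}

#' Write regions as BED
#'
#' @param regions Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a read set as FASTQ (fixed quality)
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_read_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             path)
  invisible(path)
}
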