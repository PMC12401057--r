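#' Discover orphon regions from read placements
#'
#' Merges overlapping-or-abutting read placements into maximal regions and
#' drops regions shorter than the expected read length, reproducing how
#' orphon look-alike regions are identified from database-derived reads
#' mapped back to a reference genome.
#'
#' @param placements A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. parsed from an aligner's SAM output.
#' @param min_region_len Minimum region length kept (strictly shorter
#'   regions are removed); default one read length (150 bp).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
discover_orphons <- function(placements, min_region_len = 150L) {
  if (is.null(placements) || nrow(placements) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  stopifnot(all(placements$start < placements$end))
  gr <- GenomicRanges::GRanges(placements$chrom,
                               IRanges::IRanges(placements$start + 1L, placements$end))
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and abutting ranges
  merged <- merged[IRanges::width(merged) >= min_region_len]
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(merged)),
                start = GenomicRanges::start(merged) - 1L,
                end = GenomicRanges::end(merged))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Parse aligner SAM output into read placements
#'
#' Convenience adapter feeding [discover_orphons()] from an external
#' aligner's SAM: mapped primary records become (chrom, start, end)
#' placements spanning the read length on the reference.
#'
#' @param sam_path Path to an uncompressed SAM file.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
read_sam_placements <- function(sam_path) {
  lines <- readr::read_lines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  fields <- strsplit(lines, "\t")
  purrr::map_dfr(fields, function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)
    start <- as.integer(f[4]) - 1L
    tibble(chrom = f[3], start = start, end = start + nchar(f[10]))
  })
}

# Resolve region chromosome names against a BAM header, accepting chr1/1
# synonyms; errors listing the header names when unresolvable.
resolve_chroms <- function(chroms, header_names) {
  vapply(chroms, function(ch) {
    if (ch %in% header_names) return(ch)
    alt <- if (startsWith(ch, "chr")) sub("^chr", "", ch) else paste0("chr", ch)
    if (alt %in% header_names) return(alt)
    abort(paste0("chromosome `", ch, "` not in alignment header; header has: ",
                 paste(head(header_names, 10), collapse = ", ")))
  }, character(1))
}

#' Recruit reads overlapping target and orphon regions
#'
#' Extracts every read whose alignment overlaps any target or orphon
#' region, deduplicated by read identity (name plus first/second-of-pair
#' flag) so a read overlapping several regions, or recruited through a
#' secondary alignment, appears exactly once with its primary sequence.
#' Reads are treated as single-end from here on.
#'
#' @param bam_path Indexed BAM file.
#' @param target_regions,orphon_regions Data frames with `chrom`, `start`,
#'   `end` (0-based half-open); `orphon_regions` may be NULL.
#' @return A tibble of class `read_set` (`read_id`, `sequence`).
#' @export
recruit_reads <- function(bam_path, target_regions, orphon_regions = NULL) {
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    abort(paste0("missing BAM index for ", bam_path,
                 " (create one with Rsamtools::indexBam or `samtools index`)"))
  }
  regions <- dplyr::bind_rows(as_tibble(target_regions),
                              if (!is.null(orphon_regions)) as_tibble(orphon_regions))
  if (nrow(regions) == 0L) abort("no regions to recruit from")
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  regions$chrom <- resolve_chroms(regions$chrom, names(hdr))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("qname", "flag", "seq"))
  res <- Rsamtools::scanBam(bam_path, param = param)
  qname <- unlist(lapply(res, `[[`, "qname"), use.names = FALSE)
  flag <- unlist(lapply(res, `[[`, "flag"), use.names = FALSE)
  seqs <- unlist(lapply(res, function(x) as.character(x$seq)), use.names = FALSE)
  if (length(qname) == 0L) {
    out <- tibble(read_id = character(0), sequence = character(0))
    return(structure(out, class = c("read_set", class(out))))
  }
  mate <- dplyr::case_when(bitwAnd(flag, 64L) > 0L ~ "/1",
                           bitwAnd(flag, 128L) > 0L ~ "/2",
                           TRUE ~ "")
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  out <- tibble(read_id = paste0(qname, mate), sequence = seqs,
                primary = primary) |>
    dplyr::arrange(.data$read_id, dplyr::desc(.data$primary)) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE) |>
    dplyr::select("read_id", "sequence")
  structure(out, class = c("read_set", class(out)))
}

#' Construct a depth profile directly
#'
#' @param mean_depth,sd_depth Expected per-base depth mean and SD.
#' @param n_positions Number of positions the estimate is based on.
#' @param region Optional source region.
#' @return A list of class `depth_profile`.
#' @export
depth_profile <- function(mean_depth, sd_depth, n_positions = NA_integer_,
                          region = NULL) {
  if (!(mean_depth > 0)) abort("mean_depth must be > 0")
  if (sd_depth < 0) abort("sd_depth must be >= 0")
  structure(list(mean_depth = mean_depth, sd_depth = sd_depth,
                 n_positions = n_positions, region = region),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> mean %.2f, sd %.2f (%s positions)\n",
              x$mean_depth, x$sd_depth, format(x$n_positions)))
  invisible(x)
}

#' Estimate the genome-wide depth profile from a background region
#'
#' Samples `n_positions` uniformly random positions in `region` (typically a
#' large stretch of chromosome 1, away from the target locus), reads the
#' per-base depth there, and reports mean and SD.  Zero-depth positions are
#' included, so an exome or otherwise patchy file yields a conservative,
#' low mean.  Note the estimate is on the raw (diploid) scale; divide by
#' ploidy before feeding the ILP (see [haploid_depth()]).
#'
#' @param bam_path Indexed BAM file.
#' @param region A list/one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param n_positions Number of positions to sample (must not exceed the
#'   region length).
#' @param seed Integer seed for position sampling.
#' @return A [depth_profile].
#' @export
estimate_depth <- function(bam_path, region, n_positions = 10000L, seed = 42L) {
  region <- as.list(as_tibble(region)[1, ])
  width <- region$end - region$start
  if (n_positions > width) abort("n_positions exceeds region length")
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  region$chrom <- resolve_chroms(region$chrom, names(hdr))
  pos <- with_seed(seed, sort(sample.int(width, n_positions)) + region$start)  # 1-based
  gr <- GenomicRanges::GRanges(region$chrom,
                               IRanges::IRanges(region$start + 1L, region$end))
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  sbp <- Rsamtools::ScanBamParam(which = gr)
  pu <- Rsamtools::pileup(bam_path, scanBamParam = sbp, pileupParam = pp)
  depth_at <- setNames(rep(0L, n_positions), pos)
  hitpos <- match(pu$pos, pos)
  ok <- !is.na(hitpos)
  if (any(ok)) {
    agg <- tapply(pu$count[ok], hitpos[ok], sum)
    depth_at[as.integer(names(agg))] <- as.integer(agg)
  }
  m <- mean(depth_at)
  if (m == 0) abort("estimated depth is zero over the background region; cannot genotype")
  depth_profile(m, stats::sd(depth_at), n_positions, region)
}

#' Convert a raw depth profile to the per-copy (haploid) scale
#'
#' The ILP's copy-number variable multiplies a per-copy expected depth, so
#' a profile measured on a diploid background must be rescaled: mean is
#' divided by `ploidy` and SD by `sqrt(ploidy)` (Poisson-consistent).
#'
#' @param profile A [depth_profile] on the raw scale.
#' @param ploidy Background copy number (2 for autosomal background).
#' @return A [depth_profile] on the per-copy scale.
#' @export
haploid_depth <- function(profile, ploidy = 2) {
  depth_profile(profile$mean_depth / ploidy,
                profile$sd_depth / sqrt(ploidy),
                profile$n_positions, profile$region)
}
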