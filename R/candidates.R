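#' Map reads against every allele in the database
#'
#' Produces the candidate-assignment table the ILP consumes: for every read,
#' every allele it can be placed on end-to-end within `max_distance` edits.
#' The internal aligner is seed-and-extend (exact k-mer seeds over the
#' allele index, banded semi-global dynamic-programming verification);
#' substitutions and gaps cost 1 edit, positions aligned against `N` in the
#' padded allele are free, and both strands are tried (ties go to the
#' forward strand).  Only the best placement per (read, allele) is kept.
#'
#' @param reads A `read_set` tibble (columns `read_id`, `sequence`).
#' @param db A padded [allele_db].
#' @param max_distance Maximum edit distance retained (default 25,
#'   equivalent to an end-to-end score floor of -50 at mismatch penalty 2).
#' @param k Seed k-mer length.
#' @param band Extra DP band around the seeded diagonals (bounds the number
#'   of gap bases considered).
#' @param seed_stride Spacing of seed k-mers along the read.
#' @return A tibble of class `candidate_tbl` with columns `read_id`,
#'   `allele_id`, `edit_distance`, `start` (0-based on the padded allele)
#'   and `strand`, sorted by read then (edit_distance, allele_id).
#'   Attributes: `zero_candidate_reads` (read ids with no candidate) and
#'   `read_length`.
#' @export
map_reads_to_alleles <- function(reads, db, max_distance = 25L, k = 15L,
                                 band = 5L, seed_stride = 5L) {
  if (db_pad_len(db) == 0L) {
    warn("mapping against an un-padded database; reads overhanging allele ends will be penalised")
  }
  read_length <- attr(reads, "read_length") %||%
    (if (nrow(reads)) as.integer(max(nchar(reads$sequence))) else 0L)
  if (nrow(reads) == 0L) {
    out <- tibble(read_id = character(0), allele_id = character(0),
                  edit_distance = integer(0), start = integer(0),
                  strand = character(0))
    return(structure(out, zero_candidate_reads = character(0),
                     read_length = read_length,
                     class = c("candidate_tbl", class(out))))
  }
  raw <- .map_reads_cpp(reads$read_id, toupper(reads$sequence),
                        db$allele_id, db$sequence,
                        as.integer(k), as.integer(max_distance),
                        as.integer(band), as.integer(seed_stride))
  out <- as_tibble(raw) |>
    dplyr::arrange(match(.data$read_id, reads$read_id),
                   .data$edit_distance, .data$allele_id)
  zero <- sort(setdiff(reads$read_id, unique(out$read_id)))
  structure(out, zero_candidate_reads = zero, read_length = read_length,
            class = c("candidate_tbl", class(out)))
}

#' Per-allele and per-read candidate diagnostics
#'
#' @param table A `candidate_tbl`.
#' @return A list with tibbles `per_allele` (`allele_id`, `n_reads`,
#'   `mean_distance`) and `per_read` (`read_id`, `n_candidates`,
#'   `min_distance`), both deterministically ordered.
#' @export
candidate_summary <- function(table) {
  if (nrow(table) == 0L) {
    return(list(
      per_allele = tibble(allele_id = character(0), n_reads = integer(0),
                          mean_distance = numeric(0)),
      per_read = tibble(read_id = character(0), n_candidates = integer(0),
                        min_distance = numeric(0))))
  }
  per_allele <- table |>
    dplyr::group_by(.data$allele_id) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     mean_distance = mean(.data$edit_distance),
                     .groups = "drop") |>
    dplyr::arrange(.data$allele_id)
  per_read <- table |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(n_candidates = dplyr::n(),
                     min_distance = min(.data$edit_distance),
                     .groups = "drop") |>
    dplyr::arrange(.data$read_id)
  list(per_allele = per_allele, per_read = per_read)
}

#' Import candidates from an external all-mapping SAM file
#'
#' Adapter for parity runs against a real all-mapper: each SAM alignment
#' line against an allele reference becomes a candidate, with the edit
#' distance taken from the `NM` tag (re-computed with the internal
#' semi-global scorer when `NM` is absent).  Only the best record per
#' (read, allele) is kept.
#'
#' @param sam_path Path to an uncompressed SAM file.
#' @param db The padded [allele_db] the reads were mapped against.
#' @param max_distance Maximum edit distance retained.
#' @return A `candidate_tbl`.
#' @export
read_sam_candidates <- function(sam_path, db, max_distance = 25L) {
  lines <- readr::read_lines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(structure(tibble(read_id = character(0), allele_id = character(0),
                            edit_distance = integer(0), start = integer(0),
                            strand = character(0)),
                     zero_candidate_reads = character(0), read_length = 0L,
                     class = c("candidate_tbl", "tbl_df", "tbl", "data.frame")))
  }
  fields <- strsplit(lines, "\t")
  recs <- purrr::map_dfr(fields, function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)  # unmapped
    nm_tok <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    allele <- f[3]
    j <- match(allele, db$allele_id)
    if (is.na(j)) return(NULL)
    dist <- if (length(nm_tok)) {
      as.integer(sub("^NM:i:", "", nm_tok[1]))
    } else {
      .semiglobal_distance_cpp(toupper(f[10]), db$sequence[j],
                               as.integer(max_distance))$edit_distance
    }
    tibble(read_id = f[1], allele_id = allele,
           edit_distance = as.integer(dist), start = as.integer(f[4]) - 1L,
           strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+")
  })
  recs <- recs |>
    dplyr::filter(.data$edit_distance <= max_distance) |>
    dplyr::group_by(.data$read_id, .data$allele_id) |>
    dplyr::slice_min(.data$edit_distance, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$read_id, .data$edit_distance, .data$allele_id)
  rl <- max(c(0L, nchar(purrr::map_chr(fields, 10))), na.rm = TRUE)
  structure(recs, zero_candidate_reads = character(0),
            read_length = as.integer(rl),
            class = c("candidate_tbl", class(recs)))
}
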