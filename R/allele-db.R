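#' Allele database objects
#'
#' An allele database is a tibble with one row per allele and columns
#' `allele_id` (IMGT-style `GENE*ALLELE`), `gene_id` (the part before `*`),
#' `sequence` (uppercase DNA, possibly N-padded), `core_start`/`core_end`
#' (0-based half-open offsets of the un-padded allele within `sequence`) and
#' `functional` (logical).  The attribute `pad_len` records the symmetric N
#' padding applied by [pad_alleles()] (0 for an un-padded database).
#'
#' @param records A data frame with at least `allele_id` and `sequence`.
#' @param pad_len Padding already present in `sequence` (normally 0).
#' @return A tibble of class `allele_db`.
#' @export
allele_db <- function(records, pad_len = 0L) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("allele database is empty")
  if (!all(c("allele_id", "sequence") %in% names(records))) {
    abort("records need `allele_id` and `sequence` columns")
  }
  if (anyDuplicated(records$allele_id)) {
    dup <- unique(records$allele_id[duplicated(records$allele_id)])
    abort(paste0("duplicate allele_id(s): ", paste(dup, collapse = ", ")))
  }
  bad <- !grepl("\\*", records$allele_id)
  if (any(bad)) {
    abort(paste0("allele_id without `*`: ", paste(records$allele_id[bad], collapse = ", ")))
  }
  records$sequence <- toupper(records$sequence)
  if (any(grepl("[^ACGTN]", records$sequence))) {
    abort("sequences must be over {A,C,G,T,N}")
  }
  if (is.null(records[["gene_id"]])) {
    records$gene_id <- sub("\\*.*$", "", records$allele_id)
  }
  if (is.null(records[["core_start"]])) records$core_start <- 0L
  if (is.null(records[["core_end"]])) records$core_end <- nchar(records$sequence)
  if (is.null(records[["functional"]])) records$functional <- TRUE
  stopifnot(all(records$core_start >= 0L),
            all(records$core_end <= nchar(records$sequence)),
            all(records$core_end > records$core_start))
  records <- records[, c("allele_id", "gene_id", "sequence",
                         "core_start", "core_end", "functional")]
  structure(records, pad_len = as.integer(pad_len),
            class = c("allele_db", class(records)))
}

#' @export
print.allele_db <- function(x, ...) {
  cat(sprintf("<allele_db> %d alleles, %d genes, pad_len = %d\n",
              nrow(x), dplyr::n_distinct(x$gene_id), db_pad_len(x)))
  NextMethod()
}

db_pad_len <- function(db) as.integer(attr(db, "pad_len") %||% 0L)

core_length <- function(db) db$core_end - db$core_start

core_sequence <- function(db) {
  substr(db$sequence, db$core_start + 1L, db$core_end)
}

# Parse one FASTA header into an allele record skeleton, or NULL if it does
# not carry a GENE*ALLELE token.  Two dialects: pipe-delimited IMGT headers
# (allele id in field 2, functionality in field 4) and bare headers whose
# first whitespace token is the allele id; bare headers may carry
# `core=<start>-<end>` and `functional=<T|F>` tokens written by
# [write_allele_database()].
parse_fasta_header <- function(header) {
  header <- trimws(header)
  if (grepl("|", header, fixed = TRUE)) {
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) >= 2L && grepl("\\*", fields[2])) {
      func <- if (length(fields) >= 4L) startsWith(trimws(fields[4]), "F") else TRUE
      return(list(allele_id = trimws(fields[2]), functional = func, core = NULL))
    }
    return(NULL)
  }
  tokens <- strsplit(header, "\\s+")[[1]]
  if (length(tokens) == 0L || !grepl("\\*", tokens[1])) return(NULL)
  out <- list(allele_id = tokens[1], functional = TRUE, core = NULL)
  core_tok <- grep("^core=", tokens, value = TRUE)
  if (length(core_tok) == 1L) {
    se <- as.integer(strsplit(sub("^core=", "", core_tok), "-")[[1]])
    if (length(se) == 2L && !anyNA(se)) out$core <- se
  }
  func_tok <- grep("^functional=", tokens, value = TRUE)
  if (length(func_tok) == 1L) {
    out$functional <- startsWith(toupper(sub("^functional=", "", func_tok)), "T")
  }
  out
}

#' Load an allele database from FASTA
#'
#' Reads an IMGT-style allele FASTA.  Headers may be bare `GENE*ALLELE`
#' tokens or pipe-delimited IMGT headers (`ACC|GENE*ALLELE|species|F|...`);
#' records whose header carries no `GENE*ALLELE` token are skipped with a
#' warning.  Functionality is taken from the IMGT header field when present
#' (`F` = functional, `P`/`ORF` = not), from `functional_ids` when supplied,
#' and defaults to functional.
#'
#' @param fasta_path Path to the FASTA file.
#' @param functional_ids Optional character vector of allele_ids to mark
#'   functional (all others become non-functional).
#' @return An [allele_db] tibble.
#' @export
load_allele_database <- function(fasta_path, functional_ids = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) abort("empty allele database FASTA")
  headers <- names(seqs)
  parsed <- lapply(headers, parse_fasta_header)
  keep <- !vapply(parsed, is.null, logical(1))
  if (any(!keep)) {
    warn(paste0("skipping ", sum(!keep), " FASTA record(s) without a GENE*ALLELE header token"))
  }
  if (!any(keep)) abort("no parseable allele records in FASTA")
  parsed <- parsed[keep]
  sequences <- toupper(as.character(seqs[keep]))
  rec <- tibble(
    allele_id = vapply(parsed, `[[`, character(1), "allele_id"),
    sequence = unname(sequences),
    functional = vapply(parsed, `[[`, logical(1), "functional")
  )
  cores <- lapply(parsed, `[[`, "core")
  has_core <- !vapply(cores, is.null, logical(1))
  rec$core_start <- as.integer(ifelse(has_core,
    vapply(cores, function(x) as.numeric((x %||% NA)[1]), numeric(1)), 0))
  rec$core_end <- as.integer(ifelse(has_core,
    vapply(cores, function(x) as.numeric((x %||% c(NA, NA))[2]), numeric(1)),
    nchar(rec$sequence)))
  if (!is.null(functional_ids)) {
    rec$functional <- rec$allele_id %in% functional_ids
  }
  pad <- if (any(has_core)) unique(rec$core_start[has_core]) else 0L
  pad_len <- if (length(pad) == 1L && all(rec$core_start == pad) &&
                 all(nchar(rec$sequence) - rec$core_end == pad)) pad else 0L
  allele_db(rec, pad_len = pad_len)
}

#' Write an allele database to FASTA
#'
#' Headers are `GENE*ALLELE core=<start>-<end> functional=<T|F>`, a dialect
#' [load_allele_database()] reads back so that a write/reload round trip
#' preserves allele ids, sequences and core offsets.
#'
#' @param db An [allele_db].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_database <- function(db, path) {
  headers <- sprintf("%s core=%d-%d functional=%s",
                     db$allele_id, db$core_start, db$core_end,
                     ifelse(db$functional, "T", "F"))
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Pad alleles with flanking N bases
#'
#' Adds `pad_len` N bases to both ends of every allele so that reads
#' overhanging an allele end can still align end-to-end at zero cost against
#' the unknown flanking context.  Padding an already padded database is an
#' error (padding is applied exactly once).
#'
#' @param db An un-padded [allele_db].
#' @param pad_len Number of N bases on each side; the default of one read
#'   length lets a read overhang almost entirely.
#' @return A padded [allele_db].
#' @export
pad_alleles <- function(db, pad_len = 150L) {
  pad_len <- as.integer(pad_len)
  if (pad_len < 0L) abort("pad_len must be >= 0")
  if (db_pad_len(db) > 0L) abort("database is already padded; re-padding is refused")
  if (pad_len == 0L) return(db)
  pad <- strrep("N", pad_len)
  out <- db
  out$sequence <- paste0(pad, db$sequence, pad)
  out$core_start <- db$core_start + pad_len
  out$core_end <- db$core_end + pad_len
  allele_db(out, pad_len = pad_len)
}

#' Landmark positions for a core of given length
#'
#' Landmarks are the positions at which the ILP's depth-consistency
#' constraints measure read coverage.  `n_groups * per_group` positions are
#' spread uniformly over the interior of the core (offsets
#' `round(k * len / (n+1))`, `k = 1..n`, which avoids the allele termini
#' where alignment clipping makes coverage unreliable).  For short cores
#' (`len < 2n`) evenly spaced distinct offsets are used instead, saturating
#' at one landmark per base; a core shorter than `n` yields `len` landmarks
#' with a warning.  Positions depend only on the core length, so alleles of
#' equal length share landmarks.
#'
#' @param core_len Length of the un-padded allele core in bp.
#' @param n_groups,per_group Landmark layout (defaults 6 and 6); groups are
#'   consecutive runs of `per_group` positions.
#' @return A tibble with columns `group` and `position` (0-based offsets
#'   into the core), sorted by position.
#' @export
compute_landmarks <- function(core_len, n_groups = 6L, per_group = 6L) {
  core_len <- as.integer(core_len)
  n_groups <- as.integer(n_groups)
  per_group <- as.integer(per_group)
  stopifnot(n_groups >= 1L, per_group >= 1L, core_len >= 1L)
  n <- n_groups * per_group
  if (core_len < n) {
    warn(sprintf("core length %d < %d landmarks; falling back to %d", core_len, n, core_len))
  }
  if (core_len >= 2L * n) {
    pos <- as.integer(floor(seq_len(n) * core_len / (n + 1) + 0.5))
  } else {
    m <- min(n, core_len)
    pos <- as.integer(floor(seq(0, core_len - 1L, length.out = m)))
  }
  m <- length(pos)
  # groups: contiguous runs, sizes as equal as possible when m < n
  sizes <- rep(m %/% n_groups, n_groups) + (seq_len(n_groups) <= m %% n_groups)
  grp <- rep(seq_len(n_groups), times = sizes)
  tibble(group = grp[seq_len(m)], position = pos)
}

#' Landmark table for every allele in a database
#'
#' @param db An [allele_db].
#' @inheritParams compute_landmarks
#' @return Tibble with columns `allele_id`, `group`, `position`.
#' @export
landmark_table <- function(db, n_groups = 6L, per_group = 6L) {
  lens <- core_length(db)
  purrr::map2_dfr(db$allele_id, lens, function(id, len) {
    dplyr::mutate(compute_landmarks(len, n_groups, per_group), allele_id = id,
                  .before = 1L)
  })
}
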