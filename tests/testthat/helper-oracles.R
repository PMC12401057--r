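# Independent oracles and fixture builders used across the suite.

# Quadratic-time semi-global edit distance (read global, placement on ref
# free, ref N matches anything at zero cost) -- independent of the C++
# aligner it checks.
r_semiglobal_distance <- function(read, ref) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); L <- length(rf)
  prev <- rep(0, L + 1)
  for (i in seq_len(m)) {
    cur <- numeric(L + 1)
    cur[1] <- i
    for (j in seq_len(L)) {
      cost <- if (rf[j] == "N" || rf[j] == rd[i]) 0 else 1
      cur[j + 1] <- min(prev[j] + cost, prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  min(prev)
}

# Brute-force interval union + length filter over read placements.
r_union_filter <- function(placements, min_len = 150L) {
  out <- list()
  for (ch in sort(unique(placements$chrom))) {
    p <- placements[placements$chrom == ch, , drop = FALSE]
    covered <- rep(FALSE, max(p$end))
    for (i in seq_len(nrow(p))) covered[(p$start[i] + 1):p$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                  end = ends[keep])
    }
  }
  dplyr::bind_rows(out)
}

# Build a candidate table directly (bypassing alignment) for ILP tests.
# `cands` is a data frame with read_id, allele_id, edit_distance and
# optionally start (default 0).  All reads are assumed to span every
# landmark unless start says otherwise.
toy_candidates <- function(cands, read_length = 200L,
                           zero_candidate_reads = character(0)) {
  cands <- tibble::as_tibble(cands)
  if (is.null(cands[["start"]])) cands$start <- 0L
  if (is.null(cands[["strand"]])) cands$strand <- "+"
  cands <- cands[, c("read_id", "allele_id", "edit_distance", "start", "strand")]
  structure(cands, zero_candidate_reads = zero_candidate_reads,
            read_length = as.integer(read_length),
            class = c("candidate_tbl", class(cands)))
}

# A toy database of unpadded alleles with fixed-length cores; sequences are
# arbitrary (ILP tests only use core lengths for landmarks).
toy_db <- function(allele_ids, core_len = 36L) {
  vgenotyper::allele_db(tibble::tibble(
    allele_id = allele_ids,
    sequence = vapply(seq_along(allele_ids),
                      function(i) strrep("ACGT", ceiling(core_len / 4)) |>
                        substr(1, core_len), character(1))))
}

# Exhaustive near-optimal band oracle: minimum-objective feasible solution
# subject to objective >= bound; mirrors brute_force_solve's enumeration.
band_oracle <- function(table, db, depth, params, bound) {
  reads <- unique(table$read_id)
  P <- params$discard_penalty
  mu <- depth$mean_depth
  tol <- params$sd_scaling * depth$sd_depth
  w <- vgenotyper:::candidate_landmark_weights(
    table, db, attr(table, "read_length"), params$n_groups, params$per_group)
  groups <- vgenotyper::landmark_table(
    db[db$allele_id %in% unique(table$allele_id), , drop = FALSE],
    params$n_groups, params$per_group)
  groups <- dplyr::distinct(groups, allele_id, group)
  opts <- lapply(reads, function(r) c(which(table$read_id == r), 0L))
  combos <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(opts)), drop = FALSE]
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    pick <- as.integer(combos[ci, ])
    rows <- pick[pick > 0L]
    obj <- sum(table$edit_distance[rows]) + P * sum(pick == 0L)
    if (obj < bound - 1e-9) next
    feasible <- TRUE
    present <- character(0)
    for (a in sort(unique(table$allele_id[rows]))) {
      ag <- groups$group[groups$allele_id == a]
      covs <- vapply(ag, function(g)
        sum(w$w[w$cand %in% rows & w$allele_id == a & w$group == g]), numeric(1))
      fc <- vgenotyper:::feasible_copies(covs, mu, tol, params$copy_max)
      if (!length(fc)) { feasible <- FALSE; break }
      present <- c(present, a)
    }
    if (!feasible) next
    if (is.null(best) || obj < best$objective) {
      best <- list(objective = obj, present = present)
    }
  }
  best
}

# Write a synthetic coordinate-sorted SAM and convert to an indexed BAM.
# `reads` is a data frame with qname, chrom, pos (0-based), seq; optional
# flag (default 0).
write_test_bam <- function(reads, chrom_lens,
                           dir = local({
                             d <- tempfile("testbam")
                             dir.create(d)
                             d
                           })) {
  reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
  if (is.null(reads[["flag"]])) reads$flag <- 0L
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$chrom, reads$pos + 1L,
                  nchar(reads$seq), reads$seq)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# Small padded locus + genotype + reads, shared by pipeline-level tests.
small_locus_fixture <- function(n_genes = 4L, alleles_per_gene = 3L,
                                depth = 30, seed = 101L) {
  db <- generate_locus(n_genes = n_genes, alleles_per_gene = alleles_per_gene,
                       seed = seed)
  padded <- pad_alleles(db, 150L)
  geno <- simulate_genotype(db, seed = seed + 1L)
  reads <- simulate_reads(geno, padded, depth = depth, seed = seed + 2L)
  list(db = db, padded = padded, genotype = geno, reads = reads,
       depth = depth_profile(depth, sqrt(depth)))
}
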