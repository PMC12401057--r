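#' ILP model parameters
#'
#' @param n_groups,per_group Landmark layout used for the depth-consistency
#'   constraints (defaults 6 groups of 6 landmarks).
#' @param sd_scaling Additive depth tolerance in units of the depth SD
#'   (default 1.5): each copy of a called allele must see a landmark-group
#'   mean coverage within `mean +/- sd_scaling * sd`.
#' @param discard_penalty Objective penalty for discarding a read; the
#'   default `2 * max_distance + 1` (51 for the default max distance 25)
#'   makes discarding strictly worse than any single accepted assignment.
#' @param copy_max Maximum copy number per allele.
#' @param solver,time_limit,mip_gap,seed Solver backend name, wall-clock
#'   limit in seconds, relative MIP gap, and RNG seed recorded in outputs.
#' @return A list of class `model_params`.
#' @export
model_params <- function(n_groups = 6L, per_group = 6L, sd_scaling = 1.5,
                         discard_penalty = 51, copy_max = 4L,
                         solver = "highs", time_limit = 600, mip_gap = 0,
                         seed = 1L) {
  stopifnot(n_groups >= 1L, per_group >= 1L, sd_scaling > 0,
            discard_penalty > 0, copy_max >= 1L)
  structure(list(n_groups = as.integer(n_groups),
                 per_group = as.integer(per_group),
                 sd_scaling = sd_scaling, discard_penalty = discard_penalty,
                 copy_max = as.integer(copy_max), solver = solver,
                 time_limit = time_limit, mip_gap = mip_gap,
                 seed = as.integer(seed)),
            class = "model_params")
}

# Landmark coverage weights for each candidate: for candidate row i and
# landmark group g of its allele, the fraction of the group's landmarks the
# alignment span covers.  Returns a tibble (cand, allele_id, group, w).
candidate_landmark_weights <- function(table, db, read_length, n_groups, per_group) {
  lms <- landmark_table(db[db$allele_id %in% unique(table$allele_id), , drop = FALSE],
                        n_groups, per_group)
  lms <- dplyr::left_join(lms,
                          tibble(allele_id = db$allele_id, core_start = db$core_start),
                          by = "allele_id")
  lms$abs_pos <- lms$core_start + lms$position
  per_group_n <- lms |>
    dplyr::count(.data$allele_id, .data$group, name = "group_size")
  cand <- dplyr::mutate(table, cand = dplyr::row_number())
  hits <- dplyr::inner_join(cand, lms, by = "allele_id",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$abs_pos >= .data$start,
                  .data$abs_pos < .data$start + read_length) |>
    dplyr::count(.data$cand, .data$allele_id, .data$group, name = "n_cov") |>
    dplyr::left_join(per_group_n, by = c("allele_id", "group")) |>
    dplyr::mutate(w = .data$n_cov / .data$group_size)
  hits
}

#' Build the read-assignment ILP
#'
#' Variables: one binary `x[r,a]` per candidate (read r assigned to allele
#' a), one binary `d[r]` per read (discarded, with additive penalty), one
#' binary `z[a]` (allele called) and one integer `c[a] in [0, copy_max]`
#' (copy number) per candidate allele.  The objective minimises total edit
#' distance plus `discard_penalty * #discards`.  Constraints: every read is
#' assigned exactly once or discarded; reads only go to called alleles
#' (`x <= z`, `z <= c <= copy_max * z`); and for every called allele and
#' every landmark group, the group-mean read coverage must lie within
#' `c * (mean +/- sd_scaling * sd)` of the per-copy depth profile --- the
#' depth-consistency constraint that forces called copy numbers to explain
#' the observed coverage.
#'
#' @param table A `candidate_tbl` from [map_reads_to_alleles()].
#' @param db The padded [allele_db].
#' @param depth A [depth_profile] on the per-copy (haploid) scale.
#' @param params [model_params()].
#' @return A list of class `vg_ilp` (objective/bounds/sparse constraint
#'   triplets plus variable metadata), ready for [solve_assignment()].
#' @export
build_model <- function(table, db, depth, params = model_params()) {
  stopifnot(inherits(depth, "depth_profile"))
  if (depth$mean_depth <= 0) abort("depth profile mean must be > 0")
  read_length <- attr(table, "read_length") %||% abort("candidate table lacks read_length")
  zero_reads <- attr(table, "zero_candidate_reads") %||% character(0)
  reads <- unique(table$read_id)
  alleles <- sort(unique(table$allele_id))
  n_cand <- nrow(table)
  n_r <- length(reads)
  n_a <- length(alleles)
  if (n_a > 0L) {
    core_lens <- core_length(db)[match(alleles, db$allele_id)]
    if (anyNA(core_lens)) abort("candidate allele missing from database")
    if (any(core_lens < 1L)) abort("candidate allele with empty core (zero landmarks)")
  }

  # variable layout: [x (n_cand)] [d (n_r)] [z (n_a)] [c (n_a)]
  ix <- seq_len(n_cand)
  id <- n_cand + seq_len(n_r)
  iz <- n_cand + n_r + seq_len(n_a)
  ic <- n_cand + n_r + n_a + seq_len(n_a)
  nvar <- n_cand + n_r + 2L * n_a

  obj <- c(table$edit_distance, rep(params$discard_penalty, n_r), rep(0, 2L * n_a))
  lb <- rep(0, nvar)
  ub <- c(rep(1, n_cand + n_r + n_a), rep(params$copy_max, n_a))

  cand_read <- match(table$read_id, reads)
  cand_allele <- match(table$allele_id, alleles)

  tri_i <- integer(0); tri_j <- integer(0); tri_v <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0)
  add_rows <- function(i, j, v, lo, hi) {
    tri_i <<- c(tri_i, i); tri_j <<- c(tri_j, j); tri_v <<- c(tri_v, v)
    rlb <<- c(rlb, lo); rub <<- c(rub, hi)
  }
  nrow_ <- 0L

  # (i) sum_a x[r,a] + d[r] = 1 for every read with candidates
  add_rows(c(cand_read, seq_len(n_r)) - 1L + nrow_,
           c(ix, id) - 1L,
           rep(1, n_cand + n_r),
           rep(1, n_r), rep(1, n_r))
  nrow_ <- nrow_ + n_r

  if (n_a > 0L) {
    # (ii) x[r,a] - z[a] <= 0, one row per candidate
    add_rows(rep(nrow_ + seq_len(n_cand) - 1L, 2L),
             c(ix, iz[cand_allele]) - 1L,
             c(rep(1, n_cand), rep(-1, n_cand)),
             rep(-Inf, n_cand), rep(0, n_cand))
    nrow_ <- nrow_ + n_cand
    # z[a] - c[a] <= 0
    add_rows(rep(nrow_ + seq_len(n_a) - 1L, 2L),
             c(iz, ic) - 1L, c(rep(1, n_a), rep(-1, n_a)),
             rep(-Inf, n_a), rep(0, n_a))
    nrow_ <- nrow_ + n_a
    # c[a] - copy_max * z[a] <= 0
    add_rows(rep(nrow_ + seq_len(n_a) - 1L, 2L),
             c(ic, iz) - 1L, c(rep(1, n_a), rep(-params$copy_max, n_a)),
             rep(-Inf, n_a), rep(0, n_a))
    nrow_ <- nrow_ + n_a

    # (iii) depth consistency per (allele, landmark group):
    #   lo: cov - c*(mu - s*sd) >= 0 ; hi: cov - c*(mu + s*sd) <= 0
    w <- candidate_landmark_weights(table, db, read_length,
                                    params$n_groups, params$per_group)
    mu <- depth$mean_depth; tol <- params$sd_scaling * depth$sd_depth
    groups <- landmark_table(db[db$allele_id %in% alleles, , drop = FALSE],
                             params$n_groups, params$per_group) |>
      dplyr::distinct(.data$allele_id, .data$group)
    grow <- dplyr::mutate(groups, row_lo = nrow_ + dplyr::row_number() - 1L)
    n_g <- nrow(grow)
    grow$row_hi <- grow$row_lo + n_g
    wj <- dplyr::inner_join(w, grow, by = c("allele_id", "group"))
    a_of_group <- match(grow$allele_id, alleles)
    add_rows(c(wj$row_lo, grow$row_lo, wj$row_hi, grow$row_hi),
             c(ix[wj$cand], ic[a_of_group], ix[wj$cand], ic[a_of_group]) - 1L,
             c(wj$w, rep(-(mu - tol), n_g), wj$w, rep(-(mu + tol), n_g)),
             c(rep(0, n_g), rep(-Inf, n_g)),
             c(rep(Inf, n_g), rep(0, n_g)))
    nrow_ <- nrow_ + 2L * n_g
  }

  vars <- tibble(
    type = c(rep("x", n_cand), rep("d", n_r), rep("z", n_a), rep("c", n_a)),
    read_id = c(table$read_id, reads, rep(NA_character_, 2L * n_a)),
    allele_id = c(table$allele_id, rep(NA_character_, n_r), alleles, alleles)
  )

  structure(list(obj = obj, lb = lb, ub = ub,
                 A = list(i = tri_i, j = tri_j, v = tri_v),
                 rlb = rlb, rub = rub, n_rows = nrow_, n_vars = nvar,
                 vars = vars, reads = reads, alleles = alleles,
                 zero_candidate_reads = zero_reads,
                 # zero-candidate reads are pre-discarded: constant objective term
                 obj_offset = params$discard_penalty * length(zero_reads),
                 table = table, params = params, depth = depth),
            class = "vg_ilp")
}

#' @export
print.vg_ilp <- function(x, ...) {
  cat(sprintf("<vg_ilp> %d reads (%d zero-candidate), %d alleles, %d vars, %d rows\n",
              length(x$reads), length(x$zero_candidate_reads),
              length(x$alleles), x$n_vars, x$n_rows))
  invisible(x)
}
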