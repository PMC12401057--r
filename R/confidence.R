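#' Near-optimal solution bands
#'
#' Re-solves the assignment ILP under constraints forcing the objective to
#' be at least 2%, 4%, 6% and 8% (configurable) worse than the optimum, a
#' pseudobootstrap over ILP solutions: alleles that persist across
#' progressively worse solutions are stably supported by the reads, those
#' that vanish immediately are interchangeable with alternatives.  Each
#' band is an independent solve of a fresh model with one added row
#' `objective >= bound(delta)`; `bound(delta) = optimum * (1 + delta)` for
#' a positive optimum, and `delta * discard_penalty * n_reads` when the
#' optimum is 0 (where a multiplicative bound would collapse).
#'
#' @param model The `vg_ilp` the optimum was solved from.
#' @param optimal The optimal `vg_solution`.
#' @param deltas Strictly increasing positive fractions.
#' @return A tibble of class `solution_bands`: `delta` (0 = the optimum),
#'   `objective_bound`, `status`, `objective` and `present_alleles`
#'   (list-column).
#' @export
near_optimal_solutions <- function(model, optimal,
                                   deltas = c(0.02, 0.04, 0.06, 0.08)) {
  if (!identical(optimal$status, "optimal")) abort("optimal solution required")
  if (any(deltas <= 0) || is.unsorted(deltas, strictly = TRUE)) {
    abort("deltas must be strictly increasing and > 0")
  }
  n_reads <- length(model$reads) + length(model$zero_candidate_reads)
  bounds <- vapply(deltas, function(d) {
    if (optimal$objective > 0) optimal$objective * (1 + d)
    else d * model$params$discard_penalty * n_reads
  }, numeric(1))
  # one extra row per model: sum(obj_i * var_i) >= bound - obj_offset
  nz <- which(model$obj != 0)
  extra <- lapply(bounds, function(b) {
    list(j = nz - 1L, v = model$obj[nz], lo = b - model$obj_offset, hi = Inf)
  })
  res <- solve_models_raw(rep(list(model), length(deltas)), extra_rows = extra)
  bands <- purrr::map2_dfr(res, seq_along(deltas), function(r, k) {
    if (identical(r$status, "optimal")) {
      sol <- solution_from_x(model, r$x, r$objective, "optimal")
      tibble(delta = deltas[k], objective_bound = bounds[k],
             status = "optimal", objective = sol$objective,
             present_alleles = list(sol$present_alleles))
    } else {
      tibble(delta = deltas[k], objective_bound = bounds[k],
             status = r$status %||% "error", objective = NA_real_,
             present_alleles = list(character(0)))
    }
  })
  out <- dplyr::bind_rows(
    tibble(delta = 0, objective_bound = optimal$objective, status = "optimal",
           objective = optimal$objective,
           present_alleles = list(optimal$present_alleles)),
    bands)
  class(out) <- c("solution_bands", class(out))
  out
}

#' Prefix consistency of an allele call
#'
#' The number of consecutive near-optimal solution bands (in increasing
#' delta order, starting after the optimum) in which the allele remains
#' present; counting stops at the first band from which it is absent.  An
#' allele present only in the optimal solution scores 0; one present in
#' every band scores the number of bands.
#'
#' @param allele_id Allele to score (must be present in the optimum).
#' @param bands A `solution_bands` tibble.
#' @return Integer in `[0, n_bands]`.
#' @export
prefix_consistency <- function(allele_id, bands) {
  stopifnot(inherits(bands, "solution_bands"))
  opt <- bands$present_alleles[[which(bands$delta == 0)]]
  if (!allele_id %in% opt) {
    abort(paste0("allele ", allele_id, " is not in the optimal call set"))
  }
  later <- bands[bands$delta > 0, , drop = FALSE]
  pc <- 0L
  for (k in seq_len(nrow(later))) {
    if (allele_id %in% later$present_alleles[[k]]) pc <- pc + 1L else break
  }
  pc
}

#' Attach prefix-consistency scores to a call set
#'
#' @param calls A `vg_calls` tibble.
#' @param bands A `solution_bands` tibble for the same sample.
#' @return `calls` with `prefix_consistency` filled in.
#' @export
add_prefix_consistency <- function(calls, bands) {
  calls$prefix_consistency <- vapply(calls$allele_id, prefix_consistency,
                                     integer(1), bands = bands)
  calls
}

#' Calibrate per-gene confidence thresholds
#'
#' Given truth-labelled calls, scans every prefix-consistency threshold per
#' gene and reports PPV (precision among passing calls), recall, passing
#' proportion and the F-beta score (beta = 0.5 by default, prioritising
#' precision); the optimal threshold maximises F-beta, ties resolved to the
#' lower threshold.  Recall is computed against the gene's total
#' true-positive calls by default, or against a supplied per-gene truth
#' count (`truth_total` column) when `recall_denominator = "truth_total"`.
#'
#' @param calls_with_truth A data frame with columns `gene_id`,
#'   `allele_id`, `prefix_consistency` and `is_tp` (logical), and
#'   optionally `truth_total`.
#' @param beta F-beta weighting (beta < 1 weights precision more).
#' @param n_bands Number of near-optimal bands used (thresholds run
#'   0..n_bands).
#' @param recall_denominator `"tp_total"` or `"truth_total"`.
#' @return A tibble of class `vg_calibration`: per gene and threshold,
#'   `n_passing`, `passing_proportion`, `ppv`, `recall`, `f_beta`,
#'   `is_optimal`.
#' @export
calibrate_thresholds <- function(calls_with_truth, beta = 0.5, n_bands = 4L,
                                 recall_denominator = c("tp_total", "truth_total")) {
  recall_denominator <- match.arg(recall_denominator)
  stopifnot(all(c("gene_id", "prefix_consistency", "is_tp") %in%
                  names(calls_with_truth)))
  out <- calls_with_truth |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      denom <- switch(recall_denominator,
                      tp_total = sum(g$is_tp),
                      truth_total = g$truth_total[1])
      purrr::map_dfr(0:n_bands, function(t) {
        passing <- g[g$prefix_consistency >= t, , drop = FALSE]
        if (nrow(passing) == 0L) return(NULL)  # PPV undefined: skip
        ppv <- sum(passing$is_tp) / nrow(passing)
        recall <- if (denom > 0) sum(passing$is_tp) / denom else NA_real_
        f <- if (!is.na(recall) && (beta^2 * ppv + recall) > 0) {
          (1 + beta^2) * ppv * recall / (beta^2 * ppv + recall)
        } else 0
        tibble(threshold = t, n_passing = nrow(passing),
               passing_proportion = nrow(passing) / nrow(g),
               ppv = ppv, recall = recall, f_beta = f)
      })
    }) |>
    dplyr::ungroup()
  # optimal threshold: first (lowest-t) argmax of F-beta within each gene
  out <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(is_optimal = .data$threshold ==
                    .data$threshold[which.max(.data$f_beta)]) |>
    dplyr::ungroup()
  class(out) <- c("vg_calibration", class(out))
  out
}
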