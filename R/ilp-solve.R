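# MILP backend bridge.  Models are serialised to JSON and solved by the
# bundled inst/python/milp_solve.py, which calls scipy.optimize.milp
# (HiGHS, single-threaded and deterministic).  Several models can be solved
# in one interpreter invocation; the confidence bands and the test-suite
# oracle batches use that.

find_python <- function() {
  py <- getOption("vgenotyper.python", Sys.getenv("VGENOTYPER_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) abort("no `python` found on PATH for the MILP backend")
  py
}

finite_or <- function(x, sub) ifelse(is.finite(x), x, sign(x) * sub)

# Solve a list of vg_ilp models (optionally with one extra objective-bound
# row each); returns a list of raw results (status, objective, x).
solve_models_raw <- function(models, extra_rows = NULL) {
  payload <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    A <- m$A; rlb <- m$rlb; rub <- m$rub; nrow_ <- m$n_rows
    ex <- extra_rows[[k]]
    if (!is.null(ex)) {
      A <- list(i = c(A$i, rep(nrow_, length(ex$j))), j = c(A$j, ex$j),
                v = c(A$v, ex$v))
      rlb <- c(rlb, ex$lo); rub <- c(rub, ex$hi)
      nrow_ <- nrow_ + 1L
    }
    list(n_vars = m$n_vars, n_rows = nrow_,
         obj = I(m$obj),
         lb = I(finite_or(m$lb, 1e30)), ub = I(finite_or(m$ub, 1e30)),
         ai = I(A$i), aj = I(A$j), av = I(A$v),
         rlb = I(finite_or(rlb, 1e30)), rub = I(finite_or(rub, 1e30)),
         time_limit = m$params$time_limit, mip_gap = m$params$mip_gap)
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(list(models = payload), infile,
                       auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "vgenotyper")
  if (!nzchar(script)) abort("bundled MILP bridge script not found")
  status <- system2(find_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile)) {
    abort("MILP backend failed (python/scipy unavailable or solver error)")
  }
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

solution_from_x <- function(model, x, objective, status) {
  vars <- model$vars
  xi <- round(unlist(x))
  is_x <- vars$type == "x"
  chosen <- is_x & xi > 0.5
  assigned <- tibble(read_id = vars$read_id[chosen],
                     allele_id = vars$allele_id[chosen])
  discarded <- setdiff(model$reads, assigned$read_id)
  assignments <- dplyr::bind_rows(
    assigned,
    tibble(read_id = c(discarded, model$zero_candidate_reads),
           allele_id = NA_character_)) |>
    dplyr::arrange(.data$read_id)
  is_c <- vars$type == "c"
  alleles <- tibble(allele_id = vars$allele_id[is_c],
                    copy_number = as.integer(xi[is_c])) |>
    dplyr::arrange(.data$allele_id)
  structure(list(status = status,
                 objective = objective + model$obj_offset,
                 assignments = assignments,
                 alleles = alleles,
                 present_alleles = alleles$allele_id[alleles$copy_number >= 1L],
                 params = model$params),
            class = "vg_solution")
}

#' Solve the read-assignment ILP
#'
#' Runs the MILP backend (HiGHS through scipy, deterministic for a fixed
#' model) and returns the optimal assignment.  The model is always feasible
#' in principle --- any read can be discarded --- so infeasibility indicates
#' contradictory depth bounds; the error suggests a larger `sd_scaling`.
#'
#' @param model A `vg_ilp` from [build_model()].
#' @return A list of class `vg_solution`: `status`, `objective`,
#'   `assignments` (read_id, allele_id or NA = discarded), `alleles`
#'   (allele_id, copy_number) and `present_alleles`.
#' @export
solve_assignment <- function(model) {
  res <- solve_models_raw(list(model))[[1]]
  if (identical(res$status, "infeasible")) {
    abort("ILP infeasible: depth-consistency window too tight; increase sd_scaling")
  }
  if (!identical(res$status, "optimal")) {
    abort(paste0("MILP solve failed with status: ", res$status))
  }
  solution_from_x(model, res$x, res$objective, "optimal")
}

#' @export
print.vg_solution <- function(x, ...) {
  nd <- sum(is.na(x$assignments$allele_id))
  cat(sprintf("<vg_solution> %s; objective %.3f; %d reads (%d discarded); %d alleles called\n",
              x$status, x$objective, nrow(x$assignments), nd,
              length(x$present_alleles)))
  invisible(x)
}

# Feasible copy numbers for one allele given its per-group coverage values:
# integers c in 1..copy_max with every group mean in [c*(mu-tol), c*(mu+tol)].
feasible_copies <- function(covs, mu, tol, copy_max) {
  ok <- vapply(seq_len(copy_max), function(cc) {
    all(covs >= cc * (mu - tol) - 1e-9) && all(covs <= cc * (mu + tol) + 1e-9)
  }, logical(1))
  which(ok)
}

#' Exhaustive oracle for small read-assignment instances
#'
#' Enumerates every combination of per-read assignment/discard and checks
#' depth feasibility of each induced allele set, returning a
#' minimum-objective solution (ties broken towards lexicographically
#' smaller present-allele sets).  Guard rails restrict use to tiny
#' instances; this is the independent reference for [solve_assignment()].
#'
#' @inheritParams build_model
#' @param max_reads,max_alleles Guard rails on instance size.
#' @return A `vg_solution`.
#' @export
brute_force_solve <- function(table, db, depth, params = model_params(),
                              max_reads = 10L, max_alleles = 6L) {
  reads <- unique(table$read_id)
  alleles <- sort(unique(table$allele_id))
  if (length(reads) > max_reads || length(alleles) > max_alleles) {
    abort("instance too large for brute force enumeration")
  }
  zero_reads <- attr(table, "zero_candidate_reads") %||% character(0)
  read_length <- attr(table, "read_length") %||% abort("candidate table lacks read_length")
  P <- params$discard_penalty
  mu <- depth$mean_depth; tol <- params$sd_scaling * depth$sd_depth

  # per-candidate landmark coverage weights, split by allele and group
  w <- candidate_landmark_weights(table, db, read_length,
                                  params$n_groups, params$per_group)
  groups <- landmark_table(db[db$allele_id %in% alleles, , drop = FALSE],
                           params$n_groups, params$per_group) |>
    dplyr::distinct(.data$allele_id, .data$group)

  options_per_read <- lapply(reads, function(r) c(which(table$read_id == r), 0L))
  combos <- expand.grid(rev(options_per_read), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(options_per_read)), drop = FALSE]

  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    pick <- as.integer(combos[ci, ])
    cand_rows <- pick[pick > 0L]
    objective <- sum(table$edit_distance[cand_rows]) + P * sum(pick == 0L)
    if (!is.null(best) && objective > best$objective) next
    used_alleles <- sort(unique(table$allele_id[cand_rows]))
    copies <- setNames(integer(length(alleles)), alleles)
    feasible <- TRUE
    for (a in used_alleles) {
      agroups <- groups$group[groups$allele_id == a]
      covs <- vapply(agroups, function(g) {
        sum(w$w[w$cand %in% cand_rows & w$allele_id == a & w$group == g])
      }, numeric(1))
      fc <- feasible_copies(covs, mu, tol, params$copy_max)
      if (length(fc) == 0L) { feasible <- FALSE; break }
      copies[a] <- min(fc)
    }
    if (!feasible) next
    key <- paste(used_alleles, collapse = ",")
    if (is.null(best) || objective < best$objective ||
        (objective == best$objective && key < best$key)) {
      best <- list(objective = objective, pick = pick, copies = copies, key = key)
    }
  }
  assigned <- tibble(
    read_id = reads[best$pick > 0L],
    allele_id = table$allele_id[best$pick[best$pick > 0L]])
  assignments <- dplyr::bind_rows(
    assigned,
    tibble(read_id = c(reads[best$pick == 0L], zero_reads),
           allele_id = NA_character_)) |>
    dplyr::arrange(.data$read_id)
  alleles_tbl <- tibble(allele_id = alleles,
                        copy_number = as.integer(best$copies)) |>
    dplyr::arrange(.data$allele_id)
  structure(list(status = "optimal",
                 objective = best$objective + P * length(zero_reads),
                 assignments = assignments, alleles = alleles_tbl,
                 present_alleles = alleles_tbl$allele_id[alleles_tbl$copy_number >= 1L],
                 params = params),
            class = "vg_solution")
}

#' Extract genotype calls from a solution
#'
#' One call per allele with copy number >= 1, annotated with assigned read
#' count and mean edit distance, grouped by gene and stably sorted.
#'
#' @param solution A `vg_solution`.
#' @param db The [allele_db] (for gene grouping).
#' @param table Optional `candidate_tbl` to recover per-assignment edit
#'   distances (defaults to distances of the chosen candidates when the
#'   solution came from [solve_assignment()] on a model that kept them).
#' @return A tibble of class `vg_calls`: `gene_id`, `allele_id`,
#'   `copy_number`, `n_assigned_reads`, `mean_edit_distance`,
#'   `prefix_consistency` (NA until confidence analysis runs).
#' @export
calls_from_solution <- function(solution, db, table = NULL) {
  present <- solution$alleles |> dplyr::filter(.data$copy_number >= 1L)
  assigned <- solution$assignments |> dplyr::filter(!is.na(.data$allele_id))
  if (!is.null(table)) {
    assigned <- dplyr::left_join(assigned,
                                 dplyr::select(table, "read_id", "allele_id", "edit_distance"),
                                 by = c("read_id", "allele_id"))
  } else {
    assigned$edit_distance <- NA_real_
  }
  stats <- assigned |>
    dplyr::group_by(.data$allele_id) |>
    dplyr::summarise(n_assigned_reads = dplyr::n(),
                     mean_edit_distance = mean(.data$edit_distance),
                     .groups = "drop")
  out <- present |>
    dplyr::left_join(stats, by = "allele_id") |>
    dplyr::mutate(
      gene_id = db$gene_id[match(.data$allele_id, db$allele_id)],
      gene_id = dplyr::coalesce(.data$gene_id, sub("\\*.*$", "", .data$allele_id)),
      n_assigned_reads = dplyr::coalesce(.data$n_assigned_reads, 0L),
      prefix_consistency = NA_integer_) |>
    dplyr::select("gene_id", "allele_id", "copy_number", "n_assigned_reads",
                  "mean_edit_distance", "prefix_consistency") |>
    dplyr::arrange(.data$gene_id, .data$allele_id)
  class(out) <- c("vg_calls", class(out))
  out
}
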