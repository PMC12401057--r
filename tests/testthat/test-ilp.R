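# Toy instances use one landmark group with one landmark (core 36, landmark
# at offset 18) and start 0 with a long read length, so every candidate
# covers every landmark and an allele's coverage equals its assigned read
# count.
toy_params <- function(...) {
  model_params(n_groups = 1L, per_group = 1L, sd_scaling = 1.5,
               discard_penalty = 51, copy_max = 4L, ...)
}

test_that("model dimensions match closed-form counts", {
  db <- toy_db(c("A*01", "B*01"))
  tab <- toy_candidates(data.frame(
    read_id = c("r1", "r1", "r2"), allele_id = c("A*01", "B*01", "A*01"),
    edit_distance = c(0L, 1L, 2L)))
  dp <- depth_profile(2, 0.5)
  m <- build_model(tab, db, dp, toy_params())
  n_cand <- 3L; n_r <- 2L; n_a <- 2L; n_groups_total <- 2L
  expect_equal(m$n_vars, n_cand + n_r + 2L * n_a)
  # rows: assignment (n_r) + x<=z (n_cand) + 2 allele-copy links + depth lo/hi
  expect_equal(m$n_rows, n_r + n_cand + 2L * n_a + 2L * n_groups_total)
  expect_equal(length(m$rlb), m$n_rows)
  expect_equal(length(m$obj), m$n_vars)
})

test_that("a tiling read set at nominal depth is explained with one copy and no discards", {
  db <- toy_db("A*01")
  tab <- toy_candidates(data.frame(
    read_id = sprintf("r%d", 1:10), allele_id = "A*01",
    edit_distance = rep(0L, 10)))
  dp <- depth_profile(10, 1)
  sol <- solve_assignment(build_model(tab, db, dp, toy_params()))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  expect_equal(sol$alleles$copy_number, 1L)
  expect_equal(sum(is.na(sol$assignments$allele_id)), 0L)
})

test_that("doubled coverage of a single allele is called at copy two", {
  db <- toy_db("A*01")
  tab <- toy_candidates(data.frame(
    read_id = sprintf("r%d", 1:20), allele_id = "A*01",
    edit_distance = rep(0L, 20)))
  dp <- depth_profile(10, 1)
  sol <- solve_assignment(build_model(tab, db, dp, toy_params()))
  bf <- brute_force_solve(tab, db, dp, toy_params(), max_reads = 20L)
  expect_equal(sol$objective, bf$objective)
  expect_equal(sol$alleles$copy_number, 2L)
})

test_that("reads are discarded rather than the model going infeasible", {
  db <- toy_db("A*01")
  # far too few reads to justify one copy at depth 10 +- 1.5
  tab <- toy_candidates(data.frame(read_id = "r1", allele_id = "A*01",
                                   edit_distance = 0L))
  dp <- depth_profile(10, 1)
  sol <- solve_assignment(build_model(tab, db, dp, toy_params()))
  expect_equal(sol$objective, 51)
  expect_equal(sum(is.na(sol$assignments$allele_id)), 1L)
  expect_length(sol$present_alleles, 0L)
})

test_that("zero-candidate reads are pre-discarded with the additive penalty", {
  db <- toy_db("A*01")
  tab <- toy_candidates(data.frame(
    read_id = sprintf("r%d", 1:10), allele_id = "A*01",
    edit_distance = rep(1L, 10)),
    zero_candidate_reads = c("lost1", "lost2"))
  dp <- depth_profile(10, 1)
  sol <- solve_assignment(build_model(tab, db, dp, toy_params()))
  expect_equal(sol$objective, 10 + 2 * 51)
  expect_true(all(c("lost1", "lost2") %in%
                    sol$assignments$read_id[is.na(sol$assignments$allele_id)]))
  # conservation: every read exactly once
  expect_equal(sort(sol$assignments$read_id),
               sort(c(sprintf("r%d", 1:10), "lost1", "lost2")))
})

test_that("solver agrees with the brute-force oracle on random guarded instances", {
  set.seed(424)
  alleles <- c("A*01", "B*01", "C*01")
  db <- toy_db(alleles)
  dp <- depth_profile(2, 1)
  params <- model_params(n_groups = 1L, per_group = 1L, sd_scaling = 1.5,
                         discard_penalty = 11, copy_max = 2L)
  models <- list(); oracles <- list()
  n_inst <- 40L
  for (k in seq_len(n_inst)) {
    n_r <- sample(2:6, 1)
    rows <- purrr::map_dfr(seq_len(n_r), function(r) {
      picks <- sample(alleles, sample(1:3, 1))
      tibble::tibble(read_id = sprintf("r%d", r), allele_id = picks,
                     edit_distance = sample(0:5, length(picks), replace = TRUE))
    })
    tab <- toy_candidates(rows)
    models[[k]] <- build_model(tab, db, dp, params)
    oracles[[k]] <- brute_force_solve(tab, db, dp, params)
  }
  res <- vgenotyper:::solve_models_raw(models)
  for (k in seq_len(n_inst)) {
    expect_equal(res[[k]]$status, "optimal")
    expect_equal(res[[k]]$objective + models[[k]]$obj_offset,
                 oracles[[k]]$objective,
                 tolerance = 1e-9, label = sprintf("instance %d", k))
  }
})

test_that("increasing the depth tolerance never worsens the optimum", {
  set.seed(77)
  db <- toy_db(c("A*01", "B*01"))
  dp <- depth_profile(3, 1)
  rows <- purrr::map_dfr(1:6, function(r) {
    picks <- sample(c("A*01", "B*01"), sample(1:2, 1))
    tibble::tibble(read_id = sprintf("r%d", r), allele_id = picks,
                   edit_distance = sample(0:4, length(picks), replace = TRUE))
  })
  tab <- toy_candidates(rows)
  objs <- vapply(c(0.5, 1, 1.5, 2.5), function(s) {
    brute_force_solve(tab, db, dp,
                      model_params(n_groups = 1L, per_group = 1L,
                                   sd_scaling = s, discard_penalty = 11,
                                   copy_max = 2L))$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-9))
})

test_that("calls are grouped by gene with read statistics and conservation", {
  db <- toy_db(c("IGLV2-14*01", "IGLV2-14*04"))
  tab <- toy_candidates(dplyr::bind_rows(
    data.frame(read_id = sprintf("a%d", 1:10), allele_id = "IGLV2-14*01",
               edit_distance = 0L),
    data.frame(read_id = sprintf("b%d", 1:10), allele_id = "IGLV2-14*04",
               edit_distance = 1L)))
  dp <- depth_profile(10, 1)
  sol <- solve_assignment(build_model(tab, db, dp, toy_params()))
  calls <- calls_from_solution(sol, db, tab)
  expect_equal(nrow(calls), 2L)
  expect_equal(unique(calls$gene_id), "IGLV2-14")
  expect_setequal(calls$allele_id, c("IGLV2-14*01", "IGLV2-14*04"))
  expect_equal(sum(calls$n_assigned_reads) +
                 sum(is.na(sol$assignments$allele_id)), 20L)
  expect_equal(calls$mean_edit_distance[calls$allele_id == "IGLV2-14*04"], 1)

  empty <- structure(list(status = "optimal", objective = 0,
                          assignments = tibble::tibble(read_id = character(0),
                                                       allele_id = character(0)),
                          alleles = tibble::tibble(allele_id = character(0),
                                                   copy_number = integer(0)),
                          present_alleles = character(0)),
                     class = "vg_solution")
  expect_equal(nrow(calls_from_solution(empty, db)), 0L)
})
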