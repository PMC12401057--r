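#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genotyping result into its call table
#'
#' @param x A `vg_genotype`.
#' @param ... Unused.
#' @return The `vg_calls` tibble.
#' @export
tidy.vg_genotype <- function(x, ...) as_tibble(x$calls)

#' One-row summary of a genotyping result
#'
#' @param x A `vg_genotype`.
#' @param ... Unused.
#' @return Tibble with objective, solver status, read/call counts.
#' @export
glance.vg_genotype <- function(x, ...) {
  sol <- x$solution
  tibble(
    status = sol$status %||% "empty",
    objective = sol$objective %||% NA_real_,
    n_reads = if (is.null(sol)) 0L else nrow(sol$assignments),
    n_discarded = if (is.null(sol)) 0L else sum(is.na(sol$assignments$allele_id)),
    n_calls = nrow(x$calls),
    n_genes = dplyr::n_distinct(x$calls$gene_id),
    mean_depth = x$depth$mean_depth,
    sd_depth = x$depth$sd_depth)
}

#' Tidy an assignment solution
#'
#' @param x A `vg_solution`.
#' @param ... Unused.
#' @return The per-read assignment tibble (`allele_id` NA = discarded).
#' @export
tidy.vg_solution <- function(x, ...) as_tibble(x$assignments)

#' One-row summary of an assignment solution
#'
#' @param x A `vg_solution`.
#' @param ... Unused.
#' @return Tibble with status, objective and counts.
#' @export
glance.vg_solution <- function(x, ...) {
  tibble(status = x$status, objective = x$objective,
         n_reads = nrow(x$assignments),
         n_discarded = sum(is.na(x$assignments$allele_id)),
         n_alleles_called = length(x$present_alleles))
}

#' Tidy a concordance result
#'
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.concordance_result <- function(x, ...) as_tibble(x$per_gene)

#' One-row summary of a concordance result
#'
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return Tibble with the trio concordance and counts.
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(trio_concordance = x$trio_concordance,
         n_genes = length(x$denominator),
         n_concordant = sum(x$per_gene$concordant),
         n_parent_missing = sum(x$per_gene$reason == "parent_missing"))
}
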