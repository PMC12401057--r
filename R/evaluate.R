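#' Mendelian concordance of one gene in a trio
#'
#' Implements the per-gene inheritance rules: with two child copies, one
#' copy's allele must be present in the mother's calls and the other's in
#' the father's (in some order); with more than two copies, some pair of
#' distinct copies must be explainable one from each parent; with a single
#' copy, the allele must be present in at least one parent.  A gene whose
#' required parental calls are missing is nonconcordant with reason
#' `parent_missing`.  Symmetric in mother and father.
#'
#' @param child,mother,father Character vectors of allele ids
#'   (copy-expanded multisets; one element per called copy).
#' @return A list with `concordant` (logical) and `reason` (one of
#'   `two_copy_match`, `multi_copy_pair`, `single_in_parent`,
#'   `unexplained`, `parent_missing`).
#' @export
gene_concordance <- function(child, mother, father) {
  n <- length(child)
  if (n == 0L) abort("child multiset must be non-empty")
  if (n == 1L) {
    if (length(mother) == 0L && length(father) == 0L) {
      return(list(concordant = FALSE, reason = "parent_missing"))
    }
    ok <- child %in% c(mother, father)
    return(list(concordant = ok,
                reason = if (ok) "single_in_parent" else "unexplained"))
  }
  if (length(mother) == 0L || length(father) == 0L) {
    return(list(concordant = FALSE, reason = "parent_missing"))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (child[i] %in% mother && child[j] %in% father) {
        return(list(concordant = TRUE,
                    reason = if (n == 2L) "two_copy_match" else "multi_copy_pair"))
      }
    }
  }
  list(concordant = FALSE, reason = "unexplained")
}

#' Trio-level Mendelian concordance
#'
#' Evaluates [gene_concordance()] for every gene in the denominator set and
#' reports the concordant fraction.  The default denominator is every
#' functional gene with at least one child call (genes absent from the
#' child cannot be tested under the stated rules); a fixed gene set can be
#' supplied instead for loci conventionally scored over all genes.
#'
#' @param child,mother,father Data frames with columns `gene_id`,
#'   `allele_id`, one row per called copy (e.g. `sim_genotype` tibbles or
#'   copy-expanded `vg_calls`).
#' @param db Optional [allele_db]; when given, non-functional genes are
#'   excluded from the default denominator.
#' @param denominator Optional character vector fixing the gene set.
#' @return A list of class `concordance_result`: `per_gene` tibble
#'   (`gene_id`, `concordant`, `reason`), `trio_concordance` (fraction; NA
#'   when the denominator is empty) and `denominator`.
#' @export
trio_concordance <- function(child, mother, father, db = NULL,
                             denominator = NULL) {
  child <- as_tibble(child); mother <- as_tibble(mother); father <- as_tibble(father)
  genes <- if (!is.null(denominator)) denominator else {
    g <- unique(child$gene_id)
    if (!is.null(db)) {
      functional_genes <- unique(db$gene_id[db$functional])
      g <- intersect(g, functional_genes)
    }
    sort(g)
  }
  per_gene <- purrr::map_dfr(genes, function(g) {
    ch <- child$allele_id[child$gene_id == g]
    if (length(ch) == 0L) {
      return(tibble(gene_id = g, concordant = FALSE, reason = "unexplained"))
    }
    res <- gene_concordance(ch,
                            mother$allele_id[mother$gene_id == g],
                            father$allele_id[father$gene_id == g])
    tibble(gene_id = g, concordant = res$concordant, reason = res$reason)
  })
  rate <- if (nrow(per_gene) == 0L) NA_real_ else mean(per_gene$concordant)
  structure(list(per_gene = per_gene, trio_concordance = rate,
                 denominator = genes),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s over %d genes\n",
              ifelse(is.na(x$trio_concordance), "NA",
                     sprintf("%.4f", x$trio_concordance)),
              length(x$denominator)))
  invisible(x)
}

multiset_intersection_size <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Allele-presence precision and recall
#'
#' By default copy numbers are ignored (set semantics), matching how calls
#' are benchmarked against unphased assembly annotations whose CNV counts
#' are unreliable; `cnv_sensitive = TRUE` uses multiset intersection
#' counts instead.
#'
#' @param calls,truth Character vectors of allele ids (repeats = copies).
#' @param cnv_sensitive Use multiset (copy-aware) intersection.
#' @return A tibble with `precision` and `recall` (NA when undefined:
#'   empty calls or empty truth respectively).
#' @export
presence_precision_recall <- function(calls, truth, cnv_sensitive = FALSE) {
  if (!cnv_sensitive) {
    calls <- unique(calls); truth <- unique(truth)
  }
  inter <- multiset_intersection_size(calls, truth)
  tibble(
    precision = if (length(calls) == 0L) NA_real_ else inter / length(calls),
    recall = if (length(truth) == 0L) NA_real_ else inter / length(truth))
}

#' Annotate assembly contigs with allele presence
#'
#' An allele is present in the sample iff its full core sequence occurs in
#' some contig (either strand) with at most `max_mismatches` mismatches and
#' no indels.  Output is a set: an allele found on several (overlapping)
#' contigs is reported once.  Deterministic exact/near-exact search, suited
#' to short alleles against modest contigs.
#'
#' @param contigs A named character vector, `Biostrings::DNAStringSet`, or
#'   path to a FASTA file.
#' @param db The [allele_db] whose alleles are searched for.
#' @param max_mismatches Mismatch budget (default 0, exact match).
#' @return Sorted character vector of present allele ids.
#' @export
annotate_contigs <- function(contigs, db, max_mismatches = 0L) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  } else if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (length(contigs) == 0L) abort("contigs must be non-empty")
  cores <- core_sequence(db)
  present <- vapply(cores, function(cs) {
    pat <- Biostrings::DNAString(cs)
    fwd <- Biostrings::vcountPattern(pat, contigs, max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    if (any(fwd > 0L)) return(TRUE)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), contigs,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    any(rev > 0L)
  }, logical(1))
  sort(db$allele_id[present])
}
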