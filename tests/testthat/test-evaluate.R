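test_that("gene concordance implements the per-copy inheritance rules", {
  # two copies, one from each parent (in either order)
  expect_true(gene_concordance(c("x*01", "x*02"), c("x*01", "x*03"),
                               c("x*02", "x*02"))$concordant)
  r <- gene_concordance(c("x*02", "x*01"), c("x*01", "x*03"), c("x*02", "x*02"))
  expect_true(r$concordant)
  expect_equal(r$reason, "two_copy_match")
  # homozygous child needs the allele in BOTH parents
  r2 <- gene_concordance(c("x*01", "x*01"), c("x*01", "x*02"), c("x*03"))
  expect_false(r2$concordant)
  expect_equal(r2$reason, "unexplained")
  expect_true(gene_concordance(c("x*01", "x*01"), c("x*01", "x*02"),
                               c("x*03", "x*01"))$concordant)
  # single copy: at least one parent
  r3 <- gene_concordance("x*01", character(0), "x*01")
  expect_true(r3$concordant)
  expect_equal(r3$reason, "single_in_parent")
  # >2 copies: some pair of distinct copies, one per parent
  r4 <- gene_concordance(c("x*01", "x*02", "x*05"), c("x*05"), c("x*02", "x*03"))
  expect_true(r4$concordant)
  expect_equal(r4$reason, "multi_copy_pair")
  expect_false(gene_concordance(c("x*01", "x*01", "x*01"), c("x*01"),
                                c("x*02"))$concordant)
  # missing parental data
  r5 <- gene_concordance(c("x*01", "x*02"), character(0), c("x*01", "x*02"))
  expect_false(r5$concordant)
  expect_equal(r5$reason, "parent_missing")
  r6 <- gene_concordance("x*01", character(0), character(0))
  expect_equal(r6$reason, "parent_missing")
})

test_that("gene concordance is symmetric in the parents", {
  set.seed(321)
  pool <- sprintf("g*%02d", 1:5)
  for (i in 1:50) {
    ch <- sample(pool, sample(1:3, 1), replace = TRUE)
    mo <- sample(pool, sample(0:2, 1), replace = TRUE)
    fa <- sample(pool, sample(0:2, 1), replace = TRUE)
    expect_equal(gene_concordance(ch, mo, fa)$concordant,
                 gene_concordance(ch, fa, mo)$concordant)
  }
})

test_that("trio concordance counts concordant genes over the child-called denominator", {
  db <- generate_locus(n_genes = 6, alleles_per_gene = 5, seed = 201)
  trio <- simulate_trio(db, seed = 202, n_discordant = 1)
  res <- trio_concordance(trio$child, trio$mother, trio$father, db = db)
  expect_equal(res$trio_concordance, 5 / 6)
  expect_equal(sum(!res$per_gene$concordant), 1L)
  expect_equal(res$per_gene$gene_id[!res$per_gene$concordant],
               attr(trio, "discordant_genes"))

  all_bad <- trio_concordance(
    tibble::tibble(gene_id = c("g1", "g2"), allele_id = c("g1*09", "g2*09")),
    tibble::tibble(gene_id = c("g1", "g2"), allele_id = c("g1*01", "g2*01")),
    tibble::tibble(gene_id = c("g1", "g2"), allele_id = c("g1*02", "g2*02")))
  expect_equal(all_bad$trio_concordance, 0)

  none <- trio_concordance(tibble::tibble(gene_id = character(0),
                                          allele_id = character(0)),
                           trio$mother, trio$father)
  expect_true(is.na(none$trio_concordance))
})

test_that("non-functional genes are excluded from the default denominator", {
  db <- generate_locus(n_genes = 4, alleles_per_gene = 5, seed = 205)
  db$functional[db$gene_id == "SYNV4"] <- FALSE
  trio <- simulate_trio(db, seed = 206)
  res <- trio_concordance(trio$child, trio$mother, trio$father, db = db)
  expect_equal(length(res$denominator), 3L)
  expect_false("SYNV4" %in% res$denominator)
})

test_that("presence precision/recall handles set and multiset semantics", {
  pr <- presence_precision_recall(c("A", "B"), c("A", "C"))
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)
  same <- presence_precision_recall(c("A", "B"), c("B", "A"))
  expect_equal(c(same$precision, same$recall), c(1, 1))
  multi <- presence_precision_recall(c("A", "A"), "A", cnv_sensitive = TRUE)
  expect_equal(multi$precision, 0.5)
  expect_equal(multi$recall, 1)
  # copy-insensitive: duplicates collapse
  expect_equal(presence_precision_recall(c("A", "A"), "A")$precision, 1)
  expect_true(is.na(presence_precision_recall(character(0), "A")$precision))
  expect_true(is.na(presence_precision_recall("A", character(0))$recall))
})

test_that("contig annotation finds planted alleles within the mismatch budget", {
  db <- generate_locus(n_genes = 3, alleles_per_gene = 2, seed = 211)
  planted <- db$allele_id[c(1, 3)]
  cores <- substr(db$sequence, db$core_start + 1, db$core_end)
  spacer <- function(n) strrep("T", n)
  contig1 <- paste0(spacer(50), cores[1], spacer(40), cores[3], spacer(30))
  # the same allele on a second, overlapping contig must not double count
  contig2 <- paste0(spacer(10), cores[3], spacer(20))
  # reverse-strand copy
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cores[1])))
  contig3 <- paste0(spacer(15), rc, spacer(15))
  found <- annotate_contigs(c(c1 = contig1, c2 = contig2, c3 = contig3), db)
  expect_equal(found, sort(planted))

  # one planted mismatch: absent at budget 0, present at budget 1
  mut <- cores[2]
  substr(mut, 100, 100) <- if (substr(mut, 100, 100) == "A") "C" else "A"
  contig_mut <- paste0(spacer(25), mut, spacer(25))
  expect_false(db$allele_id[2] %in% annotate_contigs(contig_mut, db, 0L))
  expect_true(db$allele_id[2] %in% annotate_contigs(contig_mut, db, 1L))
})

test_that("simulated trios score (G - k)/G for k injected discordances", {
  for (G in c(6L, 20L)) {
    db <- generate_locus(n_genes = G, alleles_per_gene = 5, seed = 300 + G)
    for (k in 0:2) {
      trio <- simulate_trio(db, seed = 310 + G + k, n_discordant = k)
      res <- trio_concordance(trio$child, trio$mother, trio$father, db = db)
      expect_equal(res$trio_concordance, (G - k) / G)
    }
  }
})
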