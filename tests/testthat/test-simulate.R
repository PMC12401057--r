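test_that("locus generation is seed-deterministic and respects divergence", {
  db1 <- generate_locus(n_genes = 20, alleles_per_gene = 3,
                        gene_divergence = 0.05, allele_divergence = 0.01,
                        seed = 7)
  db2 <- generate_locus(n_genes = 20, alleles_per_gene = 3,
                        gene_divergence = 0.05, allele_divergence = 0.01,
                        seed = 7)
  expect_identical(db1$sequence, db2$sequence)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_allele_database(db1, f1); write_allele_database(db2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # within-gene pairwise divergence matches the closed-form substitution
  # model: P(site differs) = 2q(1-q) + (2/3)q^2
  q <- 0.01
  p_diff <- 2 * q * (1 - q) + (2 / 3) * q^2
  divs <- unlist(lapply(unique(db1$gene_id), function(g) {
    s <- strsplit(db1$sequence[db1$gene_id == g], "")
    utils::combn(length(s), 2, function(ij) {
      mean(s[[ij[1]]] != s[[ij[2]]])
    })
  }))
  n_sites <- sum(nchar(db1$sequence)) # rough scale for the binomial SE
  se <- sqrt(p_diff * (1 - p_diff) / (length(divs) * 290))
  expect_lt(abs(mean(divs) - p_diff), 4 * se + 0.001)
  expect_error(generate_locus(gene_divergence = 0.01, allele_divergence = 0.05),
               "allele_divergence")
})

test_that("zero allele divergence is refused only above gene divergence", {
  db <- generate_locus(n_genes = 2, alleles_per_gene = 2,
                       gene_divergence = 0.05, allele_divergence = 0, seed = 3)
  expect_equal(nrow(db), 4L)
})

test_that("genotype simulation follows the copy-number distribution", {
  db <- generate_locus(n_genes = 5, alleles_per_gene = 3, seed = 1)
  g <- simulate_genotype(db, seed = 2)
  expect_equal(unname(table(g$gene_id)), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(unique(g$haplotype), c("M", "P"))
  expect_true(all(g$allele_id %in% db$allele_id))

  empty <- simulate_genotype(db, cn_distribution = c("0" = 1), seed = 2)
  expect_equal(nrow(empty), 0L)

  big <- generate_locus(n_genes = 500, alleles_per_gene = 2, seed = 4,
                        length_range = c(60, 70), gene_divergence = 0.1,
                        allele_divergence = 0.01)
  mixed <- simulate_genotype(big, cn_distribution = c("1" = 0.5, "2" = 0.5),
                             seed = 5)
  mean_copies <- nrow(mixed) / 500
  se <- sqrt(0.25 / 500)
  expect_lt(abs(mean_copies - 1.5), 3 * se)
  expect_error(simulate_genotype(db, cn_distribution = c("2" = 0.5)), "sum to 1")
})

test_that("trio simulation is Mendelian unless discordances are injected", {
  db <- generate_locus(n_genes = 6, alleles_per_gene = 5, seed = 11)
  trio <- simulate_trio(db, seed = 12)
  res <- trio_concordance(trio$child, trio$mother, trio$father)
  expect_equal(res$trio_concordance, 1.0)

  trio2 <- simulate_trio(db, seed = 12)
  expect_identical(trio$child, trio2$child)

  disc <- simulate_trio(db, seed = 13, n_discordant = 1)
  g <- attr(disc, "discordant_genes")
  expect_length(g, 1L)
  bad <- disc$child$allele_id[disc$child$gene_id == g]
  parents <- c(disc$mother$allele_id[disc$mother$gene_id == g],
               disc$father$allele_id[disc$father$gene_id == g])
  expect_true(any(!bad %in% parents))
  expect_error(simulate_trio(db, seed = 13, n_discordant = 7), "exceeds")
})

test_that("read counts follow the uniform-coverage Poisson model", {
  db <- allele_db(tibble::tibble(allele_id = "G1*01",
                                 sequence = strrep("ACGT", 75)))  # core 300
  padded <- pad_alleles(db, 150L)
  geno <- tibble::tibble(sample_id = "s", gene_id = "G1",
                         allele_id = c("G1*01", "G1*01"), haplotype = c("M", "P"))
  reads <- simulate_reads(geno, padded, depth = 30, read_length = 150L,
                          error_rate = 0, seed = 21)
  lambda <- 2 * 30 * (300 + 150 - 1) / 150
  expect_lt(abs(nrow(reads) - lambda), 4 * sqrt(lambda))

  # error-free reads are exact substrings wherever the template is not N
  tmpl <- strsplit(padded$sequence, "")[[1]]
  for (i in head(seq_len(nrow(reads)), 25)) {
    r <- strsplit(reads$sequence[i], "")[[1]]
    t <- tmpl[(reads$truth_offset[i] + 1):(reads$truth_offset[i] + 150)]
    expect_true(all(r[t != "N"] == t[t != "N"]))
  }

  # per-core-base expected depth equals the nominal depth (interior bases)
  mid <- padded$core_start + 150
  cov_mid <- sum(reads$truth_offset <= mid & reads$truth_offset + 150 > mid)
  expect_lt(abs(cov_mid - 60), 4 * sqrt(60))
})

test_that("gene dropout silences a gene's reads", {
  fx <- small_locus_fixture(n_genes = 3, seed = 31)
  g <- unique(fx$genotype$gene_id)[1]
  reads <- simulate_reads(fx$genotype, fx$padded, depth = 10, seed = 32,
                          dropout_genes = g)
  expect_false(any(reads$truth_allele_id %in%
                     fx$db$allele_id[fx$db$gene_id == g]))
  expect_true(nrow(reads) > 0)
})

test_that("downsampling is binomial, seeded and an identity at fraction 1", {
  fx <- small_locus_fixture(n_genes = 4, seed = 41)
  reads <- fx$reads
  expect_identical(downsample_reads(reads, 1, seed = 1), reads)
  d1 <- downsample_reads(reads, 1 / 3, seed = 5)
  d2 <- downsample_reads(reads, 1 / 3, seed = 5)
  expect_identical(d1$read_id, d2$read_id)
  n <- nrow(reads)
  kept <- nrow(downsample_reads(reads, 2 / 3, seed = 6))
  expect_lt(abs(kept - 2 / 3 * n), 4 * sqrt(n * 2 / 9))
  expect_error(downsample_reads(reads, 0), "fraction")
})

test_that("read truth labels partition the read set", {
  fx <- small_locus_fixture(n_genes = 3, seed = 51)
  counts <- table(fx$reads$truth_allele_id)
  expect_equal(sum(counts), nrow(fx$reads))
  expect_false(anyDuplicated(fx$reads$read_id) > 0)
})
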