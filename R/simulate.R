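#' Generate a synthetic multi-copy gene locus
#'
#' Emulates an immune-receptor V-gene family: one random ancestor sequence,
#' from which each gene diverges by point substitutions at
#' `gene_divergence`, and each allele of a gene by further substitutions at
#' `allele_divergence`.  Defaults mirror the field's loci: short genes
#' (280-300 bp), within-family identity around 80-90% and within-gene allele
#' identity around 98-99%.  Alleles within a gene are guaranteed distinct.
#' Deterministic for a fixed seed.
#'
#' @param n_genes,alleles_per_gene Locus size.
#' @param gene_divergence,allele_divergence Per-base substitution rates
#'   (must satisfy `0 <= allele_divergence < gene_divergence < 0.25`).
#' @param length_range Gene length range in bp, `c(min, max)`.
#' @param seed Integer seed.
#' @param indel_rate Per-base indel rate applied on top of substitutions
#'   when generating genes (default 0; substitution-only model).
#' @return An un-padded [allele_db]; genes are named `SYNV1..SYNVn`, alleles
#'   `SYNVi*01`, `SYNVi*02`, ...
#' @export
generate_locus <- function(n_genes = 20L, alleles_per_gene = 3L,
                           gene_divergence = 0.10, allele_divergence = 0.01,
                           length_range = c(280L, 300L), seed = 1L,
                           indel_rate = 0) {
  stopifnot(n_genes >= 1L, alleles_per_gene >= 1L)
  if (!(allele_divergence >= 0 && allele_divergence < gene_divergence &&
        gene_divergence < 0.25)) {
    abort("need 0 <= allele_divergence < gene_divergence < 0.25")
  }
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 30L) {
    abort("degenerate length_range")
  }
  with_seed(seed, {
    anc <- strsplit(random_dna(length_range[2]), "")[[1]]
    recs <- purrr::map_dfr(seq_len(n_genes), function(g) {
      lens <- length_range[1]:length_range[2]
      len <- lens[sample.int(length(lens), 1L)]
      gene_seq <- mutate_seq(anc[seq_len(len)], gene_divergence, indel_rate)
      alleles <- character(0)
      for (a in seq_len(alleles_per_gene)) {
        for (try in 1:50) {
          cand <- paste(mutate_seq(gene_seq, allele_divergence, 0), collapse = "")
          if (!cand %in% alleles) break
        }
        alleles <- c(alleles, cand)
      }
      tibble(
        allele_id = sprintf("SYNV%d*%02d", g, seq_len(alleles_per_gene)),
        gene_id = sprintf("SYNV%d", g),
        sequence = alleles
      )
    })
    allele_db(recs)
  })
}

# Point-substitute (and optionally indel) a character-vector sequence.
mutate_seq <- function(chars, sub_rate, indel_rate = 0) {
  n <- length(chars)
  hit <- which(runif(n) < sub_rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
  }
  if (indel_rate > 0) {
    ind <- which(runif(length(chars)) < indel_rate)
    for (i in rev(ind)) {
      if (runif(1) < 0.5 && length(chars) > 30L) {
        chars <- chars[-i]
      } else {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i)
      }
    }
  }
  chars
}

#' Simulate a diploid-with-CNV genotype
#'
#' Draws a copy number for every gene from `cn_distribution`, then draws
#' that many alleles uniformly with replacement from the gene's alleles and
#' splits the copies across the two haplotypes.  The default distribution
#' puts all mass on two copies (one per haplotype).
#'
#' @param db An [allele_db].
#' @param cn_distribution Named numeric vector mapping copy number to
#'   probability (names are copy counts); probabilities must sum to 1.
#' @param seed Integer seed.
#' @param sample_id Sample label stored in the output.
#' @return A tibble of class `sim_genotype`, one row per gene copy:
#'   `sample_id`, `gene_id`, `allele_id`, `haplotype` (`"M"`/`"P"`).
#' @export
simulate_genotype <- function(db, cn_distribution = c("2" = 1), seed = 1L,
                              sample_id = "sample") {
  p <- as.numeric(cn_distribution)
  cn_vals <- as.integer(names(cn_distribution))
  if (anyNA(cn_vals) || any(cn_vals < 0L)) abort("cn_distribution names must be copy counts")
  if (abs(sum(p) - 1) > 1e-8) abort("cn_distribution probabilities must sum to 1")
  genes <- unique(db$gene_id)
  with_seed(seed, {
    out <- purrr::map_dfr(genes, function(g) {
      cn <- cn_vals[sample.int(length(cn_vals), 1L, prob = p)]
      if (cn == 0L) return(NULL)
      alleles <- db$allele_id[db$gene_id == g]
      picked <- sample(alleles, cn, replace = TRUE)
      hap <- rep(c("M", "P"), length.out = cn)
      if (cn > 1L) hap <- sample(hap)
      tibble(sample_id = sample_id, gene_id = g, allele_id = picked, haplotype = hap)
    })
    if (nrow(out) == 0L) {
      out <- tibble(sample_id = character(0), gene_id = character(0),
                    allele_id = character(0), haplotype = character(0))
    }
    class(out) <- c("sim_genotype", class(out))
    out
  })
}

#' Simulate a parent-child trio with Mendelian inheritance
#'
#' Parents are drawn with [simulate_genotype()]; for every gene the child
#' inherits one uniformly chosen copy from each parent.  `n_discordant`
#' child genes then have one copy's allele replaced by an allele of the same
#' gene absent from both parents, injecting non-Mendelian events for
#' benchmarking the concordance machinery.
#'
#' @param db An [allele_db].
#' @param seed Integer seed.
#' @param n_discordant Number of child genes to make discordant.
#' @param cn_distribution Parent copy-number distribution (default: always
#'   two copies).
#' @return A list with elements `mother`, `father`, `child`
#'   (`sim_genotype` tibbles) and attribute `discordant_genes`.
#' @export
simulate_trio <- function(db, seed = 1L, n_discordant = 0L,
                          cn_distribution = c("2" = 1)) {
  seeds <- derive_seeds(seed, 3L)
  mother <- simulate_genotype(db, cn_distribution, seeds[1], "mother")
  father <- simulate_genotype(db, cn_distribution, seeds[2], "father")
  with_seed(seeds[3], {
    genes <- intersect(unique(mother$gene_id), unique(father$gene_id))
    child <- purrr::map_dfr(genes, function(g) {
      m <- mother$allele_id[mother$gene_id == g]
      f <- father$allele_id[father$gene_id == g]
      tibble(sample_id = "child", gene_id = g,
             allele_id = c(sample(m, 1L), sample(f, 1L)),
             haplotype = c("M", "P"))
    })
    disc_genes <- character(0)
    if (n_discordant > 0L) {
      child_genes <- unique(child$gene_id)
      if (n_discordant > length(child_genes)) {
        abort("n_discordant exceeds the number of child genes")
      }
      # genes where some allele is absent from both parents
      eligible <- purrr::keep(child_genes, function(g) {
        pool <- db$allele_id[db$gene_id == g]
        used <- c(mother$allele_id[mother$gene_id == g],
                  father$allele_id[father$gene_id == g])
        length(setdiff(pool, used)) > 0L
      })
      if (length(eligible) < n_discordant) {
        abort("not enough genes with an allele absent from both parents; increase alleles_per_gene")
      }
      disc_genes <- sample(eligible, n_discordant)
      for (g in disc_genes) {
        pool <- db$allele_id[db$gene_id == g]
        used <- c(mother$allele_id[mother$gene_id == g],
                  father$allele_id[father$gene_id == g])
        novel <- sample(setdiff(pool, used), 1L)
        idx <- which(child$gene_id == g)
        child$allele_id[sample(idx, 1L)] <- novel
      }
    }
    class(child) <- c("sim_genotype", class(child))
    structure(list(mother = mother, father = father, child = child),
              discordant_genes = sort(disc_genes), class = "sim_trio")
  })
}

#' Simulate uniform-coverage short reads from a genotype
#'
#' For each gene copy in the genotype, reads of length `read_length` start
#' uniformly over the window `core_start - read_length + 1 ..  core_end - 1`
#' of the padded allele, with a Poisson read count chosen so that the
#' expected depth at every core base equals `depth` per copy.  Template N
#' bases (the padding) are emitted as random bases: the flanking context is
#' unknown, not literally N.  Each base is substituted with a random
#' different base with probability `error_rate`.  Genes in `dropout_genes`
#' emit reads at `dropout_rate` times the nominal depth (default 0, i.e.
#' complete dropout, emulating V(D)J-rearrangement read loss).
#'
#' @param genotype A `sim_genotype` tibble.
#' @param db A padded [allele_db] with `pad_len >= read_length - 1`.
#' @param depth Expected per-copy coverage depth at each core base.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param dropout_genes Optional character vector of gene_ids.
#' @param dropout_rate Depth multiplier for dropout genes.
#' @return A tibble of class `read_set` with columns `read_id`, `sequence`,
#'   `truth_allele_id`, `truth_offset` (0-based start on the padded allele)
#'   and attributes `read_length` and `nominal_depth`.
#' @export
simulate_reads <- function(genotype, db, depth = 30, read_length = 150L,
                           error_rate = 0.005, seed = 1L,
                           dropout_genes = NULL, dropout_rate = 0) {
  read_length <- as.integer(read_length)
  if (db_pad_len(db) < read_length - 1L) {
    abort("db pad_len must be >= read_length - 1 (pad with pad_alleles() first)")
  }
  if (read_length > min(nchar(db$sequence))) {
    abort("read_length exceeds the shortest padded allele")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pieces <- vector("list", nrow(genotype))
    for (i in seq_len(nrow(genotype))) {
      aid <- genotype$allele_id[i]
      j <- match(aid, db$allele_id)
      if (is.na(j)) abort(paste0("genotype allele not in database: ", aid))
      core_len <- db$core_end[j] - db$core_start[j]
      d <- depth
      if (!is.null(dropout_genes) && genotype$gene_id[i] %in% dropout_genes) {
        d <- depth * dropout_rate
      }
      window <- core_len + read_length - 1L
      n <- rpois(1L, d * window / read_length)
      if (n == 0L) next
      starts <- db$core_start[j] - read_length + 1L +
        sample.int(window, n, replace = TRUE) - 1L
      tmpl <- strsplit(db$sequence[j], "")[[1]]
      seqs <- vapply(starts, function(s) {
        r <- tmpl[(s + 1L):(s + read_length)]
        nn <- r == "N"
        if (any(nn)) r[nn] <- sample(bases, sum(nn), replace = TRUE)
        err <- runif(read_length) < error_rate
        if (any(err)) {
          r[err] <- vapply(r[err], function(b) sample(setdiff(bases, b), 1L),
                           character(1))
        }
        paste(r, collapse = "")
      }, character(1))
      pieces[[i]] <- tibble(sequence = seqs, truth_allele_id = aid,
                            truth_offset = as.integer(starts))
    }
    out <- dplyr::bind_rows(pieces)
    if (nrow(out) == 0L) {
      out <- tibble(sequence = character(0), truth_allele_id = character(0),
                    truth_offset = integer(0))
    }
    out <- dplyr::mutate(out, read_id = sprintf("read%06d", dplyr::row_number()),
                         .before = 1L)
    structure(out, read_length = read_length, nominal_depth = depth,
              class = c("read_set", class(out)))
  })
}

#' Randomly downsample a read set
#'
#' Each read is kept independently with probability `fraction`; the same
#' seed always keeps the same subset.
#'
#' @param reads A `read_set` (or any tibble with one row per read).
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return The subsetted read set (attributes preserved).
#' @export
downsample_reads <- function(reads, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  if (fraction == 1) return(reads)
  keep <- with_seed(seed, runif(nrow(reads)) < fraction)
  out <- reads[keep, , drop = FALSE]
  attributes(out) <- modifyList(attributes(out),
                                attributes(reads)[c("read_length", "nominal_depth", "class")])
  out
}
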