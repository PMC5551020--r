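test_that("simulated genomes contain exactly the planted restriction sites", {
  g <- simulate_genome(3, 2000, spacing = 250, seed = 71)
  for (id in names(g$genome)) {
    planted <- g$sites$start[g$sites$seq_id == id]
    found <- find_cut_sites(g$genome[[id]]) - enzyme("PstI")$cut_offset
    expect_identical(sort(found), sort(as.integer(planted)))
  }
  # fixed spacing 100 on 1000 bp -> 9 interior sites, 10 fragments
  g1 <- simulate_genome(1, 1000, spacing = 100, seed = 72)
  expect_equal(nrow(g1$sites), 9)
  expect_equal(nrow(digest(g1$genome)), 10)

  # determinism: identical seeds give byte-identical sequences
  g2 <- simulate_genome(3, 2000, spacing = 250, seed = 71)
  expect_identical(g1$genome, simulate_genome(1, 1000, spacing = 100,
                                              seed = 72)$genome)
  expect_identical(g$genome, g2$genome)

  # FASTA round trip through Biostrings
  fa <- tempfile(fileext = ".fasta")
  write_fasta(g$genome, fa)
  back <- as.character(Biostrings::readDNAStringSet(fa))
  expect_identical(unname(back), unname(g$genome))

  expect_error(simulate_genome(1, 500, spacing = 4), "tight")
})

test_that("genotype generator hits configured class fractions and dosage invariants", {
  truth <- simulate_genotypes(10000, accessions = c(s1 = 12L),
                              het_rate = 0.55, sd_fraction = 0.50,
                              multi_allelic_fraction = 0.03, seed = 73)
  # dosages always sum to ploidy
  expect_true(all(vapply(truth$dosage, sum, numeric(1)) == truth$ploidy))
  # realized SD fraction within 3 binomial sd of the configured 0.50
  p_sd <- mean(truth$class == "single_dose")
  expect_lt(abs(p_sd - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))

  # degenerate settings
  hom <- simulate_genotypes(100, accessions = c(s1 = 6L), het_rate = 0,
                            sd_fraction = 0, multi_allelic_fraction = 0,
                            seed = 74)
  expect_true(all(hom$class == "homozygous"))
  allsd <- simulate_genotypes(100, accessions = c(s1 = 6L), het_rate = 1,
                              sd_fraction = 1, multi_allelic_fraction = 0,
                              seed = 74)
  expect_true(all(allsd$class == "single_dose"))
  expect_error(simulate_genotypes(10, het_rate = 0.3, sd_fraction = 0.5),
               "het_rate")

  # transition fraction shows up in the alternate alleles
  ts <- simulate_genotypes(20000, accessions = c(s1 = 6L),
                           ts_fraction = 1.66 / 2.66, seed = 75)
  bi <- ts[!grepl(",", ts$alt), ]
  is_ts <- (pmin(bi$ref, bi$alt) == "A" & pmax(bi$ref, bi$alt) == "G") |
    (pmin(bi$ref, bi$alt) == "C" & pmax(bi$ref, bi$alt) == "T")
  ratio <- sum(is_ts) / sum(!is_ts)
  # within 3 sd of 1.66 (delta-method sd of the ratio at n sites)
  p <- 1.66 / 2.66
  sd_ratio <- sqrt(p * (1 - p) / nrow(bi)) / (1 - p)^2
  expect_lt(abs(ratio - 1.66), 3 * sd_ratio)
})

test_that("allele-read simulation follows the multinomial dosage model", {
  truth <- simulate_genotypes(500, accessions = c(s1 = 12L), seed = 76)
  reads <- simulate_allele_reads(truth, mean_depth = 56, seed = 76)
  # allele depths sum to the total depth and cover only genotype alleles
  for (i in sample(nrow(reads), 50)) {
    expect_equal(sum(reads$allele_depths[[i]]), reads$total_depth[i])
    expect_true(all(names(reads$allele_depths[[i]]) %in%
                      names(reads$dosage[[i]])))
  }
  # homozygous genotypes yield reads of a single allele
  hom <- reads[reads$class == "homozygous", ]
  expect_true(all(vapply(hom$allele_depths,
                         function(a) sum(a > 0) <= 1, logical(1))))

  # expected minor-read count at SD loci is depth / ploidy
  sd_rows <- reads[reads$class == "single_dose" & reads$total_depth > 0, ]
  minor_counts <- vapply(seq_len(nrow(sd_rows)), function(i) {
    d <- sd_rows$dosage[[i]]
    sd_rows$allele_depths[[i]][[names(d)[d == 1]]]
  }, numeric(1))
  expected <- sum(sd_rows$total_depth) / 12
  expect_lt(abs(sum(minor_counts) - expected),
            3 * sqrt(sum(sd_rows$total_depth) * (1 / 12) * (11 / 12)))
})

test_that("caller emission controls sensitivity and keeps false positives off the truth set", {
  truth <- simulate_genotypes(2000, accessions = c(s1 = 6L, s2 = 8L),
                              seed = 77)
  truth <- simulate_allele_reads(truth, seed = 77)
  out <- emit_caller_vcfs(truth, tempdir(),
                          callers = c("c1", "c2", "c3"),
                          sensitivity = c(1, 0.7, 0.9),
                          fp_fraction = 0.02, seed = 77)
  expect_equal(length(out$caller_loci$c1), 2000)
  n2 <- length(out$caller_loci$c2)
  expect_lt(abs(n2 - 0.7 * 2000), 3 * sqrt(2000 * 0.7 * 0.3))

  # false positives never collide with truth positions
  rec2 <- load_caller_vcf(out$paths[["c2"]], "c2", c(s1 = 6L, s2 = 8L))
  truth_pos <- unique(truth$pos)
  fp_pos <- setdiff(unique(rec2$pos), truth_pos)
  expect_equal(length(unique(rec2$key)),
               n2 + round(0.02 * 2000))
  expect_true(all(fp_pos > max(truth_pos)))

  # sensitivity 1 and no FPs -> identical callsets, all keys concordant
  out1 <- emit_caller_vcfs(truth, tempdir(), callers = c("a", "b"),
                           sensitivity = 1, fp_fraction = 0, seed = 78)
  ra <- load_caller_vcf(out1$paths[["a"]], "a", c(s1 = 6L, s2 = 8L))
  rb <- load_caller_vcf(out1$paths[["b"]], "b", c(s1 = 6L, s2 = 8L))
  cc <- concordance(list(a = unique(ra$key), b = unique(rb$key)))
  expect_equal(cc$n_concordant_all, cc$union_size)
})

test_that("region-count simulation satisfies its Poisson oracles", {
  # no implants, high baseline: zero cells essentially impossible
  sim <- simulate_region_counts(1000, mean_count = 40, seed = 79)
  expect_equal(nrow(call_pav(sim$matrix)), 0)
  expect_true(all(sim$truth$class == "normal"))

  # column sums scale with configured totals
  tot <- colSums(sim$matrix$counts)
  ratio <- tot / sim$matrix$totals
  expect_lt(max(ratio) / min(ratio), 1.1)

  expect_error(simulate_region_counts(100, cnv_fraction = 0.1, cnv_fold = 1),
               "unidentifiable")
  expect_error(simulate_region_counts(5), "at least 10")

  # determinism under a fixed seed
  sim2 <- simulate_region_counts(1000, mean_count = 40, seed = 79)
  expect_identical(sim$matrix$counts, sim2$matrix$counts)
})
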