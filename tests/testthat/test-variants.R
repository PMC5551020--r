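test_that("dosage classification covers the taxonomy and is exhaustive", {
  sd8 <- classify_dosage(c(A = 7, C = 1), 8)
  expect_equal(sd8$class, "single_dose")
  expect_equal(sd8$minor_allele, "C")
  expect_equal(sd8$major_allele, "A")

  md <- classify_dosage(c(A = 3, G = 3), 6)
  expect_equal(md$class, "multi_dose")
  expect_equal(md$minor_allele, "A")   # lexicographic tie-break

  ma <- classify_dosage(c(A = 9, C = 2, T = 1), 12)
  expect_equal(ma$class, "multi_allelic")
  expect_true(ma$heterozygous)

  hom <- classify_dosage(c(G = 6), 6)
  expect_equal(hom$class, "homozygous")
  expect_false(hom$heterozygous)

  expect_error(classify_dosage(c(A = 3, C = 1), 6), "ploidy")

  # exhaustive and mutually exclusive over random valid genotypes
  set.seed(51)
  for (rep in 1:50) {
    p <- sample(c(6L, 8L, 12L), 1)
    n_al <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(p - 1), n_al - 1))
    copies <- diff(c(0L, cuts, p))
    d <- setNames(copies, sample(c("A", "C", "G", "T"), n_al))
    cls <- classify_dosage(d, p)$class
    expect_true(cls %in% c("homozygous", "single_dose", "multi_dose",
                           "multi_allelic"))
    expected <- if (n_al == 1) "homozygous"
      else if (n_al >= 3) "multi_allelic"
      else if (min(copies) == 1) "single_dose" else "multi_dose"
    expect_equal(cls, expected)
  }
})

test_that("concordance cells match the brute-force tally and partition the union", {
  expect_error(concordance(list(a = "k1")), "two callsets")
  simple <- concordance(list(a = c("k1", "k2", "k3"),
                             b = c("k2", "k3", "k4")))
  expect_equal(simple$union_size, 4)
  expect_equal(simple$cells$count[simple$cells$subset == "a+b"], 2)

  ident <- concordance(list(a = c("k1", "k2"), b = c("k1", "k2"),
                            c = c("k1", "k2")))
  expect_equal(ident$n_concordant_all, 2)
  expect_equal(nrow(ident$cells), 1)

  set.seed(52)
  keys <- sprintf("chr%d:%d:A:G", sample(1:3, 500, TRUE),
                  sample(1:10000, 500))
  callsets <- lapply(setNames(1:5, paste0("caller", 1:5)), function(i)
    sample(keys, rbinom(1, 500, 0.6)))
  cc <- concordance(callsets)
  oracle <- brute_venn(callsets)
  expect_equal(sum(cc$cells$count), cc$union_size)
  for (i in seq_len(nrow(cc$cells))) {
    expect_equal(cc$cells$count[i],
                 unname(oracle[[cc$cells$subset[i]]]))
  }
  expect_equal(cc$per_caller$pct_concordant,
               unname(100 * cc$n_concordant_all /
                        lengths(lapply(callsets, unique))))
})

test_that("VCF loading parses polyploid genotypes and round-trips generator truth", {
  truth <- simulate_genotypes(120, seed = 53)
  truth <- simulate_allele_reads(truth, mean_depth = 60, seed = 53)
  out <- emit_caller_vcfs(truth, tempdir(), callers = c("gatk", "freebayes"),
                          sensitivity = 1, fp_fraction = 0, seed = 53)
  rec <- load_caller_vcf(out$truth_path, "truth", default_accessions())

  expect_equal(nrow(rec), 120 * length(default_accessions()))
  expect_false(any(rec$missing))
  # every parsed dosage equals the generator truth
  lookup <- setNames(seq_len(nrow(truth)),
                     paste(truth$locus_id, truth$accession))
  set.seed(1)
  for (i in sample(nrow(rec), 200)) {
    locus <- sprintf("locus%06d", as.integer(rec$pos[i] / 10))
    t_row <- truth[lookup[[paste(locus, rec$sample_id[i])]], ]
    got <- rec$dosage[[i]][rec$dosage[[i]] > 0]
    want <- t_row$dosage[[1]]
    expect_equal(got[order(names(got))], want[order(names(want))])
    expect_equal(rec$total_depth[i], t_row$total_depth)
  }
})

test_that("missing and arity-mismatched genotypes are excluded from dosage stats", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tG\t.\t.\t.\tGT:DP\t0/0/0/0/0/1:40\t./.:0",
    "chr1\t20\t.\tC\tT\t.\t.\t.\tGT:DP\t0/1:30\t0/0/0/0/0/0:50",
    "chr1\t30\t.\tG\tGA\t.\t.\t.\tGT:DP\t0/0/0/0/0/0:9\t0/0/0/0/0/1:9"),
    vcf)
  rec <- load_caller_vcf(vcf, "test", c(s1 = 6L, s2 = 6L))
  expect_equal(length(unique(rec$key)), 2)   # indel record skipped
  r1 <- rec[rec$pos == 10 & rec$sample_id == "s1", ]
  expect_equal(r1$dosage[[1]], c(A = 5L, G = 1L))
  expect_true(rec$missing[rec$pos == 10 & rec$sample_id == "s2"])
  # GT arity 2 at declared ploidy 6 -> flagged and missing
  r2 <- rec[rec$pos == 20 & rec$sample_id == "s1", ]
  expect_true(r2$flagged && r2$missing)
})

test_that("depth filter honors scope, is identity at 0 and antitone in min_depth", {
  truth <- simulate_genotypes(80, seed = 54)
  truth <- simulate_allele_reads(truth, mean_depth = 40, seed = 54)
  out <- emit_caller_vcfs(truth, tempdir(), callers = c("a", "b"),
                          sensitivity = 1, fp_fraction = 0, seed = 54)
  rec <- load_caller_vcf(out$truth_path, "truth", default_accessions())

  expect_equal(nrow(depth_filter(rec, 0)), nrow(rec))

  # counting oracle: survivors equal direct evaluation of the rule
  dp <- matrix(rec$total_depth, nrow = 80,
               dimnames = list(unique(rec$key), NULL))
  for (min_d in c(25, 35, 45)) {
    keep_all <- rownames(dp)[apply(dp, 1, function(r) all(r >= min_d))]
    got <- unique(depth_filter(rec, min_d, scope = "all")$key)
    expect_setequal(got, keep_all)
    keep_any <- rownames(dp)[apply(dp, 1, function(r) any(r >= min_d))]
    expect_setequal(unique(depth_filter(rec, min_d, scope = "any")$key),
                    keep_any)
  }
  # antitone: survivor sets nested as the threshold rises
  s35 <- unique(depth_filter(rec, 35)$key)
  s45 <- unique(depth_filter(rec, 45)$key)
  expect_true(all(s45 %in% s35))
})

test_that("per-sample summaries equal statistics computed from the truth table", {
  truth <- simulate_genotypes(400, seed = 55)
  truth <- simulate_allele_reads(truth, seed = 55)
  out <- emit_caller_vcfs(truth, tempdir(), callers = c("a", "b"),
                          sensitivity = 1, fp_fraction = 0, seed = 55)
  rec <- load_caller_vcf(out$truth_path, "truth", default_accessions())
  for (acc in c("acc6x_1", "acc8x_3", "acc12x_4")) {
    got <- sample_summary(rec, acc)
    want <- truth_summary(truth, acc)
    expect_equal(got$heterozygosity_pct, want$heterozygosity_pct)
    expect_equal(got$sd_pct, want$sd_pct)
    expect_equal(got$multi_allelic_pct, want$multi_allelic_pct)
    expect_equal(got$tstv, want$tstv)
    expect_equal(got$n_loci, want$n_loci)
  }
})

test_that("transition/transversion ratio counts the six substitution pairs correctly", {
  rec <- data.frame(key = sprintf("c:%d:%s:%s", 1:4,
                                  c("A", "C", "A", "G"),
                                  c("G", "T", "C", "T")),
                    seq_id = "c", pos = 1:4,
                    ref = c("A", "C", "A", "G"),
                    alt = c("G", "T", "C", "T"),
                    sample_id = "s", missing = FALSE)
  rec$dosage <- list(c(A = 5, G = 1), c(C = 5, T = 1),
                     c(A = 5, C = 1), c(G = 5, T = 1))
  expect_equal(tstv(rec), 1.0)            # {A/G, C/T} vs {A/C, G/T}
  expect_equal(tstv(rec, "s"), 1.0)
  rec2 <- rec[c(1, 1), ]
  expect_equal(tstv(rec2), Inf)           # no transversions
})

test_that("genic annotation of variants converts 1-based positions correctly", {
  rec <- data.frame(seq_id = "chr1", pos = c(19L, 10L, 31L))
  genes <- data.frame(seq_id = "chr1", start = 18, end = 30)
  ann <- annotate_genic(rec, genes)
  # 1-based 19 and covered range (0-based [18,30) = 1-based 19..30)
  expect_equal(ann$genic, c(TRUE, FALSE, FALSE))
  expect_equal(annotate_genic(rec, genes[0, ])$percent_genic, 0)

  set.seed(56)
  recs <- data.frame(seq_id = sample(c("c1", "c2"), 300, TRUE),
                     pos = sample(1:5000, 300))
  genes <- data.frame(seq_id = sample(c("c1", "c2"), 30, TRUE),
                      start = sample(0:4500, 30))
  genes$end <- genes$start + sample(50:500, 30, TRUE)
  ann <- annotate_genic(recs, genes)
  oracle <- brute_overlap(data.frame(seq_id = recs$seq_id,
                                     start = recs$pos - 1L,
                                     end = recs$pos), genes)
  expect_identical(ann$genic, oracle)
})
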