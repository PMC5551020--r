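# Independent oracles used across the suite.

# Explicit term-by-term summation of the binomial tail:
# P(X >= k) = 1 - sum_{i=0}^{k-1} C(n,i) x^i (1-x)^(n-i)
binom_tail_sum <- function(n, x, k) {
  i <- 0:(k - 1)
  1 - sum(choose(n, i) * x^i * (1 - x)^(n - i))
}

# Brute-force all-pairs interval overlap (0-based half-open).
brute_overlap <- function(frags, genes) {
  vapply(seq_len(nrow(frags)), function(i) {
    any(genes$seq_id == frags$seq_id[i] &
          genes$start < frags$end[i] &
          genes$end > frags$start[i])
  }, logical(1))
}

# Brute-force Venn membership tally: named list of key vectors ->
# named count per membership pattern ("a+b" style).
brute_venn <- function(callsets) {
  keys <- unique(unlist(callsets))
  pat <- vapply(keys, function(k) {
    paste(names(callsets)[vapply(callsets, function(s) k %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  table(pat)
}

# Dosage-class statistics straight off a genotype_truth table.
truth_summary <- function(truth, acc) {
  tr <- truth[truth$accession == acc, ]
  n <- nrow(tr)
  ts_sites <- tr[tr$class != "homozygous" & !grepl(",", tr$alt), ]
  is_ts <- (pmin(ts_sites$ref, ts_sites$alt) == "A" &
              pmax(ts_sites$ref, ts_sites$alt) == "G") |
    (pmin(ts_sites$ref, ts_sites$alt) == "C" &
       pmax(ts_sites$ref, ts_sites$alt) == "T")
  data.frame(heterozygosity_pct = 100 * sum(tr$class != "homozygous") / n,
             sd_pct = 100 * sum(tr$class == "single_dose") / n,
             multi_allelic_pct = 100 * sum(tr$class == "multi_allelic") / n,
             tstv = sum(is_ts) / sum(!is_ts),
             n_loci = n)
}
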