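#' Probability of sampling at least k reads of an allele
#'
#' Under the binomial read-sampling model, the number of reads carrying a
#' given allele at a locus sequenced to total depth \code{n} is
#' \eqn{Binomial(n, x)}, where \eqn{x} is the allele's frequency within the
#' genotype. For a single-dose allele in a p-ploid genotype, \eqn{x = 1/p}.
#' This returns \eqn{P(X \ge k) = 1 - F(k - 1; n, x)}, the probability that
#' the allele is observed at least \code{k} times.
#'
#' @param n integer vector, total read depth at the locus (>= 0).
#' @param x numeric vector of allele frequencies in \[0, 1\].
#' @param k integer vector, required number of reads (>= 1).
#' @return numeric vector of probabilities in \[0, 1\]. \code{k > n} gives 0.
#' @examples
#' prob_at_least_k(56, 1 / 12, 2)   # detectability of a single-dose allele
#'                                  # in a dodecaploid at depth 56
#' @seealso [min_depth()], [depth_table()]
#' @export
prob_at_least_k <- function(n, x, k) {
  stopifnot(is.numeric(n), is.numeric(x), is.numeric(k))
  if (any(n < 0) || any(n != floor(n))) stop("'n' must be a non-negative integer")
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  if (any(k < 1) || any(k != floor(k))) stop("'k' must be a positive integer")
  # pbinom is numerically stable for the n used here (up to ~1e4 and beyond)
  stats::pbinom(k - 1, size = n, prob = x, lower.tail = FALSE)
}

#' Minimum sequencing depth to detect a minor allele
#'
#' Smallest total read depth \code{n} such that a minor allele at frequency
#' \code{x} is sampled at least \code{k} times with probability at least
#' \code{confidence}. For the workhorse single-dose markers of polyploid
#' linkage analysis, \code{x = 1/ploidy}; at 95\% confidence and \code{k = 2}
#' this gives 27 reads for a hexaploid, 37 for an octoploid and 56 for a
#' dodecaploid.
#'
#' The tail probability is non-decreasing in \code{n}, so an incremental
#' search from \code{n = k} finds the exact minimum.
#'
#' @param x minor-allele frequency, in (0, 1).
#' @param k required number of minor-allele reads (>= 1).
#' @param confidence required detection probability, in (0, 1); default 0.95.
#' @param n_max search guard; an error is thrown if no depth up to
#'   \code{n_max} suffices.
#' @return integer, the minimum depth.
#' @examples
#' min_depth(1 / 6, 2)    # 27
#' min_depth(1 / 12, 2)   # 56
#' @export
min_depth <- function(x, k, confidence = 0.95, n_max = 1e6L) {
  stopifnot(length(x) == 1L, length(k) == 1L, length(confidence) == 1L)
  if (x <= 0 || x >= 1) stop("'x' must lie strictly in (0, 1)")
  if (k < 1 || k != floor(k)) stop("'k' must be a positive integer")
  if (confidence >= 1) stop("'confidence' >= 1 is unattainable for x < 1")
  if (confidence <= 0) stop("'confidence' must lie in (0, 1)")
  n <- as.integer(k)
  while (prob_at_least_k(n, x, k) < confidence) {
    n <- n + 1L
    if (n > n_max) stop("no depth up to n_max = ", n_max, " attains the confidence")
  }
  n
}

#' Minimum-depth table across ploidies and read requirements
#'
#' Tabulates [min_depth()] for single-dose minor alleles (frequency
#' \code{1/ploidy}) over a grid of ploidy levels and required read counts,
#' the planning table used to choose a depth filter for polyploid GBS.
#'
#' @param ploidies integer vector of ploidy levels (>= 2).
#' @param k_range integer vector of required read counts; default 1:5.
#' @param confidence detection probability; default 0.95.
#' @return data.frame with columns \code{ploidy}, \code{k},
#'   \code{confidence}, \code{min_depth}. Within the table \code{min_depth}
#'   is non-decreasing in both \code{ploidy} and \code{k}.
#' @examples
#' depth_table(c(6, 8, 10, 12), k_range = 2)
#' @export
depth_table <- function(ploidies, k_range = 1:5, confidence = 0.95) {
  stopifnot(all(ploidies >= 2), all(ploidies == floor(ploidies)))
  grid <- expand.grid(k = as.integer(k_range), ploidy = as.integer(ploidies),
                      KEEP.OUT.ATTRS = FALSE)
  grid$confidence <- confidence
  grid$min_depth <- mapply(function(p, k) min_depth(1 / p, k, confidence),
                           grid$ploidy, grid$k)
  grid[, c("ploidy", "k", "confidence", "min_depth")]
}

#' Subsample-saturation analysis of SNP discovery
#'
#' Emulates the read-subsampling experiment used to decide whether
#' sequencing depth saturates SNP discovery: the whole read set defines
#' 100\% recovery; random fractions of reads are drawn (without
#' replacement, several replicates each) and the fraction of the whole-set
#' SNPs rediscovered in each subset is recorded. A least-squares line is
#' fitted through (fraction, mean recovery), from which the read fraction
#' needed to reach a target recovery (e.g. 90\%) is read off.
#'
#' @param read_loci character or integer vector, one element per read,
#'   giving the locus each read maps to. The "whole set" is this vector.
#' @param fractions numeric vector of subsample fractions in (0, 1\];
#'   default \code{seq(0.2, 0.9, by = 0.1)}.
#' @param reps number of independent subsamples per fraction; default 10.
#' @param discover function mapping a vector of read loci to the character
#'   vector of discovered SNP loci. Default: loci covered by at least
#'   \code{min_reads} reads.
#' @param min_reads read threshold for the default discovery rule; default 2.
#' @param seed integer seed for the subsampling RNG.
#' @return object of class \code{saturation_result}: list with
#'   \code{summary} (data.frame: fraction, mean_recovery, sd_recovery),
#'   \code{slope}, \code{intercept} of the fitted line, the function
#'   \code{required_fraction_for(target)}, and \code{n_whole} (SNPs in the
#'   whole set).
#' @examples
#' reads <- rep(sprintf("locus%03d", 1:50), times = rpois(50, 6) + 1)
#' sat <- subsample_saturation(reads, reps = 5, seed = 1)
#' sat$required_fraction_for(0.90)
#' @export
subsample_saturation <- function(read_loci,
                                 fractions = seq(0.2, 0.9, by = 0.1),
                                 reps = 10,
                                 discover = NULL,
                                 min_reads = 2,
                                 seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  stopifnot(reps >= 1, length(read_loci) >= 1)
  if (is.null(discover)) {
    discover <- function(loci) names(which(table(loci) >= min_reads))
  }
  whole <- discover(read_loci)
  n_whole <- length(whole)
  if (n_whole == 0) stop("no SNPs discovered in the whole read set")
  n_reads <- length(read_loci)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rec <- matrix(NA_real_, nrow = reps, ncol = length(fractions))
  for (j in seq_along(fractions)) {
    f <- fractions[j]
    if (f == 1) {
      rec[, j] <- 1
      next
    }
    m <- round(f * n_reads)
    for (r in seq_len(reps)) {
      sub <- read_loci[sample.int(n_reads, m)]
      rec[r, j] <- length(intersect(discover(sub), whole)) / n_whole
    }
  }
  summary <- data.frame(fraction = fractions,
                        mean_recovery = colMeans(rec),
                        sd_recovery = apply(rec, 2, stats::sd))
  fit <- stats::lm(mean_recovery ~ fraction, data = summary)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  res <- list(summary = summary,
              slope = slope,
              intercept = intercept,
              required_fraction_for = function(target) (target - intercept) / slope,
              n_whole = n_whole,
              recovery = rec)
  class(res) <- "saturation_result"
  res
}

#' @export
print.saturation_result <- function(x, ...) {
  cat("Subsample-saturation analysis:", x$n_whole, "SNPs in the whole set\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("fitted line: recovery = %.4f + %.4f * fraction\n",
              x$intercept, x$slope))
  invisible(x)
}

# Preserve and restore the global RNG state so seeded helpers do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
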