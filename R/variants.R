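#' Build a canonical SNP key
#'
#' Callers are matched on (seq_id, pos, ref, alt set): position alone would
#' conflate different substitutions at one site. Alts are sorted so the key
#' is order-invariant.
#'
#' @param seq_id,pos,ref,alt vectors; \code{alt} may be comma-joined.
#' @return character vector of keys \code{"seq:pos:ref:alts"}.
#' @export
snp_key <- function(seq_id, pos, ref, alt) {
  alt_sorted <- vapply(strsplit(as.character(alt), ","),
                       function(a) paste(sort(a), collapse = ","), character(1))
  paste(seq_id, pos, toupper(ref), toupper(alt_sorted), sep = ":")
}

#' Load a caller's VCF into normalized dosage records
#'
#' Reads a VCF (via vcfR), keeps SNP records only (ref and every alt a
#' single base), and parses polyploid genotype strings with ploidy-many
#' allele slots (e.g. \code{0/0/0/0/0/1} at ploidy 6) into per-sample
#' allele-dosage maps. Genotypes containing '.' are missing; genotypes
#' whose slot count differs from the declared ploidy are flagged and
#' treated as missing for dosage statistics.
#'
#' @param path path to the VCF file.
#' @param caller_name label attached to every record.
#' @param ploidy named integer vector of per-sample ploidies, or a single
#'   integer applied to all samples.
#' @return data.frame of class \code{snp_records}, one row per
#'   (site, sample): \code{key}, \code{seq_id}, \code{pos}, \code{ref},
#'   \code{alt}, \code{caller}, \code{sample_id}, \code{ploidy},
#'   \code{gt}, \code{dosage} (list-column of named integer vectors, NULL
#'   when missing), \code{total_depth}, \code{missing}, \code{flagged}.
#' @export
load_caller_vcf <- function(path, caller_name, ploidy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1 &
    vapply(strsplit(alt, ","), function(a) all(nchar(a) == 1), logical(1))
  if (!all(is_snp)) {
    message(sum(!is_snp), " non-SNP record(s) skipped in ", basename(path))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  if (length(ploidy) == 1 && is.null(names(ploidy)))
    ploidy <- stats::setNames(rep(as.integer(ploidy), length(samples)), samples)
  if (!all(samples %in% names(ploidy)))
    stop("ploidy missing for sample(s): ",
         paste(setdiff(samples, names(ploidy)), collapse = ", "))

  n_sites <- nrow(fix)
  keys <- snp_key(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"])
  rows <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    s <- samples[j]
    p <- ploidy[[s]]
    parsed <- parse_gt(gt[, j], fix[, "REF"], fix[, "ALT"], p)
    rows[[j]] <- data.frame(key = keys,
                            seq_id = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            ref = fix[, "REF"],
                            alt = fix[, "ALT"],
                            caller = caller_name,
                            sample_id = s,
                            ploidy = p,
                            gt = unname(gt[, j]),
                            total_depth = unname(dp[, j]),
                            missing = parsed$missing,
                            flagged = parsed$flagged,
                            stringsAsFactors = FALSE)
    rows[[j]]$dosage <- parsed$dosage
  }
  rec <- do.call(rbind, rows)
  rec$total_depth[is.na(rec$total_depth)] <- 0L
  rownames(rec) <- NULL
  class(rec) <- c("snp_records", "data.frame")
  rec
}

# Parse GT strings into dosage maps. Returns list(dosage = list of named
# integer vectors (NULL when missing), missing, flagged).
parse_gt <- function(gt, ref, alt, ploidy) {
  n <- length(gt)
  dosage <- vector("list", n)
  missing <- logical(n)
  flagged <- logical(n)
  alt_split <- strsplit(alt, ",")
  for (i in seq_len(n)) {
    g <- gt[i]
    if (is.na(g) || grepl("\\.", g)) {
      missing[i] <- TRUE
      next
    }
    idx <- as.integer(strsplit(g, "[/|]")[[1]])
    if (length(idx) != ploidy) {
      flagged[i] <- TRUE
      missing[i] <- TRUE
      next
    }
    alleles <- c(ref[i], alt_split[[i]])[idx + 1L]
    tab <- table(alleles)
    dosage[[i]] <- stats::setNames(as.integer(tab), names(tab))
  }
  list(dosage = dosage, missing = missing, flagged = flagged)
}

#' Multi-caller SNP concordance
#'
#' For every nonempty subset of callers, counts the SNP keys present in
#' exactly those callers (the cells of a Venn diagram). The cells partition
#' the union, whose size is the non-redundant SNP count.
#'
#' @param callsets named list (>= 2 elements) of character vectors of SNP
#'   keys, one per caller.
#' @return list with \code{cells} (data.frame: \code{subset}
#'   (caller names joined by '+'), \code{n_callers}, \code{count}),
#'   \code{union_size}, \code{n_concordant_all} (keys in every caller), and
#'   \code{per_caller} (data.frame: caller, n, n_specific,
#'   pct_concordant = 100 * n_concordant_all / n).
#' @export
concordance <- function(callsets) {
  if (length(callsets) < 2) stop("need at least two callsets")
  if (is.null(names(callsets)) || any(!nzchar(names(callsets))))
    stop("callsets must be named by caller")
  callsets <- lapply(callsets, unique)
  union_keys <- unique(unlist(callsets, use.names = FALSE))
  member <- vapply(callsets, function(ks) union_keys %in% ks,
                   logical(length(union_keys)))
  if (length(union_keys) == 1) member <- matrix(member, nrow = 1,
                                                dimnames = list(NULL, names(callsets)))
  pattern <- apply(member, 1, function(m)
    paste(names(callsets)[m], collapse = "+"))
  tab <- table(pattern)
  cells <- data.frame(subset = names(tab),
                      n_callers = lengths(strsplit(names(tab), "\\+")),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
  cells <- cells[order(-cells$n_callers, cells$subset), , drop = FALSE]
  rownames(cells) <- NULL
  n_all <- sum(rowSums(member) == length(callsets))
  specific <- vapply(names(callsets), function(cl) {
    sum(member[, cl] & rowSums(member) == 1)
  }, integer(1))
  per_caller <- data.frame(caller = names(callsets),
                           n = lengths(callsets),
                           n_specific = unname(specific),
                           pct_concordant = 100 * n_all / lengths(callsets),
                           stringsAsFactors = FALSE)
  rownames(per_caller) <- NULL
  list(cells = cells, union_size = length(union_keys),
       n_concordant_all = n_all, per_caller = per_caller)
}

#' Filter SNP records by per-sample depth
#'
#' Retains a site iff its samples meet the minimum total depth: with
#' \code{scope = "all"} (default, the strict reading of a "minimum depth
#' per sample" filter) every non-missing sample must reach
#' \code{min_depth}; with \code{scope = "any"} at least one must.
#' Sites where every sample is missing are dropped under both scopes.
#'
#' @param records \code{snp_records} data.frame.
#' @param min_depth minimum per-sample total depth (>= 0).
#' @param scope \code{"all"} or \code{"any"}.
#' @return the surviving rows.
#' @export
depth_filter <- function(records, min_depth, scope = c("all", "any")) {
  scope <- match.arg(scope)
  if (min_depth < 0) stop("min_depth must be >= 0")
  ok <- !records$missing
  pass <- ok & records$total_depth >= min_depth
  agg_fun <- if (scope == "all") {
    function(p, o) any(o) && all(p[o])
  } else {
    function(p, o) any(o) && any(p[o])
  }
  keep_key <- vapply(split(seq_len(nrow(records)), records$key), function(idx) {
    agg_fun(pass[idx], ok[idx])
  }, logical(1))
  records[records$key %in% names(keep_key)[keep_key], , drop = FALSE]
}

#' Classify a polyploid dosage genotype
#'
#' Applies the standard dosage taxonomy for polyploid SNPs: one allele at
#' full ploidy is homozygous; two alleles with the rarer at exactly one
#' copy is single-dose (the 1:1-segregating marker class); two alleles
#' both at >= 2 copies is multi-dose; three or more alleles is
#' multi-allelic. The minor allele is the one with fewer copies (ties
#' broken toward the lexicographically smaller allele, which never affects
#' single-dose calls).
#'
#' @param dosage named integer vector mapping allele to copy count.
#' @param ploidy the sample's ploidy; dosage must sum to it.
#' @return list with \code{class} (one of \code{"homozygous"},
#'   \code{"single_dose"}, \code{"multi_dose"}, \code{"multi_allelic"}),
#'   \code{minor_allele}, \code{major_allele} (NA for homozygous and
#'   multi-allelic), \code{heterozygous}.
#' @examples
#' classify_dosage(c(A = 7, C = 1), 8)   # single_dose, minor C
#' @export
classify_dosage <- function(dosage, ploidy) {
  dosage <- dosage[dosage > 0]
  if (sum(dosage) != ploidy)
    stop("dosage sums to ", sum(dosage), ", not the ploidy ", ploidy)
  n_alleles <- length(dosage)
  if (n_alleles == 1) {
    return(list(class = "homozygous", minor_allele = NA_character_,
                major_allele = names(dosage), heterozygous = FALSE))
  }
  if (n_alleles >= 3) {
    return(list(class = "multi_allelic", minor_allele = NA_character_,
                major_allele = NA_character_, heterozygous = TRUE))
  }
  ord <- order(dosage, names(dosage))  # fewest copies first, lexicographic ties
  minor <- names(dosage)[ord[1]]
  major <- names(dosage)[ord[2]]
  cls <- if (min(dosage) == 1) "single_dose" else "multi_dose"
  list(class = cls, minor_allele = minor, major_allele = major,
       heterozygous = TRUE)
}

#' Per-sample variation summary
#'
#' Computes, over the sample's non-missing SNP loci: heterozygosity
#' percent (loci with >= 2 distinct alleles in the genotype), single-dose
#' percent, multi-allelic percent (all with the same denominator, the
#' total non-missing loci), the transition/transversion ratio
#' (see [tstv()]), and the locus count.
#'
#' @param records \code{snp_records} data.frame.
#' @param sample_id sample to summarize.
#' @return data.frame with one row: \code{sample_id}, \code{n_loci},
#'   \code{heterozygosity_pct}, \code{sd_pct}, \code{multi_allelic_pct},
#'   \code{tstv}.
#' @export
sample_summary <- function(records, sample_id) {
  rec <- records[records$sample_id == sample_id & !records$missing, ,
                 drop = FALSE]
  if (nrow(rec) == 0) stop("no non-missing loci for sample '", sample_id, "'")
  cls <- vapply(seq_len(nrow(rec)), function(i) {
    classify_dosage(rec$dosage[[i]], rec$ploidy[i])$class
  }, character(1))
  n <- nrow(rec)
  data.frame(sample_id = sample_id,
             n_loci = n,
             heterozygosity_pct = 100 * sum(cls != "homozygous") / n,
             sd_pct = 100 * sum(cls == "single_dose") / n,
             multi_allelic_pct = 100 * sum(cls == "multi_allelic") / n,
             tstv = tstv(records, sample_id),
             stringsAsFactors = FALSE)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; the other four unordered base pairs
#' are transversions. In per-sample mode the ratio is computed over loci
#' where the sample's genotype carries exactly one distinct non-reference
#' allele (different accessions therefore see different site sets), using
#' the ref/carried-allele pair; in global mode over all bi-allelic sites.
#'
#' @param records \code{snp_records} data.frame.
#' @param sample_id sample for per-sample mode, or NULL (default) for all
#'   sites.
#' @return the ratio; \code{Inf} when there are no transversions.
#' @export
tstv <- function(records, sample_id = NULL) {
  if (!is.null(sample_id)) {
    rec <- records[records$sample_id == sample_id & !records$missing, ,
                   drop = FALSE]
    carried <- lapply(seq_len(nrow(rec)), function(i) {
      setdiff(names(rec$dosage[[i]]), rec$ref[i])
    })
    keep <- lengths(carried) == 1
    sites <- data.frame(ref = rec$ref[keep],
                        alt = unlist(carried[keep]),
                        stringsAsFactors = FALSE)
  } else {
    sites <- unique(records[, c("key", "ref", "alt")])
    sites <- sites[!grepl(",", sites$alt), , drop = FALSE]  # bi-allelic only
  }
  if (nrow(sites) == 0) return(NaN)
  is_ts <- is_transition(sites$ref, sites$alt)
  n_tv <- sum(!is_ts)
  if (n_tv == 0) return(Inf)
  sum(is_ts) / n_tv
}

is_transition <- function(a, b) {
  pair <- paste(pmin(toupper(a), toupper(b)), pmax(toupper(a), toupper(b)))
  pair %in% c("A G", "C T")
}

#' Annotate SNP records with genic location
#'
#' A variant at 1-based position p on a sequence is genic iff p falls
#' within a gene interval (0-based half-open \[start, end\): genic iff
#' start < p <= end).
#'
#' @param records \code{snp_records} data.frame (or any data.frame with
#'   \code{seq_id} and \code{pos}, 1-based).
#' @param genes data.frame with \code{seq_id}, \code{start}, \code{end}
#'   (0-based half-open).
#' @return list with \code{genic} (logical per row), \code{percent_genic}.
#' @export
annotate_genic <- function(records, genes) {
  frags <- data.frame(seq_id = records$seq_id,
                      start = records$pos - 1L,
                      end = records$pos)
  ov <- suppressWarnings(genic_overlap(frags, genes))
  list(genic = ov$genic, percent_genic = ov$percent_genic)
}
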