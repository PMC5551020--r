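#' Default accession panel
#'
#' A panel mirroring a diverse sugarcane germplasm study: four hexaploid,
#' six octoploid and four dodecaploid accessions.
#'
#' @return named integer vector mapping accession id to ploidy.
#' @export
default_accessions <- function() {
  c(acc6x_1 = 6L, acc6x_2 = 6L, acc6x_3 = 6L, acc6x_4 = 6L,
    acc8x_1 = 8L, acc8x_2 = 8L, acc8x_3 = 8L, acc8x_4 = 8L,
    acc8x_5 = 8L, acc8x_6 = 8L,
    acc12x_1 = 12L, acc12x_2 = 12L, acc12x_3 = 12L, acc12x_4 = 12L)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted restriction sites
#'
#' Generates random sequences and implants recognition sites at known
#' positions (fixed spacing or geometric gaps). A rejection pass mutates
#' any accidental occurrence of the recognition site outside the planted
#' footprints, so the planted positions are the complete ground truth.
#'
#' @param n_sequences number of sequences; default 5.
#' @param seq_length length of each sequence in bp; default 10000.
#' @param spacing distance between consecutive planted site starts
#'   (\code{spacing_model = "fixed"}) or the mean gap
#'   (\code{"geometric"}); default 1000.
#' @param spacing_model \code{"fixed"} or \code{"geometric"}.
#' @param enz a \code{restriction_enzyme}; default PstI.
#' @param seed RNG seed.
#' @return list with \code{genome} (named character vector) and
#'   \code{sites} (data.frame: \code{seq_id}, \code{start} — 0-based start
#'   of each planted recognition site).
#' @export
simulate_genome <- function(n_sequences = 5L, seq_length = 10000L,
                            spacing = 1000L,
                            spacing_model = c("fixed", "geometric"),
                            enz = enzyme("PstI"), seed = 1L) {
  spacing_model <- match.arg(spacing_model)
  site <- enz$recognition
  slen <- nchar(site)
  if (seq_length <= slen) stop("seq_length must exceed the recognition site")
  if (spacing <= slen) stop("spacing too tight to fit non-overlapping sites")
  with_seed(seed, {
    genome <- character(n_sequences)
    names(genome) <- sprintf("seq%02d", seq_len(n_sequences))
    sites <- list()
    for (i in seq_len(n_sequences)) {
      s <- random_dna(seq_length)
      starts0 <- if (spacing_model == "fixed") {
        seq(spacing, seq_length - slen, by = spacing)
      } else {
        gaps <- stats::rgeom(ceiling(2 * seq_length / spacing),
                             prob = 1 / spacing) + 1L
        pos <- cumsum(gaps + slen) - slen
        pos[pos <= seq_length - slen & pos >= 1]
      }
      for (p in starts0) substr(s, p + 1, p + slen) <- site
      s <- scrub_accidental_sites(s, site, starts0)
      genome[i] <- s
      if (length(starts0))
        sites[[i]] <- data.frame(seq_id = names(genome)[i],
                                 start = as.integer(starts0))
    }
    sites <- if (length(sites)) do.call(rbind, sites)
             else data.frame(seq_id = character(), start = integer())
    rownames(sites) <- NULL
    list(genome = genome, sites = sites)
  })
}

# Mutate bases (outside planted footprints) until the only occurrences of
# `site` are the planted ones.
scrub_accidental_sites <- function(s, site, planted_starts0) {
  slen <- nchar(site)
  protected <- unlist(lapply(planted_starts0, function(p) p + seq_len(slen)))
  bases <- c("A", "C", "G", "T")
  repeat {
    occ <- BiocGenerics::start(
      Biostrings::matchPattern(site, Biostrings::DNAString(s))) - 1L
    bad <- setdiff(occ, planted_starts0)
    if (length(bad) == 0) return(s)
    for (p in bad) {
      cand <- setdiff(p + seq_len(slen), protected)  # 1-based positions
      if (length(cand) == 0) next  # fully inside planted footprints: keep
      j <- cand[[sample.int(length(cand), 1)]]
      cur <- substr(s, j, j)
      substr(s, j, j) <- sample(setdiff(bases, cur), 1)
    }
  }
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Simulate polyploid dosage genotypes with known truth
#'
#' Per locus and accession the genotype class is drawn from
#' {homozygous-reference, single-dose, multi-dose, multi-allelic} with
#' probabilities \code{1 - het_rate}, \code{sd_fraction},
#' \code{het_rate - sd_fraction - multi_allelic_fraction} and
#' \code{multi_allelic_fraction}. Each locus carries a reference base and
#' an alternate chosen as a transition with probability
#' \code{ts_fraction} (a second, distinct alternate is used for the
#' multi-allelic class). Single-dose genotypes carry the alternate at one
#' copy; multi-dose genotypes at a uniform 2..ploidy/2 copies.
#'
#' @param n_loci number of SNP loci.
#' @param accessions named integer vector mapping accession to ploidy;
#'   default [default_accessions()].
#' @param het_rate probability a genotype is heterozygous; default 0.55.
#' @param sd_fraction probability a genotype is single-dose; default 0.50.
#' @param multi_allelic_fraction probability a genotype carries >= 3
#'   alleles; default 0.03.
#' @param ts_fraction probability the ref->alt substitution is a
#'   transition; default 1.66 / 2.66 (a Ts/Tv ratio of 1.66).
#' @param seq_id sequence name for the loci; default "seq01".
#' @param seed RNG seed.
#' @return data.frame of class \code{genotype_truth}, one row per
#'   (locus, accession): \code{locus_id}, \code{seq_id}, \code{pos}
#'   (1-based, distinct per locus), \code{ref}, \code{alt}
#'   (comma-joined site alternates), \code{accession}, \code{ploidy},
#'   \code{class}, and list-column \code{dosage}.
#' @export
simulate_genotypes <- function(n_loci,
                               accessions = default_accessions(),
                               het_rate = 0.55,
                               sd_fraction = 0.50,
                               multi_allelic_fraction = 0.03,
                               ts_fraction = 1.66 / 2.66,
                               seq_id = "seq01",
                               seed = 1L) {
  md_fraction <- het_rate - sd_fraction - multi_allelic_fraction
  if (md_fraction < 0 || het_rate > 1)
    stop("need sd_fraction + multi_allelic_fraction <= het_rate <= 1")
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  with_seed(seed, {
    pos <- seq_len(n_loci) * 10L   # distinct, ordered positions
    ref <- sample(bases, n_loci, replace = TRUE)
    is_ts <- stats::runif(n_loci) < ts_fraction
    alt1 <- ifelse(is_ts, transition_of[ref],
                   vapply(ref, function(r)
                     sample(setdiff(bases, c(r, transition_of[r])), 1),
                     character(1)))
    alt2 <- mapply(function(r, a) sample(setdiff(bases, c(r, a)), 1),
                   ref, alt1, USE.NAMES = FALSE)
    probs <- c(hom = 1 - het_rate, sd = sd_fraction,
               md = md_fraction, ma = multi_allelic_fraction)
    out <- vector("list", length(accessions))
    for (j in seq_along(accessions)) {
      acc <- names(accessions)[j]
      p <- accessions[[j]]
      cls <- sample(names(probs), n_loci, replace = TRUE, prob = probs)
      dosage <- vector("list", n_loci)
      for (i in seq_len(n_loci)) {
        dosage[[i]] <- switch(cls[i],
          hom = stats::setNames(p, ref[i]),
          sd = stats::setNames(c(p - 1L, 1L), c(ref[i], alt1[i])),
          md = {
            m <- sample(2:(p %/% 2), 1)
            stats::setNames(c(p - m, m), c(ref[i], alt1[i]))
          },
          ma = stats::setNames(c(p - 2L, 1L, 1L),
                               c(ref[i], alt1[i], alt2[i])))
      }
      df <- data.frame(locus_id = sprintf("locus%06d", seq_len(n_loci)),
                       seq_id = seq_id, pos = pos, ref = ref,
                       alt = ifelse(cls == "ma",
                                    paste(alt1, alt2, sep = ","), alt1),
                       accession = acc, ploidy = p,
                       class = c(hom = "homozygous", sd = "single_dose",
                                 md = "multi_dose", ma = "multi_allelic")[cls],
                       stringsAsFactors = FALSE)
      df$dosage <- dosage
      out[[j]] <- df
    }
    truth <- do.call(rbind, out)
    rownames(truth) <- NULL
    class(truth) <- c("genotype_truth", "data.frame")
    truth
  })
}

#' Simulate allele read depths for true genotypes
#'
#' Total depth per (locus, accession) is Poisson around \code{mean_depth}
#' (or fixed when \code{fixed_depth} is given, for exact binomial-model
#' checks); reads are then apportioned among the genotype's alleles by a
#' multinomial with probabilities dosage / ploidy — the binomial
#' read-sampling model underlying the depth calculations.
#'
#' @param truth a \code{genotype_truth} data.frame.
#' @param mean_depth mean total depth, a single value or named per
#'   accession; default 56.
#' @param fixed_depth if non-NULL, every locus gets exactly this depth.
#' @param seed RNG seed.
#' @return the input with columns \code{total_depth} (integer) and
#'   list-column \code{allele_depths} (named integer vectors) added.
#' @export
simulate_allele_reads <- function(truth, mean_depth = 56, fixed_depth = NULL,
                                  seed = 1L) {
  n <- nrow(truth)
  md <- if (length(mean_depth) == 1 && is.null(names(mean_depth)))
    rep(mean_depth, n) else unname(mean_depth[truth$accession])
  with_seed(seed, {
    depth <- if (is.null(fixed_depth)) stats::rpois(n, md)
             else rep(as.integer(fixed_depth), n)
    ad <- vector("list", n)
    for (i in seq_len(n)) {
      d <- truth$dosage[[i]]
      ad[[i]] <- if (depth[i] == 0) stats::setNames(integer(length(d)), names(d))
                 else stats::setNames(
                   as.integer(stats::rmultinom(1, depth[i], d / sum(d))),
                   names(d))
    }
    truth$total_depth <- as.integer(depth)
    truth$allele_depths <- ad
    truth
  })
}

#' Emit multi-caller VCFs from a genotype truth table
#'
#' Each caller reports a truth locus with its sensitivity probability
#' (independent Bernoulli per locus), writing genotypes with ploidy-many
#' GT slots matching the true dosage, plus DP and AD from the simulated
#' reads. Caller-specific false-positive sites are added at positions
#' absent from the truth set, so the all-caller intersection stays
#' interpretable. A truth VCF containing every locus is written alongside.
#'
#' @param truth a \code{genotype_truth} with read columns from
#'   [simulate_allele_reads()] (added automatically if absent).
#' @param out_dir output directory.
#' @param callers character vector of caller names; default five generic
#'   callers.
#' @param sensitivity per-caller inclusion probability, recycled; default
#'   0.9.
#' @param fp_fraction per-caller false-positive sites as a fraction of the
#'   truth locus count; default 0.02.
#' @param seed RNG seed.
#' @return list with \code{paths} (named caller -> VCF path),
#'   \code{truth_path}, and \code{caller_loci} (named list of the truth
#'   locus_ids each caller reports).
#' @export
emit_caller_vcfs <- function(truth, out_dir,
                             callers = paste0("caller", 1:5),
                             sensitivity = 0.9,
                             fp_fraction = 0.02,
                             seed = 1L) {
  if (length(callers) < 2) stop("need at least two callers")
  if (!"total_depth" %in% names(truth))
    truth <- simulate_allele_reads(truth, seed = seed)
  sensitivity <- rep_len(sensitivity, length(callers))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loci <- unique(truth[, c("locus_id", "seq_id", "pos", "ref")])
  loci <- loci[order(loci$pos), , drop = FALSE]
  # site-level ALT set: union of alternates over accessions at the locus
  alt_by_locus <- vapply(split(truth$alt, truth$locus_id), function(a)
    paste(sort(unique(unlist(strsplit(a, ",")))), collapse = ","),
    character(1))
  loci$alt <- unname(alt_by_locus[loci$locus_id])
  accs <- unique(truth$accession)

  with_seed(seed, {
    paths <- character(length(callers))
    names(paths) <- callers
    caller_loci <- vector("list", length(callers))
    names(caller_loci) <- callers
    truth_path <- file.path(out_dir, "truth.vcf")
    .write_sim_vcf(truth, loci, accs, truth_path)
    max_pos <- max(loci$pos)
    for (ci in seq_along(callers)) {
      keep <- stats::runif(nrow(loci)) < sensitivity[ci]
      caller_loci[[ci]] <- loci$locus_id[keep]
      n_fp <- round(fp_fraction * nrow(loci))
      fp <- NULL
      if (n_fp > 0) {
        # positions beyond (and interleaved past) the truth positions
        fp_pos <- max_pos + ci * 5L + seq_len(n_fp) * 1000L
        fp <- data.frame(seq_id = loci$seq_id[1], pos = fp_pos,
                         ref = sample(c("A", "C", "G", "T"), n_fp, TRUE),
                         stringsAsFactors = FALSE)
        fp$alt <- vapply(fp$ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
      }
      paths[ci] <- file.path(out_dir, paste0(callers[ci], ".vcf"))
      .write_sim_vcf(truth, loci[keep, , drop = FALSE], accs, paths[ci],
                     fp = fp)
    }
    list(paths = paths, truth_path = truth_path, caller_loci = caller_loci)
  })
}

# Write a minimal VCF 4.2 with GT:DP:AD for the given loci.
.write_sim_vcf <- function(truth, loci, accs, path, fp = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", accs), collapse = "\t"))
  by_acc <- split(seq_len(nrow(truth)), truth$accession)
  # index rows by locus within accession for fast lookup
  rec_lines <- character(0)
  if (nrow(loci) > 0) {
    idx <- lapply(by_acc, function(ix)
      stats::setNames(ix, truth$locus_id[ix]))
    rec_lines <- vapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i, ]
      alleles <- c(l$ref, strsplit(l$alt, ",")[[1]])
      cells <- vapply(accs, function(a) {
        r <- idx[[a]][[l$locus_id]]
        d <- truth$dosage[[r]]
        slots <- rep(match(names(d), alleles) - 1L, times = d)
        ad <- truth$allele_depths[[r]]
        ad_full <- vapply(alleles, function(al)
          if (al %in% names(ad)) ad[[al]] else 0L, integer(1))
        paste(paste(sort(slots), collapse = "/"),
              truth$total_depth[r],
              paste(ad_full, collapse = ","), sep = ":")
      }, character(1))
      paste(c(l$seq_id, l$pos, l$locus_id, l$ref, l$alt, ".", "PASS", ".",
              "GT:DP:AD", cells), collapse = "\t")
    }, character(1))
  }
  fp_lines <- character(0)
  if (!is.null(fp) && nrow(fp) > 0) {
    ploidies <- vapply(accs, function(a)
      truth$ploidy[truth$accession == a][1], integer(1))
    fp_lines <- vapply(seq_len(nrow(fp)), function(i) {
      carrier <- sample(seq_along(accs), 1)
      cells <- vapply(seq_along(accs), function(j) {
        p <- ploidies[j]
        gt <- if (j == carrier) paste(c(rep("0", p - 1), "1"), collapse = "/")
              else paste(rep("0", p), collapse = "/")
        ad <- if (j == carrier) paste(c(40L, 2L), collapse = ",") else "42,0"
        paste(gt, 42L, ad, sep = ":")
      }, character(1))
      paste(c(fp$seq_id[i], fp$pos[i], sprintf("fp%04d", i), fp$ref[i],
              fp$alt[i], ".", "PASS", ".", "GT:DP:AD", cells), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, rec_lines, fp_lines), path)
  invisible(path)
}

#' Simulate a raw GBS FASTQ with demultiplexing truth
#'
#' A configured fraction of reads is "clean": barcode + cut-site remnant +
#' random insert, with read lengths drawn uniformly over
#' \code{len_range} (so both trimming and padding are exercised
#' downstream). The remainder are junk reads guaranteed not to start with
#' any barcode+remnant prefix.
#'
#' @param n_reads total number of reads.
#' @param barcodes data.frame with \code{sample_id}, \code{barcode}.
#' @param clean_fraction fraction of clean reads; default 0.74.
#' @param remnant cut-site remnant; default \code{"CTGCAG"}.
#' @param len_range inclusive total-read-length range; default c(40, 100).
#' @param seed RNG seed.
#' @return list with \code{reads} (data.frame: read_id, sequence,
#'   quality) and \code{truth} (data.frame: read_id, sample_id — NA for
#'   junk reads).
#' @export
simulate_fastq <- function(n_reads, barcodes, clean_fraction = 0.74,
                           remnant = "CTGCAG", len_range = c(40L, 100L),
                           seed = 1L) {
  if (nrow(barcodes) < 1) stop("need at least one barcode")
  prefixes <- paste0(barcodes$barcode, remnant)
  if (len_range[1] <= max(nchar(prefixes)))
    stop("len_range minimum must exceed the longest barcode+remnant prefix")
  with_seed(seed, {
    is_clean <- stats::runif(n_reads) < clean_fraction
    which_bc <- sample(nrow(barcodes), n_reads, replace = TRUE)
    lens <- sample(len_range[1]:len_range[2], n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (is_clean[i]) {
        pre <- prefixes[which_bc[i]]
        seqs[i] <- paste0(pre, random_dna(lens[i] - nchar(pre)))
      } else {
        repeat {
          s <- random_dna(lens[i])
          if (!any(startsWith(s, prefixes))) break
        }
        seqs[i] <- s
      }
    }
    ids <- sprintf("read%07d", seq_len(n_reads))
    reads <- data.frame(read_id = ids, sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids,
                        sample_id = ifelse(is_clean,
                                           barcodes$sample_id[which_bc],
                                           NA_character_),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a region count matrix with implanted PAVs and CNVs
#'
#' The null model: expected count proportional to region length times the
#' accession's total mapped reads (so normalized depths are equal in
#' expectation across accessions), multiplied by log-normal noise with
#' standard deviation \code{noise_sd_log2} in log2 units, then
#' Poisson-sampled. PAV regions get expected count zero in a random
#' accession subset; CNV regions get the expectation multiplied by
#' \code{cnv_fold} in one random accession.
#'
#' @param n_regions number of regions (>= 10).
#' @param totals named numeric vector of per-accession total mapped reads;
#'   default four accessions at 0.8-1.4 million.
#' @param mean_count target mean expected count per cell under the null;
#'   default 50.
#' @param pav_fraction fraction of regions implanted as PAVs; default 0.
#' @param cnv_fraction fraction implanted as CNVs; default 0.
#' @param cnv_fold expected-count fold change for CNV regions (not 1);
#'   default 4.
#' @param noise_sd_log2 sd of the multiplicative noise in log2 units;
#'   default 0.2.
#' @param len_range inclusive region-length range in bp; default the GBS
#'   size-selection window c(51, 500).
#' @param seed RNG seed.
#' @return list with \code{matrix} (a \code{region_count_matrix}) and
#'   \code{truth} (data.frame: \code{region_id}, \code{class} in
#'   {normal, pav, cnv}, \code{affected} accession(s), \code{fold}).
#' @export
simulate_region_counts <- function(n_regions,
                                   totals = c(accA = 8e5, accB = 1e6,
                                              accC = 1.2e6, accD = 1.4e6),
                                   mean_count = 50,
                                   pav_fraction = 0,
                                   cnv_fraction = 0,
                                   cnv_fold = 4,
                                   noise_sd_log2 = 0.2,
                                   len_range = c(51L, 500L),
                                   seed = 1L) {
  if (n_regions < 10) stop("need at least 10 regions")
  if (cnv_fraction > 0 && cnv_fold == 1)
    stop("cnv_fold = 1 makes implanted CNVs unidentifiable")
  accs <- names(totals)
  n_acc <- length(totals)
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n_regions, replace = TRUE)
    starts <- cumsum(c(0L, utils::head(lens, -1) + 200L))
    regions <- data.frame(region_id = sprintf("region%05d", seq_len(n_regions)),
                          seq_id = "seq01",
                          start = starts, end = starts + lens,
                          stringsAsFactors = FALSE)
    # scale so the mean expected cell count under the null is mean_count
    base <- outer(lens, unname(totals))
    lambda <- base * (mean_count / mean(base))
    colnames(lambda) <- accs
    n_pav <- round(pav_fraction * n_regions)
    n_cnv <- round(cnv_fraction * n_regions)
    special <- sample(n_regions, n_pav + n_cnv)
    pav_idx <- special[seq_len(n_pav)]
    cnv_idx <- special[n_pav + seq_len(n_cnv)]
    truth <- data.frame(region_id = regions$region_id,
                        class = "normal", affected = "", fold = 1,
                        stringsAsFactors = FALSE)
    for (i in pav_idx) {
      k <- sample(seq_len(n_acc - 1), 1)   # absent in 1..n-1 accessions
      absent <- sample(accs, k)
      lambda[i, absent] <- 0
      truth$class[i] <- "pav"
      truth$affected[i] <- paste(sort(absent), collapse = ",")
    }
    for (i in cnv_idx) {
      a <- sample(accs, 1)
      lambda[i, a] <- lambda[i, a] * cnv_fold
      truth$class[i] <- "cnv"
      truth$affected[i] <- a
      truth$fold[i] <- cnv_fold
    }
    noise <- 2^matrix(stats::rnorm(n_regions * n_acc, 0, noise_sd_log2),
                      n_regions, n_acc)
    counts <- matrix(stats::rpois(n_regions * n_acc, lambda * noise),
                     n_regions, n_acc, dimnames = list(NULL, accs))
    list(matrix = region_count_matrix(regions, counts, totals),
         truth = truth)
  })
}
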