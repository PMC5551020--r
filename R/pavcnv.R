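#' Construct a region read-count matrix
#'
#' Container for per-region, per-accession raw read counts over the GBS
#' target-region universe (size-selected restriction fragments), together
#' with each accession's total mapped reads, needed for depth
#' normalization.
#'
#' @param regions data.frame with \code{region_id}, \code{seq_id},
#'   \code{start}, \code{end} (0-based half-open); lengths are derived.
#' @param counts integer matrix, regions x accessions (rownames =
#'   region_id, colnames = accession ids).
#' @param totals named numeric vector of total mapped reads per accession
#'   (> 0).
#' @return object of class \code{region_count_matrix}.
#' @export
region_count_matrix <- function(regions, counts, totals) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(regions))
  if (any(counts < 0)) stop("counts must be non-negative")
  regions$length <- regions$end - regions$start
  if (any(regions$length <= 0)) stop("region lengths must be positive")
  if (is.null(colnames(counts))) stop("counts must have accession colnames")
  if (!all(colnames(counts) %in% names(totals)))
    stop("totals missing for some accessions")
  totals <- totals[colnames(counts)]
  if (any(totals <= 0)) stop("totals must be positive")
  rownames(counts) <- regions$region_id
  structure(list(regions = regions, counts = counts, totals = totals),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat("region_count_matrix:", nrow(x$counts), "regions x",
      ncol(x$counts), "accessions\n")
  invisible(x)
}

#' Read a region count matrix from TSV files
#'
#' The counts file has columns region_id, seq_id, start, end, length,
#' then one count column per accession; the totals file has columns
#' accession, total_mapped_reads.
#'
#' @param counts_path,totals_path file paths.
#' @return a \code{region_count_matrix}.
#' @export
read_region_counts <- function(counts_path, totals_path) {
  tab <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  tot <- utils::read.table(totals_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  meta_cols <- c("region_id", "seq_id", "start", "end", "length")
  acc <- setdiff(names(tab), meta_cols)
  counts <- as.matrix(tab[, acc, drop = FALSE])
  region_count_matrix(tab[, c("region_id", "seq_id", "start", "end")],
                      counts,
                      stats::setNames(tot$total_mapped_reads, tot$accession))
}

#' Write a region count matrix to TSV files
#'
#' @param x a \code{region_count_matrix}.
#' @param counts_path,totals_path output paths.
#' @export
write_region_counts <- function(x, counts_path, totals_path) {
  tab <- cbind(x$regions[, c("region_id", "seq_id", "start", "end", "length")],
               as.data.frame(x$counts))
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(accession = names(x$totals),
                                total_mapped_reads = unname(x$totals)),
                     totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Normalize region read depth
#'
#' Library-size and region-length normalization:
#' \deqn{depth = 10^9 \times count / (total\_mapped\_reads \times length)}
#' making columns comparable across accessions with different sequencing
#' effort. Invariant under jointly scaling an accession's counts and total.
#'
#' @param x a \code{region_count_matrix}.
#' @return numeric matrix of normalized depths, same shape as the counts.
#' @export
normalize_depth <- function(x) {
  stopifnot(inherits(x, "region_count_matrix"))
  1e9 * x$counts / outer(x$regions$length, unname(x$totals))
}

#' Call presence/absence variations
#'
#' A region is a PAV iff at least one accession has zero reads while at
#' least one other reaches \code{min_reads} (default 5): robust presence
#' next to complete absence. Raw counts are used (absence is a zero, not a
#' normalized quantity).
#'
#' @param x a \code{region_count_matrix}.
#' @param min_reads presence threshold; default 5.
#' @return data.frame with \code{region_id}, \code{absent_in},
#'   \code{present_in} (comma-joined accession ids), \code{n_absent},
#'   \code{n_present}.
#' @export
call_pav <- function(x, min_reads = 5L) {
  stopifnot(inherits(x, "region_count_matrix"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  cnt <- x$counts
  acc <- colnames(cnt)
  is_pav <- apply(cnt, 1, min) == 0 & apply(cnt, 1, max) >= min_reads
  idx <- which(is_pav)
  out <- data.frame(
    region_id = x$regions$region_id[idx],
    absent_in = vapply(idx, function(i)
      paste(acc[cnt[i, ] == 0], collapse = ","), character(1)),
    present_in = vapply(idx, function(i)
      paste(acc[cnt[i, ] >= min_reads], collapse = ","), character(1)),
    n_absent = vapply(idx, function(i) sum(cnt[i, ] == 0), integer(1)),
    n_present = vapply(idx, function(i) sum(cnt[i, ] >= min_reads), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call copy-number variations from pairwise log2 depth ratios
#'
#' For every unordered pair of accessions, the per-region log2 ratio of
#' normalized depths is computed and regions falling outside
#' mean +/- \code{sd_mult} * sd of that pair's ratio distribution are
#' flagged (the classical mean-plus-3-sd outlier rule). A region is a CNV
#' iff flagged in at least one pair.
#'
#' Zero counts: with \code{exclude_pav = TRUE} (default) regions with a
#' zero raw count in either accession of a pair are excluded from that
#' pair's statistics — zeros are the presence/absence signal, not a copy
#' number. With \code{exclude_pav = FALSE} a pseudocount (\code{pseudocount}
#' raw reads, scaled to each accession's normalization unit) is added
#' instead. Pairs with zero ratio-sd flag nothing.
#'
#' @param x a \code{region_count_matrix}.
#' @param sd_mult outlier multiple; default 3.
#' @param exclude_pav drop zero-count regions per pair; default TRUE.
#' @param pseudocount raw-read pseudocount used when
#'   \code{exclude_pav = FALSE}; default 0.5.
#' @return list with \code{calls} (data.frame: \code{region_id},
#'   \code{pair}, \code{log2_ratio}, \code{pair_mean}, \code{pair_sd}),
#'   \code{cnv_regions} (unique flagged region ids) and \code{pair_stats}
#'   (data.frame: pair, n_eligible, n_flagged, mean, sd).
#' @export
call_cnv <- function(x, sd_mult = 3, exclude_pav = TRUE, pseudocount = 0.5) {
  stopifnot(inherits(x, "region_count_matrix"))
  acc <- colnames(x$counts)
  if (length(acc) < 2) stop("need at least two accessions")
  norm <- normalize_depth(x)
  # pseudocount in normalized units, per accession x region
  pc <- if (exclude_pav) NULL
        else {
          m <- 1e9 * pseudocount / outer(x$regions$length, unname(x$totals))
          colnames(m) <- acc
          m
        }
  pairs <- utils::combn(acc, 2, simplify = FALSE)
  calls <- list(); stats_rows <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    if (exclude_pav) {
      elig <- x$counts[, a] > 0 & x$counts[, b] > 0
      if (sum(elig) < 3) {
        warning("pair ", a, "-", b, ": fewer than 3 eligible regions; skipped")
        next
      }
      r <- log2(norm[elig, a] / norm[elig, b])
    } else {
      if (pseudocount == 0 && any(x$counts[, a] == 0 | x$counts[, b] == 0))
        stop("zero counts with exclude_pav = FALSE require pseudocount > 0")
      elig <- rep(TRUE, nrow(norm))
      r <- log2((norm[, a] + pc[, a]) / (norm[, b] + pc[, b]))
    }
    m <- mean(r); s <- stats::sd(r)
    flag <- if (s == 0) rep(FALSE, length(r)) else abs(r - m) > sd_mult * s
    pair_name <- paste(a, b, sep = "-")
    stats_rows[[pair_name]] <- data.frame(pair = pair_name,
                                          n_eligible = length(r),
                                          n_flagged = sum(flag),
                                          mean = m, sd = s,
                                          stringsAsFactors = FALSE)
    if (any(flag)) {
      calls[[pair_name]] <- data.frame(
        region_id = x$regions$region_id[which(elig)][flag],
        pair = pair_name,
        log2_ratio = r[flag],
        pair_mean = m, pair_sd = s,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(region_id = character(), pair = character(),
                           log2_ratio = numeric(), pair_mean = numeric(),
                           pair_sd = numeric())
  rownames(calls) <- NULL
  pair_stats <- do.call(rbind, stats_rows)
  rownames(pair_stats) <- NULL
  list(calls = calls,
       cnv_regions = unique(calls$region_id),
       pair_stats = pair_stats)
}

#' Summarize PAV and CNV calls
#'
#' Totals, genic percentages (via [genic_overlap()] on the region
#' coordinates) and per-accession absence counts.
#'
#' @param pav data.frame from [call_pav()].
#' @param cnv list from [call_cnv()].
#' @param x the \code{region_count_matrix} the calls came from.
#' @param genes optional gene data.frame (0-based half-open) for genic
#'   percentages.
#' @return list with \code{summary} (data.frame: variant_type, n,
#'   percent_genic) and \code{absence_by_accession}.
#' @export
pavcnv_report <- function(pav, cnv, x, genes = NULL) {
  stopifnot(inherits(x, "region_count_matrix"))
  pct_genic <- function(region_ids) {
    if (length(region_ids) == 0 || is.null(genes)) return(NA_real_)
    reg <- x$regions[x$regions$region_id %in% region_ids, , drop = FALSE]
    suppressWarnings(genic_overlap(reg, genes)$percent_genic)
  }
  summary <- data.frame(
    variant_type = c("PAV", "CNV"),
    n = c(nrow(pav), length(cnv$cnv_regions)),
    percent_genic = c(pct_genic(pav$region_id), pct_genic(cnv$cnv_regions)),
    stringsAsFactors = FALSE)
  absent <- unlist(strsplit(pav$absent_in, ","))
  absence <- if (length(absent)) as.data.frame(table(accession = absent),
                                               stringsAsFactors = FALSE)
             else data.frame(accession = character(), Freq = integer())
  names(absence)[2] <- "n_absent_regions"
  list(summary = summary, absence_by_accession = absence)
}
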