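#' Read a barcode table
#'
#' Two-column TSV (sample_id, barcode); lines starting with '#' are
#' comments. Barcodes are validated: DNA over A/C/G/T, length 4-10, unique,
#' and prefix-free (no barcode is a prefix of another), which guarantees
#' unambiguous demultiplexing.
#'
#' @param path path to the TSV file.
#' @param validate check the barcode-set invariants; default TRUE.
#' @return data.frame with \code{sample_id}, \code{barcode}.
#' @export
read_barcodes <- function(path, validate = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           col.names = c("sample_id", "barcode"),
                           colClasses = "character")
  if (validate) validate_barcodes(tab)
  tab
}

#' Validate a barcode set
#'
#' @param barcodes data.frame with \code{sample_id}, \code{barcode}.
#' @return the input, invisibly; errors on violation.
#' @export
validate_barcodes <- function(barcodes) {
  bc <- barcodes$barcode
  if (!all(grepl("^[ACGT]+$", bc)))
    stop("barcodes must be DNA strings over A/C/G/T")
  if (any(nchar(bc) < 4 | nchar(bc) > 10))
    stop("barcode lengths must be between 4 and 10")
  if (anyDuplicated(bc)) stop("barcodes must be unique")
  for (i in seq_along(bc)) for (j in seq_along(bc)) {
    if (i != j && startsWith(bc[j], bc[i]))
      stop("barcode '", bc[i], "' is a prefix of '", bc[j], "'")
  }
  invisible(barcodes)
}

#' Read a FASTQ file
#'
#' Plain 4-line-record FASTQ (Phred+33), returned with per-record quality
#' strings so they can be carried through trimming and padding.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with \code{read_id}, \code{sequence}, \code{quality}.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("FASTQ file is truncated: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 4)]))
  data.frame(read_id = ids,
             sequence = lines[seq(2, length(lines), by = 4)],
             quality = lines[seq(4, length(lines), by = 4)],
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence and quality lengths differ")
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$sequence
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Demultiplex GBS reads by barcode and restriction-site remnant
#'
#' A read is kept iff its sequence begins with exactly one barcode
#' immediately followed by the expected remnant of the restriction cut site
#' (default CTGCAG, the full PstI recognition sequence). The barcode is
#' stripped; the remnant is retained at the start of the kept read. Reads
#' matching two or more barcode+remnant prefixes are counted as ambiguous
#' and rejected (impossible for a prefix-free barcode set); reads with
#' non-ACGT characters in the matched prefix region are rejected.
#'
#' @param reads data.frame from [read_fastq()] (\code{read_id},
#'   \code{sequence}, optional \code{quality}).
#' @param barcodes data.frame with \code{sample_id}, \code{barcode}.
#' @param remnant expected cut-site remnant; default \code{"CTGCAG"}.
#' @return list with \code{reads} (data.frame: \code{sample_id},
#'   \code{read_id}, \code{sequence}, \code{quality}) and \code{stats}
#'   (data.frame: total, kept, rejected, ambiguous, kept_fraction).
#'   kept + rejected + ambiguous == total.
#' @export
filter_reads <- function(reads, barcodes, remnant = "CTGCAG") {
  if (!nzchar(remnant) || !grepl("^[ACGT]+$", remnant))
    stop("remnant must be a nonempty DNA string")
  if (any(!nzchar(reads$sequence))) stop("read sequences must be nonempty")
  seqs <- reads$sequence
  n <- length(seqs)
  prefixes <- paste0(barcodes$barcode, remnant)
  # match matrix: reads x barcodes
  m <- vapply(prefixes, function(p) startsWith(seqs, p), logical(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  nmatch <- rowSums(m)
  ambiguous <- nmatch >= 2
  kept <- nmatch == 1 & !ambiguous
  # non-ACGT inside the matched prefix region rejects the read
  if (any(kept)) {
    wb <- max.col(m, ties.method = "first")
    plen <- nchar(prefixes)[wb]
    bad <- kept & !grepl("^[ACGT]*$", substr(seqs, 1, plen))
    kept <- kept & !bad
  }
  widx <- which(kept)
  wb <- if (length(widx)) max.col(m[widx, , drop = FALSE], ties.method = "first")
        else integer(0)
  bclen <- nchar(barcodes$barcode)[wb]
  out <- data.frame(
    sample_id = barcodes$sample_id[wb],
    read_id = reads$read_id[widx],
    sequence = substring(seqs[widx], bclen + 1L),
    quality = if ("quality" %in% names(reads))
      substring(reads$quality[widx], bclen + 1L) else NA_character_,
    stringsAsFactors = FALSE)
  stats <- data.frame(total = n,
                      kept = sum(kept),
                      rejected = n - sum(kept) - sum(ambiguous),
                      ambiguous = sum(ambiguous),
                      kept_fraction = sum(kept) / max(n, 1))
  list(reads = out, stats = stats)
}

#' Trim or pad sequences to a fixed length
#'
#' Sequences longer than \code{target_len} are truncated to their first
#' \code{target_len} characters; shorter ones are padded at the end with
#' \code{pad_char} (default 'A', the GBS convention for length-normalizing
#' clean reads to 64 bp).
#'
#' @param sequence character vector of nonempty sequences.
#' @param target_len target length; default 64.
#' @param pad_char single padding character; default \code{"A"}.
#' @return character vector, every element exactly \code{target_len} long.
#' @examples
#' trim_pad(c("ACGTACGT", "AC"), target_len = 4)  # "ACGT", "ACAA"
#' @export
trim_pad <- function(sequence, target_len = 64L, pad_char = "A") {
  if (target_len < 1) stop("target_len must be >= 1")
  if (nchar(pad_char) != 1) stop("pad_char must be a single character")
  if (any(!nzchar(sequence))) stop("sequences must be nonempty")
  len <- nchar(sequence)
  short <- len < target_len
  padded <- sequence
  if (any(short)) {
    padded[short] <- paste0(sequence[short],
                            strrep(pad_char, target_len - len[short]))
  }
  substr(padded, 1, target_len)
}

#' Demultiplex, trim and pad a FASTQ file
#'
#' End-to-end preprocessing: [filter_reads()] then [trim_pad()] applied to
#' both sequence and quality (pad positions get quality '!', the lowest
#' Phred+33 symbol). Writes one FASTQ per sample plus a stats TSV when
#' \code{out_dir} is given.
#'
#' @param fastq path to the raw FASTQ file, or a data.frame from
#'   [read_fastq()].
#' @param barcodes data.frame with \code{sample_id}, \code{barcode}, or a
#'   path to a barcode TSV.
#' @param remnant expected cut-site remnant; default \code{"CTGCAG"}.
#' @param trim_to target read length; default 64.
#' @param out_dir optional output directory for per-sample FASTQs and
#'   \code{stats.tsv}.
#' @return list with \code{reads} (sample_id, read_id, sequence, quality,
#'   was_padded) and \code{stats}.
#' @export
demultiplex_fastq <- function(fastq, barcodes, remnant = "CTGCAG",
                              trim_to = 64L, out_dir = NULL) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  if (is.character(barcodes)) barcodes <- read_barcodes(barcodes)
  res <- filter_reads(reads, barcodes, remnant)
  kept <- res$reads
  kept$was_padded <- nchar(kept$sequence) < trim_to
  kept$sequence <- trim_pad(kept$sequence, trim_to, "A")
  if (!all(is.na(kept$quality)))
    kept$quality <- trim_pad(kept$quality, trim_to, "!")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in unique(kept$sample_id)) {
      write_fastq(kept[kept$sample_id == s, ],
                  file.path(out_dir, paste0(s, ".fastq")))
    }
    utils::write.table(res$stats, file.path(out_dir, "stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = kept, stats = res$stats)
}
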