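#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition site, a DNA string over A/C/G/T.
#' @param cut_offset position within the recognition site after which the
#'   top strand is cut (0 to nchar(recognition)). PstI (CTGCA^G) cuts after
#'   position 5.
#' @return object of class \code{restriction_enzyme}.
#' @examples
#' pstI <- restriction_enzyme("PstI", "CTGCAG", 5L)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition))
    stop("recognition site must contain only A, C, G, T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' Built-in enzyme registry
#'
#' Currently registers PstI, the rare cutter (CTGCAG, palindromic) used to
#' bias GBS libraries toward low-copy genomic regions. Extend by calling
#' [restriction_enzyme()] directly.
#'
#' @param name enzyme name to look up.
#' @return a \code{restriction_enzyme}.
#' @export
enzyme <- function(name = "PstI") {
  registry <- list(PstI = restriction_enzyme("PstI", "CTGCAG", 5L))
  if (!name %in% names(registry))
    stop("unknown enzyme '", name, "'; use restriction_enzyme() to define it")
  registry[[name]]
}

#' Locate restriction cut sites in a sequence
#'
#' Scans for every occurrence of the recognition site (overlapping
#' occurrences are all reported; occurrences containing N never match) and
#' returns the 0-based cut coordinates \code{site_start + cut_offset}.
#'
#' @param sequence a DNA string (character or \code{Biostrings::DNAString})
#'   over A/C/G/T/N.
#' @param enz a \code{restriction_enzyme}; default PstI.
#' @return strictly increasing integer vector of 0-based cut coordinates.
#' @examples
#' find_cut_sites("ACTGCAGT")   # site at index 1 -> cut at 6
#' @export
find_cut_sites <- function(sequence, enz = enzyme("PstI")) {
  seq <- if (inherits(sequence, "DNAString")) sequence
         else Biostrings::DNAString(toupper(as.character(sequence)))
  hits <- Biostrings::matchPattern(enz$recognition, seq, fixed = TRUE)
  starts0 <- BiocGenerics::start(hits) - 1L   # to 0-based
  sort(starts0 + enz$cut_offset)
}

#' In-silico restriction digestion of a genome
#'
#' Splits each sequence at every recognition-site cut, producing for a
#' sequence with c cut sites exactly c + 1 fragments that tile it without
#' gaps or overlap. Coordinates are 0-based half-open.
#'
#' @param genome a named character vector or \code{Biostrings::DNAStringSet}.
#' @param enz a \code{restriction_enzyme}; default PstI.
#' @return data.frame with columns \code{seq_id}, \code{start}, \code{end}
#'   (0-based half-open), \code{length}, \code{fragment_id}.
#' @examples
#' digest(c(chr1 = "ACTGCAGT"))   # two fragments: ACTGCA, GT
#' @export
digest <- function(genome, enz = enzyme("PstI")) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else {
    nm <- names(genome)
    seqs <- toupper(as.character(genome))
    names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  }
  if (length(seqs) == 0) stop("genome is empty")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    len <- nchar(seqs[[i]])
    if (len == 0) {
      warning("sequence '", id, "' is empty; no fragments produced")
      out[[i]] <- NULL
      next
    }
    cuts <- find_cut_sites(seqs[[i]], enz)
    cuts <- cuts[cuts > 0 & cuts < len]  # cuts at sequence ends split nothing
    bounds <- c(0L, cuts, len)
    out[[i]] <- data.frame(seq_id = id,
                           start = bounds[-length(bounds)],
                           end = bounds[-1],
                           stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  if (is.null(frags)) frags <- data.frame(seq_id = character(), start = integer(),
                                          end = integer())
  frags$length <- frags$end - frags$start
  frags$fragment_id <- sprintf("%s_frag%d", frags$seq_id,
                               stats::ave(frags$start, frags$seq_id,
                                          FUN = seq_along))
  rownames(frags) <- NULL
  frags
}

#' Size-select digested fragments
#'
#' Retains fragments whose length lies in \code{[min_len, max_len]}
#' (inclusive bounds), the size window enriched during GBS library
#' construction (default 51-500 bp).
#'
#' @param fragments data.frame from [digest()].
#' @param min_len,max_len inclusive length bounds; defaults 51 and 500.
#' @return the retained rows, original order preserved.
#' @export
size_select <- function(fragments, min_len = 51L, max_len = 500L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  fragments[fragments$length >= min_len & fragments$length <= max_len, ,
            drop = FALSE]
}

#' Annotate fragments with genic overlap
#'
#' A fragment is genic iff it overlaps at least one gene interval by at
#' least 1 bp. Both inputs use 0-based half-open coordinates.
#'
#' @param fragments data.frame with \code{seq_id}, \code{start}, \code{end}.
#' @param genes data.frame with \code{seq_id}, \code{start}, \code{end}
#'   (0-based half-open), e.g. from [read_gene_models()]. Genes on sequences
#'   absent from \code{fragments} are ignored with a warning.
#' @return list with \code{genic} (logical per fragment), \code{n_genic},
#'   \code{n_total}, \code{percent_genic}.
#' @export
genic_overlap <- function(fragments, genes) {
  unknown <- setdiff(unique(genes$seq_id), unique(fragments$seq_id))
  if (length(unknown) > 0) {
    warning("ignoring genes on sequences absent from fragments: ",
            paste(unknown, collapse = ", "))
    genes <- genes[!genes$seq_id %in% unknown, , drop = FALSE]
  }
  n <- nrow(fragments)
  if (n == 0) return(list(genic = logical(0), n_genic = 0L, n_total = 0L,
                          percent_genic = NaN))
  genic <- rep(FALSE, n)
  if (nrow(genes) > 0) {
    # half-open [start, end) -> 1-based closed [start + 1, end]
    fr <- GenomicRanges::GRanges(fragments$seq_id,
                                 IRanges::IRanges(fragments$start + 1L,
                                                  fragments$end))
    gr <- GenomicRanges::GRanges(genes$seq_id,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
    genic <- IRanges::overlapsAny(fr, gr)
  }
  list(genic = genic, n_genic = sum(genic), n_total = n,
       percent_genic = 100 * sum(genic) / n)
}

#' Genome-wide fragment density
#'
#' Counts fragment midpoints in fixed-width bins per sequence, for plotting
#' the genome-wide distribution of digestion fragments.
#'
#' @param fragments data.frame from [digest()].
#' @param bin_size bin width in bp (>= 1).
#' @return data.frame with \code{seq_id}, \code{bin_start} (0-based),
#'   \code{count}. Bin counts sum to the number of fragments.
#' @export
fragment_density <- function(fragments, bin_size) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (nrow(fragments) == 0)
    return(data.frame(seq_id = character(), bin_start = integer(),
                      count = integer()))
  mid <- floor((fragments$start + fragments$end) / 2)
  bin <- floor(mid / bin_size) * bin_size
  agg <- stats::aggregate(list(count = rep(1L, nrow(fragments))),
                          by = list(seq_id = fragments$seq_id, bin_start = bin),
                          FUN = sum)
  agg[order(agg$seq_id, agg$bin_start), , drop = FALSE]
}

#' Import gene models from GFF3 or BED
#'
#' Reads gene intervals via rtracklayer and converts them to the package's
#' internal 0-based half-open convention. For GFF3, only features of type
#' \code{gene} are kept; BED features are taken as-is.
#'
#' @param path path to a \code{.gff3}/\code{.gff} or \code{.bed} file.
#' @return data.frame with \code{seq_id}, \code{start}, \code{end}
#'   (0-based half-open), \code{feature_id}.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$ID)
  } else if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else sprintf("gene%d", seq_along(gr))
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,   # GRanges is 1-based closed
             end = BiocGenerics::end(gr),
             feature_id = ids,
             stringsAsFactors = FALSE)
}

#' Write fragments as BED
#'
#' 0-based half-open BED with fragment id (column 4) and length (column 5).
#'
#' @param fragments data.frame from [digest()].
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- fragments[, c("seq_id", "start", "end", "fragment_id", "length")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
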