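# Demultiplexing of dual-barcoded paired-end amplicon libraries.
#
# A read pair is assigned to a sample only when BOTH mates carry that
# sample's barcode as an exact prefix and, after skipping the linker bases,
# its primer with zero mismatches under IUPAC expansion. Base qualities are
# carried through but never consulted: abundance filtering downstream, not
# Phred scores, is the error control of this workflow.

#' Read a pair of synchronized FASTQ files
#'
#' Loads forward and reverse FASTQ files (plain or gzip) into a read-pair
#' table. The two files must be record-synchronized; differing counts or
#' differing record ids (compared up to the first whitespace or `/`) are a
#' fatal input error.
#'
#' @param r1,r2 paths to forward and reverse FASTQ files.
#' @return a data.frame with columns `read_id`, `fwd`, `rev`, `fwd_qual`,
#'   `rev_qual`.
#' @export
readFastqPairs <- function(r1, r2) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(f) != length(r))
    stop("desynchronized FASTQ streams: ", length(f), " forward vs ",
         length(r), " reverse records")
  idf <- sub("[/ \t].*$", "", names(f))
  idr <- sub("[/ \t].*$", "", names(r))
  if (!identical(idf, idr)) {
    k <- which(idf != idr)[1]
    stop("desynchronized FASTQ streams: record ", k, " ids differ ('",
         idf[k], "' vs '", idr[k], "')")
  }
  data.frame(read_id = idf,
             fwd = as.character(f),
             rev = as.character(r),
             fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
             rev_qual = as.character(S4Vectors::mcols(r)$qualities),
             row.names = NULL)
}

#' Test barcode + primer prefix of reads
#'
#' The demultiplexing acceptance test for one mate: `TRUE` iff the read
#' starts with `barcode` exactly, and the `primer` matches with zero
#' mismatches under IUPAC expansion immediately after `linker_len` skipped
#' bases. Reads too short for barcode + linker + primer yield `FALSE`.
#'
#' @param reads character vector of reads.
#' @param barcode concrete ACGT barcode.
#' @param linker_len number of spacer bases between barcode and primer
#'   (skipped, not checked).
#' @param primer IUPAC primer sequence.
#' @return logical vector.
#' @examples
#' matchesPrefix("ACGTACGTCAGTGCCAGCAGCCGCGGTAATTTT",
#'               "ACGTACGT", 2, "GTGCCAGCMGCCGCGGTAA")
#' @export
matchesPrefix <- function(reads, barcode, linker_len, primer) {
  nb <- nchar(barcode)
  ok <- substr(reads, 1L, nb) == barcode
  ok & iupacMatchAt(primer, reads, at = nb + linker_len + 1L)
}

#' Demultiplex paired reads by dual barcodes
#'
#' Partitions read pairs across the samples of a [SampleMap-class]. Every
#' input pair lands in exactly one bucket: a sample (both mates match that
#' sample's barcode/primer), or the reject pile with reason
#' `"cross-sample chimera"` (each mate individually matches some sample's
#' barcode+primer, but the barcode combination belongs to no sample — the
#' signature of hybrid molecules formed after pooling of per-sample PCR
#' products, which dual barcoding exists to catch) or
#' `"barcode/primer mismatch"` (anything else).
#'
#' @param pairs read-pair table from [readFastqPairs()] (columns `read_id`,
#'   `fwd`, `rev` and optionally `fwd_qual`, `rev_qual`).
#' @param map a [SampleMap-class].
#' @return list with elements
#'   \describe{
#'     \item{samples}{named list of per-sample read-pair tables;}
#'     \item{rejected}{read-pair table with an extra `reason` column;}
#'     \item{report}{data.frame (`category`, `count`) covering every sample
#'       and both reject reasons; counts sum to `nrow(pairs)`.}
#'   }
#' @export
demultiplex <- function(pairs, map) {
  validObject(map)
  n <- nrow(pairs)
  S <- nrow(map)
  fwd_ok <- matrix(FALSE, nrow = n, ncol = S)
  rev_ok <- matrix(FALSE, nrow = n, ncol = S)
  for (s in seq_len(S)) {
    fwd_ok[, s] <- matchesPrefix(pairs$fwd, map$fwd_barcode[s],
                                 map$linker_len[s], map$fwd_primer[s])
    rev_ok[, s] <- matchesPrefix(pairs$rev, map$rev_barcode[s],
                                 map$linker_len[s], map$rev_primer[s])
  }
  both <- fwd_ok & rev_ok
  n_match <- rowSums(both)
  if (any(n_match > 1L))
    stop("internal error: read pair matched multiple samples despite unique barcode pairs")
  assigned_to <- ifelse(n_match == 1L, max.col(both, ties.method = "first"), NA_integer_)
  cross <- is.na(assigned_to) & rowSums(fwd_ok) > 0L & rowSums(rev_ok) > 0L
  reason <- rep(NA_character_, n)
  reason[is.na(assigned_to)] <- "barcode/primer mismatch"
  reason[cross] <- "cross-sample chimera"

  samples <- lapply(seq_len(S), function(s)
    pairs[which(assigned_to == s), , drop = FALSE])
  names(samples) <- map$sample_id
  rejected <- pairs[is.na(assigned_to), , drop = FALSE]
  rejected$reason <- reason[is.na(assigned_to)]
  report <- data.frame(
    category = c(map$sample_id,
                 "rejected:barcode/primer mismatch",
                 "rejected:cross-sample chimera"),
    count = c(vapply(samples, nrow, integer(1)),
              sum(reason == "barcode/primer mismatch", na.rm = TRUE),
              sum(reason == "cross-sample chimera", na.rm = TRUE)))
  list(samples = samples, rejected = rejected, report = report)
}

#' Strip technical bases and trim to fixed length
#'
#' Removes barcode + linker + primer from the 5' end of each mate of pairs
#' already assigned to a sample, then keeps exactly the next `read_len`
#' bases. Pairs with fewer than `read_len` remaining bases on either mate
#' are discarded and counted.
#'
#' @param pairs read-pair table for one sample.
#' @param entry one-row subset of a [SampleMap-class] (the sample's entry).
#' @param read_len retained sub-read length (default 70, i.e. ~140 nt of
#'   information per pair).
#' @return list with `trimmed` (data.frame `read_id`, `fwd`, `rev`, each
#'   sequence exactly `read_len` bases) and `n_short` (discarded pairs).
#' @export
stripTechnical <- function(pairs, entry, read_len = 70L) {
  stopifnot(nrow(entry) == 1L)
  off_f <- nchar(entry$fwd_barcode) + entry$linker_len + nchar(entry$fwd_primer)
  off_r <- nchar(entry$rev_barcode) + entry$linker_len + nchar(entry$rev_primer)
  fwd <- substr(pairs$fwd, off_f + 1L, off_f + read_len)
  rev <- substr(pairs$rev, off_r + 1L, off_r + read_len)
  full <- nchar(fwd) == read_len & nchar(rev) == read_len
  list(trimmed = data.frame(read_id = pairs$read_id[full],
                            fwd = fwd[full], rev = rev[full],
                            row.names = NULL),
       n_short = sum(!full))
}

#' Write demultiplexed reads as per-sample FASTQ pairs
#'
#' @param dmx result of [demultiplex()].
#' @param out_dir output directory (created if absent). Files are named
#'   `<sample>_R1.fastq` / `<sample>_R2.fastq`; a `demux_report.tsv` with
#'   per-category counts is written alongside.
#' @return invisibly, the report data.frame.
#' @export
writeDemuxFastq <- function(dmx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(dmx$samples)) {
    p <- dmx$samples[[s]]
    writeFastq(p$fwd, p$read_id, p$fwd_qual,
               file.path(out_dir, paste0(s, "_R1.fastq")))
    writeFastq(p$rev, p$read_id, p$rev_qual,
               file.path(out_dir, paste0(s, "_R2.fastq")))
  }
  utils::write.table(dmx$report, file.path(out_dir, "demux_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dmx$report)
}

# Plain 4-line FASTQ writer (constant-quality streams make Biostrings'
# QualityScaledDNAStringSet machinery unnecessary here).
writeFastq <- function(seqs, ids, quals, path) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}
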