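#' Construct a SampleMap
#'
#' @param sample_id character vector of unique sample names.
#' @param fwd_barcode,rev_barcode per-sample barcodes (equal length, ACGT).
#' @param fwd_primer,rev_primer IUPAC primer sequences (amplicon
#'   orientation; recycled if length 1).
#' @param linker_len number of spacer bases between barcode and primer
#'   (skipped, never matched); recycled.
#' @param library_id library label; recycled.
#' @return a validated [SampleMap-class] object.
#' @examples
#' pr <- standardPrimers()$V4
#' SampleMap(c("S1", "S2"),
#'           fwd_barcode = c("ACGTACGT", "TGCATGCA"),
#'           rev_barcode = c("GGTTCCAA", "AACCGGTT"),
#'           fwd_primer = pr[["fwd"]], rev_primer = pr[["rev"]])
#' @export
SampleMap <- function(sample_id, fwd_barcode, rev_barcode,
                      fwd_primer, rev_primer,
                      linker_len = 2L, library_id = "lib1") {
  n <- length(sample_id)
  df <- S4Vectors::DataFrame(
    sample_id = as.character(sample_id),
    fwd_barcode = toupper(rep_len(fwd_barcode, n)),
    rev_barcode = toupper(rep_len(rev_barcode, n)),
    fwd_primer = toupper(rep_len(fwd_primer, n)),
    rev_primer = toupper(rep_len(rev_primer, n)),
    linker_len = as.integer(rep_len(linker_len, n)),
    library_id = as.character(rep_len(library_id, n)))
  new("SampleMap", df)
}

#' Read a sample mapping file
#'
#' Tab-delimited with a header row naming at least `SampleID`, `FwdBarcode`,
#' `RevBarcode`, `FwdPrimer` and `RevPrimer`; optional columns `LinkerLen`
#' (default 2) and `LibraryID` (default "lib1"). Lines starting with `#`
#' are ignored (the header may itself start with `#SampleID`, the common
#' mapping-file dialect).
#'
#' @param path path to the mapping file.
#' @return a validated [SampleMap-class] object.
#' @export
readSampleMap <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  raw <- readLines(path)
  lineno <- seq_along(raw)
  keep <- nzchar(trimws(raw))
  raw <- raw[keep]; lineno <- lineno[keep]
  is_comment <- startsWith(trimws(raw), "#")
  header_at <- which(!is_comment | grepl("SampleID", raw, fixed = TRUE))[1]
  if (is.na(header_at)) stop("mapping file has no header row")
  header <- trimws(strsplit(sub("^#", "", raw[header_at]), "\t")[[1]])
  body_sel <- seq_along(raw) > header_at & !is_comment
  body_lines <- raw[body_sel]
  body_lineno <- lineno[body_sel]
  req <- c("SampleID", "FwdBarcode", "RevBarcode", "FwdPrimer", "RevPrimer")
  missing_cols <- setdiff(req, header)
  if (length(missing_cols))
    stop("mapping file lacks column(s): ", paste(missing_cols, collapse = ", "))
  rows <- strsplit(body_lines, "\t")
  n_field <- lengths(rows)
  bad <- which(n_field < length(req))
  if (length(bad))
    stop(sprintf("malformed mapping row at line %d: expected at least %d fields, found %d",
                 body_lineno[bad[1]], length(req), n_field[bad[1]]))
  get_col <- function(nm, default = NULL) {
    j <- match(nm, header)
    if (is.na(j)) return(rep(default, length(rows)))
    vapply(rows, function(r) if (j <= length(r)) trimws(r[j]) else "",
           character(1))
  }
  SampleMap(sample_id = get_col("SampleID"),
            fwd_barcode = get_col("FwdBarcode"),
            rev_barcode = get_col("RevBarcode"),
            fwd_primer = get_col("FwdPrimer"),
            rev_primer = get_col("RevPrimer"),
            linker_len = as.integer(get_col("LinkerLen", default = "2")),
            library_id = get_col("LibraryID", default = "lib1"))
}

#' @rdname SampleMap-class
#' @aliases sampleIds,SampleMap-method
setMethod("sampleIds", "SampleMap", function(x) x$sample_id)

#' @rdname SampleMap-class
#' @aliases barcodeLength,SampleMap-method
setMethod("barcodeLength", "SampleMap", function(x) {
  if (nrow(x) == 0L) return(NA_integer_)
  nchar(x$fwd_barcode[1])
})

setMethod("show", "SampleMap", function(object) {
  cat(sprintf("SampleMap with %d sample(s), %s-nt dual barcodes, linker %s nt\n",
              nrow(object), barcodeLength(object),
              paste(unique(object$linker_len), collapse = "/")))
  if (nrow(object)) {
    n_show <- min(nrow(object), 5L)
    df <- as.data.frame(object[seq_len(n_show),
                               c("sample_id", "fwd_barcode", "rev_barcode")])
    print(df, row.names = FALSE)
    if (nrow(object) > n_show) cat("  ...\n")
  }
})
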