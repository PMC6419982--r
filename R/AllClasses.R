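#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
NULL

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' SampleMap: sample-to-barcode/primer bindings
#'
#' A `SampleMap` binds each sample to its forward/reverse barcode, its
#' degenerate (IUPAC) primer pair, the linker length separating barcode and
#' primer, and a library identifier. It is the object that drives
#' demultiplexing: a read pair is assigned to a sample only if both mates
#' carry that sample's barcode as an exact prefix and its primer (after the
#' linker) under IUPAC expansion with zero mismatches.
#'
#' Invariants enforced by the validity method: all barcodes share one length
#' (8 nt in the default dual-barcoding layout), `(fwd_barcode, rev_barcode)`
#' combinations are unique across samples, and sample ids are unique and
#' non-empty.
#'
#' @slot .Data inherited `DFrame` with columns `sample_id`, `fwd_barcode`,
#'   `rev_barcode`, `fwd_primer`, `rev_primer`, `linker_len`, `library_id`.
#' @seealso [SampleMap()], [readSampleMap()], [demultiplex()]
#' @exportClass SampleMap
setClass("SampleMap", contains = "DFrame")

.validSampleMap <- function(object) {
  msgs <- character(0)
  req <- c("sample_id", "fwd_barcode", "rev_barcode",
           "fwd_primer", "rev_primer", "linker_len", "library_id")
  missing_cols <- setdiff(req, colnames(object))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(object) == 0L)
    return(msgs)
  if (any(is.na(object$sample_id)) || any(!nzchar(object$sample_id)))
    msgs <- c(msgs, "sample ids must be non-empty")
  if (anyDuplicated(object$sample_id))
    msgs <- c(msgs, "sample ids must be unique")
  bl <- unique(nchar(c(object$fwd_barcode, object$rev_barcode)))
  if (length(bl) != 1L)
    msgs <- c(msgs, sprintf("all barcodes must have equal length (found lengths %s)",
                            paste(sort(bl), collapse = ", ")))
  key <- paste(object$fwd_barcode, object$rev_barcode, sep = "|")
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicate (fwd_barcode, rev_barcode) combination")
  bad <- grepl("[^ACGT]", c(object$fwd_barcode, object$rev_barcode))
  if (any(bad))
    msgs <- c(msgs, "barcodes must be plain ACGT sequences")
  for (p in c(object$fwd_primer, object$rev_primer))
    if (grepl(sprintf("[^%s]", IUPAC_CODES_STRING), p))
      msgs <- c(msgs, sprintf("primer '%s' contains non-IUPAC characters", p))
  if (any(object$linker_len < 0L))
    msgs <- c(msgs, "linker_len must be >= 0")
  if (length(msgs)) msgs else TRUE
}
setValidity("SampleMap", .validSampleMap)

#' Per-sample OTU table
#'
#' In this workflow an OTU is a unique pair of 5' and 3' sub-reads of fixed
#' length within one sample. The table stores, per OTU, the exact-match read
#' count, the count of reads rescued at one mismatch after abundance
#' filtering, and a de novo chimera flag. `total_reads` is the number of read
#' pairs that entered OTU picking for this sample, so `count / total_reads`
#' is the relative abundance the threshold was applied to.
#'
#' @slot sample_id sample identifier.
#' @slot total_reads integer, read pairs entering OTU picking.
#' @slot threshold minimum relative abundance (fraction) used for acceptance.
#' @slot records data.frame with columns `otu_id`, `fwd`, `rev`, `count`,
#'   `rescued`, `chimera`, ordered by decreasing `count` (ties broken
#'   lexicographically on `fwd` then `rev`).
#' @seealso [pickOTUs()], [rescueDiscarded()], [flagChimeras()]
#' @exportClass SampleOTUTable
setClass("SampleOTUTable",
  representation(sample_id = "character",
                 total_reads = "integer",
                 threshold = "numeric",
                 records = "data.frame"))

.validSampleOTUTable <- function(object) {
  msgs <- character(0)
  rec <- object@records
  req <- c("otu_id", "fwd", "rev", "count", "rescued", "chimera")
  if (!all(req %in% colnames(rec)))
    return(paste0("records must have columns ", paste(req, collapse = ", ")))
  if (length(object@threshold) != 1L ||
      object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must be a fraction in (0, 1)")
  if (nrow(rec)) {
    if (any(rec$count < 1L))
      msgs <- c(msgs, "accepted OTUs must have count >= 1")
    if (any(rec$rescued < 0L))
      msgs <- c(msgs, "rescued counts must be >= 0")
    if (anyDuplicated(paste(rec$fwd, rec$rev, sep = "|")))
      msgs <- c(msgs, "(fwd, rev) pairs must be unique within a sample")
    if (object@total_reads > 0L &&
        any(rec$count / object@total_reads < object@threshold - 1e-12))
      msgs <- c(msgs, "every accepted OTU must meet the abundance threshold")
    if (sum(rec$count + rec$rescued) > object@total_reads)
      msgs <- c(msgs, "sum(count + rescued) cannot exceed total_reads")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SampleOTUTable", .validSampleOTUTable)

#' Primer-trimmed reference database
#'
#' Full-length 16S reference sequences cut down to the amplified region
#' using the primer pair as a guide. For each retained reference the first
#' `read_len` bases after the forward-primer site (`fwd_frag`) and the
#' reverse complement of the last `read_len` bases before the reverse-primer
#' site (`rev_frag`, stored in the orientation of the reverse sequencing
#' read) are kept together with a six-rank lineage. References with no
#' primer site or an inter-primer region shorter than `read_len` are listed
#' in `rejected` with a reason.
#'
#' @slot frags data.frame: `accession`, `fwd_frag`, `rev_frag`, and the six
#'   lineage columns `domain` ... `genus` (empty string = unresolved).
#' @slot read_len fragment length in bases.
#' @slot rejected data.frame: `accession`, `reason`.
#' @seealso [trimReferences()], [searchHits()]
#' @exportClass TrimmedReferenceSet
setClass("TrimmedReferenceSet",
  representation(frags = "data.frame",
                 read_len = "integer",
                 rejected = "data.frame"))

.validTrimmedReferenceSet <- function(object) {
  msgs <- character(0)
  fr <- object@frags
  req <- c("accession", "fwd_frag", "rev_frag", LINEAGE_RANKS)
  if (!all(req %in% colnames(fr)))
    return(paste0("frags must have columns ", paste(req, collapse = ", ")))
  if (nrow(fr)) {
    if (any(nchar(fr$fwd_frag) != object@read_len) ||
        any(nchar(fr$rev_frag) != object@read_len))
      msgs <- c(msgs, "all fragments must be exactly read_len bases")
    if (anyDuplicated(fr$accession))
      msgs <- c(msgs, "accessions must be unique")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("TrimmedReferenceSet", .validTrimmedReferenceSet)

#' Hit profile of one OTU against a trimmed reference set
#'
#' Holds every reference whose combined identity with the OTU reaches the
#' lowest configured threshold, together with the descending identity
#' threshold levels. The per-level hit lists are nested by construction:
#' a hit at a higher level is a hit at every lower level.
#'
#' @slot otu_id the query OTU.
#' @slot hits data.frame: `accession`, `identity`, lineage columns.
#' @slot levels descending identity thresholds (default 1.00, 0.98, 0.97,
#'   0.95, 0.92, 0.90).
#' @seealso [searchHits()], [hitsAtLevel()], [consensusLabel()]
#' @exportClass HitProfile
setClass("HitProfile",
  representation(otu_id = "character",
                 hits = "data.frame",
                 levels = "numeric"))

.validHitProfile <- function(object) {
  if (any(diff(object@levels) >= 0))
    return("levels must be strictly descending")
  if (any(object@levels <= 0) || any(object@levels > 1))
    return("levels must lie in (0, 1]")
  TRUE
}
setValidity("HitProfile", .validHitProfile)

#' Relative-abundance profile at one taxonomic rank
#'
#' Abundance mass of the non-chimeric OTUs of one sample aggregated to a
#' taxonomic rank. Mass from OTUs whose assignment is shallower than the
#' requested rank is pooled under the reserved label `"unassigned"`, so the
#' profile always sums to one and distances penalise poor classification.
#'
#' @slot sample_id sample identifier.
#' @slot rank the rank the profile was aggregated at.
#' @slot abundances named numeric vector of fractions summing to 1.
#' @seealso [makeProfile()], [weightedDifference()]
#' @exportClass TaxProfile
setClass("TaxProfile",
  representation(sample_id = "character",
                 rank = "character",
                 abundances = "numeric"))

.validTaxProfile <- function(object) {
  msgs <- character(0)
  x <- object@abundances
  if (is.null(names(x)) || any(!nzchar(names(x))))
    msgs <- c(msgs, "abundances must be a named vector")
  if (any(x < 0))
    msgs <- c(msgs, "abundances must be non-negative")
  if (length(x) && abs(sum(x) - 1) > 1e-9)
    msgs <- c(msgs, "abundances must sum to 1 (within 1e-9)")
  if (!object@rank %in% LINEAGE_RANKS)
    msgs <- c(msgs, "rank must be one of the six lineage ranks")
  if (length(msgs)) msgs else TRUE
}
setValidity("TaxProfile", .validTaxProfile)

#' Mock-community design
#'
#' The blueprint the read simulator executes: which templates at which
#' relative abundances, how many read pairs, the per-base substitution
#' error rate on payload bases, the fraction of read pairs assembled from
#' two templates (chimeras), the per-pair probability of a substitution in
#' the technical prefix (barcode/linker/primer), and the RNG seed.
#'
#' @slot name design name.
#' @slot members data.frame: `template_id`, `abundance` (fractions, sum 1).
#' @slot n_reads number of read pairs to simulate.
#' @slot error_rate per-base substitution probability on payload bases.
#' @slot chimera_rate fraction of pairs drawing 5' and 3' sides from two
#'   different templates.
#' @slot technical_error_rate per-pair probability of one substitution at a
#'   random technical base.
#' @slot seed integer RNG seed.
#' @seealso [mockDesign()], [presetDesigns()], [simulateReads()]
#' @exportClass MockDesign
setClass("MockDesign",
  representation(name = "character",
                 members = "data.frame",
                 n_reads = "integer",
                 error_rate = "numeric",
                 chimera_rate = "numeric",
                 technical_error_rate = "numeric",
                 seed = "integer"))

.validMockDesign <- function(object) {
  msgs <- character(0)
  m <- object@members
  if (!all(c("template_id", "abundance") %in% colnames(m)))
    return("members must have columns template_id, abundance")
  if (abs(sum(m$abundance) - 1) > 1e-9)
    msgs <- c(msgs, "member abundances must sum to 1 (within 1e-9)")
  if (any(m$abundance < 0))
    msgs <- c(msgs, "abundances must be non-negative")
  if (anyDuplicated(m$template_id))
    msgs <- c(msgs, "template ids must be unique")
  for (r in c(object@error_rate, object@chimera_rate,
              object@technical_error_rate))
    if (r < 0 || r >= 1)
      msgs <- c(msgs, "rates must lie in [0, 1)")
  if (object@n_reads < 1L)
    msgs <- c(msgs, "n_reads must be >= 1")
  if (length(msgs)) msgs else TRUE
}
setValidity("MockDesign", .validMockDesign)

#' Pipeline configuration
#'
#' All tunable constants of the workflow in one validated object. Defaults
#' are the standard operating point: 70-base retained sub-reads (~140 nt of
#' information per pair), a 0.1% per-sample minimum relative-abundance
#' threshold, identity threshold levels 100/98/97/95/92/90%, a 50% minimum
#' specificity for modal-label acceptance, a 2-fold parent-abundance
#' requirement for chimera flagging, and at most 1 mismatch when locating
#' primer sites in reference sequences.
#'
#' @slot read_len retained sub-read length (bases).
#' @slot threshold minimum per-sample relative abundance, fraction in (0,1).
#' @slot identity_levels strictly descending identity thresholds in (0,1].
#' @slot min_spec minimum specificity (percent) for accepting a modal label.
#' @slot chimera_fold fold-abundance both parents must reach (>= 1).
#' @slot max_primer_mismatch mismatches tolerated at reference primer sites.
#' @slot rank rank profiles are aggregated at ("genus" or "family").
#' @slot use_rescued logical; include rescued counts in profile mass.
#' @slot paths named character vector of input/output paths (r1, r2, map,
#'   ref_fasta, ref_tax, out_dir); may be empty for in-memory use.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(read_len = "integer",
                 threshold = "numeric",
                 identity_levels = "numeric",
                 min_spec = "numeric",
                 chimera_fold = "numeric",
                 max_primer_mismatch = "integer",
                 rank = "character",
                 use_rescued = "logical",
                 paths = "character"))

.validPipelineConfig <- function(object) {
  msgs <- character(0)
  if (object@read_len < 1L)
    msgs <- c(msgs, "read_len must be >= 1")
  if (object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must be a fraction in (0, 1)")
  lv <- object@identity_levels
  if (any(diff(lv) >= 0) || any(lv <= 0) || any(lv > 1))
    msgs <- c(msgs, "identity_levels must be strictly descending in (0, 1]")
  if (object@chimera_fold < 1)
    msgs <- c(msgs, "chimera_fold must be >= 1")
  if (object@min_spec < 0 || object@min_spec > 100)
    msgs <- c(msgs, "min_spec is a percentage in [0, 100]")
  if (!object@rank %in% c("genus", "family"))
    msgs <- c(msgs, "rank must be 'genus' or 'family'")
  if (length(msgs)) msgs else TRUE
}
setValidity("PipelineConfig", .validPipelineConfig)
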