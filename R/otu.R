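# Per-sample OTU picking. An OTU is a unique (5' read, 3' read) pair of
# trimmed sub-reads. Error control is per-sample abundance filtering (not
# Phred scores): unique pairs below a minimum relative abundance are
# discarded, then rescued at one mismatch so that error-prone templates are
# not systematically under-counted, and finally a de novo rule flags
# chimeric OTUs from the abundances of their putative parents.

#' Dereplicate trimmed read pairs
#'
#' Counts exactly identical (fwd, rev) pairs. Pair identity is the
#' concatenation of both mates; pairs differing in either mate are distinct.
#'
#' @param trimmed data.frame with columns `fwd` and `rev` (equal-length
#'   sequences from [stripTechnical()]).
#' @return data.frame `fwd`, `rev`, `count`, ordered by decreasing count,
#'   ties broken lexicographically on `fwd` then `rev`. `sum(count)` equals
#'   `nrow(trimmed)`.
#' @export
dereplicate <- function(trimmed) {
  if (!nrow(trimmed))
    return(data.frame(fwd = character(0), rev = character(0),
                      count = integer(0)))
  key <- paste(trimmed$fwd, trimmed$rev, sep = "|")
  tab <- table(key)
  u <- !duplicated(key)
  out <- data.frame(fwd = trimmed$fwd[u], rev = trimmed$rev[u],
                    count = as.integer(tab[key[u]]), row.names = NULL)
  out <- out[order(-out$count, out$fwd, out$rev), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick OTUs by minimum relative abundance
#'
#' Accepts every dereplicated pair whose `count / total_reads` reaches the
#' per-sample threshold (default operating point 0.001, i.e. 0.1%); all
#' other pairs go to the discarded set, available for one-mismatch rescue.
#' Applying the threshold per sample (rather than dataset-wide) avoids
#' under-representing OTUs in shallowly sequenced samples.
#'
#' @param derep output of [dereplicate()].
#' @param total_reads reads entering OTU picking; must equal `sum(count)`.
#' @param threshold minimum relative abundance, fraction in (0,1).
#' @param sample_id sample name used for `otu_id`s (`<sample>_OTU<rank>`).
#' @return list with `table` (a [SampleOTUTable-class]) and `discarded`
#'   (data.frame `fwd`, `rev`, `count` of sub-threshold pairs).
#' @export
pickOTUs <- function(derep, total_reads, threshold = 0.001,
                     sample_id = "sample") {
  stopifnot(threshold > 0, threshold < 1)
  if (total_reads != sum(derep$count))
    stop("total_reads (", total_reads, ") != sum of dereplicated counts (",
         sum(derep$count), ")")
  if (total_reads == 0L) {
    warning("no reads entered OTU picking for sample ", sample_id)
    rec <- data.frame(otu_id = character(0), fwd = character(0),
                      rev = character(0), count = integer(0),
                      rescued = integer(0), chimera = logical(0))
    return(list(table = new("SampleOTUTable", sample_id = sample_id,
                            total_reads = 0L, threshold = threshold,
                            records = rec),
                discarded = derep))
  }
  keep <- derep$count / total_reads >= threshold
  acc <- derep[keep, , drop = FALSE]
  acc <- acc[order(-acc$count, acc$fwd, acc$rev), , drop = FALSE]
  rec <- data.frame(
    otu_id = sprintf("%s_OTU%04d", sample_id, seq_len(nrow(acc))),
    fwd = acc$fwd, rev = acc$rev, count = as.integer(acc$count),
    rescued = rep(0L, nrow(acc)), chimera = rep(FALSE, nrow(acc)),
    row.names = NULL)
  tab <- new("SampleOTUTable", sample_id = sample_id,
             total_reads = as.integer(total_reads),
             threshold = threshold, records = rec)
  list(table = tab, discarded = derep[!keep, , drop = FALSE])
}

#' Rescue discarded reads at one mismatch
#'
#' Each discarded unique pair whose concatenated sequence (fwd + rev) lies
#' at Hamming distance 1 from at least one accepted OTU's concatenation
#' adds its count to that OTU's `rescued` field. When several accepted OTUs
#' qualify, the one with the largest exact-match count wins (ties broken by
#' lexicographic order of the concatenated sequence). Rescue never changes
#' `count` fields or acceptance; unmatched pairs are returned unassigned.
#'
#' @param table a [SampleOTUTable-class].
#' @param discarded data.frame `fwd`, `rev`, `count` from [pickOTUs()].
#' @return list with `table` (rescued counts filled in) and `unassigned`
#'   (discarded pairs not within one mismatch of any accepted OTU).
#' @export
rescueDiscarded <- function(table, discarded) {
  rec <- table@records
  if (!nrow(rec) || !nrow(discarded))
    return(list(table = table, unassigned = discarded))
  cat_acc <- paste0(rec$fwd, rec$rev)
  cat_dis <- paste0(discarded$fwd, discarded$rev)
  L <- nchar(cat_acc[1])
  if (any(nchar(cat_dis) != L))
    stop("discarded pairs must have the same trimmed length as accepted OTUs")
  am <- seqCharMatrix(cat_acc)
  dm <- seqCharMatrix(cat_dis)
  # Hamming distances, discarded x accepted
  D <- vapply(seq_len(nrow(rec)), function(i)
    rowSums(dm != matrix(am[i, ], nrow = nrow(dm), ncol = L, byrow = TRUE)),
    numeric(nrow(dm)))
  D <- matrix(D, nrow = nrow(dm))
  hit <- logical(nrow(dm))
  for (j in seq_len(nrow(dm))) {
    cand <- which(D[j, ] <= 1L)
    if (!length(cand)) next
    best <- cand[rec$count[cand] == max(rec$count[cand])]
    if (length(best) > 1L) best <- best[order(cat_acc[best])][1L]
    rec$rescued[best[1L]] <- rec$rescued[best[1L]] + discarded$count[j]
    hit[j] <- TRUE
  }
  table@records <- rec
  validObject(table)
  list(table = table, unassigned = discarded[!hit, , drop = FALSE])
}

#' Flag chimeric OTUs de novo
#'
#' Rule: an OTU C is flagged as a chimera when there exist accepted OTUs
#' A != C and B != C such that A's 5' read is identical to C's, B's 3' read
#' is identical to C's, and both A and B are at least `fold` times as
#' abundant as C (default 2, exact-match counts, pre-rescue — stable counts
#' make the flags order-independent). Flagged records stay in the table;
#' downstream consumers exclude them via the flag.
#'
#' @param table a [SampleOTUTable-class].
#' @param fold parent-abundance multiple required (default 2; "at least"
#'   is non-strict, so a parent at exactly `fold`x qualifies).
#' @param distinct_parents require A and B to be different records. With
#'   unique (fwd, rev) pairs a single record can never play both roles
#'   (it would be sequence-identical to C), so this changes nothing in
#'   valid tables; the switch exists to make that reading explicit.
#' @return the table with the `chimera` column filled in.
#' @export
flagChimeras <- function(table, fold = 2, distinct_parents = FALSE) {
  rec <- table@records
  n <- nrow(rec)
  if (n < 3L) {
    if (n) rec$chimera <- FALSE
    table@records <- rec
    return(table)
  }
  flag <- logical(n)
  for (k in seq_len(n)) {
    others <- setdiff(seq_len(n), k)
    a_set <- others[rec$fwd[others] == rec$fwd[k] &
                    rec$count[others] >= fold * rec$count[k]]
    b_set <- others[rec$rev[others] == rec$rev[k] &
                    rec$count[others] >= fold * rec$count[k]]
    if (!length(a_set) || !length(b_set)) next
    flag[k] <- if (distinct_parents)
      any(outer(a_set, b_set, "!=")) else TRUE
  }
  rec$chimera <- flag
  table@records <- rec
  table
}

#' Build a per-sample OTU table in one call
#'
#' Convenience wrapper running [dereplicate()], [pickOTUs()],
#' [rescueDiscarded()] and [flagChimeras()] in order.
#'
#' @param trimmed data.frame `fwd`, `rev` from [stripTechnical()].
#' @param sample_id sample name.
#' @param threshold minimum relative abundance.
#' @param chimera_fold parent-abundance multiple for chimera flagging.
#' @return a [SampleOTUTable-class] with rescue and chimera flags applied.
#' @export
buildOTUTable <- function(trimmed, sample_id, threshold = 0.001,
                          chimera_fold = 2) {
  derep <- dereplicate(trimmed)
  picked <- pickOTUs(derep, total_reads = nrow(trimmed),
                     threshold = threshold, sample_id = sample_id)
  rescued <- rescueDiscarded(picked$table, picked$discarded)
  flagChimeras(rescued$table, fold = chimera_fold)
}

#' Write an OTU table as TSV
#'
#' @param table a [SampleOTUTable-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeOTUTable <- function(table, path) {
  utils::write.table(table@records, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname SampleOTUTable-class
#' @aliases sampleId,SampleOTUTable-method
setMethod("sampleId", "SampleOTUTable", function(x) x@sample_id)

#' @rdname SampleOTUTable-class
#' @aliases otuRecords,SampleOTUTable-method
setMethod("otuRecords", "SampleOTUTable", function(x) x@records)

#' @rdname SampleOTUTable-class
#' @aliases totalReads,SampleOTUTable-method
setMethod("totalReads", "SampleOTUTable", function(x) x@total_reads)

#' @rdname SampleOTUTable-class
#' @aliases abundanceThreshold,SampleOTUTable-method
setMethod("abundanceThreshold", "SampleOTUTable", function(x) x@threshold)

setMethod("length", "SampleOTUTable", function(x) nrow(x@records))

setMethod("show", "SampleOTUTable", function(object) {
  rec <- object@records
  cat(sprintf("SampleOTUTable '%s': %d OTU(s) from %d reads (threshold %.4g)\n",
              object@sample_id, nrow(rec), object@total_reads,
              object@threshold))
  if (nrow(rec))
    cat(sprintf("  reads in OTUs: %d exact + %d rescued; chimera-flagged: %d\n",
                sum(rec$count), sum(rec$rescued), sum(rec$chimera)))
})
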