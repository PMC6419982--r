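# Taxonomic assignment of OTUs against a primer-trimmed reference database.
#
# A full-length 16S reference set is cut to the amplified region using the
# primer pair as a guide, each OTU is compared against every trimmed
# reference (combined identity = mean of the 5' and 3' fragment
# identities), hits are collected at six descending identity thresholds,
# and a consensus label is accepted at the deepest rank whose modal label
# is specific enough and concordant across all lower thresholds.

#' Read a full-length reference set with lineages
#'
#' Loads a FASTA (plain or gzip) of full-length 16S sequences and a
#' lineage table. Sequences are upper-cased, alignment gap characters are
#' removed and U is mapped to T. Lineages come from `tax_path`, a
#' tab-delimited file `accession<TAB>domain;phylum;class;order;family;genus`
#' (the usual taxonomy-export dialect; shorter lineages are padded with
#' empty ranks), or, if `tax_path` is `NULL`, from the FASTA headers after
#' the first space.
#'
#' @param fasta_path reference FASTA.
#' @param tax_path lineage TSV, or `NULL` to parse headers.
#' @return data.frame: `accession`, `seq`, and the six lineage columns.
#' @export
readReferenceSet <- function(fasta_path, tax_path = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  acc <- sub("[ \t].*$", "", names(ss))
  refs <- data.frame(accession = acc,
                     seq = cleanRefSequence(as.character(ss)),
                     row.names = NULL)
  if (is.null(tax_path)) {
    lin_str <- ifelse(grepl("[ \t]", names(ss)),
                      sub("^[^ \t]+[ \t]+", "", names(ss)), "")
    lin <- parseLineages(lin_str)
  } else {
    tx <- utils::read.table(tax_path, sep = "\t", header = FALSE,
                            quote = "", comment.char = "#",
                            col.names = c("accession", "lineage"),
                            colClasses = "character")
    lin_str <- tx$lineage[match(acc, tx$accession)]
    lin_str[is.na(lin_str)] <- ""
    lin <- parseLineages(lin_str)
  }
  cbind(refs, lin)
}

parseLineages <- function(lin_str) {
  parts <- strsplit(lin_str, ";", fixed = TRUE)
  out <- lapply(seq_along(LINEAGE_RANKS), function(i)
    vapply(parts, function(p)
      if (length(p) >= i) trimws(p[i]) else "", character(1)))
  names(out) <- LINEAGE_RANKS
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Best primer site in one subject: minimal mismatches up to max_mm, ties
# resolved to the 5'-most (from5 = TRUE) or 3'-most site.
bestPrimerSite <- function(subject, primer, max_mm, from5 = TRUE) {
  pat <- Biostrings::DNAString(primer)
  for (mm in 0:max_mm) {
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                  with.indels = FALSE, fixed = "subject")
    if (length(m)) {
      if (length(m) > 1L)
        warning("multiple equally good primer sites; taking the ",
                if (from5) "5'-most" else "3'-most", call. = FALSE)
      r <- IRanges::ranges(m)
      i <- if (from5) which.min(IRanges::start(r)) else which.max(IRanges::start(r))
      return(c(start = IRanges::start(r)[i], end = IRanges::end(r)[i]))
    }
  }
  NULL
}

#' Trim full-length references to the amplified region
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer in each reference (IUPAC matching, at most `max_primer_mismatch`
#' mismatches, preferring sites with fewer mismatches; among equally good
#' sites the 5'-most forward and 3'-most reverse site are used) and
#' extracts the inter-primer region. The stored fragments are the first
#' `read_len` bases of that region (`fwd_frag`) and the reverse complement
#' of its last `read_len` bases (`rev_frag`, i.e. the orientation of the
#' reverse sequencing read). References lacking either site, with the
#' reverse site not downstream of the forward site, or with an inter-primer
#' region shorter than `read_len`, are rejected and counted.
#'
#' @param refs data.frame from [readReferenceSet()].
#' @param fwd_primer,rev_primer IUPAC primers in amplicon orientation (the
#'   reverse primer is reverse-complemented internally).
#' @param read_len fragment length (default 70).
#' @param max_primer_mismatch mismatches tolerated per site (default 1).
#' @return a [TrimmedReferenceSet-class].
#' @export
trimReferences <- function(refs, fwd_primer, rev_primer, read_len = 70L,
                           max_primer_mismatch = 1L) {
  stopifnot(read_len >= 1L)
  rev_rc <- revComp(toupper(rev_primer))
  fwd_primer <- toupper(fwd_primer)
  n <- nrow(refs)
  keep <- logical(n)
  fwd_frag <- rev_frag <- character(n)
  reject_reason <- character(n)
  for (i in seq_len(n)) {
    subj <- Biostrings::DNAString(refs$seq[i])
    fs <- bestPrimerSite(subj, fwd_primer, max_primer_mismatch, from5 = TRUE)
    rs <- bestPrimerSite(subj, rev_rc, max_primer_mismatch, from5 = FALSE)
    if (is.null(fs) || is.null(rs)) {
      reject_reason[i] <- if (is.null(fs) && is.null(rs)) "no primer site"
                          else if (is.null(fs)) "no forward-primer site"
                          else "no reverse-primer site"
      next
    }
    from <- fs[["end"]] + 1L
    to <- rs[["start"]] - 1L
    if (to < from || (to - from + 1L) < read_len) {
      reject_reason[i] <- "inter-primer region shorter than read_len"
      next
    }
    insert <- substr(refs$seq[i], from, to)
    fwd_frag[i] <- substr(insert, 1L, read_len)
    rev_frag[i] <- revComp(substr(insert, nchar(insert) - read_len + 1L,
                                  nchar(insert)))
    keep[i] <- TRUE
  }
  frags <- data.frame(accession = refs$accession[keep],
                      fwd_frag = fwd_frag[keep], rev_frag = rev_frag[keep],
                      refs[keep, LINEAGE_RANKS, drop = FALSE],
                      row.names = NULL)
  rejected <- data.frame(accession = refs$accession[!keep],
                         reason = reject_reason[!keep], row.names = NULL)
  new("TrimmedReferenceSet", frags = frags,
      read_len = as.integer(read_len), rejected = rejected)
}

#' Pairwise sequence identity
#'
#' End-to-end identity between two sequences under unit substitution and
#' gap costs: `1 - d / max(nchar(a), nchar(b))` where `d` is the
#' Levenshtein distance. Symmetric and deterministic; for equal-length
#' sequences differing only by substitutions this equals the fraction of
#' matching columns (one substitution in a 70-mer gives 69/70).
#'
#' @param a,b character vectors; if one has length 1 it is compared against
#'   every element of the other, otherwise the two are paired elementwise.
#' @return numeric vector of identities in \[0, 1\].
#' @examples
#' sequenceIdentity("ACGTACGT", "ACGTACGT")  # 1
#' sequenceIdentity(strrep("A", 70), paste0(strrep("A", 69), "C"))  # 69/70
#' @export
sequenceIdentity <- function(a, b) {
  stopifnot(all(nzchar(a)), all(nzchar(b)))
  if (length(a) == 1L || length(b) == 1L) {
    d <- as.vector(utils::adist(a, b))
    L <- pmax(nchar(a), nchar(b))
  } else {
    stopifnot(length(a) == length(b))
    d <- vapply(seq_along(a), function(i)
      utils::adist(a[i], b[i])[1, 1], numeric(1))
    L <- pmax(nchar(a), nchar(b))
  }
  1 - d / L
}

#' Search one OTU against a trimmed reference set
#'
#' Combined identity per reference is the mean of
#' `sequenceIdentity(fwd, fwd_frag)` and `sequenceIdentity(rev, rev_frag)`.
#' All references whose combined identity reaches the lowest threshold are
#' retained; the per-level hit lists (see [hitsAtLevel()]) are nested by
#' construction.
#'
#' @param fwd,rev the OTU's trimmed sub-reads.
#' @param db a [TrimmedReferenceSet-class].
#' @param levels descending identity thresholds (default
#'   `c(1, 0.98, 0.97, 0.95, 0.92, 0.90)`).
#' @param otu_id label carried into the result.
#' @return a [HitProfile-class].
#' @export
searchHits <- function(fwd, rev, db,
                       levels = c(1, 0.98, 0.97, 0.95, 0.92, 0.90),
                       otu_id = "otu") {
  fr <- db@frags
  if (!nrow(fr)) stop("empty reference database")
  id_f <- sequenceIdentity(fwd, fr$fwd_frag)
  id_r <- sequenceIdentity(rev, fr$rev_frag)
  combined <- (id_f + id_r) / 2
  keep <- combined >= min(levels) - 1e-9
  hits <- data.frame(accession = fr$accession[keep],
                     identity = combined[keep],
                     fr[keep, LINEAGE_RANKS, drop = FALSE],
                     row.names = NULL)
  hits <- hits[order(-hits$identity, hits$accession), , drop = FALSE]
  rownames(hits) <- NULL
  new("HitProfile", otu_id = otu_id, hits = hits, levels = sort(levels, decreasing = TRUE))
}

#' @rdname HitProfile-class
#' @aliases hitsAtLevel,HitProfile-method
setMethod("hitsAtLevel", "HitProfile", function(x, level) {
  x@hits[x@hits$identity >= level - 1e-9, , drop = FALSE]
})

#' @rdname HitProfile-class
#' @aliases identityLevels,HitProfile-method
setMethod("identityLevels", "HitProfile", function(x) x@levels)

setMethod("show", "HitProfile", function(object) {
  cat(sprintf("HitProfile for '%s': %d hit(s) at the lowest level\n",
              object@otu_id, nrow(object@hits)))
  for (t in object@levels)
    cat(sprintf("  >= %.2f: %d hit(s)\n", t, nrow(hitsAtLevel(object, t))))
})

#' Modal label and specificity at one rank
#'
#' The specificity of a hit list at a rank is the percentage of hits (with
#' a non-empty label at that rank) carrying the most frequent label. Hits
#' with an empty label at the rank are excluded from both numerator and
#' denominator; ties between equally frequent labels go to the
#' lexicographically first.
#'
#' @param hits data.frame of hits (as from [hitsAtLevel()]).
#' @param rank `"genus"`, `"family"`, or any of the six ranks.
#' @return list `label` (modal label, `""` if no labelled hit), `pct`
#'   (specificity percentage) and `n` (number of labelled hits).
#' @export
labelSpecificity <- function(hits, rank) {
  stopifnot(rank %in% LINEAGE_RANKS)
  lab <- hits[[rank]]
  lab <- lab[!is.na(lab) & nzchar(lab)]
  if (!length(lab)) return(list(label = "", pct = 0, n = 0L))
  tab <- table(lab)
  top <- names(tab)[tab == max(tab)]
  modal <- sort(top)[1L]
  list(label = modal, pct = 100 * as.integer(tab[modal]) / length(lab),
       n = length(lab))
}

#' Consensus taxonomic label from a hit profile
#'
#' Scans the identity thresholds from the highest downward; `T` is the
#' highest level with at least one hit. The genus modal label at `T` is
#' accepted iff its specificity reaches `min_spec` and the modal genus at
#' every lower threshold (which always has hits, by nesting) agrees. If
#' genus fails, the same test is applied at family. If family also fails,
#' the deepest lineage prefix shared by all hits at level `T` is emitted
#' (possibly down to order or above). Specificity and supporting hits are
#' reported for the accepted rank at level `T`.
#'
#' @param profile a [HitProfile-class].
#' @param min_spec minimum specificity percentage (default 50).
#' @return one-row data.frame: `otu_id`, the six lineage columns (truncated
#'   below the accepted rank), `assigned_rank`, `specificity`,
#'   `supporting_hits`, `top_level`.
#' @export
consensusLabel <- function(profile, min_spec = 50) {
  empty <- data.frame(otu_id = profile@otu_id,
                      as.list(stats::setNames(rep("", 6), LINEAGE_RANKS)),
                      assigned_rank = "unassigned", specificity = 0,
                      supporting_hits = 0L, top_level = NA_real_,
                      stringsAsFactors = FALSE)
  hits <- profile@hits
  if (!nrow(hits)) return(empty)
  levels <- profile@levels
  present <- levels[vapply(levels, function(t)
    nrow(hitsAtLevel(profile, t)) > 0L, logical(1))]
  Tlev <- present[1L]
  top_hits <- hitsAtLevel(profile, Tlev)
  lower <- levels[levels < Tlev]

  tryRank <- function(rank) {
    s <- labelSpecificity(top_hits, rank)
    if (s$n == 0L || s$pct < min_spec) return(NULL)
    for (t in lower) {
      st <- labelSpecificity(hitsAtLevel(profile, t), rank)
      if (st$n > 0L && st$label != s$label) return(NULL)
    }
    s
  }

  finish <- function(lineage, rank, spec, nhits) {
    out <- empty
    out[LINEAGE_RANKS] <- lineage
    out$assigned_rank <- rank
    out$specificity <- spec
    out$supporting_hits <- as.integer(nhits)
    out$top_level <- Tlev
    out
  }

  for (rank in c("genus", "family")) {
    s <- tryRank(rank)
    if (is.null(s)) next
    depth <- match(rank, LINEAGE_RANKS)
    carrier <- top_hits[top_hits[[rank]] == s$label, , drop = FALSE][1L, ]
    lineage <- unlist(carrier[LINEAGE_RANKS], use.names = FALSE)
    lineage[seq_along(lineage) > depth] <- ""
    return(finish(lineage, rank, s$pct, s$n))
  }

  # shared-prefix fallback over all hits at level T
  lineage <- rep("", 6L)
  rank <- "unassigned"
  for (i in seq_along(LINEAGE_RANKS)) {
    lab <- unique(top_hits[[LINEAGE_RANKS[i]]])
    if (length(lab) == 1L && nzchar(lab)) {
      lineage[i] <- lab
      rank <- LINEAGE_RANKS[i]
    } else break
  }
  spec <- if (rank == "unassigned") 0 else 100
  finish(lineage, rank, spec, nrow(top_hits))
}

#' Classify all OTUs of a sample
#'
#' Runs [searchHits()] and [consensusLabel()] for every non-chimeric OTU.
#' Chimera-flagged records are reported with `assigned_rank = "chimera"`
#' and an empty lineage so the output has one row per OTU.
#'
#' @param table a [SampleOTUTable-class].
#' @param db a [TrimmedReferenceSet-class].
#' @param levels descending identity thresholds.
#' @param min_spec minimum specificity percentage.
#' @return data.frame with one row per OTU: `otu_id`, six lineage columns,
#'   `assigned_rank`, `specificity`, `supporting_hits`, `top_level`.
#' @export
classifyOTUs <- function(table, db,
                         levels = c(1, 0.98, 0.97, 0.95, 0.92, 0.90),
                         min_spec = 50) {
  rec <- table@records
  rows <- lapply(seq_len(nrow(rec)), function(k) {
    if (rec$chimera[k]) {
      out <- consensusLabel(new("HitProfile", otu_id = rec$otu_id[k],
                                hits = data.frame(), levels = levels))
      out$assigned_rank <- "chimera"
      return(out)
    }
    pr <- searchHits(rec$fwd[k], rec$rev[k], db, levels = levels,
                     otu_id = rec$otu_id[k])
    consensusLabel(pr, min_spec = min_spec)
  })
  do.call(rbind, rows)
}

#' @rdname TrimmedReferenceSet-class
#' @aliases refFragments,TrimmedReferenceSet-method
setMethod("refFragments", "TrimmedReferenceSet", function(x) x@frags)

#' @rdname TrimmedReferenceSet-class
#' @aliases readLength,TrimmedReferenceSet-method
setMethod("readLength", "TrimmedReferenceSet", function(x) x@read_len)

#' @rdname TrimmedReferenceSet-class
#' @aliases rejectedRefs,TrimmedReferenceSet-method
setMethod("rejectedRefs", "TrimmedReferenceSet", function(x) x@rejected)

setMethod("length", "TrimmedReferenceSet", function(x) nrow(x@frags))

setMethod("show", "TrimmedReferenceSet", function(object) {
  cat(sprintf("TrimmedReferenceSet: %d reference(s) at 2 x %d nt (%d rejected)\n",
              nrow(object@frags), object@read_len, nrow(object@rejected)))
})
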