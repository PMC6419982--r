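# Relative-abundance profiles and the weighted-difference divergence.
#
# The divergence between two profiles x and y sums, per taxon i, the
# absolute difference dif_i = (x_i - y_i) multiplied by a weighting factor
# w_i = (x_i - y_i) / avg(x_i + y_i), i.e. (x_i - y_i)^2 / ((x_i + y_i)/2)
# under the per-taxon-average reading. The weight makes a 1-point absolute
# change count for more when the shared abundance is small (a 1% change is
# a 200% relative change at 0.5% expected abundance but only 20% at 5%),
# so relative as well as absolute composition errors are penalised.

#' Aggregate an OTU table into a taxonomic profile
#'
#' Abundance mass of each non-chimeric OTU (`count`, plus `rescued` when
#' `use_rescued`) is normalised over the sample's non-chimeric OTUs and
#' accrued to the OTU's label at `rank`. OTUs whose assignment is shallower
#' than `rank` (or unassigned/chimeric in the assignment table) contribute
#' to the reserved `"unassigned"` label, so mass is conserved.
#'
#' @param table a [SampleOTUTable-class].
#' @param assignments data.frame from [classifyOTUs()].
#' @param rank `"genus"` or `"family"` (any of the six ranks accepted).
#' @param use_rescued include rescued counts in the mass (default TRUE).
#' @return a [TaxProfile-class].
#' @export
makeProfile <- function(table, assignments, rank = "genus",
                        use_rescued = TRUE) {
  stopifnot(rank %in% LINEAGE_RANKS)
  rec <- table@records[!table@records$chimera, , drop = FALSE]
  if (!nrow(rec))
    stop("sample '", table@sample_id, "' has no non-chimeric OTUs")
  i <- match(rec$otu_id, assignments$otu_id)
  if (anyNA(i))
    stop("missing assignment for OTU(s): ",
         paste(rec$otu_id[is.na(i)], collapse = ", "))
  lab <- assignments[[rank]][i]
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  mass <- rec$count + if (use_rescued) rec$rescued else 0L
  ab <- tapply(mass, lab, sum)
  ab <- ab / sum(mass)
  new("TaxProfile", sample_id = table@sample_id, rank = rank,
      abundances = stats::setNames(as.numeric(ab), names(ab)))
}

#' Build a profile directly from labelled abundances
#'
#' Low-level constructor used for expected (design) profiles and tests.
#'
#' @param abundances named numeric vector; normalised to sum to 1.
#' @param sample_id sample name.
#' @param rank taxonomic rank.
#' @return a [TaxProfile-class].
#' @export
taxProfile <- function(abundances, sample_id = "sample", rank = "genus") {
  ab <- tapply(abundances, names(abundances), sum)
  ab <- ab / sum(ab)
  new("TaxProfile", sample_id = sample_id, rank = rank,
      abundances = stats::setNames(as.numeric(ab), names(ab)))
}

#' Relative change implied by an absolute change
#'
#' `100 * abs_change / expected`: a 1-point absolute change is a 200%
#' relative change at an expected abundance of 0.5%, but only 20% at 5%.
#'
#' @param abs_change absolute change in percentage points.
#' @param expected expected abundance (percent), strictly positive.
#' @return relative change in percent.
#' @examples
#' relativeChange(1, 0.5)  # 200
#' relativeChange(1, 5)    # 20
#' @export
relativeChange <- function(abs_change, expected) {
  if (any(expected <= 0))
    stop("expected abundance must be strictly positive")
  100 * abs_change / expected
}

#' Weighted-difference divergence between two profiles
#'
#' For each taxon in the union of supports (absent labels read as 0):
#' contribution `(x_i - y_i)^2 / ((x_i + y_i)/2)` (per-taxon average
#' reading, the default) or `(x_i - y_i)^2 / mean(x + y)` with
#' `average = "taxa"`. Taxa with `x_i + y_i == 0` contribute 0. The total
#' is symmetric, non-negative, and zero exactly when the profiles agree on
#' their union support; it is a divergence, not a proven metric.
#'
#' @param x,y [TaxProfile-class] objects at the same rank.
#' @param average denominator reading: `"pair"` (per-taxon `(x_i+y_i)/2`)
#'   or `"taxa"` (mean of `x_i + y_i` over union taxa).
#' @return list with `total` and `per_taxon` (named contributions).
#' @examples
#' x <- taxProfile(c(A = 0.6, B = 0.4))
#' y <- taxProfile(c(A = 0.5, B = 0.5))
#' weightedDifference(x, y)$total  # 0.01/0.55 + 0.01/0.45 ~= 0.0404
#' @export
weightedDifference <- function(x, y, average = c("pair", "taxa")) {
  average <- match.arg(average)
  if (x@rank != y@rank)
    stop("profiles are at different ranks: ", x@rank, " vs ", y@rank)
  taxa <- sort(union(names(x@abundances), names(y@abundances)))
  xi <- ifelse(taxa %in% names(x@abundances), x@abundances[taxa], 0)
  yi <- ifelse(taxa %in% names(y@abundances), y@abundances[taxa], 0)
  xi[is.na(xi)] <- 0; yi[is.na(yi)] <- 0
  contrib <- numeric(length(taxa))
  nz <- xi + yi > 0
  if (average == "pair") {
    contrib[nz] <- (xi[nz] - yi[nz])^2 / ((xi[nz] + yi[nz]) / 2)
  } else {
    denom <- mean(xi + yi)
    contrib[nz] <- (xi[nz] - yi[nz])^2 / denom
  }
  names(contrib) <- taxa
  list(total = sum(contrib), per_taxon = contrib)
}

#' Profile matrix (taxa x samples)
#'
#' @param profiles list of [TaxProfile-class] objects at one rank.
#' @return numeric matrix, rows = union of taxa, columns = samples.
#' @export
profileMatrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ranks <- unique(vapply(profiles, function(p) p@rank, character(1)))
  if (length(ranks) != 1L) stop("profiles are at different ranks")
  taxa <- sort(Reduce(union, lapply(profiles, function(p) names(p@abundances))))
  m <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p@abundances)] <- p@abundances
    v
  }, numeric(length(taxa)))
  m <- matrix(m, nrow = length(taxa),
              dimnames = list(taxa, vapply(profiles, function(p)
                p@sample_id, character(1))))
  m
}

#' Pairwise weighted-difference distance matrix
#'
#' @param profiles list of [TaxProfile-class] objects at one rank.
#' @param average see [weightedDifference()].
#' @return symmetric numeric matrix of totals with zero diagonal.
#' @export
weightedDifferenceMatrix <- function(profiles, average = "pair") {
  n <- length(profiles)
  ids <- vapply(profiles, function(p) p@sample_id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <-
      weightedDifference(profiles[[i]], profiles[[j]], average = average)$total
  }
  m
}

#' @rdname TaxProfile-class
#' @aliases abundances,TaxProfile-method
setMethod("abundances", "TaxProfile", function(x) x@abundances)

#' @rdname TaxProfile-class
#' @aliases profileRank,TaxProfile-method
setMethod("profileRank", "TaxProfile", function(x) x@rank)

#' @rdname TaxProfile-class
#' @aliases sampleId,TaxProfile-method
setMethod("sampleId", "TaxProfile", function(x) x@sample_id)

setMethod("show", "TaxProfile", function(object) {
  cat(sprintf("TaxProfile '%s' at rank %s: %d label(s)\n",
              object@sample_id, object@rank, length(object@abundances)))
  top <- sort(object@abundances, decreasing = TRUE)
  top <- utils::head(top, 8L)
  for (i in seq_along(top))
    cat(sprintf("  %-28s %6.2f%%\n", names(top)[i], 100 * top[i]))
  if (length(object@abundances) > 8L) cat("  ...\n")
})
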