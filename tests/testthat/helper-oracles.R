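# Independent oracles and fixture builders used across the suite.
# Oracles deliberately re-derive quantities by brute force, sharing no code
# with the package implementations they check.

# Full dynamic-programming Levenshtein distance (unit substitution and gap
# costs), written as an explicit matrix recurrence.
levenshteinOracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n)) {
    D[i + 1L, j + 1L] <- min(D[i, j] + (A[i] != B[j]),
                             D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L)
  }
  D[m + 1L, n + 1L]
}

identityOracle <- function(a, b) {
  1 - levenshteinOracle(a, b) / max(nchar(a), nchar(b))
}

# Exhaustive triple-enumeration chimera oracle over ordered (A, B, C).
chimeraOracle <- function(rec, fold = 2) {
  n <- nrow(rec)
  flag <- logical(n)
  for (ci in seq_len(n)) for (ai in seq_len(n)) for (bi in seq_len(n)) {
    if (ai == ci || bi == ci) next
    if (rec$fwd[ai] == rec$fwd[ci] && rec$rev[bi] == rec$rev[ci] &&
        rec$count[ai] >= fold * rec$count[ci] &&
        rec$count[bi] >= fold * rec$count[ci])
      flag[ci] <- TRUE
  }
  flag
}

hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Build a SampleOTUTable directly from record vectors (threshold kept tiny
# so arbitrary counts validate).
makeTable <- function(fwd, rev, count, sample_id = "T",
                      total_reads = sum(count)) {
  rec <- data.frame(otu_id = sprintf("%s_OTU%04d", sample_id,
                                     seq_along(fwd)),
                    fwd = fwd, rev = rev, count = as.integer(count),
                    rescued = 0L, chimera = FALSE, row.names = NULL)
  new("SampleOTUTable", sample_id = sample_id,
      total_reads = as.integer(total_reads), threshold = 1e-9, records = rec)
}

# Random OTU table with deliberate fwd/rev collisions (pools of few
# sequences) so the chimera rule has material to fire on.
randomCollisionTable <- function(max_otus = 12L) {
  fwd_pool <- c("AAAA", "CCCC", "GGGG", "TTTT")
  rev_pool <- c("ACAC", "GTGT", "AGAG", "CTCT")
  combos <- expand.grid(fwd = fwd_pool, rev = rev_pool,
                        stringsAsFactors = FALSE)
  n <- sample.int(max_otus, 1L)
  pick <- combos[sample.int(nrow(combos), n), , drop = FALSE]
  makeTable(pick$fwd, pick$rev, sample(1:200, n, replace = TRUE))
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

flipBase <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

# k substitutions at distinct random positions
mutateRandom <- function(seq, k) {
  if (k == 0L) return(seq)
  pos <- sample.int(nchar(seq), k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- flipBase(ch[p])
  paste(ch, collapse = "")
}

# Toy dual-barcode map over the V4 primer pair.
toyMap <- function(n = 2L) {
  pr <- standardPrimers()$V4
  barcodes_f <- c("ACGTACGT", "TGCATGCA", "GGAACCTT", "CATGCATG")[seq_len(n)]
  barcodes_r <- c("GGTTCCAA", "AACCGGTT", "TTGGAACC", "GTACGTAC")[seq_len(n)]
  SampleMap(sprintf("S%d", seq_len(n)), barcodes_f, barcodes_r,
            pr[["fwd"]], pr[["rev"]])
}

# Assemble one mate: barcode + linker + concrete primer + payload.
buildRead <- function(barcode, primer, payload, linker = "CA") {
  paste0(barcode, linker, expandPrimer(primer), payload)
}
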