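# Demultiplexing: mapping-file validation, IUPAC primer matching,
# dual-barcode assignment, rejection semantics, technical stripping.

test_that("IUPAC codes match exactly their base sets", {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  for (code in names(sets)) {
    got <- iupacMatchAt(code, bases, at = 1L)
    expect_identical(got, bases %in% sets[[code]],
                     info = paste("code", code))
  }
  # degenerate expansion always matches the primer it came from
  pr <- standardPrimers()
  for (p in unlist(pr)) {
    expect_true(iupacMatchAt(p, expandPrimer(p), 1L))
    set.seed(7)
    expect_true(all(iupacMatchAt(p, replicate(5, expandPrimer(p, random = TRUE)), 1L)))
  }
  expect_error(iupacMatchAt("AXG", "AAG", 1L), "invalid IUPAC")
})

test_that("mapping files parse and invalid maps are rejected", {
  pr <- standardPrimers()$V4
  lines <- c("# a comment",
             "#SampleID\tFwdBarcode\tRevBarcode\tFwdPrimer\tRevPrimer",
             paste("S1", "ACGTACGT", "GGTTCCAA", pr[["fwd"]], pr[["rev"]], sep = "\t"),
             paste("S2", "TGCATGCA", "AACCGGTT", pr[["fwd"]], pr[["rev"]], sep = "\t"),
             paste("S3", "GGAACCTT", "TTGGAACC", pr[["fwd"]], pr[["rev"]], sep = "\t"))
  f <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  map <- readSampleMap(f)
  expect_s4_class(map, "SampleMap")
  expect_identical(sampleIds(map), c("S1", "S2", "S3"))
  expect_identical(barcodeLength(map), 8L)

  # duplicate (fwd, rev) barcode combination
  dup <- c(lines, paste("S4", "ACGTACGT", "GGTTCCAA", pr[["fwd"]], pr[["rev"]],
                        sep = "\t"))
  f2 <- withr::local_tempfile(lines = dup, fileext = ".tsv")
  expect_error(readSampleMap(f2), "duplicate")

  # a 7-nt barcode among 8-nt ones breaks length uniformity
  short <- c(lines, paste("S4", "ACGTACG", "CCAATTGG", pr[["fwd"]], pr[["rev"]],
                          sep = "\t"))
  f3 <- withr::local_tempfile(lines = short, fileext = ".tsv")
  expect_error(readSampleMap(f3), "equal length")

  # malformed row is reported with its line number
  bad <- c(lines, "S4\tACGTACGT")
  f4 <- withr::local_tempfile(lines = bad, fileext = ".tsv")
  expect_error(readSampleMap(f4), "line 6")
})

test_that("prefix matching demands exact barcode and IUPAC-exact primer", {
  pr <- standardPrimers()$V4
  payload <- strrep("ACGT", 20)
  read <- buildRead("ACGTACGT", pr[["fwd"]], payload)
  expect_true(matchesPrefix(read, "ACGTACGT", 2L, pr[["fwd"]]))

  # any single substitution in the barcode rejects
  mutated <- read
  substr(mutated, 3, 3) <- if (substr(read, 3, 3) == "A") "C" else "A"
  expect_false(matchesPrefix(mutated, "ACGTACGT", 2L, pr[["fwd"]]))

  # positional IUPAC semantics: 515F position 9 is M = A/C
  stopifnot(substr(pr[["fwd"]], 9, 9) == "M")
  base_at <- function(b) {
    r <- read
    substr(r, 8 + 2 + 9, 8 + 2 + 9) <- b
    r
  }
  expect_true(matchesPrefix(base_at("A"), "ACGTACGT", 2L, pr[["fwd"]]))
  expect_true(matchesPrefix(base_at("C"), "ACGTACGT", 2L, pr[["fwd"]]))
  expect_false(matchesPrefix(base_at("G"), "ACGTACGT", 2L, pr[["fwd"]]))
  expect_false(matchesPrefix(base_at("T"), "ACGTACGT", 2L, pr[["fwd"]]))

  # linker bases are skipped, never checked
  relinked <- read
  substr(relinked, 9, 10) <- "TT"
  expect_true(matchesPrefix(relinked, "ACGTACGT", 2L, pr[["fwd"]]))

  # too-short read yields FALSE, not an error
  expect_false(matchesPrefix("ACGTACGT", "ACGTACGT", 2L, pr[["fwd"]]))
})

test_that("pairs route to their sample; hybrid barcode pairs are flagged", {
  map <- toyMap(2L)
  pr <- standardPrimers()$V4
  pay <- strrep("A", 70)
  mk <- function(fb, rb) data.frame(
    read_id = "r", fwd = buildRead(fb, pr[["fwd"]], pay),
    rev = buildRead(rb, pr[["rev"]], pay),
    fwd_qual = NA, rev_qual = NA)

  clean <- mk("ACGTACGT", "GGTTCCAA")       # sample S1
  cross <- mk("ACGTACGT", "AACCGGTT")       # S1 fwd x S2 rev
  junk  <- mk("ACGTACGT", "CCCCCCCC")       # rev barcode matches nothing
  pairs <- rbind(clean, cross, junk)
  pairs$read_id <- c("r1", "r2", "r3")
  dmx <- demultiplex(pairs, map)
  expect_identical(dmx$samples$S1$read_id, "r1")
  expect_identical(nrow(dmx$samples$S2), 0L)
  expect_identical(dmx$rejected$reason[dmx$rejected$read_id == "r2"],
                   "cross-sample chimera")
  expect_identical(dmx$rejected$reason[dmx$rejected$read_id == "r3"],
                   "barcode/primer mismatch")
  expect_identical(sum(dmx$report$count), nrow(pairs))
})

test_that("demultiplexing partitions input, ignores qualities and order", {
  map <- toyMap(2L)
  refs <- synthReferences(5, 5, seed = 11)
  d <- mockDesign("toy", refs$accession, rep(0.2, 5), n_reads = 400L,
                  error_rate = 0.01, technical_error_rate = 0.15, seed = 3L)
  sim <- simulateReads(d, refs, map[1, , drop = FALSE])
  dmx <- demultiplex(sim$pairs, map)

  n_assigned <- sum(vapply(dmx$samples, nrow, integer(1)))
  expect_identical(n_assigned + nrow(dmx$rejected), nrow(sim$pairs))

  # zero tolerance: every pair with a technical substitution is rejected,
  # every pair without one is assigned (payload errors never matter)
  bad_ids <- sim$truth$read_id[sim$truth$tech_error]
  expect_true(all(bad_ids %in% dmx$rejected$read_id))
  expect_setequal(dmx$samples$S1$read_id,
                  setdiff(sim$pairs$read_id, bad_ids))
  expect_gt(length(bad_ids), 0L)

  # flipping qualities changes nothing
  flipped <- sim$pairs
  flipped$fwd_qual <- strrep("#", nchar(flipped$fwd))
  flipped$rev_qual <- strrep("#", nchar(flipped$rev))
  dmx2 <- demultiplex(flipped, map)
  expect_identical(dmx2$samples$S1$read_id, dmx$samples$S1$read_id)
  expect_identical(dmx2$report$count, dmx$report$count)

  # permuting input order permutes per-sample reads only
  set.seed(1)
  perm <- sample.int(nrow(sim$pairs))
  dmx3 <- demultiplex(sim$pairs[perm, ], map)
  expect_setequal(dmx3$samples$S1$read_id, dmx$samples$S1$read_id)
  expect_identical(sort(dmx3$rejected$read_id), sort(dmx$rejected$read_id))
})

test_that("technical stripping recovers the simulated payload exactly", {
  map <- toyMap(1L)
  refs <- synthReferences(4, 4, seed = 5)
  d <- mockDesign("toy", refs$accession, rep(0.25, 4), n_reads = 200L,
                  seed = 9L)
  sim <- simulateReads(d, refs, map[1, , drop = FALSE], read_len = 70L)
  dmx <- demultiplex(sim$pairs, map)
  st <- stripTechnical(dmx$samples$S1, map[1, , drop = FALSE], read_len = 70L)
  expect_identical(st$n_short, 0L)
  i <- match(st$trimmed$read_id, sim$truth$read_id)
  tm <- match(sim$truth$template[i], sim$templates$template_id)
  expect_identical(st$trimmed$fwd, sim$templates$fwd_frag[tm])
  expect_identical(st$trimmed$rev, sim$templates$rev_frag[tm])
})

test_that("pairs left shorter than read_len are discarded and counted", {
  map <- toyMap(1L)
  pr <- standardPrimers()$V4
  entry <- map[1, , drop = FALSE]
  long <- buildRead("ACGTACGT", pr[["fwd"]], strrep("G", 72))
  shrt <- buildRead("ACGTACGT", pr[["fwd"]], strrep("G", 60))
  rev_ok <- buildRead("GGTTCCAA", pr[["rev"]], strrep("C", 72))
  pairs <- data.frame(read_id = c("a", "b"), fwd = c(long, shrt),
                      rev = c(rev_ok, rev_ok))
  st <- stripTechnical(pairs, entry, read_len = 70L)
  expect_identical(st$trimmed$read_id, "a")
  expect_identical(nchar(st$trimmed$fwd), 70L)
  expect_identical(st$n_short, 1L)
})

test_that("FASTQ pairs round-trip through files and desync is fatal", {
  map <- toyMap(1L)
  refs <- synthReferences(3, 3, seed = 2)
  d <- mockDesign("toy", refs$accession, rep(1 / 3, 3), n_reads = 50L,
                  seed = 4L)
  sim <- simulateReads(d, refs, map[1, , drop = FALSE])
  dir <- withr::local_tempdir()
  paths <- writeSimulation(sim, dir, refs = refs)
  back <- readFastqPairs(paths[["r1"]], paths[["r2"]])
  expect_identical(back$fwd, sim$pairs$fwd)
  expect_identical(back$rev, sim$pairs$rev)
  expect_identical(back$read_id, sim$pairs$read_id)

  # truncate R2 -> desynchronized streams
  r2 <- readLines(paths[["r2"]])
  writeLines(r2[1:(length(r2) - 4)], file.path(dir, "trunc_R2.fastq"))
  expect_error(readFastqPairs(paths[["r1"]], file.path(dir, "trunc_R2.fastq")),
               "desynchronized")
})
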