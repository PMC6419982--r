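# Reference trimming, identity, threshold search, specificity, consensus.

v4 <- standardPrimers()$V4

test_that("references trim to the region between the primer sites", {
  set.seed(8)
  insert <- randomSeq(253)
  seq <- paste0(randomSeq(40), expandPrimer(v4[["fwd"]]), insert,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(expandPrimer(v4[["rev"]])))),
                randomSeq(40))
  refs <- data.frame(accession = "R1", seq = seq,
                     domain = "Bacteria", phylum = "P", class = "C",
                     order = "O", family = "F", genus = "G")
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  fr <- refFragments(db)
  expect_identical(fr$fwd_frag, substr(insert, 1, 70))
  expect_identical(fr$rev_frag,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(insert, 184, 253)))))

  # no reverse-primer site -> rejected and counted
  refs2 <- refs
  refs2$seq <- paste0(randomSeq(40), expandPrimer(v4[["fwd"]]), insert)
  db2 <- trimReferences(refs2, v4[["fwd"]], v4[["rev"]])
  expect_identical(length(db2), 0L)
  expect_identical(rejectedRefs(db2)$reason, "no reverse-primer site")

  # inter-primer region shorter than read_len -> rejected
  refs3 <- refs
  refs3$seq <- sub(insert, substr(insert, 1, 50), refs3$seq, fixed = TRUE)
  db3 <- trimReferences(refs3, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  expect_identical(rejectedRefs(db3)$reason,
                   "inter-primer region shorter than read_len")

  # one mismatch inside the primer site is tolerated by default
  refs4 <- refs
  pos <- 41L  # first base of the forward primer site
  substr(refs4$seq, pos, pos) <-
    if (substr(refs4$seq, pos, pos) == "A") "C" else "A"
  db4 <- trimReferences(refs4, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  expect_identical(length(db4), 1L)
  expect_identical(refFragments(db4)$fwd_frag, substr(insert, 1, 70))
})

test_that("trimmed fragments equal the simulator's template truth", {
  map <- toyMap(1L)
  refs <- synthReferences(10, 5, seed = 3)
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  expect_identical(length(db), 10L)
  fr <- refFragments(db)
  expect_identical(fr$fwd_frag, substr(refs$insert, 1, 70))
  d <- mockDesign("t", refs$accession, rep(0.1, 10), n_reads = 10L, seed = 1L)
  sim <- simulateReads(d, refs, map[1, , drop = FALSE], read_len = 70L)
  i <- match(sim$templates$template_id, fr$accession)
  expect_identical(sim$templates$fwd_frag, fr$fwd_frag[i])
  expect_identical(sim$templates$rev_frag, fr$rev_frag[i])
})

test_that("identity is exact on substitutions and matches the DP oracle", {
  a70 <- strrep("ACGTCGA", 10)
  expect_equal(sequenceIdentity(a70, a70), 1)
  b70 <- a70; substr(b70, 33, 33) <- "T"
  expect_equal(sequenceIdentity(a70, b70), 69 / 70)

  set.seed(123)
  for (i in 1:40) {
    a <- randomSeq(sample(5:30, 1))
    b <- if (runif(1) < 0.5) randomSeq(sample(5:30, 1)) else
      mutateRandom(a, sample(0:3, 1))
    expect_equal(sequenceIdentity(a, b), identityOracle(a, b),
                 info = paste(a, b))
    expect_equal(sequenceIdentity(a, b), sequenceIdentity(b, a))
  }
})

test_that("hit lists nest across thresholds and match brute force", {
  refs <- synthReferences(20, 10, seed = 77)
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  fr <- refFragments(db)
  levels <- c(1, 0.98, 0.97, 0.95, 0.92, 0.90)

  # a db entry's own fragments hit it at 1.00
  pr <- searchHits(fr$fwd_frag[1], fr$rev_frag[1], db, otu_id = "self")
  expect_true(fr$accession[1] %in% hitsAtLevel(pr, 1)$accession)

  # two substitutions across 140 nt: hit at 0.98, no longer at 1.00
  fwd2 <- fr$fwd_frag[1]; substr(fwd2, 5, 5) <- flipBase(substr(fwd2, 5, 5))
  rev2 <- fr$rev_frag[1]; substr(rev2, 9, 9) <- flipBase(substr(rev2, 9, 9))
  pr2 <- searchHits(fwd2, rev2, db)
  expect_false(fr$accession[1] %in% hitsAtLevel(pr2, 1)$accession)
  expect_true(fr$accession[1] %in% hitsAtLevel(pr2, 0.98)$accession)

  # nesting + equality with an exhaustive all-pairs identity scan
  set.seed(5)
  for (k in sample(nrow(fr), 4)) {
    prk <- searchHits(fr$fwd_frag[k], fr$rev_frag[k], db)
    prev <- character(0)
    for (t in levels) {
      at <- hitsAtLevel(prk, t)$accession
      expect_true(all(prev %in% at))
      brute <- fr$accession[
        (sequenceIdentity(fr$fwd_frag[k], fr$fwd_frag) +
         sequenceIdentity(fr$rev_frag[k], fr$rev_frag)) / 2 >= t - 1e-9]
      expect_setequal(at, brute)
      prev <- at
    }
  }
})

test_that("specificity is the share of hits carrying the modal label", {
  hits <- data.frame(genus = rep("G", 10))
  expect_equal(labelSpecificity(hits, "genus"),
               list(label = "G", pct = 100, n = 10L))
  hits2 <- data.frame(genus = c(rep("G", 8), rep("H", 2)))
  expect_equal(labelSpecificity(hits2, "genus"),
               list(label = "G", pct = 80, n = 10L))
  # empty labels excluded from numerator and denominator
  hits3 <- data.frame(genus = c(rep("G", 4), "", ""))
  s <- labelSpecificity(hits3, "genus")
  expect_equal(s$pct, 100); expect_identical(s$n, 4L)
  expect_equal(labelSpecificity(data.frame(genus = character(0)), "genus"),
               list(label = "", pct = 0, n = 0L))

  # counting oracle on multinomial draws
  set.seed(4)
  for (i in 1:10) {
    lab <- sample(c("A", "B", "C"), 30, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
    s <- labelSpecificity(data.frame(genus = lab), "genus")
    tab <- sort(table(lab), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    expect_identical(s$label, sort(top)[1])
    expect_equal(s$pct, 100 * max(tab) / length(lab))
  }
})

test_that("consensus accepts the deepest concordant specific rank", {
  levels <- c(1, 0.98, 0.97, 0.95, 0.92, 0.90)
  mkProfile <- function(identity, genus, family = "Fam1") {
    hits <- data.frame(accession = sprintf("a%02d", seq_along(identity)),
                       identity = identity, domain = "Bacteria",
                       phylum = "P", class = "C", order = "O",
                       family = family, genus = genus)
    new("HitProfile", otu_id = "q", hits = hits, levels = levels)
  }

  # all hits share a genus at every level -> genus, specificity 100
  a <- consensusLabel(mkProfile(c(1, 1, 0.95, 0.91), rep("G", 4)))
  expect_identical(a$assigned_rank, "genus")
  expect_identical(a$genus, "G")
  expect_equal(a$specificity, 100)
  expect_equal(a$top_level, 1)

  # top-level genus G but modal genus H at 0.90 -> genus fails,
  # family is concordant -> family
  b <- consensusLabel(mkProfile(c(1, 0.90, 0.90, 0.90),
                                c("G", "H", "H", "H")))
  expect_identical(b$assigned_rank, "family")
  expect_identical(b$family, "Fam1")
  expect_identical(b$genus, "")

  # three families split the hits at every level: neither genus nor
  # family reaches 50% specificity -> shared prefix stops at order
  cc <- consensusLabel(mkProfile(c(1, 1, 1, 0.95, 0.95, 0.95),
                                 c("G", "H", "I", "G", "H", "I"),
                                 family = rep(c("F1", "F2", "F3"), 2)))
  expect_identical(cc$assigned_rank, "order")
  expect_identical(cc$order, "O")
  expect_identical(cc$family, "")

  # sub-threshold specificity at genus falls through to family
  d <- consensusLabel(mkProfile(c(1, 1, 1), c("G", "H", "I")),
                      min_spec = 50)
  expect_identical(d$assigned_rank, "family")

  # empty profile -> unassigned
  e <- consensusLabel(new("HitProfile", otu_id = "q",
                          hits = data.frame(), levels = levels))
  expect_identical(e$assigned_rank, "unassigned")
  expect_identical(e$supporting_hits, 0L)
})

test_that("every reference self-classifies to its own genus at 100%", {
  refs <- synthReferences(12, 12, seed = 19)
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  fr <- refFragments(db)
  for (k in seq_len(nrow(fr))) {
    a <- consensusLabel(searchHits(fr$fwd_frag[k], fr$rev_frag[k], db,
                                   otu_id = fr$accession[k]))
    expect_identical(a$genus, fr$genus[k])
    expect_equal(a$specificity, 100)
  }
  # and assignments do not depend on db order
  perm <- db
  set.seed(2)
  perm@frags <- fr[sample(nrow(fr)), , drop = FALSE]
  a1 <- consensusLabel(searchHits(fr$fwd_frag[3], fr$rev_frag[3], db))
  a2 <- consensusLabel(searchHits(fr$fwd_frag[3], fr$rev_frag[3], perm))
  expect_identical(a1[, c("genus", "assigned_rank", "specificity")],
                   a2[, c("genus", "assigned_rank", "specificity")])
})

test_that("up to two substitutions never change the family call", {
  refs <- synthReferences(6, 6, seed = 55)  # one genus per family pair
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  fr <- refFragments(db)
  set.seed(6)
  for (k in seq_len(nrow(fr))) {
    base <- consensusLabel(searchHits(fr$fwd_frag[k], fr$rev_frag[k], db))
    for (rep in 1:3) {
      fwd <- mutateRandom(fr$fwd_frag[k], sample(0:2, 1))
      rev <- mutateRandom(fr$rev_frag[k],
                          sample(0:(2 - hammingDist(fwd, fr$fwd_frag[k])), 1))
      a <- consensusLabel(searchHits(fwd, rev, db))
      expect_identical(a$family, base$family)
    }
  }
})

test_that("chimera-flagged OTUs are reported, not classified", {
  refs <- synthReferences(4, 4, seed = 9)
  db <- trimReferences(refs, v4[["fwd"]], v4[["rev"]], read_len = 70L)
  fr <- refFragments(db)
  tab <- makeTable(fwd = fr$fwd_frag[c(1, 2, 1)],
                   rev = fr$rev_frag[c(1, 2, 2)],
                   count = c(100L, 90L, 10L))
  tab <- flagChimeras(tab)
  asg <- classifyOTUs(tab, db)
  expect_identical(nrow(asg), 3L)
  expect_identical(asg$assigned_rank[3], "chimera")
  expect_identical(asg$genus[1:2], fr$genus[1:2])
})
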