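# Synthetic mock communities with full ground truth.
#
# The generator builds reference templates that carry real primer sites,
# assembles barcoded paired reads from them (multinomial template draws,
# i.i.d. substitution errors on payload bases, optional chimeric pairs
# recombining at the fwd/rev boundary, optional corruption of checked
# technical bases), and records everything, so every pipeline stage can be
# tested against known truth without downloading a reference database.

#' Generate synthetic full-length-like reference templates
#'
#' Each template is `pad5 + <concrete forward primer> + insert +
#' revcomp(<concrete reverse primer>) + pad3`, with a random insert of
#' `insert_len` bases (default 253, V4-like). Templates are grouped into
#' genera: within a genus, members differ from the genus backbone by 1-3
#' substitutions placed inside the first / last `frag_len` bases of the
#' insert (so within-genus insert identity stays >= 97% and trimmed
#' fragment pairs remain distinct); between genera, inserts are independent
#' random sequences (identity far below 90%). Lineages are assigned from
#' the genus grouping (genera nested two-per-family, and so on upward).
#'
#' @param n number of templates (>= n_genera).
#' @param n_genera number of genera.
#' @param seed RNG seed.
#' @param fwd_primer,rev_primer IUPAC primers (default V4 pair).
#' @param insert_len inter-primer region length (default 253).
#' @param frag_len fragment length used to place distinguishing
#'   substitutions (default 70; match the pipeline's read_len).
#' @param pad5,pad3 flanking pad lengths (default 120 each).
#' @return data.frame: `accession`, `seq`, `insert`, and the six lineage
#'   columns; directly usable by [trimReferences()] and [simulateReads()].
#' @export
synthReferences <- function(n, n_genera, seed = 42L,
                            fwd_primer = standardPrimers()$V4[["fwd"]],
                            rev_primer = standardPrimers()$V4[["rev"]],
                            insert_len = 253L, frag_len = 70L,
                            pad5 = 120L, pad3 = 120L) {
  stopifnot(n >= n_genera, n_genera >= 1L)
  if (insert_len < 2L * frag_len)
    stop("insert_len must be at least 2 * frag_len so that the 5' and 3' ",
         "fragments do not overlap")
  genus_of <- sort(rep_len(seq_len(n_genera), n))
  max_members <- max(tabulate(genus_of))
  if (max_members > 2L * frag_len)
    stop("too many members per genus for distinct fragment pairs")
  withSeed(seed, {
    backbones <- randomDNA(n_genera, insert_len)
    inserts <- character(n)
    for (g in seq_len(n_genera)) {
      idx <- which(genus_of == g)
      frag_region <- c(seq_len(frag_len),
                       seq(insert_len - frag_len + 1L, insert_len))
      for (tries in 1:50) {
        ins <- backbones[g]
        ins <- c(ins, vapply(seq_along(idx)[-1], function(j) {
          k <- sample(1:3, 1L)
          mutateBases(backbones[g], sample(frag_region, k))
        }, character(1)))
        key <- paste(substr(ins, 1L, frag_len),
                     substr(ins, insert_len - frag_len + 1L, insert_len))
        if (!anyDuplicated(key)) break
        if (tries == 50L) stop("could not generate distinct members for genus ", g)
      }
      inserts[idx] <- ins
    }
    seqs <- vapply(seq_len(n), function(i) {
      paste0(paste(randomDNA(1L, pad5), collapse = ""),
             expandPrimer(fwd_primer, random = TRUE),
             inserts[i],
             revComp(expandPrimer(rev_primer, random = TRUE)),
             paste(randomDNA(1L, pad3), collapse = ""))
    }, character(1))
    fam <- ceiling(genus_of / 2); ord <- ceiling(genus_of / 4)
    cls <- ceiling(genus_of / 8); phy <- ceiling(genus_of / 16)
    data.frame(accession = sprintf("SYNREF_%03d", seq_len(n)),
               seq = seqs, insert = inserts,
               domain = "Bacteria",
               phylum = sprintf("Phylum_%02d", phy),
               class = sprintf("Class_%02d", cls),
               order = sprintf("Order_%02d", ord),
               family = sprintf("Family_%02d", fam),
               genus = sprintf("Genus_%02d", genus_of),
               row.names = NULL)
  })
}

#' Construct a mock-community design
#'
#' @param name design name.
#' @param template_ids member template accessions.
#' @param abundances member relative abundances (normalised to sum to 1).
#' @param n_reads number of read pairs to simulate.
#' @param error_rate per-base substitution probability on payload bases.
#' @param chimera_rate fraction of pairs recombining two templates.
#' @param technical_error_rate per-pair probability of one substitution at
#'   a checked technical base (barcode or primer; the skipped linker is
#'   never corrupted).
#' @param seed RNG seed for the simulation.
#' @return a [MockDesign-class].
#' @export
mockDesign <- function(name, template_ids, abundances, n_reads = 10000L,
                       error_rate = 0, chimera_rate = 0,
                       technical_error_rate = 0, seed = 1L) {
  ab <- abundances / sum(abundances)
  new("MockDesign", name = name,
      members = data.frame(template_id = template_ids, abundance = ab,
                           row.names = NULL),
      n_reads = as.integer(n_reads), error_rate = error_rate,
      chimera_rate = chimera_rate,
      technical_error_rate = technical_error_rate, seed = as.integer(seed))
}

#' Standard mock-community designs
#'
#' Four designs over a panel of 55 templates, mirroring the classic
#' validation setup:
#' \describe{
#'   \item{mc1}{17 members, equimolar; 10,000 read pairs.}
#'   \item{mc2}{55 members, equimolar; 50,000 read pairs.}
#'   \item{mc3}{55 members, staggered: geometric ladder spanning three
#'     orders of magnitude; 50,000 read pairs.}
#'   \item{mc4}{50 members with abundances between 0.001% and 2.49%,
#'     including sentinel members at exactly 0.1%, 0.01% and 0.001%
#'     (fractions 1e-3, 1e-4, 1e-5); 50,000 read pairs.}
#' }
#'
#' @param template_ids accessions of the 55-template panel (default the
#'   [synthReferences()] naming, `SYNREF_001` ... `SYNREF_055`).
#' @param seed seed stored in each design.
#' @return named list of [MockDesign-class] objects.
#' @export
presetDesigns <- function(template_ids = sprintf("SYNREF_%03d", 1:55),
                          seed = 1L) {
  stopifnot(length(template_ids) >= 55L)
  template_ids <- template_ids[1:55]
  mc1 <- mockDesign("mc1", template_ids[1:17], rep(1 / 17, 17),
                    n_reads = 10000L, seed = seed)
  mc2 <- mockDesign("mc2", template_ids, rep(1 / 55, 55),
                    n_reads = 50000L, seed = seed)
  mc3 <- mockDesign("mc3", template_ids, 10^seq(0, -3, length.out = 55),
                    n_reads = 50000L, seed = seed)
  # mc4: 3 sentinels at 1e-5, 1e-4, 1e-3 plus 47 members geometrically
  # spaced with the top fixed at 2.49%; lower end solved so the design
  # sums to exactly 1.
  sentinels <- c(1e-5, 1e-4, 1e-3)
  rest_mass <- 1 - sum(sentinels)
  ladder <- function(a) exp(seq(log(a), log(0.0249), length.out = 47))
  a <- stats::uniroot(function(a) sum(ladder(a)) - rest_mass,
                      lower = 1e-6, upper = 0.0249, tol = 1e-14)$root
  ab4 <- c(sort(ladder(a), decreasing = TRUE), rev(sentinels))
  mc4 <- mockDesign("mc4", template_ids[1:50], ab4,
                    n_reads = 50000L, seed = seed)
  list(mc1 = mc1, mc2 = mc2, mc3 = mc3, mc4 = mc4)
}

# Technical prefix layout for one map entry and one mate.
techPrefix <- function(barcode, linker_len, primer_concrete) {
  linker <- substr(strrep("CA", linker_len), 1L, linker_len)
  paste0(barcode, linker, primer_concrete)
}

#' Simulate barcoded paired-end reads from a mock design
#'
#' Draws `n_reads` template assignments from the design's multinomial,
#' optionally recombines a fraction of pairs from two templates (5' side
#' from one, 3' side from the other — the recombination point is the
#' fwd/rev boundary, maximally detectable by the chimera rule; set
#' `intra_read_breakpoints = TRUE` to place the breakpoint inside the
#' forward payload instead, producing chimeras the rule cannot see),
#' applies i.i.d. substitutions at `error_rate` to payload bases, prepends
#' barcode + linker + concrete primer to each mate, and emits constant
#' `"I"` qualities (qualities are never consulted downstream). With
#' probability `technical_error_rate` a pair receives one substitution at a
#' random *checked* technical base (barcode, or a primer base mutated
#' outside its IUPAC set), guaranteeing demultiplexing rejection; the
#' skipped linker is never corrupted. Payload fragments are taken from
#' [trimReferences()] run on `refs`, so the simulator's truth fragments are
#' by construction identical to the pipeline's trimmed references. A fixed
#' seed gives byte-identical output.
#'
#' @param design a [MockDesign-class].
#' @param refs reference data.frame ([synthReferences()] or
#'   [readReferenceSet()]).
#' @param map_entry one-row [SampleMap-class] subset naming the barcodes
#'   and primers to prepend.
#' @param read_len payload length per mate (default 70).
#' @param intra_read_breakpoints place chimera breakpoints inside the
#'   forward payload (default FALSE: breakpoint at the fwd/rev boundary).
#' @return list with
#'   \describe{
#'     \item{pairs}{read-pair table (`read_id`, `fwd`, `rev`, `fwd_qual`,
#'       `rev_qual`);}
#'     \item{truth}{per-read data.frame: source template(s), chimera flag
#'       and breakpoint, payload error counts/positions, technical-error
#'       flag;}
#'     \item{templates}{per-member truth: trimmed fragment pair + lineage;}
#'     \item{design, map_entry, read_len, seed}{echoes.}
#'   }
#' @export
simulateReads <- function(design, refs, map_entry, read_len = 70L,
                          intra_read_breakpoints = FALSE) {
  validObject(design)
  stopifnot(nrow(map_entry) == 1L)
  trimmed <- trimReferences(refs, map_entry$fwd_primer, map_entry$rev_primer,
                            read_len = read_len, max_primer_mismatch = 1L)
  fr <- trimmed@frags
  mem <- design@members
  miss <- setdiff(mem$template_id, fr$accession)
  if (length(miss))
    stop("design member(s) without a usable reference amplicon: ",
         paste(miss, collapse = ", "))
  mi <- match(mem$template_id, fr$accession)
  tmpl <- data.frame(template_id = mem$template_id,
                     abundance = mem$abundance,
                     fwd_frag = fr$fwd_frag[mi], rev_frag = fr$rev_frag[mi],
                     fr[mi, LINEAGE_RANKS, drop = FALSE], row.names = NULL)
  n <- design@n_reads

  fwd_tech <- techPrefix(map_entry$fwd_barcode, map_entry$linker_len,
                         expandPrimer(map_entry$fwd_primer))
  rev_tech <- techPrefix(map_entry$rev_barcode, map_entry$linker_len,
                         expandPrimer(map_entry$rev_primer))
  # checked technical positions: barcode bases, and primer bases whose
  # IUPAC code is not N (an N position matches any base, so no
  # substitution there can force a rejection)
  checkedPositions <- function(barcode, linker_len, primer) {
    nb <- nchar(barcode)
    codes <- strsplit(toupper(primer), "")[[1]]
    c(seq_len(nb), nb + linker_len + which(codes != "N"))
  }
  chk_f <- checkedPositions(map_entry$fwd_barcode, map_entry$linker_len,
                            map_entry$fwd_primer)
  chk_r <- checkedPositions(map_entry$rev_barcode, map_entry$linker_len,
                            map_entry$rev_primer)

  withSeed(design@seed, {
    t1 <- sample.int(nrow(tmpl), n, replace = TRUE, prob = tmpl$abundance)
    chim <- stats::runif(n) < design@chimera_rate
    t2 <- rep(NA_integer_, n)
    for (i in which(chim)) {
      p <- tmpl$abundance; p[t1[i]] <- 0
      t2[i] <- sample.int(nrow(tmpl), 1L, prob = p)
    }
    bp <- rep(NA_integer_, n)
    fwd_pay <- tmpl$fwd_frag[t1]
    rev_pay <- tmpl$rev_frag[t1]
    if (any(chim)) {
      if (intra_read_breakpoints) {
        for (i in which(chim)) {
          bp[i] <- sample(seq_len(read_len - 1L), 1L)
          fwd_pay[i] <- paste0(substr(tmpl$fwd_frag[t1[i]], 1L, bp[i]),
                               substr(tmpl$fwd_frag[t2[i]], bp[i] + 1L,
                                      read_len))
          rev_pay[i] <- tmpl$rev_frag[t2[i]]
        }
      } else {
        bp[chim] <- read_len  # fwd side from t1, rev side from t2
        rev_pay[chim] <- tmpl$rev_frag[t2[chim]]
      }
    }
    ef <- stats::rbinom(n, read_len, design@error_rate)
    er <- stats::rbinom(n, read_len, design@error_rate)
    pos_f <- pos_r <- character(n)
    for (i in which(ef > 0L)) {
      p <- sort(sample.int(read_len, ef[i]))
      fwd_pay[i] <- mutateBases(fwd_pay[i], p)
      pos_f[i] <- paste(p, collapse = ",")
    }
    for (i in which(er > 0L)) {
      p <- sort(sample.int(read_len, er[i]))
      rev_pay[i] <- mutateBases(rev_pay[i], p)
      pos_r[i] <- paste(p, collapse = ",")
    }
    fwd <- paste0(fwd_tech, fwd_pay)
    rev <- paste0(rev_tech, rev_pay)
    tech <- stats::runif(n) < design@technical_error_rate
    for (i in which(tech)) {
      if (stats::runif(1) < 0.5) {
        p <- chk_f[sample.int(length(chk_f), 1L)]
        allowed <- techAllowed(map_entry$fwd_barcode, map_entry$linker_len,
                               map_entry$fwd_primer, p)
        substr(fwd[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1L)
      } else {
        p <- chk_r[sample.int(length(chk_r), 1L)]
        allowed <- techAllowed(map_entry$rev_barcode, map_entry$linker_len,
                               map_entry$rev_primer, p)
        substr(rev[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1L)
      }
    }
    read_id <- sprintf("%s_%06d", design@name, seq_len(n))
    qual_f <- strrep("I", nchar(fwd))
    qual_r <- strrep("I", nchar(rev))
    list(pairs = data.frame(read_id = read_id, fwd = fwd, rev = rev,
                            fwd_qual = qual_f, rev_qual = qual_r,
                            row.names = NULL),
         truth = data.frame(read_id = read_id,
                            template = tmpl$template_id[t1],
                            template2 = ifelse(chim, tmpl$template_id[t2], NA),
                            chimeric = chim, breakpoint = bp,
                            n_err_fwd = ef, n_err_rev = er,
                            err_pos_fwd = pos_f, err_pos_rev = pos_r,
                            tech_error = tech, row.names = NULL),
         templates = tmpl,
         design = design, map_entry = map_entry,
         read_len = as.integer(read_len), seed = design@seed)
  })
}

# Bases that would still be accepted at checked position p of a mate
# (barcode base, or IUPAC set of the primer code at that offset).
techAllowed <- function(barcode, linker_len, primer, p) {
  nb <- nchar(barcode)
  if (p <= nb) return(substr(barcode, p, p))
  j <- p - nb - linker_len
  IUPAC_TABLE[[substr(toupper(primer), j, j)]]
}

#' Write a simulation to disk
#'
#' Emits the paired FASTQ files, the mapping file, the reference FASTA and
#' lineage TSV (when `refs` is supplied), and the per-read and per-template
#' truth tables. The simulation seed is recorded as a comment in the truth
#' table header.
#'
#' @param sim result of [simulateReads()].
#' @param out_dir output directory (created).
#' @param refs optional reference data.frame to write alongside.
#' @return invisibly, a named character vector of the written paths.
#' @export
writeSimulation <- function(sim, out_dir, refs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(r1 = file.path(out_dir, "reads_R1.fastq"),
             r2 = file.path(out_dir, "reads_R2.fastq"),
             map = file.path(out_dir, "mapping.tsv"),
             truth = file.path(out_dir, "truth_reads.tsv"),
             templates = file.path(out_dir, "truth_templates.tsv"))
  p <- sim$pairs
  writeFastq(p$fwd, p$read_id, p$fwd_qual, paths[["r1"]])
  writeFastq(p$rev, p$read_id, p$rev_qual, paths[["r2"]])
  me <- sim$map_entry
  map_lines <- c(
    "#SampleID\tFwdBarcode\tRevBarcode\tFwdPrimer\tRevPrimer\tLinkerLen\tLibraryID",
    paste(me$sample_id, me$fwd_barcode, me$rev_barcode, me$fwd_primer,
          me$rev_primer, me$linker_len, me$library_id, sep = "\t"))
  writeLines(map_lines, paths[["map"]])
  con <- file(paths[["truth"]], "wt")
  writeLines(sprintf("# seed: %d", sim$seed), con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  utils::write.table(sim$templates, paths[["templates"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(refs)) {
    paths <- c(paths, fasta = file.path(out_dir, "references.fasta"),
               tax = file.path(out_dir, "references_tax.tsv"))
    writeLines(paste0(">", refs$accession, "\n", refs$seq), paths[["fasta"]])
    lin <- apply(refs[, LINEAGE_RANKS], 1L, paste, collapse = ";")
    writeLines(paste(refs$accession, lin, sep = "\t"), paths[["tax"]])
  }
  invisible(paths)
}

#' Expected profile of a mock design
#'
#' Aggregates the design's member abundances to a taxonomic rank using the
#' member lineages — the in-silico "expected" profile the observed one is
#' compared against with [weightedDifference()].
#'
#' @param design a [MockDesign-class].
#' @param refs reference data.frame carrying the member lineages.
#' @param rank taxonomic rank (default `"genus"`).
#' @return a [TaxProfile-class] with `sample_id = "<name>_expected"`.
#' @export
expectedProfile <- function(design, refs, rank = "genus") {
  mem <- design@members
  i <- match(mem$template_id, refs$accession)
  if (anyNA(i))
    stop("design member(s) missing from refs: ",
         paste(mem$template_id[is.na(i)], collapse = ", "))
  lab <- refs[[rank]][i]
  lab[!nzchar(lab)] <- "unassigned"
  taxProfile(stats::setNames(mem$abundance, lab),
             sample_id = paste0(design@name, "_expected"), rank = rank)
}

#' @rdname MockDesign-class
#' @aliases designMembers,MockDesign-method
setMethod("designMembers", "MockDesign", function(x) x@members)

setMethod("show", "MockDesign", function(object) {
  ab <- object@members$abundance
  cat(sprintf(
    "MockDesign '%s': %d member(s), abundances %.3g-%.3g, %d read pairs\n",
    object@name, nrow(object@members), min(ab), max(ab), object@n_reads))
  cat(sprintf("  error_rate %.4g, chimera_rate %.4g, technical_error_rate %.4g, seed %d\n",
              object@error_rate, object@chimera_rate,
              object@technical_error_rate, object@seed))
})
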