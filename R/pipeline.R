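# One-call pipeline: demultiplex -> per-sample OTU picking -> consensus
# taxonomy -> profiles, with per-stage read accounting and a config echo
# so a run can be reproduced exactly from its report.

#' Construct a pipeline configuration
#'
#' @param r1,r2 forward/reverse FASTQ paths.
#' @param map mapping-file path.
#' @param ref_fasta,ref_tax reference FASTA and lineage TSV paths
#'   (`ref_tax` may be `NA` to parse lineages from FASTA headers).
#' @param out_dir output directory.
#' @param read_len retained sub-read length (default 70).
#' @param threshold minimum per-sample relative abundance (default 0.001).
#' @param identity_levels descending identity thresholds (default
#'   1.00, 0.98, 0.97, 0.95, 0.92, 0.90).
#' @param min_spec minimum specificity percentage (default 50).
#' @param chimera_fold parent-abundance multiple (default 2).
#' @param max_primer_mismatch mismatches at reference primer sites
#'   (default 1).
#' @param rank profile rank (default "genus").
#' @param use_rescued include rescued counts in profiles (default TRUE).
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(r1 = NA_character_, r2 = NA_character_,
                           map = NA_character_,
                           ref_fasta = NA_character_,
                           ref_tax = NA_character_,
                           out_dir = NA_character_,
                           read_len = 70L, threshold = 0.001,
                           identity_levels = c(1, 0.98, 0.97, 0.95, 0.92, 0.90),
                           min_spec = 50, chimera_fold = 2,
                           max_primer_mismatch = 1L,
                           rank = "genus", use_rescued = TRUE) {
  new("PipelineConfig",
      read_len = as.integer(read_len), threshold = threshold,
      identity_levels = identity_levels, min_spec = min_spec,
      chimera_fold = chimera_fold,
      max_primer_mismatch = as.integer(max_primer_mismatch),
      rank = rank, use_rescued = use_rescued,
      paths = c(r1 = r1, r2 = r2, map = map, ref_fasta = ref_fasta,
                ref_tax = ref_tax, out_dir = out_dir))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path YAML file.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

configAsList <- function(config) {
  list(read_len = config@read_len, threshold = config@threshold,
       identity_levels = config@identity_levels,
       min_spec = config@min_spec, chimera_fold = config@chimera_fold,
       max_primer_mismatch = config@max_primer_mismatch,
       rank = config@rank, use_rescued = config@use_rescued,
       r1 = unname(config@paths[["r1"]]), r2 = unname(config@paths[["r2"]]),
       map = unname(config@paths[["map"]]),
       ref_fasta = unname(config@paths[["ref_fasta"]]),
       ref_tax = unname(config@paths[["ref_tax"]]),
       out_dir = unname(config@paths[["out_dir"]]))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  read_len %d, threshold %.4g, chimera_fold %.3g, min_spec %.3g%%\n",
              object@read_len, object@threshold, object@chimera_fold,
              object@min_spec))
  cat("  identity levels:", paste(sprintf("%.2f", object@identity_levels),
                                  collapse = " "), "\n")
})

#' Run the full pipeline
#'
#' Executes demultiplexing, per-sample OTU picking (threshold, rescue,
#' chimera flagging), reference trimming, consensus classification and
#' profile aggregation, writing every intermediate artifact under
#' `out_dir` together with a per-stage read-accounting report and a YAML
#' echo of the configuration. Any stage failure writes a `FAILED` marker
#' naming the stage (partial outputs are retained) and aborts with a
#' stage-named error.
#'
#' @param config a [PipelineConfig-class] with all paths set.
#' @param write_fastq write per-sample FASTQ pairs (default TRUE).
#' @return invisibly, a list: `tables` (per-sample
#'   [SampleOTUTable-class]), `assignments`, `profiles`, `distances`,
#'   `refdb`, `report`, `config`.
#' @export
runPipeline <- function(config, write_fastq = TRUE) {
  validObject(config)
  paths <- config@paths
  for (p in c("r1", "r2", "map", "ref_fasta"))
    if (is.na(paths[[p]]) || !file.exists(paths[[p]]))
      stop("input path '", p, "' is missing or does not exist")
  out_dir <- paths[["out_dir"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), failed)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  acct <- list()
  map <- stage("demux", readSampleMap(paths[["map"]]))
  pairs <- stage("demux", readFastqPairs(paths[["r1"]], paths[["r2"]]))
  dmx <- stage("demux", demultiplex(pairs, map))
  acct$input_pairs <- nrow(pairs)
  acct$assigned <- sum(vapply(dmx$samples, nrow, integer(1)))
  acct$rejected_mismatch <-
    sum(dmx$rejected$reason == "barcode/primer mismatch")
  acct$rejected_chimera <-
    sum(dmx$rejected$reason == "cross-sample chimera")
  if (write_fastq)
    stage("demux", writeDemuxFastq(dmx, file.path(out_dir, "demux")))
  else
    utils::write.table(dmx$report, file.path(out_dir, "demux_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  refdb <- stage("classify", {
    tax <- paths[["ref_tax"]]
    refs <- readReferenceSet(paths[["ref_fasta"]],
                             if (is.na(tax)) NULL else tax)
    trimReferences(refs, map$fwd_primer[1], map$rev_primer[1],
                   read_len = config@read_len,
                   max_primer_mismatch = config@max_primer_mismatch)
  })

  otu_dir <- file.path(out_dir, "otu_tables")
  dir.create(otu_dir, showWarnings = FALSE)
  tables <- list(); assignments <- list(); profiles <- list()
  sample_rows <- list()
  for (s in sampleIds(map)) {
    entry <- map[map$sample_id == s, , drop = FALSE]
    st <- stage("otu", stripTechnical(dmx$samples[[s]], entry,
                                      read_len = config@read_len))
    tab <- stage("otu", buildOTUTable(st$trimmed, sample_id = s,
                                      threshold = config@threshold,
                                      chimera_fold = config@chimera_fold))
    stage("otu", writeOTUTable(tab, file.path(otu_dir, paste0(s, ".tsv"))))
    asg <- stage("classify",
                 classifyOTUs(tab, refdb, levels = config@identity_levels,
                              min_spec = config@min_spec))
    prof <- if (length(tab) && any(!otuRecords(tab)$chimera))
      stage("profile", makeProfile(tab, asg, rank = config@rank,
                                   use_rescued = config@use_rescued))
    else NULL
    tables[[s]] <- tab; assignments[[s]] <- asg
    if (!is.null(prof)) profiles[[s]] <- prof
    rec <- otuRecords(tab)
    sample_rows[[s]] <- data.frame(
      sample = s, pairs_assigned = nrow(dmx$samples[[s]]),
      too_short = st$n_short, entered_otu = nrow(st$trimmed),
      otus_accepted = nrow(rec), reads_exact = sum(rec$count),
      reads_rescued = sum(rec$rescued), otus_chimeric = sum(rec$chimera))
  }
  asg_all <- do.call(rbind, unname(assignments))
  utils::write.table(asg_all, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(profiles)) {
    pm <- profileMatrix(unname(profiles))
    utils::write.table(data.frame(taxon = rownames(pm), pm,
                                  check.names = FALSE),
                       file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- weightedDifferenceMatrix(unname(profiles))
    utils::write.table(data.frame(sample = rownames(dm), dm,
                                  check.names = FALSE),
                       file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else dm <- NULL

  per_sample <- do.call(rbind, unname(sample_rows))
  report <- list(accounting = acct, per_sample = per_sample)
  utils::write.table(per_sample, file.path(out_dir, "report_per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  totals <- data.frame(
    category = c("input_pairs", "assigned", "rejected:barcode/primer mismatch",
                 "rejected:cross-sample chimera", "too_short_after_trim"),
    count = c(acct$input_pairs, acct$assigned, acct$rejected_mismatch,
              acct$rejected_chimera, sum(per_sample$too_short)))
  utils::write.table(totals, file.path(out_dir, "report_totals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(configAsList(config), file.path(out_dir, "config.yaml"))

  invisible(list(tables = tables, assignments = asg_all,
                 profiles = profiles, distances = dm, refdb = refdb,
                 report = report, config = config))
}
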