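## End-to-end pipeline: filter -> group -> strand consensus -> duplex merge
## -> variant calls -> common-SNP filter -> summary metrics, plus artifact
## writing and the command-line entry points.

#' Run the duplex pipeline
#'
#' Executes the whole analysis on either a simulated library (config section
#' `sim`, forwarded to [sim_params()]) or external inputs (config section
#' `inputs` with `alignments`, `reference`, `af_table`, optional
#' `af_format`).  Optional sections `filter`, `consensus`, `snp` and
#' `profile` forward to the respective `*_config()` constructors.  A
#' top-level `seed` overrides the simulation seed, making report bytes a
#' pure function of the config.
#'
#' @param config A named list, or the path of a JSON file holding one.
#' @param out_dir Output directory for artifacts (report JSON/TSV, calls
#'   VCF/TSV, removed-common TSV, end-distance profile TSV, filter report
#'   TSV); nothing is written when NULL.
#' @return Object of class `sample_report` (printable list of summary
#'   statistics, with the intermediate objects attached in
#'   `$objects`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  fcfg <- do.call(filter_config, as.list(config$filter))
  ccfg <- do.call(consensus_config, as.list(config$consensus))
  scfg <- do.call(snp_filter_config, as.list(config$snp))
  pcfg <- do.call(profile_config, as.list(config$profile))

  truth <- NULL
  if (!is.null(config$sim)) {
    sim_args <- as.list(config$sim)
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    sp <- do.call(sim_params, sim_args)
    simref <- simulate_reference(sp)
    lib <- simulate_library(simref$reference, simref$snps, sp)
    reference <- simref$reference
    pairs <- lib$pairs
    af_table <- as_af_table(simref$snps)
    truth <- lib$truth
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c("alignments", "reference", "af_table"))
      if (is.null(inp[[f]]))
        stop("config$inputs is missing required field '", f, "'")
    reference <- read_fasta(inp$reference)
    pairs <- load_alignments(inp$alignments)
    af_table <- load_af_table(inp$af_table,
                              format = inp$af_format %||% "auto")
  } else {
    stop("config needs either a 'sim' or an 'inputs' section")
  }

  fl <- filter_pairs(pairs, fcfg, reference)
  groups <- group_templates(fl$pass)
  cset <- build_consensus_all(groups, reference, ccfg,
                              end_trim = fcfg$end_trim)
  duplexes <- merge_duplexes(cset, groups)
  calls <- call_variants(duplexes, reference)
  snp <- filter_common_snps(calls, af_table, scfg)
  report <- build_sample_report(fl, groups, cset, duplexes, snp, reference,
                                pcfg)
  report$objects <- list(pairs = pairs, filtered = fl$pass, groups = groups,
                         consensus = cset, duplexes = duplexes,
                         calls = calls, retained = snp$retained,
                         removed = snp$removed, truth = truth,
                         reference = reference,
                         profile = report$profile_table)
  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap a simulator SNP table as an AF lookup table
as_af_table <- function(snps) {
  dt <- as.data.table(snps)[, .(chrom, pos, ref, alt, af)]
  setkeyv(dt, c("chrom", "pos", "ref", "alt"))
  structure(dt, class = c("af_table", class(dt)))
}

build_sample_report <- function(fl, groups, cset, duplexes, snp, reference,
                                pcfg) {
  dfrac <- duplex_fraction(groups, duplexes)
  total_duplex <- sum(duplexes$templates$duplex_length)
  med_len <- if (nrow(groups$templates))
    stats::median(groups$templates[, end - start]) else NA_real_
  ss <- single_strand_events(cset, duplexes, reference)
  retained <- snp$retained
  ci <- mutation_rate_ci(nrow(retained), total_duplex)
  spec <- spectrum(retained)
  prof <- end_distance_profile(retained, duplexes, pcfg)
  removed_rate <- if (total_duplex > 0)
    nrow(snp$removed) / total_duplex * 1e6 else NA_real_
  structure(list(
    input_pairs = fl$report$input_pairs,
    pass_fraction = fl$report$pass_fraction,
    dropped = fl$report$dropped,
    unique_templates = dfrac$n_templates,
    duplex_templates = dfrac$n_duplex,
    duplex_fraction = dfrac$fraction,
    median_template_length = med_len,
    total_duplex_bases = total_duplex,
    total_duplex_mb = total_duplex / 1e6,
    ss_corrected_events = ss$events,
    strand_called_bases = ss$strand_called_bases,
    ss_corrected_rate_per_mb = ss$rate,
    retained_mutations = ci$k,
    mutation_rate_per_mb = ci$rate,
    mutation_rate_ci95 = c(ci$lower, ci$upper),
    snv_fraction = unname(spec$class_fractions["SNV"]),
    insertion_fraction = unname(spec$class_fractions["insertion"]),
    deletion_fraction = unname(spec$class_fractions["deletion"]),
    removed_common_snps = nrow(snp$removed),
    common_snp_rate_per_mb = removed_rate,
    profile_table = prof,
    filter_report = fl$report),
    class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Duplex pipeline sample report\n")
  cat(sprintf("  read pairs: %d (%.1f%% passed filters)\n",
              x$input_pairs, 100 * x$pass_fraction))
  cat(sprintf("  unique templates: %d; duplex fraction: %.3f\n",
              x$unique_templates, x$duplex_fraction))
  cat(sprintf("  median template length: %.0f bp; duplex sequence: %.4f Mb\n",
              x$median_template_length, x$total_duplex_mb))
  cat(sprintf("  single-strand corrected events: %d (%.0f/Mb of strand consensus)\n",
              x$ss_corrected_events, x$ss_corrected_rate_per_mb))
  cat(sprintf("  mutations retained: %d = %.1f/Mb (95%% CI %.1f-%.1f)\n",
              x$retained_mutations, x$mutation_rate_per_mb,
              x$mutation_rate_ci95[1L], x$mutation_rate_ci95[2L]))
  cat(sprintf("  spectrum: %.2f SNV / %.2f ins / %.2f del; common SNPs removed: %d (%.0f/Mb)\n",
              x$snv_fraction, x$insertion_fraction, x$deletion_fraction,
              x$removed_common_snps, x$common_snp_rate_per_mb))
  invisible(x)
}

report_scalar_table <- function(report) {
  keep <- c("input_pairs", "pass_fraction", "unique_templates",
            "duplex_templates", "duplex_fraction", "median_template_length",
            "total_duplex_bases", "total_duplex_mb", "ss_corrected_events",
            "strand_called_bases", "ss_corrected_rate_per_mb",
            "retained_mutations", "mutation_rate_per_mb", "snv_fraction",
            "insertion_fraction", "deletion_fraction",
            "removed_common_snps", "common_snp_rate_per_mb")
  vals <- unlist(report[keep])
  dt <- data.table(metric = keep, value = vals)
  dt <- rbind(dt, data.table(
    metric = c("mutation_rate_ci95_lower", "mutation_rate_ci95_upper"),
    value = report$mutation_rate_ci95))
  dt
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scal <- report_scalar_table(report)
  fwrite(scal, file.path(out_dir, "report.tsv"), sep = "\t")
  json <- report[c("input_pairs", "pass_fraction", "dropped",
                   "unique_templates", "duplex_templates", "duplex_fraction",
                   "median_template_length", "total_duplex_bases",
                   "total_duplex_mb", "ss_corrected_events",
                   "strand_called_bases", "ss_corrected_rate_per_mb",
                   "retained_mutations", "mutation_rate_per_mb",
                   "mutation_rate_ci95", "snv_fraction", "insertion_fraction",
                   "deletion_fraction", "removed_common_snps",
                   "common_snp_rate_per_mb")]
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null", na = "null"),
             file.path(out_dir, "report.json"))
  write_calls_vcf(report$objects$retained, file.path(out_dir, "calls.vcf"))
  fwrite(report$objects$retained, file.path(out_dir, "calls.tsv"),
         sep = "\t")
  fwrite(report$objects$removed, file.path(out_dir, "removed_common.tsv"),
         sep = "\t")
  fwrite(report$profile_table, file.path(out_dir, "profile.tsv"),
         sep = "\t")
  fwrite(report$objects$duplexes$templates[, .(tkey, duplex_length)],
         file.path(out_dir, "duplexes.tsv"), sep = "\t")
  fwrite(filter_report_table(report$filter_report),
         file.path(out_dir, "filter_report.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Write simulator outputs to disk
#'
#' Reference FASTA, coordinate-sorted SAM, AF table as minimal VCF, and the
#' ground-truth ledgers as TSV.
#'
#' @param simref A [simulate_reference()] result.
#' @param lib A [simulate_library()] result.
#' @param out_dir Output directory.
#' @export
write_sim_artifacts <- function(simref, lib, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(simref$reference, file.path(out_dir, "reference.fa"))
  write_sam(lib$pairs, simref$reference, file.path(out_dir, "reads.sam"))
  write_af_vcf(simref$snps, file.path(out_dir, "af.vcf"))
  tr <- lib$truth
  fwrite(tr$somatic, file.path(out_dir, "truth_somatic.tsv"), sep = "\t")
  fwrite(tr$germline, file.path(out_dir, "truth_germline.tsv"), sep = "\t")
  fwrite(tr$lesions, file.path(out_dir, "truth_lesions.tsv"), sep = "\t")
  fwrite(tr$fragments, file.path(out_dir, "truth_fragments.tsv"), sep = "\t")
  fwrite(tr$decoys, file.path(out_dir, "truth_decoys.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Command-line entry point
#'
#' `duplexffpe simulate|run|report` with `--config <json>`, `--seed <int>`,
#' `--out-dir <dir>`, `--log-level quiet|info`.  `simulate` writes a synthetic library (FASTA + SAM +
#' VCF + truth TSVs); `run` executes the pipeline; `report` reprints a
#' previously written report.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly 0 on success; errors propagate (non-zero exit under
#'   Rscript).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: duplexffpe simulate|run|report [--config F] [--seed N] ",
         "[--out-dir D]")
  cmd <- args[1L]
  opt <- list(config = NULL, seed = NULL, out_dir = NULL, log_level = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (cmd == "simulate") {
    cfg <- if (!is.null(opt$config)) jsonlite::fromJSON(opt$config)
           else list()
    sim_args <- as.list(cfg$sim %||% cfg)
    if (!is.null(opt$seed)) sim_args$seed <- as.integer(opt$seed)
    sp <- do.call(sim_params, sim_args)
    simref <- simulate_reference(sp)
    lib <- simulate_library(simref$reference, simref$snps, sp)
    write_sim_artifacts(simref, lib, opt$out_dir %||% ".")
  } else if (cmd == "run") {
    if (is.null(opt$config)) stop("run needs --config")
    cfg <- jsonlite::fromJSON(opt$config)
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    rep <- run_pipeline(cfg, out_dir = opt$out_dir)
    if (!identical(opt$log_level, "quiet")) print(rep)
  } else if (cmd == "report") {
    d <- opt$out_dir %||% "."
    f <- file.path(d, "report.tsv")
    if (!file.exists(f)) stop("no report.tsv in ", d)
    cat(readLines(f), sep = "\n")
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
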