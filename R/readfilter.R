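## Read-level exclusion and trimming rules applied before consensus building.

#' Read filter configuration
#'
#' Rules are evaluated in a fixed order -- proper pair, mapping confidence,
#' soft clips, excessive mismatches -- and a dropped pair is attributed to
#' the first rule it fails.  "Ambiguously mapped" is operationalized as
#' mapping quality below `min_mapping_confidence`; the excessive-mutation
#' filter drops a pair when either mate carries more than
#' `max(max_mismatch_count, max_mismatch_frac * aligned_length)` mismatches
#' (substitutions plus indel ops) against the reference.
#'
#' @param min_mapping_confidence Minimum mapping quality (default 30).
#' @param forbid_soft_clips Drop pairs with soft-clipped bases (default TRUE).
#' @param require_proper_pair Drop improper pairs (default TRUE).
#' @param end_trim Bases masked from each read end before consensus
#'   (default 5); template coordinates are never altered.
#' @param max_mismatch_count,max_mismatch_frac Absolute and fractional
#'   mismatch caps; the effective threshold is the larger of the two.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_mapping_confidence = 30L,
                          forbid_soft_clips = TRUE,
                          require_proper_pair = TRUE,
                          end_trim = 5L,
                          max_mismatch_count = 7L,
                          max_mismatch_frac = 0.10) {
  stopifnot(end_trim >= 0L, max_mismatch_count >= 0L,
            max_mismatch_frac >= 0, min_mapping_confidence >= 0L)
  structure(list(min_mapping_confidence = as.integer(min_mapping_confidence),
                 forbid_soft_clips = isTRUE(forbid_soft_clips),
                 require_proper_pair = isTRUE(require_proper_pair),
                 end_trim = as.integer(end_trim),
                 max_mismatch_count = as.integer(max_mismatch_count),
                 max_mismatch_frac = max_mismatch_frac),
            class = "filter_config")
}

#' Filter read pairs
#'
#' @param pairs Pair table ([load_alignments()] / [simulate_library()]).
#' @param config A [filter_config()].
#' @param reference `list(name, seq)`, needed for mismatch counting.
#' @return `list(pass, report)`: the surviving pairs (unchanged) and a
#'   `filter_report` with per-rule drop counts.
#' @export
filter_pairs <- function(pairs, config = filter_config(), reference) {
  stopifnot(inherits(config, "filter_config"))
  p <- as.data.table(pairs)
  n0 <- nrow(p)
  reason <- rep(NA_character_, n0)
  ## malformed records: missing coordinates or cigar on a mapped mate
  malformed <- is.na(p$lpos) | is.na(p$lcigar) | p$lcigar == "*"
  if (any(malformed)) {
    warning(sum(malformed), " malformed record(s) skipped")
    reason[malformed] <- "malformed"
  }
  ok <- is.na(reason)
  if (config$require_proper_pair)
    reason[ok & !p$proper] <- "improper"
  ok <- is.na(reason)
  reason[ok & p$mapq < config$min_mapping_confidence] <- "ambiguous"
  ok <- is.na(reason)
  if (config$forbid_soft_clips) {
    sc <- cigar_has_softclip(p$lcigar) |
      (!is.na(p$rcigar) & cigar_has_softclip(p$rcigar))
    reason[ok & sc] <- "soft_clip"
  }
  ok <- which(is.na(reason))
  if (length(ok)) {
    refint <- ref_codes(reference$seq)
    lst <- decode_reads(p$lpos[ok], p$lcigar[ok], p$lseq[ok],
                        refint = refint, tokens = FALSE)$stats
    lim_l <- pmax(config$max_mismatch_count,
                  config$max_mismatch_frac * lst$aligned_len)
    bad <- lst$n_mismatch > lim_l
    has_r <- which(!is.na(p$rpos[ok]))
    if (length(has_r)) {
      okr <- ok[has_r]
      rst <- decode_reads(p$rpos[okr], p$rcigar[okr], p$rseq[okr],
                          refint = refint, tokens = FALSE)$stats
      lim_r <- pmax(config$max_mismatch_count,
                    config$max_mismatch_frac * rst$aligned_len)
      bad[has_r] <- bad[has_r] | rst$n_mismatch > lim_r
    }
    reason[ok[bad]] <- "excessive_mismatch"
  }
  pass <- p[is.na(reason)]
  dropped <- table(factor(reason, levels = c("malformed", "improper",
                                             "ambiguous", "soft_clip",
                                             "excessive_mismatch")))
  report <- structure(list(
    input_pairs = n0,
    dropped = as.list(dropped),
    pass_pairs = nrow(pass),
    pass_fraction = if (n0 > 0L) nrow(pass) / n0 else NA_real_),
    class = "filter_report")
  list(pass = pass, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Read-pair filter report\n")
  cat("  input pairs:  ", x$input_pairs, "\n")
  for (r in names(x$dropped))
    cat(sprintf("  dropped %-20s %d\n", paste0(r, ":"), x$dropped[[r]]))
  cat("  passing:      ", x$pass_pairs,
      sprintf(" (%.1f%%)\n", 100 * x$pass_fraction))
  invisible(x)
}

filter_report_table <- function(report) {
  data.table(metric = c("input_pairs",
                        paste0("dropped_", names(report$dropped)),
                        "pass_pairs", "pass_fraction"),
             value = c(report$input_pairs, unlist(report$dropped),
                       report$pass_pairs, report$pass_fraction))
}

#' Mask read ends
#'
#' Masks the first and last `end_trim` aligned bases of each read to `N`,
#' removing them from consensus support without touching the template
#' coordinates that identify the molecule.  (The pipeline applies the same
#' masking internally at decode time, which additionally suppresses terminal
#' deletion columns.)
#'
#' @param pairs Pair table.
#' @param end_trim Bases masked per read end.
#' @return Pair table with masked sequences.
#' @export
trim_ends <- function(pairs, end_trim) {
  end_trim <- as.integer(end_trim)
  stopifnot(end_trim >= 0L)
  if (end_trim == 0L || nrow(pairs) == 0L) return(as.data.table(pairs))
  p <- copy(as.data.table(pairs))
  p[, lseq := mask_read_ends(lcigar, lseq, end_trim)]
  has_r <- !is.na(p$rcigar)
  p[has_r, rseq := mask_read_ends(rcigar, rseq, end_trim)]
  p
}

mask_read_ends <- function(cigar, seq, k) {
  out <- seq
  for (uc in unique(cigar)) {
    idx <- which(cigar == uc)
    ex <- expand_cigar(uc)
    drop <- !is.na(ex$colid) & (ex$colid <= k | ex$colid > ex$ncol - k)
    qmask <- ex$qoff[drop & ex$op %in% c("M", "I")]
    if (!length(qmask)) next
    for (i in idx) {
      s <- out[i]
      for (q in qmask) substr(s, q + 1L, q + 1L) <- "N"
      out[i] <- s
    }
  }
  out
}
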