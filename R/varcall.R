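## Variant calling from duplex consensuses and population-SNP filtering.
##
## Without germline whole-genome data, rare germline variants cannot be
## separated from somatic mutations; output is therefore labelled
## "mutations", and only common polymorphisms (population AF above the
## threshold) are removed.

#' SNP filter configuration
#'
#' @param af_threshold Population allele-frequency threshold; calls with
#'   table AF strictly greater than this are removed ("higher than 1%"),
#'   calls at exactly the threshold or with unknown AF are retained.
#' @return List of class `snp_filter_config`.
#' @export
snp_filter_config <- function(af_threshold = 0.01) {
  stopifnot(af_threshold >= 0, af_threshold <= 1)
  structure(list(af_threshold = af_threshold), class = "snp_filter_config")
}

#' Call variants from duplex consensuses
#'
#' Every duplex-called position differing from the reference emits one call;
#' runs of duplex-called deletion columns are merged into single anchored
#' deletion events, and duplex-supported insertions are emitted once per
#' event.  Indels are left-aligned.  Each call keeps its supporting template
#' key, so a mutation observed in several molecules is counted once per
#' molecule (the unit of the per-Mb burden).
#'
#' @param duplexes A duplex set (pipeline merge result) or a list of
#'   `duplex_consensus` objects (then `groups` template spans are not
#'   needed).
#' @param reference `list(name, seq)`.
#' @return data.table of calls: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `class`, `tkey`.
#' @export
call_variants <- function(duplexes, reference) {
  refseq <- reference$seq
  G <- nchar(refseq)
  if (inherits(duplexes, "duplex_set")) {
    calls <- duplexes$calls
    ins <- duplexes$ins
  } else {
    calls <- rbindlist(lapply(duplexes, function(d)
      if (nrow(d$calls)) data.table(tkey = d$tkey, d$calls[, .(off, tok)])
      else NULL))
    if (is.null(calls) || nrow(calls) == 0L)
      calls <- data.table(tkey = character(), off = integer(),
                          tok = integer())
    if (is.character(calls$tok)) calls[, tok := tok_encode(tok)]
    ins <- rbindlist(lapply(duplexes, function(d)
      if (nrow(d$ins)) data.table(tkey = d$tkey, d$ins[, .(anchor, iseq)])
      else NULL))
    if (is.null(ins) || nrow(ins) == 0L)
      ins <- data.table(tkey = character(), anchor = integer(),
                        iseq = character())
  }
  if (nrow(calls) && (min(calls$off) < 0L || max(calls$off) >= G))
    stop("duplex position outside the reference: corrupt input")
  refint <- ref_codes(refseq)
  chromn <- reference$name

  out <- list()
  ## SNVs
  snv <- calls[tok <= 4L & tok != refint[off + 1L]]
  if (nrow(snv)) {
    out[[1L]] <- data.table(chrom = chromn, pos = snv$off,
                            ref = BASES[refint[snv$off + 1L]],
                            alt = BASES[snv$tok], class = "SNV",
                            tkey = snv$tkey)
  }
  ## deletions: maximal runs of duplex-called deletion columns per template
  del <- calls[tok == TOK_DEL]
  if (nrow(del)) {
    setorder(del, tkey, off)
    del[, run := cumsum(c(1L, diff(off) != 1L)), by = tkey]
    dels <- del[, .(d0 = min(off), d1 = max(off) + 1L), by = .(tkey, run)]
    recs <- vector("list", nrow(dels))
    for (k in seq_len(nrow(dels))) {
      d0 <- dels$d0[k]; d1 <- dels$d1[k]
      p0 <- max(d0 - 1L, 0L)
      refa <- substring(refseq, p0 + 1L, d1)
      alta <- substring(refseq, p0 + 1L, p0 + 1L)
      nv <- normalize_variant(p0, refa, alta, refseq)
      recs[[k]] <- data.table(chrom = chromn, pos = nv$pos, ref = nv$ref,
                              alt = nv$alt, class = "deletion",
                              tkey = dels$tkey[k])
    }
    out[[length(out) + 1L]] <- rbindlist(recs)
  }
  ## insertions
  if (nrow(ins)) {
    recs <- vector("list", nrow(ins))
    for (k in seq_len(nrow(ins))) {
      a <- ins$anchor[k]
      refa <- substring(refseq, a + 1L, a + 1L)
      alta <- paste0(refa, ins$iseq[k])
      nv <- normalize_variant(a, refa, alta, refseq)
      recs[[k]] <- data.table(chrom = chromn, pos = nv$pos, ref = nv$ref,
                              alt = nv$alt, class = "insertion",
                              tkey = ins$tkey[k])
    }
    out[[length(out) + 1L]] <- rbindlist(recs)
  }
  res <- if (length(out)) rbindlist(out)
         else data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         class = character(), tkey = character())
  setorder(res, chrom, pos, tkey)
  res[]
}

#' Remove common population polymorphisms from a call set
#'
#' A call is removed iff its allele-matched population AF is strictly above
#' the threshold; calls at or below the threshold, and calls at sites absent
#' from the table ("unknown"), are retained.  The removed set is returned
#' separately: its per-Mb rate against planted heterozygosity is the
#' pipeline's SNP-density sanity metric.
#'
#' @param calls Call table from [call_variants()].
#' @param af_table An [load_af_table()] table (or equivalent data.table).
#' @param config A [snp_filter_config()].
#' @return `list(retained, removed)`; both carry a `population_af` column.
#' @export
filter_common_snps <- function(calls, af_table,
                               config = snp_filter_config()) {
  stopifnot(inherits(config, "snp_filter_config"))
  calls <- copy(as.data.table(calls))
  if (nrow(calls) == 0L) {
    calls[, population_af := numeric(0)]
    return(list(retained = calls, removed = calls[0L]))
  }
  calls[, population_af := af_lookup(af_table, chrom, pos, ref, alt)]
  common <- !is.na(calls$population_af) &
    calls$population_af > config$af_threshold
  list(retained = calls[!common], removed = calls[common])
}
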