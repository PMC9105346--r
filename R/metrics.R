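## Summary statistics: mutation load per Mb with exact binomial CIs, the
## mutation spectrum, duplex/template statistics and the fragment-end
## positional profile.

#' Mutation rate per Mb with exact binomial 95% CI
#'
#' The rate is `k / n * 1e6` and the interval is the exact Clopper-Pearson
#' binomial interval on the proportion `k / n`, scaled to per-Mb.  The exact
#' interval is used deliberately: at the small duplex footprints involved
#' (0.1-1 Mb) the mutation counts are tens, where a normal approximation
#' misbehaves.
#'
#' @param k Mutation count.
#' @param n Duplex bases (the denominator of the burden unit).
#' @param conf Confidence level (default 0.95).
#' @return `list(rate, lower, upper, k, n, undefined)`; rates per Mb.  With
#'   `n = 0` the fields are `NA` and `undefined` is TRUE (no division
#'   error).
#' @export
mutation_rate_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0)
    return(list(rate = NA_real_, lower = NA_real_, upper = NA_real_,
                k = k, n = n, undefined = TRUE))
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  list(rate = k / n * 1e6, lower = lower * 1e6, upper = upper * 1e6,
       k = k, n = n, undefined = FALSE)
}

#' Profile configuration
#'
#' @param window Positions from each fragment end to profile (default 50).
#' @export
profile_config <- function(window = 50L) {
  stopifnot(window >= 1L)
  structure(list(window = as.integer(window)), class = "profile_config")
}

#' Fragment-end distance profile of mutations
#'
#' For each retained mutation the distance to the closer template end is
#' computed (1-based: position 1 is the terminal base).  Event counts are
#' normalized by the number of duplex-called bases at each distance, so that
#' short templates do not bias the tail: the `rate` column is events per Mb
#' of duplex sequence at that distance.  End-repair error copying
#' concentrates artifacts within the overhang scale of the fragment ends;
#' nuclease-blunted libraries stay flat.
#'
#' @param calls Retained call table (needs `pos`, `tkey`).
#' @param duplexes The pipeline duplex set (supplies per-template spans and
#'   duplex-called positions for coverage).
#' @param config A [profile_config()].
#' @return data.table: `dist` (1..window), `events`, `covered` (duplex bases
#'   at that distance), `rate` (events per Mb, NA where uncovered).
#' @export
end_distance_profile <- function(calls, duplexes,
                                 config = profile_config()) {
  w <- config$window
  tmpl <- duplexes$templates
  dcalls <- duplexes$calls
  spans <- tmpl[, .(tkey, start, end)]
  cov <- spans[dcalls, on = "tkey", nomatch = NULL]
  cov[, dist := 1L + pmin(off - start, end - 1L - off)]
  covered <- cov[dist >= 1L & dist <= w, .N, keyby = dist]
  ev <- spans[as.data.table(calls), on = "tkey", nomatch = NULL]
  ev[, dist := 1L + pmin(pos - start, end - 1L - pos)]
  events <- ev[dist >= 1L & dist <= w, .N, keyby = dist]
  out <- data.table(dist = seq_len(w))
  out[covered, covered := i.N, on = "dist"]
  out[events, events := i.N, on = "dist"]
  out[is.na(covered), covered := 0L]
  out[is.na(events), events := 0L]
  out[, rate := fifelse(covered > 0L, events / covered * 1e6, NA_real_)]
  out[]
}

#' Mutation spectrum
#'
#' Class fractions (SNV / insertion / deletion) and SNV substitution types
#' on the pyrimidine-context convention (purine reference alleles are
#' complemented, giving the six classes C>A, C>G, C>T, T>A, T>C, T>G).
#'
#' @param calls Call table.
#' @return `list(n, class_fractions, substitutions)`; empty input gives an
#'   empty spectrum without division errors.
#' @export
spectrum <- function(calls) {
  calls <- as.data.table(calls)
  n <- nrow(calls)
  if (n == 0L) {
    return(list(n = 0L,
                class_fractions = setNames(numeric(3),
                                           c("SNV", "insertion", "deletion")),
                substitutions = data.table(type = character(),
                                           count = integer(),
                                           fraction = numeric())))
  }
  cls <- factor(calls$class, levels = c("SNV", "insertion", "deletion"))
  class_fractions <- as.vector(table(cls)) / n
  names(class_fractions) <- levels(cls)
  snv <- calls[class == "SNV"]
  if (nrow(snv)) {
    pur <- snv$ref %in% c("A", "G")
    r <- ifelse(pur, chartr("ACGT", "TGCA", snv$ref), snv$ref)
    a <- ifelse(pur, chartr("ACGT", "TGCA", snv$alt), snv$alt)
    type <- paste0(r, ">", a)
    tt <- as.data.table(table(type = factor(
      type, levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))))
    setnames(tt, "N", "count")
    tt[, fraction := count / sum(count)]
  } else {
    tt <- data.table(type = character(), count = integer(),
                     fraction = numeric())
  }
  list(n = n, class_fractions = class_fractions, substitutions = tt)
}

## Single-strand corrected events: positions where a strand consensus
## differs from the reference but the duplex does not confirm the change.
## Restricted to templates that formed a duplex (both strands consensused),
## the setting in which correction is observable.  The denominator is the
## summed called strand-consensus length of those templates (distinct from
## the duplex-length denominator of the mutation burden).
single_strand_events <- function(cset, duplexes, reference) {
  refint <- ref_codes(reference$seq)
  sc <- cset$strand_calls
  dup_t <- duplexes$templates$tkey
  sc <- sc[tkey %in% dup_t]
  if (nrow(sc) == 0L)
    return(list(events = 0L, strand_called_bases = 0L, rate = NA_real_))
  denom <- nrow(sc)
  var_sc <- sc[tok != refint[off + 1L]]
  if (nrow(var_sc)) {
    conf <- duplexes$calls[, .(tkey, off, dtok = tok)]
    var_sc <- conf[var_sc, on = c("tkey", "off")]
    events <- nrow(var_sc[is.na(dtok) | dtok != tok])
  } else events <- 0L
  ## single-strand insertion events: strand-called, not duplex-confirmed
  si <- cset$ins_calls[tkey %in% dup_t]
  if (nrow(si)) {
    di <- duplexes$ins[, .(tkey, anchor, iseq, dup = TRUE)]
    si <- di[si, on = c("tkey", "anchor", "iseq")]
    events <- events + nrow(si[is.na(dup)])
  }
  list(events = events, strand_called_bases = denom,
       rate = events / denom * 1e6)
}
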