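## Shared fixtures: hand-built pair records, tiny references, and an
## independent brute-force consensus oracle (plain loops, no shared code
## with the package implementation).

library(data.table)

fixture_ref <- function(seq = NULL, len = 400, seed = 11) {
  if (is.null(seq)) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  }
  list(name = "fix1", seq = seq)
}

## Build one aligned pair record covering [start, end) of `ref` with
## read-through mates.  `subs` is a named list position -> base (0-based,
## applied to both mates where covered); `cigar` overrides both mates'
## CIGAR; `seq` overrides the molecule sequence entirely.
make_pair <- function(ref, start, end, orient = "top", qname = "q1",
                      subs = NULL, mol_seq = NULL, cigar = NULL,
                      lcigar = NULL, rcigar = NULL, read_length = NULL,
                      mapq = 60L, proper = TRUE) {
  if (is.null(mol_seq)) {
    mol_seq <- substr(ref$seq, start + 1, end)
    if (!is.null(subs)) {
      for (p in names(subs)) {
        rel <- as.integer(p) - start + 1L
        substr(mol_seq, rel, rel) <- subs[[p]]
      }
    }
  }
  L <- nchar(mol_seq)
  w <- if (is.null(read_length)) L else min(read_length, L)
  cig <- if (!is.null(cigar)) cigar else paste0(w, "M")
  lc <- if (!is.null(lcigar)) lcigar else cig
  rc <- if (!is.null(rcigar)) rcigar else cig
  ## with full read-through the right mate covers the whole molecule, so it
  ## aligns from the template start (matters for indel CIGARs)
  rpos <- if (w == L) start else end - w
  data.table(qname = qname, rname = ref$name, start = as.integer(start),
             end = as.integer(end), orient = orient,
             lpos = as.integer(start), lcigar = lc,
             lseq = substr(mol_seq, 1, w), lqual = strrep("F", w),
             rpos = as.integer(rpos), rcigar = rc,
             rseq = substr(mol_seq, L - w + 1, L), rqual = strrep("F", w),
             mapq = as.integer(mapq), proper = proper)
}

## n copies of the same molecule (one strand family)
make_family <- function(ref, start, end, n, orient = "top",
                        qprefix = "fam", ...) {
  rbindlist(lapply(seq_len(n), function(i)
    make_pair(ref, start, end, orient = orient,
              qname = sprintf("%s_c%02d", qprefix, i), ...)))
}

## ---- independent consensus oracle ----
## Exhaustive per-position tally over the member reads of one family,
## written with explicit loops; ignores insertions (base/deletion columns
## only) and base qualities (fixtures use flat high quality).
oracle_family_consensus <- function(family, min_copies = 5,
                                    min_agreement = 0.8, end_trim = 0) {
  if (nrow(family) < min_copies) {
    return(list(status = "below_min_copies",
                calls = data.table(off = integer(), tok = character())))
  }
  copy_votes <- list()
  for (i in seq_len(nrow(family))) {
    m <- list()
    for (mate in c("l", "r")) {
      pos <- family[[paste0(mate, "pos")]][i]
      cig <- family[[paste0(mate, "cigar")]][i]
      sq <- family[[paste0(mate, "seq")]][i]
      if (is.na(pos) || is.na(cig)) next
      cols <- list()
      num <- ""
      r <- pos; q <- 1L
      for (ch in strsplit(cig, "")[[1]]) {
        if (ch %in% as.character(0:9)) { num <- paste0(num, ch); next }
        len <- as.integer(num); num <- ""
        for (j in seq_len(len)) {
          if (ch == "M") {
            cols[[length(cols) + 1L]] <- list(off = r,
                                              tok = substr(sq, q, q))
            r <- r + 1L; q <- q + 1L
          } else if (ch == "D") {
            cols[[length(cols) + 1L]] <- list(off = r, tok = "-")
            r <- r + 1L
          } else if (ch == "I") {
            cols[[length(cols) + 1L]] <- list(off = NA, tok = "ins")
            q <- q + 1L
          } else if (ch == "S") {
            q <- q + 1L
          }
        }
      }
      nc <- length(cols)
      for (ci in seq_len(nc)) {
        if (ci <= end_trim || ci > nc - end_trim) next
        cl <- cols[[ci]]
        if (is.na(cl$off) || cl$tok == "N") next
        key <- as.character(cl$off)
        if (is.null(m[[key]])) m[[key]] <- cl$tok
        else if (!identical(m[[key]], cl$tok)) m[[key]] <- "CONFLICT"
      }
    }
    copy_votes[[i]] <- m
  }
  allkeys <- unique(unlist(lapply(copy_votes, names)))
  out <- list()
  for (key in allkeys) {
    vs <- unlist(lapply(copy_votes, function(m) m[[key]]))
    vs <- vs[vs != "CONFLICT"]
    if (length(vs) < min_copies) next
    tb <- sort(table(vs), decreasing = TRUE)
    if (tb[[1]] / length(vs) >= min_agreement) {
      out[[length(out) + 1L]] <- data.table(off = as.integer(key),
                                            tok = names(tb)[1L])
    }
  }
  calls <- if (length(out)) rbindlist(out)
           else data.table(off = integer(), tok = character())
  setorder(calls, off)
  list(status = "ok", calls = calls)
}

## oracle duplex merge: both called and equal
oracle_merge <- function(plus, minus) {
  if (plus$status != "ok" || minus$status != "ok")
    return(data.table(off = integer(), tok = character()))
  k <- intersect(plus$calls$off, minus$calls$off)
  out <- list()
  for (o in sort(k)) {
    tp <- plus$calls[off == o, tok]
    tm <- minus$calls[off == o, tok]
    if (identical(tp, tm))
      out[[length(out) + 1L]] <- data.table(off = o, tok = tp)
  }
  if (length(out)) rbindlist(out)
  else data.table(off = integer(), tok = character())
}

## small default simulation used by several tests
quick_sim_config <- function(...) {
  args <- list(reference_length = 5e4, snp_density = 2000,
               n_templates = 400, pcr_copies_mean = 6, read_length = 120,
               fragment_median = 146, lesion_rate = 1000,
               somatic_rate_snv = 40, somatic_rate_indel = 10, seed = 42)
  args[names(list(...))] <- list(...)
  args
}

run_quick_sim <- function(...) {
  p <- do.call(duplexffpe::sim_params, quick_sim_config(...))
  sr <- duplexffpe::simulate_reference(p)
  lib <- duplexffpe::simulate_library(sr$reference, sr$snps, p)
  list(params = p, ref = sr$reference, snps = sr$snps, lib = lib)
}

## Independent Clopper-Pearson oracle: invert the binomial tail sums with
## uniroot on a log scale (no qbeta anywhere).
oracle_cp_ci <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  logrange <- c(log(1e-14), 0)
  lower <- if (k == 0) 0 else
    exp(stats::uniroot(function(lp) stats::pbinom(k - 1, n, exp(lp),
                                                  lower.tail = FALSE) - a,
                       logrange, tol = 1e-13)$root)
  upper <- if (k == n) 1 else
    exp(stats::uniroot(function(lp) stats::pbinom(k, n, exp(lp)) - a,
                       logrange, tol = 1e-13)$root)
  c(lower, upper)
}

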