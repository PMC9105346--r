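## Coordinate-keyed molecule identification and duplex consensus calling.
##
## The mapped template coordinates (reference, start, end) of a read pair
## identify the source molecule -- the defining trick of bottleneck duplex
## sequencing, which replaces molecular barcodes with an extreme library
## dilution.  Each molecule contributes up to two strand families (one per
## physical strand, distinguished by read-pair orientation); a strand
## consensus needs at least `min_copies` PCR copies, and the duplex
## consensus keeps only positions on which both strand consensuses agree.
## All sequences are represented in top (reference) strand space, so
## strand-vs-strand concordance is complement-aware by construction.

#' Consensus configuration
#'
#' @param min_copies Minimum PCR copies per strand family; families below
#'   this are rejected and, independently, a position needs at least this
#'   many contributing copies to be called (default 5).
#' @param min_agreement Minimum fraction of contributing copies supporting
#'   the modal base (default 0.8; must exceed 0.5).
#' @param min_base_quality Minimum Phred base quality for a read base to
#'   contribute support (default 20).
#' @return List of class `consensus_config`.
#' @export
consensus_config <- function(min_copies = 5L, min_agreement = 0.8,
                             min_base_quality = 20L) {
  stopifnot(min_copies >= 1L)
  if (!(min_agreement > 0.5 && min_agreement <= 1))
    stop("min_agreement must be in (0.5, 1]")
  structure(list(min_copies = as.integer(min_copies),
                 min_agreement = min_agreement,
                 min_base_quality = as.integer(min_base_quality)),
            class = "consensus_config")
}

#' Group read pairs into strand families by template coordinates
#'
#' Exact-coordinate grouping: pairs sharing `(reference, start, end)` derive
#' from one molecule, and within a molecule the orientation label separates
#' the two strand families.  Coordinates differing by a single base are
#' distinct templates.
#'
#' @param pairs Filtered pair table.
#' @return List of class `template_groups`: `pairs` (with `tkey` and family
#'   id `fam`), `families` (one row per strand family) and `templates`
#'   (one row per unique template).
#' @export
group_templates <- function(pairs) {
  p <- copy(as.data.table(pairs))
  if (nrow(p) == 0L) {
    return(structure(list(
      pairs = p,
      families = data.table(fam = integer(), tkey = character(),
                            rname = character(), start = integer(),
                            end = integer(), orient = character(),
                            n_members = integer()),
      templates = data.table(tkey = character(), rname = character(),
                             start = integer(), end = integer(),
                             n_families = integer(), n_pairs = integer())),
      class = "template_groups"))
  }
  p[, tkey := paste0(rname, ":", start, "-", end)]
  p[, fam := .GRP, by = .(tkey, orient)]
  p[, pair := .I]
  families <- p[, .(tkey = tkey[1L], rname = rname[1L], start = start[1L],
                    end = end[1L], orient = orient[1L], n_members = .N),
                by = fam]
  templates <- p[, .(rname = rname[1L], start = start[1L], end = end[1L],
                     n_families = uniqueN(orient), n_pairs = .N),
                 by = tkey]
  structure(list(pairs = p, families = families, templates = templates),
            class = "template_groups")
}

## ---- vectorized consensus core ----
##
## Builds every strand consensus at once.  Support is counted per PCR copy
## (per pair), not per read: where the two mates of a pair overlap they must
## agree to contribute a single vote, and an intra-pair conflict removes the
## position's vote from that copy.
build_consensus_all <- function(groups, reference, config = consensus_config(),
                                end_trim = 0L) {
  stopifnot(inherits(groups, "template_groups"),
            inherits(config, "consensus_config"))
  p <- groups$pairs
  fams <- copy(groups$families)
  fams[, status := fifelse(n_members >= config$min_copies, "ok",
                           "below_min_copies")]
  elig <- fams[status == "ok", fam]
  pe <- p[fam %in% elig]
  empty <- list(
    strand_calls = data.table(fam = integer(), tkey = character(),
                              orient = character(), off = integer(),
                              tok = integer(), depth = integer(),
                              agreement = numeric()),
    ins_calls = data.table(fam = integer(), tkey = character(),
                           orient = character(), anchor = integer(),
                           iseq = character(), depth = integer(),
                           agreement = numeric()),
    families = fams, tally = NULL)
  if (nrow(pe) == 0L) return(structure(empty, class = "consensus_set"))

  ## decode both mates; rid maps back to pair rows
  np <- nrow(pe)
  has_r <- !is.na(pe$rpos)
  pos <- c(pe$lpos, pe$rpos[has_r])
  cig <- c(pe$lcigar, pe$rcigar[has_r])
  sq <- c(pe$lseq, pe$rseq[has_r])
  ql <- c(pe$lqual, pe$rqual[has_r])
  pair_of <- c(seq_len(np), which(has_r))
  dec <- decode_reads(pos, cig, sq, qual = ql, end_trim = end_trim)
  tok <- dec$tokens
  tok <- tok[tok < TOK_N & qv >= config$min_base_quality]
  tok[, pair := pair_of[rid]]
  ## one vote per PCR copy: mates must agree where they overlap
  votes <- unique(tok[, .(pair, off, tok)])
  votes[, n := .N, by = .(pair, off)]
  votes <- votes[n == 1L][, n := NULL]
  votes[, fam := pe$fam[pair]]
  tally <- dcast(votes[, .(n = .N), by = .(fam, off, tok)],
                 fam + off ~ tok, value.var = "n", fill = 0L)
  tokcols <- setdiff(names(tally), c("fam", "off"))
  m <- as.matrix(tally[, ..tokcols])
  depth <- rowSums(m)
  imax <- max.col(m, ties.method = "first")
  nmax <- m[cbind(seq_len(nrow(m)), imax)]
  tokmax <- as.integer(tokcols)[imax]
  agreement <- nmax / depth
  called <- depth >= config$min_copies & agreement >= config$min_agreement
  tally[, `:=`(depth = as.integer(depth), tok = tokmax,
               agreement = agreement, called = called)]
  strand_calls <- tally[called == TRUE,
                        .(fam, off, tok, depth, agreement)]

  ## insertion consensus: votes are per copy; a copy whose mates disagree on
  ## the inserted sequence is discarded; copies covering the anchor with no
  ## insertion vote for "no insertion"
  ins <- dec$ins
  ins_calls <- empty$ins_calls[, .(fam, anchor, iseq, depth, agreement)][0L]
  if (nrow(ins)) {
    ins[, pair := pair_of[rid]]
    iv <- unique(ins[, .(pair, anchor, iseq)])
    iv[, n := .N, by = .(pair, anchor)]
    iv <- iv[n == 1L][, n := NULL]
    iv[, fam := pe$fam[pair]]
    ic <- iv[, .(n_ins = .N), by = .(fam, anchor, iseq)]
    setorder(ic, fam, anchor, -n_ins)
    ic <- ic[, .SD[1L], by = .(fam, anchor)]
    cov <- tally[, .(fam, off, depth)]
    ic <- cov[ic, on = c("fam", "off" = "anchor")]
    setnames(ic, "off", "anchor")
    ic <- ic[!is.na(depth)]
    ic[, agreement := n_ins / depth]
    ic <- ic[depth >= config$min_copies & agreement >= config$min_agreement &
               n_ins >= config$min_copies]
    ins_calls <- ic[, .(fam, anchor, iseq, depth, agreement)]
  }

  faminfo <- fams[, .(fam, tkey, orient)]
  strand_calls <- faminfo[strand_calls, on = "fam"]
  ins_calls <- faminfo[ins_calls, on = "fam"]
  fams[strand_calls[, .N, by = fam], called_len := i.N,
       on = "fam"][is.na(called_len), called_len := 0L]
  structure(list(strand_calls = strand_calls, ins_calls = ins_calls,
                 families = fams, tally = tally),
            class = "consensus_set")
}

#' Build the consensus of one strand family
#'
#' Families with fewer than `min_copies` members are rejected (a value, not
#' an error).  At every unmasked position a base (or deletion) is called
#' when at least `min_copies` copies contribute and the modal token reaches
#' `min_agreement`; contested positions stay undetermined.  Indels are
#' called from the modal alignment descriptor under the same agreement rule.
#'
#' @param family_pairs Pair rows of one strand family (identical template
#'   key and orientation).
#' @param config A [consensus_config()].
#' @param end_trim Terminal alignment columns masked per read.
#' @return Object of class `strand_consensus`: `tkey`, `orient`, `status`
#'   (`"ok"` or `"below_min_copies"`), `calls` (off, tok, depth, agreement),
#'   `ins` and the full per-position `tally`.
#' @export
build_strand_consensus <- function(family_pairs, config = consensus_config(),
                                   end_trim = 0L) {
  fp <- as.data.table(family_pairs)
  stopifnot(nrow(fp) >= 1L)
  if (uniqueN(fp[, .(rname, start, end, orient)]) != 1L)
    stop("family members must share template key and orientation")
  g <- group_templates(fp)
  cs <- build_consensus_all(g, NULL, config, end_trim)
  fam1 <- g$families$fam[1L]
  structure(list(
    tkey = g$families$tkey[1L],
    orient = g$families$orient[1L],
    n_members = nrow(fp),
    status = cs$families[fam == fam1, status],
    calls = cs$strand_calls[fam == fam1, .(off, tok = tok_decode(tok),
                                           depth, agreement)],
    ins = cs$ins_calls[fam == fam1, .(anchor, iseq, depth, agreement)],
    tally = if (!is.null(cs$tally)) {
      t1 <- cs$tally[fam == fam1]
      t1[, .(off, depth, tok = tok_decode(tok), agreement, called)]
    } else NULL),
    class = "strand_consensus")
}

#' Merge two strand consensuses into a duplex consensus
#'
#' A position is duplex-called iff both strand consensuses call it and the
#' calls agree (sequences live in reference-strand space, so equality is the
#' complement-aware concordance rule); discordant or half-called positions
#' are undetermined and never produce a variant.  Insertions require the
#' identical inserted sequence on both strands.
#'
#' @param plus,minus `strand_consensus` objects from the same template.
#' @return Object of class `duplex_consensus` with `calls` (off, tok), `ins`
#'   and `duplex_length` (number of duplex-called positions).
#' @export
merge_duplex <- function(plus, minus) {
  stopifnot(inherits(plus, "strand_consensus"),
            inherits(minus, "strand_consensus"))
  if (!identical(plus$tkey, minus$tkey))
    stop("cannot merge consensuses from different templates: ",
         plus$tkey, " vs ", minus$tkey)
  if (plus$status != "ok" || minus$status != "ok") {
    calls <- data.table(off = integer(), tok = character())
    ins <- data.table(anchor = integer(), iseq = character())
  } else {
    calls <- merge(plus$calls[, .(off, tok)], minus$calls[, .(off, tok)],
                   by = "off", suffixes = c("_p", "_m"))
    calls <- calls[tok_p == tok_m, .(off, tok = tok_p)]
    ins <- merge(plus$ins[, .(anchor, iseq)], minus$ins[, .(anchor, iseq)],
                 by = c("anchor", "iseq"))
  }
  structure(list(tkey = plus$tkey, calls = calls, ins = ins,
                 duplex_length = nrow(calls)),
            class = "duplex_consensus")
}

## Vectorized duplex merge over a whole consensus_set.
merge_duplexes <- function(cset, groups) {
  stopifnot(inherits(cset, "consensus_set"))
  sc <- cset$strand_calls
  tinfo <- groups$templates
  if (nrow(sc) == 0L) {
    return(structure(list(
      calls = data.table(tkey = character(), off = integer(),
                         tok = integer()),
      ins = data.table(tkey = character(), anchor = integer(),
                       iseq = character()),
      templates = data.table(tkey = character(), rname = character(),
                             start = integer(), end = integer(),
                             duplex_length = integer())),
      class = "duplex_set"))
  }
  plus <- sc[orient == "top", .(tkey, off, tok)]
  minus <- sc[orient == "bottom", .(tkey, off, tok)]
  calls <- plus[minus, on = c("tkey", "off"), nomatch = NULL]
  calls <- calls[tok == i.tok, .(tkey, off, tok)]
  ip <- cset$ins_calls[orient == "top", .(tkey, anchor, iseq)]
  im <- cset$ins_calls[orient == "bottom", .(tkey, anchor, iseq)]
  ins <- ip[im, on = c("tkey", "anchor", "iseq"), nomatch = NULL]
  tmpl <- calls[, .(duplex_length = .N), by = tkey]
  tmpl <- tinfo[, .(tkey, rname, start, end)][tmpl, on = "tkey"]
  structure(list(calls = calls, ins = ins, templates = tmpl),
            class = "duplex_set")
}

#' Duplex fraction
#'
#' Fraction of unique templates (among filtered reads) that yield a duplex
#' consensus with at least one duplex-called position.
#'
#' @param groups A [group_templates()] result.
#' @param duplexes A duplex set (internal result of the pipeline merge) or a
#'   list of `duplex_consensus` objects.
#' @return `list(fraction, n_duplex, n_templates, undefined)`; with zero
#'   templates `fraction` is `NA` and `undefined` is TRUE.
#' @export
duplex_fraction <- function(groups, duplexes) {
  n_templates <- nrow(groups$templates)
  n_duplex <- if (inherits(duplexes, "duplex_set")) {
    nrow(duplexes$templates[duplex_length > 0L])
  } else {
    sum(vapply(duplexes, function(d) d$duplex_length > 0L, logical(1)))
  }
  if (n_templates == 0L)
    return(list(fraction = NA_real_, n_duplex = 0L, n_templates = 0L,
                undefined = TRUE))
  list(fraction = n_duplex / n_templates, n_duplex = n_duplex,
       n_templates = n_templates, undefined = FALSE)
}
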