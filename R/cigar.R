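## CIGAR parsing and read decoding into per-reference-position tokens.
## Tokens are integer codes: A=1 C=2 G=3 T=4, deletion=5, N/other=6.

BASES <- c("A", "C", "G", "T", "-", "N")
TOK_DEL <- 5L
TOK_N <- 6L

tok_encode <- function(chars) {
  m <- match(chars, BASES)
  m[is.na(m)] <- TOK_N
  m
}

## byte-level token codes for whole sequence vectors (fast path)
CODE_LOOKUP <- local({
  v <- rep(TOK_N, 256L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("-")] <- 5L
  v
})

seq_code_matrix <- function(seqs, width) {
  matrix(CODE_LOOKUP[utf8ToInt(paste0(seqs, collapse = ""))], nrow = width)
}

ref_codes <- function(refseq) CODE_LOOKUP[utf8ToInt(refseq)]

tok_decode <- function(tok) BASES[tok]

## One CIGAR string -> list(len = integer, op = character)
parse_cigar <- function(cig) {
  lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1L]])
  ops <- regmatches(cig, gregexpr("[MIDNSHP=X]", cig))[[1L]]
  if (length(lens) != length(ops) || !length(ops))
    stop("malformed CIGAR: ", cig)
  list(len = lens, op = ops)
}

cigar_ref_width <- function(cig) {
  vapply(cig, function(x) {
    p <- parse_cigar(x)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_width <- function(cig) {
  vapply(cig, function(x) {
    p <- parse_cigar(x)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_has_softclip <- function(cig) grepl("S", cig, fixed = TRUE)

cigar_n_indel_ops <- function(cig) {
  vapply(cig, function(x) {
    p <- parse_cigar(x)
    sum(p$op %in% c("I", "D"))
  }, integer(1), USE.NAMES = FALSE)
}

## Per-unit expansion of one CIGAR, shared by all reads carrying it.
## Returns the per-base layout needed to place tokens on the reference.
expand_cigar <- function(cig) {
  p <- parse_cigar(cig)
  op <- rep(p$op, p$len)
  qcons <- op %in% c("M", "I", "S", "=", "X")
  rcons <- op %in% c("M", "D", "N", "=", "X")
  qoff <- rep(NA_integer_, length(op))
  qoff[qcons] <- seq_len(sum(qcons)) - 1L
  roff <- rep(NA_integer_, length(op))
  roff[rcons] <- seq_len(sum(rcons)) - 1L
  iscol <- op %in% c("M", "I", "D", "=", "X")   # alignment columns
  colid <- rep(NA_integer_, length(op))
  colid[iscol] <- seq_len(sum(iscol))
  ## last ref offset at or before each unit (-1 if none): insertion anchors
  lastroff <- cummax(ifelse(rcons, roff, -1L))
  list(op = op, qoff = qoff, roff = roff, colid = colid,
       ncol = sum(iscol), lastroff = lastroff,
       qlen = sum(qcons), rlen = sum(rcons))
}

## Decode a set of reads into long token tables.
##
## pos:   0-based reference position of the first aligned base
## cigar: CIGAR strings; seq: read sequences; qual: Phred+33 strings or NULL
## end_trim: number of terminal alignment columns masked at each read end
##
## Returns list(tokens = data.table(rid, off, tok, qv),
##              ins    = data.table(rid, anchor, iseq),
##              stats  = data.table(rid, aligned_len, n_indel_ops, n_mismatch))
## Mismatches are counted against `refint` (integer-encoded reference) over
## untrimmed aligned bases, plus one per indel op, when refint is supplied.
decode_reads <- function(pos, cigar, seq, qual = NULL, end_trim = 0L,
                         refint = NULL, tokens = TRUE) {
  n <- length(pos)
  stopifnot(length(cigar) == n, length(seq) == n)
  if (n == 0L) {
    return(list(
      tokens = data.table(rid = integer(), off = integer(),
                          tok = integer(), qv = integer()),
      ins = data.table(rid = integer(), anchor = integer(),
                       iseq = character()),
      stats = data.table(rid = integer(), aligned_len = integer(),
                         n_indel_ops = integer(), n_mismatch = integer())))
  }
  end_trim <- as.integer(end_trim)
  tok_parts <- list(); ins_parts <- list()
  aligned_len <- integer(n); n_indel <- integer(n); n_mm <- integer(n)
  for (uc in unique(cigar)) {
    idx <- which(cigar == uc)
    ex <- expand_cigar(uc)
    keep <- !is.na(ex$colid) & ex$colid > end_trim &
      ex$colid <= ex$ncol - end_trim
    aligned_len[idx] <- sum(ex$op == "M")
    n_indel[idx] <- sum(rle(ex$op)$values %in% c("I", "D"))
    ## token-code matrix: qlen x nreads
    B <- seq_code_matrix(seq[idx], ex$qlen)
    Q <- NULL
    if (!is.null(qual)) {
      Q <- matrix(utf8ToInt(paste0(qual[idx], collapse = "")),
                  nrow = ex$qlen) - 33L
    }
    mu <- which(ex$op == "M" & keep)
    if (tokens && length(mu)) {
      tm <- as.vector(B[ex$qoff[mu] + 1L, , drop = FALSE])
      qm <- if (is.null(Q)) rep(93L, length(tm))
            else as.vector(Q[ex$qoff[mu] + 1L, , drop = FALSE])
      tok_parts[[length(tok_parts) + 1L]] <- data.table(
        rid = rep(idx, each = length(mu)),
        off = rep(pos[idx], each = length(mu)) + rep(ex$roff[mu], length(idx)),
        tok = tm, qv = qm)
    }
    du <- which(ex$op == "D" & keep)
    if (tokens && length(du)) {
      tok_parts[[length(tok_parts) + 1L]] <- data.table(
        rid = rep(idx, each = length(du)),
        off = rep(pos[idx], each = length(du)) + rep(ex$roff[du], length(idx)),
        tok = TOK_DEL, qv = 93L)
    }
    ## insertions: whole runs, kept only if every column survives trimming
    ir <- rle(ex$op)
    if (tokens && any(ir$values == "I")) {
      ends <- cumsum(ir$lengths); starts <- ends - ir$lengths + 1L
      for (k in which(ir$values == "I")) {
        units <- starts[k]:ends[k]
        if (!all(keep[units])) next
        a_rel <- ex$lastroff[starts[k]]
        if (a_rel < 0L) next                 # insertion before first ref base
        q0 <- ex$qoff[starts[k]]; q1 <- ex$qoff[ends[k]]
        iseq <- substr(seq[idx], q0 + 1L, q1 + 1L)
        ok <- !grepl("N", iseq, fixed = TRUE)
        if (any(ok)) {
          ins_parts[[length(ins_parts) + 1L]] <- data.table(
            rid = idx[ok], anchor = pos[idx][ok] + a_rel, iseq = iseq[ok])
        }
      }
    }
    ## untrimmed mismatch count (substitutions) against reference
    if (!is.null(refint)) {
      mall <- which(ex$op == "M")
      if (length(mall)) {
        tm <- as.vector(B[ex$qoff[mall] + 1L, , drop = FALSE])
        offm <- rep(pos[idx], each = length(mall)) +
          rep(ex$roff[mall], length(idx))
        mm <- tm <= 4L & tm != refint[offm + 1L]
        n_mm[idx] <- n_mm[idx] +
          as.integer(rowsum(as.integer(mm),
                            group = rep(idx, each = length(mall)))[, 1L])
      }
    }
  }
  tokens <- if (length(tok_parts)) rbindlist(tok_parts)
            else data.table(rid = integer(), off = integer(),
                            tok = integer(), qv = integer())
  ins <- if (length(ins_parts)) rbindlist(ins_parts)
         else data.table(rid = integer(), anchor = integer(),
                         iseq = character())
  list(tokens = tokens, ins = ins,
       stats = data.table(rid = seq_len(n), aligned_len = aligned_len,
                          n_indel_ops = n_indel,
                          n_mismatch = n_mm + n_indel))
}

## Slice a molecule-vs-reference alignment (ops over the whole molecule) to
## the query interval [q0, q1) (0-based molecule coordinates), as a read
## alignment.  Returns list(cigar, ref_off): ref_off is the reference offset
## (relative to the molecule's reference start) of the read's first aligned
## base.  Leading/trailing deletions are dropped (alignments cannot start or
## end with D).
slice_cigar <- function(ops, q0, q1) {
  op <- rep(ops$op, ops$len)
  qcons <- op %in% c("M", "I")
  rcons <- op %in% c("M", "D")
  qoff <- rep(NA_integer_, length(op))
  qoff[qcons] <- seq_len(sum(qcons)) - 1L
  roff <- rep(NA_integer_, length(op))
  roff[rcons] <- seq_len(sum(rcons)) - 1L
  keep <- qcons & qoff >= q0 & qoff < q1
  ## deletions between kept query bases are retained
  kq <- which(keep)
  if (!length(kq)) stop("empty cigar slice")
  span <- seq(min(kq), max(kq))
  opk <- op[span]
  ## drop D at the very edges
  while (length(opk) && opk[1L] == "D") { span <- span[-1L]; opk <- op[span] }
  while (length(opk) && opk[length(opk)] == "D") {
    span <- span[-length(span)]; opk <- op[span]
  }
  r <- rle(opk)
  first_ref <- roff[span][rcons[span]][1L]
  list(cigar = paste0(r$lengths, r$values, collapse = ""),
       ref_off = first_ref)
}
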