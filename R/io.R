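## Format bridge: SAM/BAM alignments, FASTA references, AF tables (VCF/TSV),
## truth/report TSVs.  Internal coordinates are 0-based half-open; conversion
## to the 1-based SAM/VCF conventions happens only here.

#' Write a reference as FASTA
#'
#' @param reference `list(name, seq)`.
#' @param path Output path.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$seq)
  names(x) <- reference$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a single-sequence FASTA reference
#'
#' @param path FASTA path.
#' @return `list(name, seq)`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1L) stop("no sequences in ", path)
  list(name = sub("\\s.*$", "", names(x)[1L]),
       seq = as.character(x[[1L]]))
}

#' Write aligned read pairs as SAM
#'
#' Pair orientation is encoded in standard flags: molecules read from the
#' reference (top) strand emit flag pairs 99/147, bottom-strand molecules
#' 83/163; non-proper pairs lose the 0x2 bit.  Records are coordinate sorted.
#'
#' @param pairs Pair table as produced by [simulate_library()].
#' @param reference `list(name, seq)` used for the `@SQ` header.
#' @param path Output `.sam` path.
#' @export
write_sam <- function(pairs, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", reference$name, "\tLN:", nchar(reference$seq)))
  if (nrow(pairs) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  p <- as.data.table(pairs)
  ## top-strand molecules: R1 reads the left end forward (flags 99/147);
  ## bottom-strand molecules: R1 reads the right end reverse (83/163)
  first_l <- fifelse(p$orient == "top", 64L, 128L)
  first_r <- fifelse(p$orient == "top", 128L, 64L)
  prop <- fifelse(p$proper, 2L, 0L)
  fl_l <- 1L + prop + 32L + first_l   # left mate forward, mate reverse
  fl_r <- 1L + prop + 16L + first_r   # right mate reverse
  tlen <- p$end - p$start
  l_line <- paste(p$qname, fl_l, p$rname, p$lpos + 1L, p$mapq, p$lcigar,
                  "=", p$rpos + 1L, tlen, p$lseq, p$lqual, sep = "\t")
  r_line <- paste(p$qname, fl_r, p$rname, p$rpos + 1L, p$mapq, p$rcigar,
                  "=", p$lpos + 1L, -tlen, p$rseq, p$rqual, sep = "\t")
  dt <- data.table(pos = c(p$lpos, p$rpos), qn = c(p$qname, p$qname),
                   line = c(l_line, r_line))
  setorder(dt, pos, qn)
  writeLines(c(hdr, dt$line), path)
  invisible(path)
}

sam_flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Load aligned read pairs from SAM or BAM
#'
#' Mates are joined into pair records keyed by the unclipped outer template
#' coordinates (leftmost start to rightmost end, 0-based half-open).  Reads
#' whose mate is unmapped or missing are emitted flagged not-proper.
#' Orientation (`"top"` if the first-in-pair mate reads the leftmost end on
#' the forward strand) is defined only for proper pairs, `NA` otherwise.
#'
#' @param path `.sam` or `.bam` file, coordinate sorted.  BAM region queries
#'   require an index (`.bai`) next to the file.
#' @param region Optional `list(rname, start, end)` (0-based half-open);
#'   pairs overlapping the window are returned.
#' @return data.table of pair records, ordered by `(rname, start)`.
#' @export
load_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    reads <- read_bam_records(path, region)
  } else {
    reads <- read_sam_records(path)
  }
  pairs <- pair_records(reads)
  if (!is.null(region) && nrow(pairs)) {
    pairs <- pairs[rname == region$rname & start < region$end &
                     end > region$start]
  }
  setorder(pairs, rname, start, end, qname)
  pairs[]
}

read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.table(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character()))
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:11)
  dt <- data.table(qname = f[[1L]], flag = as.integer(f[[2L]]),
                   rname = f[[3L]], pos = as.integer(f[[4L]]) - 1L,
                   mapq = as.integer(f[[5L]]), cigar = f[[6L]],
                   seq = f[[10L]], qual = f[[11L]])
  if (anyNA(dt$flag)) stop("truncated or malformed SAM record in ", path)
  dt
}

read_bam_records <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package")
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  if (is.null(region)) {
    prm <- Rsamtools::ScanBamParam(what = what)
  } else {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("BAM region queries need an index; run ",
           "Rsamtools::indexBam(\"", path, "\") first")
    prm <- Rsamtools::ScanBamParam(
      what = what,
      which = GenomicRanges::GRanges(region$rname,
                                     IRanges::IRanges(region$start + 1L,
                                                      region$end)))
  }
  b <- Rsamtools::scanBam(path, param = prm)[[1L]]
  data.table(qname = b$qname, flag = b$flag,
             rname = as.character(b$rname), pos = b$pos - 1L,
             mapq = b$mapq, cigar = b$cigar,
             seq = as.character(b$seq), qual = as.character(b$qual))
}

## join mates into pair records
pair_records <- function(reads) {
  if (nrow(reads) == 0L) return(empty_pairs())
  leadclip <- integer(nrow(reads))
  haslead <- grepl("^[0-9]+S", reads$cigar)
  leadclip[haslead] <- as.integer(
    sub("^([0-9]+)S.*$", "\\1", reads$cigar[haslead]))
  reads[, unclip_start := pos - leadclip]
  rw <- cigar_ref_width(reads$cigar)
  tailclip <- integer(nrow(reads))
  hastail <- grepl("[0-9]+S$", reads$cigar)
  tailclip[hastail] <- as.integer(
    sub("^.*?([0-9]+)S$", "\\1", reads$cigar[hastail]))
  reads[, unclip_end := pos + rw + tailclip]
  out <- reads[, {
    if (.N == 2L) {
      o <- order(unclip_start, unclip_end)
      l <- o[1L]; r <- o[2L]
      both_mapped <- !any(sam_flag_bit(flag, 4L)) &&
        !any(sam_flag_bit(flag, 8L))
      prop <- both_mapped && all(sam_flag_bit(flag, 2L))
      ori <- NA_character_
      if (prop) {
        ## first-in-pair mate on the forward strand => top-strand molecule
        first_rev <- sam_flag_bit(flag[sam_flag_bit(flag, 64L)][1L], 16L)
        ori <- if (isTRUE(first_rev)) "bottom" else "top"
      }
      .(rname = rname[l], start = unclip_start[l],
        end = max(unclip_end), orient = ori,
        lpos = pos[l], lcigar = cigar[l], lseq = seq[l], lqual = qual[l],
        rpos = pos[r], rcigar = cigar[r], rseq = seq[r], rqual = qual[r],
        mapq = min(mapq), proper = prop)
    } else {
      .(rname = rname[1L], start = unclip_start[1L], end = unclip_end[1L],
        orient = NA_character_,
        lpos = pos[1L], lcigar = cigar[1L], lseq = seq[1L], lqual = qual[1L],
        rpos = NA_integer_, rcigar = NA_character_, rseq = NA_character_,
        rqual = NA_character_, mapq = mapq[1L], proper = FALSE)
    }
  }, by = qname]
  setcolorder(out, c("qname", "rname", "start", "end", "orient"))
  out
}

#' Load a population allele-frequency table
#'
#' Accepts a minimal VCF (`CHROM POS REF ALT` with `AF=` in INFO;
#' multiallelic rows are split per alternate allele) or a 5-column TSV
#' (`chrom pos ref alt af`, 1-based positions).  Rows with AF outside
#' `[0, 1]` are rejected with a warning naming the count.  Lookup of an
#' absent site returns "unknown" (`NA`), which is distinct from an AF of 0.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return data.table of class `af_table` keyed by
#'   `(chrom, pos, ref, alt)` with 0-based positions and column `af`.
#' @export
load_af_table <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines)) {
      f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:8)
      af_str <- sub("^.*AF=([^;\t]*).*$", "\\1", f[[8L]])
      af_str[!grepl("AF=", f[[8L]])] <- ""
      dt <- data.table(chrom = f[[1L]], pos = as.integer(f[[2L]]) - 1L,
                       ref = f[[4L]], alt = f[[5L]], af_str = af_str)
      ## split multiallelic rows: ALT and AF are parallel comma lists
      dt <- dt[, {
        alts <- strsplit(alt, ",", fixed = TRUE)[[1L]]
        afs <- suppressWarnings(
          as.numeric(strsplit(af_str, ",", fixed = TRUE)[[1L]]))
        length(afs) <- length(alts)
        .(alt = alts, af = afs)
      }, by = .(chrom, pos, ref, rowid = seq_len(nrow(dt)))]
      dt[, rowid := NULL]
    } else {
      dt <- data.table(chrom = character(), pos = integer(),
                       ref = character(), alt = character(), af = numeric())
    }
  } else {
    dt <- fread(path, header = TRUE,
                colClasses = list(character = c(1L, 3L, 4L)))
    setnames(dt, 1:5, c("chrom", "pos", "ref", "alt", "af"))
    dt[, pos := as.integer(pos) - 1L]
    dt[, af := as.numeric(af)]
  }
  bad <- is.na(dt$af) | dt$af < 0 | dt$af > 1
  if (any(bad)) {
    warning(sum(bad), " AF table row(s) rejected (AF missing or outside ",
            "[0, 1])")
    dt <- dt[!bad]
  }
  setkeyv(dt, c("chrom", "pos", "ref", "alt"))
  structure(dt, class = c("af_table", class(dt)))
}

#' Look up population allele frequencies
#'
#' @param af_table An [load_af_table()] result (or the in-memory equivalent).
#' @param chrom,pos,ref,alt Site-allele vectors (0-based positions).
#' @return Numeric AF vector; `NA` means "unknown" (site absent), which
#'   downstream filtering treats differently from an AF of 0.
#' @export
af_lookup <- function(af_table, chrom, pos, ref, alt) {
  q <- data.table(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
  af_table[q, af, on = c("chrom", "pos", "ref", "alt")]
}

#' Write a germline SNP table as a minimal VCF
#'
#' @param snps data.table with `chrom`, `pos` (0-based), `ref`, `alt`, `af`.
#' @param path Output `.vcf` path.
#' @export
write_af_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    paste(snps$chrom, snps$pos + 1L, ".", snps$ref, snps$alt, ".", ".",
          sprintf("AF=%.6g", snps$af), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write variant calls as a minimal VCF
#'
#' @param calls Call table from [call_variants()].
#' @param path Output path.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TKEY,Number=1,Type=String,Description=\"Supporting template\">",
           "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population AF (missing if unknown)\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    af <- if ("population_af" %in% names(calls)) calls$population_af
          else rep(NA_real_, nrow(calls))
    info <- paste0("TKEY=", calls$tkey,
                   fifelse(is.na(af), "", sprintf(";POPAF=%.6g", af)))
    paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt, ".", ".",
          info, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
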