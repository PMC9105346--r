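## Canonical (left-aligned, minimal) representation of variants in VCF-style
## anchored form.  Used both when planting simulated indels and when emitting
## calls, so that truth and calls compare on identical coordinates.

## pos is 0-based; ref/alt are allele strings; refseq the reference sequence.
normalize_variant <- function(pos, ref, alt, refseq) {
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    ## trim shared trailing base, shifting left when an allele would empty
    if ((rn > 1L || an > 1L) &&
        substr(ref, rn, rn) == substr(alt, an, an)) {
      ref <- substr(ref, 1L, rn - 1L)
      alt <- substr(alt, 1L, an - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 0L) {          # cannot shift past the contig start
          b <- substr(refseq, 1L, 1L)
          ref <- paste0(b, ref); alt <- paste0(b, alt)
          break
        }
        b <- substr(refseq, pos, pos)   # base at 0-based pos-1
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
      next
    }
    break
  }
  ## trim shared leading bases while both alleles keep length > 1
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  fifelse(nchar(ref) == nchar(alt), "SNV",
          fifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
}
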