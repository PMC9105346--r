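## Generative simulator for bottleneck duplex libraries from FFPE-like DNA.

#' Simulation parameters
#'
#' Collects every knob of the library simulator with defaults describing an
#' FFPE specimen: short fragments (median 146 bp), heavy single-strand damage
#' dominated by cytosine deamination, strand dropout tuned so that roughly
#' 20% of molecules retain both strands, a sequencing bottleneck of 20,000
#' molecules and PCR amplification routinely exceeding five copies per
#' strand.  Use `preset = "blood"` for a high-quality-DNA profile (longer
#' fragments, low lesion load, ~47% of molecules duplex-formable).
#'
#' @param reference_length Reference length in bases (>= 10 kb).
#' @param snp_density Germline SNPs per Mb placed on the reference; both
#'   common (population AF > 1%) and rare (<= 1%) sites are generated.
#' @param snp_common_fraction Fraction of SNP sites drawn from the common-AF
#'   stratum (AF uniform on (0.01, 0.5]); the rest are rare (AF on
#'   (1e-4, 0.01]).
#' @param somatic_rate_snv,somatic_rate_indel True double-strand somatic
#'   mutations per Mb (single-nucleotide variants / short indels).  Somatic
#'   variants are fully clonal: every overlapping molecule carries them on
#'   both strands.
#' @param lesion_rate Single-strand lesions per Mb of single-stranded
#'   sequence, per strand.
#' @param lesion_ct_fraction Fraction of lesions that are cytosine
#'   deaminations (C>T on the damaged strand, read as G>A from the other
#'   orientation); the remainder are uniform other substitutions.
#' @param fragment_median,fragment_sdlog Median fragment length in bases and
#'   log-normal dispersion (sdlog).
#' @param overhang_mean Mean 5'-overhang length per fragment end, bases;
#'   lengths are geometric on \{0, 1, ...\}, independent between ends.
#' @param strand_dropout_prob Probability that a given strand of a molecule
#'   is unamplifiable (nick/gap model); strands drop independently.
#' @param end_repair_mode `"polymerase"` (fill in 5'-overhangs, copying any
#'   lesion in the filled span onto the new strand -- the classic end-repair
#'   artifact) or `"nuclease"` (single-strand-specific nuclease removes the
#'   overhangs; the template shortens and nothing is copied).
#' @param n_templates Molecules surviving the bottleneck.
#' @param pcr_copies_mean Mean PCR copies per surviving strand; copy numbers
#'   are shifted Poisson, `1 + Poisson(mean - 1)`.
#' @param pcr_error_rate,seq_error_rate Per-base substitution rates applied
#'   per PCR copy and per sequenced read, respectively.
#' @param read_length Read length in bases (paired-end, read-through
#'   truncation when the template is shorter).
#' @param decoy_fraction Fraction of extra defective read pairs injected to
#'   exercise the read filters (soft-clipped, low mapping quality, improper,
#'   high-mismatch; cycled in that order).
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical.
#' @param preset `"ffpe"` (default) or `"blood"`; presets only change
#'   defaults, explicit arguments always win.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(reference_length = 1e6,
                       snp_density = 3000,
                       snp_common_fraction = 0.7,
                       somatic_rate_snv = 20,
                       somatic_rate_indel = 5,
                       lesion_rate = 1000,
                       lesion_ct_fraction = 0.9,
                       fragment_median = 146,
                       fragment_sdlog = 0.185,
                       overhang_mean = 6,
                       strand_dropout_prob = 0.55,
                       end_repair_mode = c("nuclease", "polymerase"),
                       n_templates = 20000,
                       pcr_copies_mean = 8,
                       pcr_error_rate = 1e-5,
                       seq_error_rate = 1e-3,
                       read_length = 150,
                       decoy_fraction = 0,
                       seed = 1L,
                       preset = c("ffpe", "blood")) {
  preset <- match.arg(preset)
  if (preset == "blood") {
    if (missing(fragment_median)) fragment_median <- 213
    if (missing(lesion_rate)) lesion_rate <- 50
    if (missing(strand_dropout_prob)) strand_dropout_prob <- 0.31
  }
  p <- list(reference_length = as.numeric(reference_length),
            snp_density = snp_density,
            snp_common_fraction = snp_common_fraction,
            somatic_rate_snv = somatic_rate_snv,
            somatic_rate_indel = somatic_rate_indel,
            lesion_rate = lesion_rate,
            lesion_ct_fraction = lesion_ct_fraction,
            fragment_median = fragment_median,
            fragment_sdlog = fragment_sdlog,
            overhang_mean = overhang_mean,
            strand_dropout_prob = strand_dropout_prob,
            end_repair_mode = match.arg(end_repair_mode),
            n_templates = as.integer(n_templates),
            pcr_copies_mean = pcr_copies_mean,
            pcr_error_rate = pcr_error_rate,
            seq_error_rate = seq_error_rate,
            read_length = as.integer(read_length),
            decoy_fraction = decoy_fraction,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  rates <- c("snp_density", "somatic_rate_snv", "somatic_rate_indel",
             "lesion_rate", "overhang_mean", "pcr_error_rate",
             "seq_error_rate", "decoy_fraction")
  for (r in rates)
    if (p[[r]] < 0) stop("sim_params: '", r, "' must be >= 0")
  if (p$strand_dropout_prob < 0 || p$strand_dropout_prob >= 1)
    stop("sim_params: 'strand_dropout_prob' must be in [0, 1)")
  if (p$lesion_ct_fraction < 0 || p$lesion_ct_fraction > 1)
    stop("sim_params: 'lesion_ct_fraction' must be in [0, 1]")
  if (p$fragment_median <= 2 * p$overhang_mean)
    stop("sim_params: fragment_median must exceed 2 * overhang_mean")
  if (p$n_templates < 1L) stop("sim_params: 'n_templates' must be >= 1")
  if (p$pcr_copies_mean < 1) stop("sim_params: 'pcr_copies_mean' must be >= 1")
  if (p$read_length < 20L) stop("sim_params: 'read_length' must be >= 20")
  invisible(p)
}

## Deterministic RNG setup shared by the simulator entry points.
sim_seed <- function(seed, stream = 0L) {
  set.seed(as.integer(seed) + stream, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulate a reference sequence with a germline SNP panel
#'
#' Generates a uniform-random reference and a table of germline SNP sites
#' with population allele frequencies drawn from a two-stratum mixture of
#' common (AF > 1%) and rare (AF <= 1%) sites, standing in for a population
#' database such as gnomAD.
#'
#' @param params A [sim_params()] object.
#' @return List of class `sim_reference` with elements `reference`
#'   (`list(name, seq)`) and `snps` (data.table: `chrom`, `pos` 0-based,
#'   `ref`, `alt`, `af`).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  G <- params$reference_length
  if (G < 1e4)
    stop("reference_length must be >= 10 kb (got ", G, ")")
  n_snp_exp <- params$snp_density * G / 1e6
  if (n_snp_exp > G / 10)
    stop("snp_density ", params$snp_density,
         "/Mb cannot be placed on a ", G, " bp reference ",
         "(more than one SNP per 10 bases)")
  sim_seed(params$seed, 0L)
  refv <- sample(BASES[1:4], G, replace = TRUE)
  refseq <- paste(refv, collapse = "")
  n_snp <- stats::rpois(1L, n_snp_exp)
  n_snp <- min(n_snp, G)
  if (n_snp > 0L) {
    pos <- sort(sample.int(G, n_snp) - 1L)
    refb <- refv[pos + 1L]
    altb <- vapply(refb, function(b) sample(setdiff(BASES[1:4], b), 1L),
                   character(1), USE.NAMES = FALSE)
    common <- runif(n_snp) < params$snp_common_fraction
    af <- ifelse(common, runif(n_snp, 0.01, 0.5), runif(n_snp, 1e-4, 0.01))
    snps <- data.table(chrom = "sim1", pos = pos, ref = refb, alt = altb,
                       af = af)
  } else {
    snps <- data.table(chrom = character(), pos = integer(),
                       ref = character(), alt = character(), af = numeric())
  }
  structure(list(reference = list(name = "sim1", seq = refseq), snps = snps),
            class = "sim_reference")
}

## positions (0-based) avoiding `occupied`, uniform on [margin, G-margin)
draw_positions <- function(n, G, occupied, margin = 10L) {
  if (n <= 0L) return(integer())
  pool <- sample.int(G - 2L * margin, min(G - 2L * margin, n * 3L + 20L)) +
    margin - 1L
  pool <- setdiff(pool, occupied)
  head(pool, n)
}

rand_other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES[1:4], x), 1L), character(1),
         USE.NAMES = FALSE)
}

rand_seq <- function(len) {
  vapply(len, function(l) paste(sample(BASES[1:4], l, replace = TRUE),
                                collapse = ""), character(1))
}

## in-place-style single-base patching of a character vector of sequences
patch_seq <- function(seqs, idx, at, base) {
  for (k in seq_along(idx)) {
    i <- idx[k]
    substr(seqs[i], at[k], at[k]) <- base[k]
  }
  seqs
}

#' Simulate a duplex sequencing library
#'
#' Realizes the generative story of bottleneck duplex sequencing of damaged
#' DNA.  Per molecule: a fragment is sampled (log-normal length, uniform
#' placement, random haplotype), germline and clonal somatic variants are
#' applied, single-strand lesions are placed per strand, 5'-overhang lengths
#' are drawn, and then either a polymerase fills the overhangs in (copying
#' overhang lesions onto the opposite strand, creating double-strand
#' artifacts at fragment ends) or a nuclease trims them off (shortening the
#' template).  Each strand then drops out independently with
#' `strand_dropout_prob`; surviving strands are PCR-amplified with shifted
#' Poisson copy numbers, and every copy is sequenced as an aligned read pair
#' with per-copy PCR errors and per-read sequencing errors.  Coordinates are
#' known by construction, so records are emitted pre-aligned.
#'
#' @param reference `list(name, seq)` as produced by [simulate_reference()].
#' @param snps Germline SNP table (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   `af`); genotypes are drawn per site under Hardy-Weinberg equilibrium.
#' @param params A [sim_params()] object.
#' @return List of class `duplex_sim`: `pairs` (aligned pair records, one row
#'   per read pair) and `truth` (ground-truth ledger with `somatic`,
#'   `germline`, `lesions`, `fragments`, `decoys`, `skipped_lesions`).
#' @export
simulate_library <- function(reference, snps, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  refseq <- reference$seq
  chromn <- reference$name
  G <- nchar(refseq)
  refint <- ref_codes(refseq)
  sim_seed(params$seed, 1L)
  snps <- as.data.table(snps)

  ## ---- germline genotypes under HWE ----
  ns <- nrow(snps)
  if (ns > 0L) {
    gt <- stats::rbinom(ns, 2L, snps$af)
    hap1 <- gt == 2L
    hap2 <- gt == 2L
    het <- which(gt == 1L)
    onhap1 <- sample(c(TRUE, FALSE), length(het), replace = TRUE)
    hap1[het[onhap1]] <- TRUE
    hap2[het[!onhap1]] <- TRUE
  } else {
    gt <- integer(); hap1 <- hap2 <- logical()
  }
  germline <- data.table(chrom = chromn, pos = snps$pos, ref = snps$ref,
                         alt = snps$alt, af = snps$af, genotype = gt,
                         hap1_alt = hap1, hap2_alt = hap2)

  ## ---- somatic variants (fully clonal, both strands) ----
  occupied <- snps$pos
  n_snv <- stats::rpois(1L, params$somatic_rate_snv * G / 1e6)
  spos <- draw_positions(n_snv, G, occupied)
  sref <- BASES[refint[spos + 1L]]
  salt <- rand_other_base(sref)
  occupied <- c(occupied, spos)
  somatic <- data.table(chrom = chromn, pos = as.integer(spos), ref = sref,
                        alt = salt, class = rep("SNV", length(spos)))

  n_ind <- stats::rpois(1L, params$somatic_rate_indel * G / 1e6)
  if (n_ind > 0L) {
    ipos <- draw_positions(n_ind, G, occupied)
    n_ind <- length(ipos)
    is_ins <- runif(n_ind) < 0.5
    ilen <- pmin(1L + stats::rgeom(n_ind, 0.6), 4L)
    iref <- ialt <- character(n_ind)
    keep <- rep(TRUE, n_ind)
    for (k in seq_len(n_ind)) {
      p0 <- ipos[k]
      if (is_ins[k]) {
        iref[k] <- substring(refseq, p0 + 1L, p0 + 1L)
        ialt[k] <- paste0(iref[k], rand_seq(ilen[k]))
      } else {
        if (p0 + ilen[k] + 1L > G) { keep[k] <- FALSE; next }
        iref[k] <- substring(refseq, p0 + 1L, p0 + 1L + ilen[k])
        ialt[k] <- substring(refseq, p0 + 1L, p0 + 1L)
      }
      nv <- normalize_variant(p0, iref[k], ialt[k], refseq)
      ipos[k] <- nv$pos; iref[k] <- nv$ref; ialt[k] <- nv$alt
    }
    idt <- data.table(chrom = chromn, pos = as.integer(ipos), ref = iref,
                      alt = ialt,
                      class = ifelse(is_ins, "insertion", "deletion"))[keep]
    ## enforce spacing: no two indels (or indel/SNV) within 10 bp
    setorder(idt, pos)
    if (nrow(idt) > 1L)
      idt <- idt[c(TRUE, diff(pos) > 10L)]
    near_sub <- idt$pos %in%
      unlist(lapply(occupied, function(x) (x - 6L):(x + 6L)))
    idt <- idt[!near_sub]
    somatic <- rbind(somatic, idt)
  }
  setorder(somatic, pos)

  ## ---- fragments ----
  n <- params$n_templates
  Lf <- as.integer(round(stats::rlnorm(n, log(params$fragment_median),
                                       params$fragment_sdlog)))
  Lf <- pmin(pmax(Lf, 40L), 2L * params$read_length, G)
  fstart <- as.integer(floor(runif(n) * (G - Lf + 1L)))
  fend <- fstart + Lf
  hap <- sample.int(2L, n, replace = TRUE)
  if (params$overhang_mean > 0) {
    pg <- 1 / (1 + params$overhang_mean)
    oL <- stats::rgeom(n, pg); oR <- stats::rgeom(n, pg)
  } else {
    oL <- oR <- integer(n)
  }
  maxo <- pmax((Lf - 30L) %/% 2L, 0L)
  oL <- as.integer(pmin(oL, maxo)); oR <- as.integer(pmin(oR, maxo))
  drop_top <- runif(n) < params$strand_dropout_prob
  drop_bot <- runif(n) < params$strand_dropout_prob

  ## pre-repair strand spans: the 5' end of the top strand protrudes on the
  ## left, the 5' end of the bottom strand on the right
  top_s <- fstart;       top_e <- fend - oR
  bot_s <- fstart + oL;  bot_e <- fend

  ## ---- single-strand lesions ----
  nl_top <- stats::rpois(n, params$lesion_rate * pmax(top_e - top_s, 0L) / 1e6)
  nl_bot <- stats::rpois(n, params$lesion_rate * pmax(bot_e - bot_s, 0L) / 1e6)
  les_mol <- c(rep(seq_len(n), nl_top), rep(seq_len(n), nl_bot))
  les_strand <- c(rep("top", sum(nl_top)), rep("bottom", sum(nl_bot)))
  n_les <- length(les_mol)
  skipped <- 0L
  if (n_les > 0L) {
    deam <- runif(n_les) < params$lesion_ct_fraction
    lpos <- integer(n_les); lalt <- character(n_les)
    ok <- rep(TRUE, n_les)
    for (k in seq_len(n_les)) {
      m <- les_mol[k]
      if (les_strand[k] == "top") { s <- top_s[m]; e <- top_e[m] }
      else { s <- bot_s[m]; e <- bot_e[m] }
      if (e <= s) { ok[k] <- FALSE; next }
      if (deam[k]) {
        ## deamination requires a C on the damaged strand: reference C for
        ## the top strand, reference G (bottom-strand C) for the bottom
        want <- if (les_strand[k] == "top") 2L else 3L   # C / G
        cand <- s + which(refint[(s + 1L):e] == want) - 1L
        if (!length(cand)) { skipped <- skipped + 1L; ok[k] <- FALSE; next }
        lpos[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        lalt[k] <- if (les_strand[k] == "top") "T" else "A"
      } else {
        lpos[k] <- s + sample.int(e - s, 1L) - 1L
        lalt[k] <- rand_other_base(BASES[refint[lpos[k] + 1L]])
      }
    }
    lesions <- data.table(mol = les_mol, strand = les_strand, pos = lpos,
                          ref = BASES[refint[lpos + 1L]], alt = lalt)[ok]
    ## drop duplicate hits at the same molecule/strand/position
    lesions <- unique(lesions, by = c("mol", "strand", "pos"))
  } else {
    lesions <- data.table(mol = integer(), strand = character(),
                          pos = integer(), ref = character(),
                          alt = character())
  }
  ## a lesion sitting in a 5'-overhang span lies where only one strand
  ## exists; the polymerase fill-in copies it to the other strand
  lesions[, copied := (strand == "top" & pos < fstart[mol] + oL[mol]) |
            (strand == "bottom" & pos >= fend[mol] - oR[mol])]
  polymerase <- params$end_repair_mode == "polymerase"
  if (polymerase) {
    ts <- fstart; te <- fend
    lesions[, removed := FALSE]
  } else {
    ts <- fstart + oL; te <- fend - oR
    lesions[, removed := copied]      # overhang lesions are nucleased away
    lesions[, copied := FALSE]
  }
  Lt <- te - ts

  ## ---- molecule sequences ----
  base <- substring(refseq, ts + 1L, te)
  ## germline carrier substitutions
  if (ns > 0L) {
    mols <- data.table(ms = ts, me = te, mol = seq_len(n))
    setkey(mols, ms, me)
    gv <- data.table(pos = snps$pos, p2 = snps$pos, alt = snps$alt,
                     hap1_alt = hap1, hap2_alt = hap2)
    ov <- foverlaps(gv, mols, by.x = c("pos", "p2"),
                    by.y = c("ms", "me"), type = "within", nomatch = NULL)
    ## 'within' treats intervals as closed; drop pos == me (half-open end)
    ov <- ov[pos < me]
    ov <- ov[(hap[mol] == 1L & hap1_alt) | (hap[mol] == 2L & hap2_alt)]
    if (nrow(ov))
      base <- patch_seq(base, ov$mol, ov$pos - ts[ov$mol] + 1L, ov$alt)
  }
  ## somatic SNVs (clonal: all molecules)
  ssnv <- somatic[class == "SNV"]
  if (nrow(ssnv)) {
    mols <- data.table(ms = ts, me = te, mol = seq_len(n))
    setkey(mols, ms, me)
    sv <- data.table(pos = ssnv$pos, p2 = ssnv$pos, alt = ssnv$alt)
    ov <- foverlaps(sv, mols, by.x = c("pos", "p2"),
                    by.y = c("ms", "me"), type = "within", nomatch = NULL)
    ov <- ov[pos < me]
    if (nrow(ov))
      base <- patch_seq(base, ov$mol, ov$pos - ts[ov$mol] + 1L, ov$alt)
  }
  seq_top <- base
  seq_bot <- base
  ## lesions: copied ones hit both strands, the rest only their own strand
  if (nrow(lesions)) {
    act <- lesions[removed == FALSE]
    if (nrow(act)) {
      both <- act[copied == TRUE]
      if (nrow(both)) {
        seq_top <- patch_seq(seq_top, both$mol, both$pos - ts[both$mol] + 1L,
                             both$alt)
        seq_bot <- patch_seq(seq_bot, both$mol, both$pos - ts[both$mol] + 1L,
                             both$alt)
      }
      tt <- act[copied == FALSE & strand == "top"]
      if (nrow(tt))
        seq_top <- patch_seq(seq_top, tt$mol, tt$pos - ts[tt$mol] + 1L,
                             tt$alt)
      bb <- act[copied == FALSE & strand == "bottom"]
      if (nrow(bb))
        seq_bot <- patch_seq(seq_bot, bb$mol, bb$pos - ts[bb$mol] + 1L,
                             bb$alt)
    }
  }
  ## somatic indels (clonal, both strands; applied only when fully inside)
  cigars <- paste0(Lt, "M")
  mol_len <- Lt
  sind <- somatic[class != "SNV"]
  if (nrow(sind)) {
    ev_mol <- list()
    for (j in seq_len(nrow(sind))) {
      p0 <- sind$pos[j]; rl <- nchar(sind$ref[j])
      hit <- which(ts < p0 & p0 + rl <= te - 1L)
      for (m in hit)
        ev_mol[[as.character(m)]] <- c(ev_mol[[as.character(m)]], j)
    }
    for (mc in names(ev_mol)) {
      m <- as.integer(mc)
      js <- ev_mol[[mc]]
      ## apply right-to-left so earlier coordinates stay valid
      for (j in js[order(sind$pos[js], decreasing = TRUE)]) {
        seq_top[m] <- apply_one_indel(seq_top[m], ts[m], sind$pos[j],
                                      sind$ref[j], sind$alt[j])$seq
        seq_bot[m] <- apply_one_indel(seq_bot[m], ts[m], sind$pos[j],
                                      sind$ref[j], sind$alt[j])$seq
      }
      cigars[m] <- build_indel_cigar(ts[m], te[m],
                                     sind[js[order(sind$pos[js])]])
      mol_len[m] <- nchar(seq_top[m])
    }
  }

  ## ---- PCR copies and read pairs ----
  strands <- rbind(
    data.table(mol = seq_len(n), strand = "top", keep = !drop_top),
    data.table(mol = seq_len(n), strand = "bottom", keep = !drop_bot))
  setorder(strands, mol, -strand)     # top before bottom, per molecule
  copies <- integer(nrow(strands))
  copies[strands$keep] <- 1L +
    stats::rpois(sum(strands$keep), max(params$pcr_copies_mean - 1, 0))
  strands[, copies := copies]
  copies_top <- strands[strand == "top", copies[order(mol)]]
  copies_bot <- strands[strand == "bottom", copies[order(mol)]]

  surv <- strands[keep == TRUE & copies > 0L]
  pairs_idx <- surv[rep(seq_len(.N), copies)]
  pairs_idx[, copy := seq_len(.N), by = .(mol, strand)]
  np <- nrow(pairs_idx)

  if (np > 0L) {
    pm <- pairs_idx$mol
    cs <- ifelse(pairs_idx$strand == "top", seq_top[pm], seq_bot[pm])
    ml <- mol_len[pm]
    ## PCR errors, independent per copy
    if (params$pcr_error_rate > 0) {
      ne <- stats::rbinom(np, ml, params$pcr_error_rate)
      for (i in which(ne > 0L)) {
        at <- sample.int(ml[i], ne[i])
        for (a in at)
          substr(cs[i], a, a) <- rand_other_base(substr(cs[i], a, a))
      }
    }
    w <- pmin(params$read_length, ml)
    lseq <- substring(cs, 1L, w)
    rseq <- substring(cs, ml - w + 1L, ml)
    ## sequencing errors, independent per read
    if (params$seq_error_rate > 0) {
      nel <- stats::rbinom(np, w, params$seq_error_rate)
      for (i in which(nel > 0L)) {
        at <- sample.int(w[i], nel[i])
        for (a in at)
          substr(lseq[i], a, a) <- rand_other_base(substr(lseq[i], a, a))
      }
      ner <- stats::rbinom(np, w, params$seq_error_rate)
      for (i in which(ner > 0L)) {
        at <- sample.int(w[i], ner[i])
        for (a in at)
          substr(rseq[i], a, a) <- rand_other_base(substr(rseq[i], a, a))
      }
    }
    ## per-read alignments
    lcig <- paste0(w, "M")
    rcig <- lcig
    lpos <- ts[pm]
    rpos <- te[pm] - w
    complex_mol <- which(cigars != paste0(Lt, "M"))
    if (length(complex_mol)) {
      idxc <- which(pm %in% complex_mol)
      for (i in idxc) {
        m <- pm[i]
        ops <- parse_cigar(cigars[m])
        sl <- slice_cigar(ops, 0L, w[i])
        lcig[i] <- sl$cigar; lpos[i] <- ts[m] + sl$ref_off
        sr <- slice_cigar(ops, ml[i] - w[i], ml[i])
        rcig[i] <- sr$cigar; rpos[i] <- ts[m] + sr$ref_off
      }
    }
    qual <- vapply(w, function(x) strrep("F", x), character(1))  # Phred 37
    pairs <- data.table(
      qname = sprintf("m%07d_%s_c%03d", pairs_idx$mol,
                      ifelse(pairs_idx$strand == "top", "t", "b"),
                      pairs_idx$copy),
      rname = chromn, start = ts[pm], end = te[pm],
      orient = pairs_idx$strand,
      lpos = lpos, lcigar = lcig, lseq = lseq, lqual = qual,
      rpos = rpos, rcigar = rcig, rseq = rseq, rqual = qual,
      mapq = 60L, proper = TRUE)
  } else {
    pairs <- empty_pairs()
  }

  ## ---- decoy reads with known defects ----
  decoys <- data.table(qname = character(), defect = character())
  if (params$decoy_fraction > 0 && np > 0L) {
    nd <- ceiling(params$decoy_fraction * np)
    src <- sample.int(np, nd, replace = TRUE)
    types <- rep(c("soft_clip", "low_mapq", "improper", "high_mismatch"),
                 length.out = nd)
    dp <- pairs[src]
    dp[, qname := sprintf("decoy%05d_%s", seq_len(nd), types)]
    for (k in seq_len(nd)) {
      wk <- nchar(dp$lseq[k])
      if (types[k] == "soft_clip") {
        ncl <- min(8L, wk - 10L)
        dp[k, `:=`(lcigar = paste0(ncl, "S", wk - ncl, "M"),
                   lpos = lpos + ncl)]
      } else if (types[k] == "low_mapq") {
        dp[k, mapq := 5L]
      } else if (types[k] == "improper") {
        dp[k, proper := FALSE]
      } else {
        sq <- dp$lseq[k]
        at <- sample.int(wk, min(15L, wk))
        for (a in at) substr(sq, a, a) <- rand_other_base(substr(sq, a, a))
        dp[k, lseq := sq]
      }
    }
    decoys <- data.table(qname = dp$qname, defect = types)
    pairs <- rbind(pairs, dp)
  }
  setorder(pairs, rname, start, end, qname)

  fragments <- data.table(
    mol = seq_len(n), chrom = chromn, start = ts, end = te,
    raw_start = fstart, raw_end = fend,
    overhang_left = oL, overhang_right = oR, hap = hap,
    drop_top = drop_top, drop_bot = drop_bot,
    copies_top = copies_top, copies_bot = copies_bot,
    n_copied_lesions = if (nrow(lesions))
      lesions[, sum(copied), by = mol][match(seq_len(n), mol), fifelse(is.na(V1), 0L, as.integer(V1))]
    else 0L)

  structure(list(
    pairs = pairs,
    truth = list(somatic = somatic, germline = germline, lesions = lesions,
                 fragments = fragments, decoys = decoys,
                 skipped_lesions = skipped, params = params),
    reference = reference), class = "duplex_sim")
}

empty_pairs <- function() {
  data.table(qname = character(), rname = character(), start = integer(),
             end = integer(), orient = character(), lpos = integer(),
             lcigar = character(), lseq = character(), lqual = character(),
             rpos = integer(), rcigar = character(), rseq = character(),
             rqual = character(), mapq = integer(), proper = logical())
}

## Apply one anchored indel (VCF-style ref/alt) to a molecule sequence that
## currently matches the reference over [ms, ms + nchar(seq)).  Only valid
## before any other indel shifted coordinates at or left of pos -- the
## simulator enforces >10 bp spacing between indels so edits can be applied
## right-to-left safely.
apply_one_indel <- function(seq, ms, pos, ref, alt) {
  rel <- pos - ms + 1L                    # 1-based anchor within molecule
  before <- substr(seq, 1L, rel - 1L + 1L)  # through the anchor base
  after <- substr(seq, rel + nchar(ref), nchar(seq))
  list(seq = paste0(before, substr(alt, 2L, nchar(alt)), after))
}

## Molecule CIGAR for a set of anchored indel events (sorted by position,
## mutually spaced by construction) on the template [ms, me).
build_indel_cigar <- function(ms, me, events) {
  pieces <- character(0)
  prev <- ms
  for (j in seq_len(nrow(events))) {
    p0 <- events$pos[j]
    mlen <- p0 + 1L - prev              # reference bases through the anchor
    pieces <- c(pieces, paste0(mlen, "M"))
    if (nchar(events$alt[j]) > nchar(events$ref[j])) {
      pieces <- c(pieces, paste0(nchar(events$alt[j]) - 1L, "I"))
      prev <- p0 + 1L
    } else {
      dlen <- nchar(events$ref[j]) - 1L
      pieces <- c(pieces, paste0(dlen, "D"))
      prev <- p0 + 1L + dlen
    }
  }
  if (me - prev > 0L) pieces <- c(pieces, paste0(me - prev, "M"))
  paste0(pieces, collapse = "")
}
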