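test_that("parameter validation enforces the stated invariants", {
  expect_error(sim_params(lesion_rate = -1), "lesion_rate")
  expect_error(sim_params(fragment_median = 10, overhang_mean = 6),
               "overhang_mean")
  expect_error(sim_params(n_templates = 0), "n_templates")
  expect_error(sim_params(strand_dropout_prob = 1.2), "strand_dropout_prob")
  expect_error(simulate_reference(sim_params(reference_length = 5e3)),
               "10 kb")
  expect_error(simulate_reference(sim_params(reference_length = 1e4,
                                             snp_density = 2e5)),
               "snp_density")
})

test_that("simulate_reference places SNPs at the requested density with valid AFs", {
  p <- sim_params(reference_length = 1e6, snp_density = 1000, seed = 5)
  sr <- simulate_reference(p)
  expect_equal(nchar(sr$reference$seq), 1e6)
  ## ~1000 rows (Poisson, 5 SD tolerance)
  expect_gt(nrow(sr$snps), 1000 - 5 * sqrt(1000))
  expect_lt(nrow(sr$snps), 1000 + 5 * sqrt(1000))
  expect_true(all(sr$snps$af > 0 & sr$snps$af <= 1))
  expect_true(any(sr$snps$af > 0.01) && any(sr$snps$af <= 0.01))
  ## alleles consistent with the sequence
  idx <- sample(nrow(sr$snps), 50)
  expect_identical(substring(sr$reference$seq, sr$snps$pos[idx] + 1,
                             sr$snps$pos[idx] + 1), sr$snps$ref[idx])
  expect_true(all(sr$snps$ref != sr$snps$alt))
})

test_that("zero SNP density yields an empty table", {
  sr <- simulate_reference(sim_params(reference_length = 2e4,
                                      snp_density = 0, seed = 1))
  expect_identical(nrow(sr$snps), 0L)
})

test_that("fixed seed gives byte-identical reference and library output", {
  p <- sim_params(reference_length = 2e4, snp_density = 500,
                  n_templates = 100, seed = 7)
  a <- simulate_reference(p)
  b <- simulate_reference(p)
  expect_identical(a$reference$seq, b$reference$seq)
  expect_identical(a$snps, b$snps)
  la <- simulate_library(a$reference, a$snps, p)
  lb <- simulate_library(b$reference, b$snps, p)
  expect_identical(la$pairs, lb$pairs)
  expect_identical(la$truth$fragments, lb$truth$fragments)
  expect_identical(la$truth$lesions, lb$truth$lesions)
  ## and byte-identical FASTA on disk
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(a$reference, f1); write_fasta(b$reference, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("noise-free simulation emits reads identical to the reference", {
  s <- run_quick_sim(snp_density = 0, somatic_rate_snv = 0,
                     somatic_rate_indel = 0, lesion_rate = 0,
                     pcr_error_rate = 0, seq_error_rate = 0,
                     strand_dropout_prob = 0, pcr_copies_mean = 8,
                     n_templates = 60)
  pr <- s$lib$pairs
  expect_gt(nrow(pr), 60)
  expect_identical(pr$lseq,
                   substring(s$ref$seq, pr$lpos + 1, pr$lpos + nchar(pr$lseq)))
  expect_identical(pr$rseq,
                   substring(s$ref$seq, pr$rpos + 1, pr$rpos + nchar(pr$rseq)))
})

test_that("reads carry the genotype-bearing haplotype", {
  ## no noise, germline SNPs only: every read base must match its molecule
  ## haplotype (reference + carried alleles), exactly
  s <- run_quick_sim(snp_density = 3000, somatic_rate_snv = 0,
                     somatic_rate_indel = 0, lesion_rate = 0,
                     pcr_error_rate = 0, seq_error_rate = 0,
                     strand_dropout_prob = 0, n_templates = 80, seed = 9)
  fr <- s$lib$truth$fragments
  germ <- s$lib$truth$germline
  pr <- s$lib$pairs
  mol_of <- as.integer(sub("^m0*([0-9]+)_.*$", "\\1", pr$qname))
  for (i in seq_len(nrow(pr))) {
    m <- mol_of[i]
    hap <- fr$hap[m]
    expected <- substr(s$ref$seq, fr$start[m] + 1, fr$end[m])
    carr <- germ[pos >= fr$start[m] & pos < fr$end[m] &
                   ((hap == 1 & hap1_alt) | (hap == 2 & hap2_alt))]
    if (nrow(carr)) {
      for (k in seq_len(nrow(carr))) {
        rel <- carr$pos[k] - fr$start[m] + 1L
        substr(expected, rel, rel) <- carr$alt[k]
      }
    }
    w <- nchar(pr$lseq[i])
    expect_identical(pr$lseq[i], substr(expected, 1, w))
    L <- nchar(expected)
    expect_identical(pr$rseq[i], substr(expected, L - w + 1, L))
  }
})

test_that("nuclease vs polymerase at the same seed differ only near fragment ends", {
  base <- quick_sim_config(pcr_error_rate = 0, seq_error_rate = 0,
                           somatic_rate_indel = 0, n_templates = 150,
                           lesion_rate = 3000, seed = 21)
  pn <- do.call(sim_params, c(base, list(end_repair_mode = "nuclease")))
  pp <- do.call(sim_params, c(base, list(end_repair_mode = "polymerase")))
  srn <- simulate_reference(pn)
  ln <- simulate_library(srn$reference, srn$snps, pn)
  lp <- simulate_library(srn$reference, srn$snps, pp)
  fn <- ln$truth$fragments; fp <- lp$truth$fragments
  ## identical molecule sampling
  expect_identical(fn$raw_start, fp$raw_start)
  expect_identical(fn$raw_end, fp$raw_end)
  expect_identical(fn$overhang_left, fp$overhang_left)
  expect_identical(fn$hap, fp$hap)
  expect_identical(ln$truth$lesions$pos, lp$truth$lesions$pos)
  ## spans differ exactly by the overhangs
  expect_identical(fp$start, fn$start - fn$overhang_left)
  expect_identical(fp$end, fn$end + fn$overhang_right)
  ## for blunt molecules (no overhang) the emitted reads are identical
  blunt <- fn[overhang_left == 0 & overhang_right == 0, mol]
  qn <- ln$pairs[, as.integer(sub("^m0*([0-9]+)_.*$", "\\1", qname))]
  qp <- lp$pairs[, as.integer(sub("^m0*([0-9]+)_.*$", "\\1", qname))]
  a <- ln$pairs[qn %in% blunt][order(qname)]
  b <- lp$pairs[qp %in% blunt][order(qname)]
  expect_identical(a$lseq, b$lseq)
  expect_identical(a$rseq, b$rseq)
})

test_that("strand dropout matches its closed-form duplex-formable fraction", {
  ## per-strand dropout 0.55 on both strands independently -> both present
  ## with probability 0.45^2 = 0.2025
  s <- run_quick_sim(strand_dropout_prob = 0.55, n_templates = 2000,
                     pcr_copies_mean = 2, seed = 13)
  fr <- s$lib$truth$fragments
  obs <- fr[, mean(!drop_top & !drop_bot)]
  p0 <- 0.45^2
  sd3 <- 3 * sqrt(p0 * (1 - p0) / nrow(fr))
  expect_lt(abs(obs - p0), sd3)
  ## no reads from a dropped strand
  pr <- s$lib$pairs
  mol_of <- as.integer(sub("^m0*([0-9]+)_.*$", "\\1", pr$qname))
  dropped_top <- fr[drop_top == TRUE, mol]
  expect_false(any(pr$orient == "top" & mol_of %in% dropped_top))
})

test_that("duplex-formable fraction is monotone in strand dropout", {
  fracs <- vapply(c(0.1, 0.4, 0.7), function(d) {
    s <- run_quick_sim(strand_dropout_prob = d, n_templates = 600,
                       pcr_copies_mean = 2, seed = 31)
    s$lib$truth$fragments[, mean(!drop_top & !drop_bot)]
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("read-through truncation handles fragments shorter than the read length", {
  s <- run_quick_sim(read_length = 300, fragment_median = 100,
                     n_templates = 50, seed = 3)
  pr <- s$lib$pairs
  expect_true(all(nchar(pr$lseq) <= 300))
  expect_identical(nchar(pr$lseq), pr$end - pr$start)  # full read-through
})

test_that("copied-lesion bookkeeping matches the overhang spans", {
  s <- run_quick_sim(end_repair_mode = "polymerase", lesion_rate = 5000,
                     n_templates = 300, seed = 17)
  les <- s$lib$truth$lesions
  fr <- s$lib$truth$fragments
  cop <- les[copied == TRUE]
  expect_gt(nrow(cop), 0)
  for (i in seq_len(nrow(cop))) {
    m <- cop$mol[i]
    inleft <- cop$pos[i] < fr$raw_start[m] + fr$overhang_left[m]
    inright <- cop$pos[i] >= fr$raw_end[m] - fr$overhang_right[m]
    expect_true(inleft || inright)
  }
  ## nuclease mode at the same seed removes exactly those events
  base <- quick_sim_config(end_repair_mode = "nuclease", lesion_rate = 5000,
                           n_templates = 300, seed = 17)
  pn <- do.call(sim_params, base)
  srn <- simulate_reference(pn)
  ln <- simulate_library(srn$reference, srn$snps, pn)
  expect_identical(ln$truth$lesions[removed == TRUE, .(mol, pos)],
                   cop[, .(mol, pos)])
})
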