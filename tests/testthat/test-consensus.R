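ref <- fixture_ref(len = 400, seed = 101)

test_that("grouping is exact-coordinate with per-orientation families", {
  p1 <- make_pair(ref, 100, 250, orient = "top", qname = "a")
  p2 <- make_pair(ref, 100, 250, orient = "bottom", qname = "b")
  p3 <- make_pair(ref, 101, 250, orient = "top", qname = "c")
  g <- group_templates(rbind(p1, p2, p3))
  expect_equal(nrow(g$templates), 2L)     # 1-base shift is a new template
  expect_equal(g$templates[tkey == "fix1:100-250", n_families], 2L)
  expect_equal(nrow(g$families), 3L)
  expect_true(all(g$families$n_members == 1L))
})

test_that("families below min_copies are rejected; five copies suffice", {
  fam4 <- make_family(ref, 50, 200, 4)
  fam5 <- make_family(ref, 50, 200, 5)
  r4 <- build_strand_consensus(fam4, consensus_config())
  r5 <- build_strand_consensus(fam5, consensus_config())
  expect_identical(r4$status, "below_min_copies")
  expect_identical(nrow(r4$calls), 0L)
  expect_identical(r5$status, "ok")
  ## consensus equals the copy over the whole template
  expect_identical(nrow(r5$calls), 150L)
  expect_identical(paste(r5$calls[order(off), tok], collapse = ""),
                   substr(ref$seq, 51, 200))
})

test_that("agreement threshold arbitrates discordant copies", {
  ## 6 copies, one with an error at one site: 5/6 = 0.83 >= 0.8 -> called
  clean <- make_family(ref, 50, 200, 5)
  mut <- make_pair(ref, 50, 200, qname = "err",
                   subs = setNames(list("A"), "120"))
  if (substr(ref$seq, 121, 121) == "A")
    mut <- make_pair(ref, 50, 200, qname = "err",
                     subs = setNames(list("C"), "120"))
  fam <- rbind(clean, mut)
  r <- build_strand_consensus(fam, consensus_config())
  expect_identical(r$calls[off == 120, tok], substr(ref$seq, 121, 121))
  ## at min_agreement 0.9 the site is undetermined, the rest still called
  r9 <- build_strand_consensus(fam, consensus_config(min_agreement = 0.9))
  expect_identical(nrow(r9$calls[off == 120]), 0L)
  expect_identical(nrow(r9$calls), 149L)
})

test_that("intra-pair mate conflicts void that copy's vote", {
  fam <- make_family(ref, 50, 170, 5)   # read-through: mates overlap fully
  ## corrupt one mate of one copy at one site: that copy abstains there,
  ## leaving 4 votes -> below min_copies -> undetermined
  b <- substr(ref$seq, 101, 101)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(fam$lseq[1], 51, 51) <- alt
  r <- build_strand_consensus(fam, consensus_config())
  expect_identical(nrow(r$calls[off == 100]), 0L)
  expect_identical(nrow(r$calls), 119L)
})

test_that("duplex merge keeps only concordant both-strand positions", {
  top <- build_strand_consensus(make_family(ref, 50, 200, 5, orient = "top"),
                                consensus_config())
  bot <- build_strand_consensus(
    make_family(ref, 50, 200, 5, orient = "bottom", qprefix = "bot"),
    consensus_config())
  d <- merge_duplex(top, bot)
  expect_identical(d$duplex_length, 150L)
  ## a single-strand lesion site (discordant between strands) is undetermined
  lesion <- setNames(list(if (substr(ref$seq, 121, 121) == "T") "A" else "T"),
                     "120")
  bot_lesion <- build_strand_consensus(
    make_family(ref, 50, 200, 5, orient = "bottom", qprefix = "les",
                subs = lesion),
    consensus_config())
  d2 <- merge_duplex(top, bot_lesion)
  expect_identical(d2$duplex_length, 149L)
  expect_identical(nrow(d2$calls[off == 120]), 0L)
  ## one strand rejected (4 copies) -> nothing duplex-called
  bot4 <- build_strand_consensus(
    make_family(ref, 50, 200, 4, orient = "bottom", qprefix = "b4"),
    consensus_config())
  d3 <- merge_duplex(top, bot4)
  expect_identical(d3$duplex_length, 0L)
  ## mismatched template keys error
  other <- build_strand_consensus(
    make_family(ref, 60, 210, 5, orient = "bottom", qprefix = "oth"),
    consensus_config())
  expect_error(merge_duplex(top, other), "different templates")
})

test_that("undetermined-on-one-strand positions never reach the duplex", {
  ## mask one strand's terminal columns via end_trim: the duplex shrinks
  top <- build_strand_consensus(make_family(ref, 50, 170, 5), end_trim = 0)
  bot <- build_strand_consensus(
    make_family(ref, 50, 170, 5, orient = "bottom", qprefix = "b"),
    end_trim = 10)
  d <- merge_duplex(top, bot)
  expect_lt(d$duplex_length, 120L)
  expect_identical(nrow(d$calls[off < 60]), 0L)
})

test_that("brute-force oracle reproduces consensus and merge on hand families", {
  ## 20 families covering: clean, below-min-copies, contested sites,
  ## intra-pair conflicts, deletions, masked ends
  del_cig <- "30M4D66M"    # 100-wide template with a 4-base deletion
  del_seq <- paste0(substr(ref$seq, 101, 130), substr(ref$seq, 135, 200))
  cases <- list()
  set.seed(202)
  for (i in 1:6) {                      # clean families, varying size
    cases[[i]] <- make_family(ref, 20 + i, 160 + i, n = i + 2,
                              qprefix = paste0("cl", i))
  }
  for (i in 7:10) {                     # one discordant copy
    b <- substr(ref$seq, 81 + i, 81 + i)
    fam <- rbind(
      make_family(ref, 40, 180, n = i - 2, qprefix = paste0("ds", i)),
      make_pair(ref, 40, 180, qname = paste0("ds", i, "_x"),
                subs = setNames(list(setdiff(c("A", "C", "G", "T"), b)[1]),
                                as.character(80 + i))))
    cases[[i]] <- fam
  }
  for (i in 11:14) {                    # deletion families
    cases[[i]] <- make_family(ref, 100, 200, n = i - 5,
                              qprefix = paste0("dl", i),
                              mol_seq = del_seq, cigar = del_cig)
  }
  for (i in 15:17) {                    # mate-conflict families
    fam <- make_family(ref, 60, 170, n = i - 9, qprefix = paste0("mc", i))
    substr(fam$lseq[1], 21, 21) <-
      setdiff(c("A", "C", "G", "T"), substr(fam$lseq[1], 21, 21))[1]
    cases[[i]] <- fam
  }
  for (i in 18:20) {                    # random mutation sprinkle
    fam <- make_family(ref, 200, 330, n = 7, qprefix = paste0("rn", i))
    for (j in 1:5) {
      row <- sample(7, 1); at <- sample(130, 1)
      substr(fam$lseq[row], at, at) <- sample(c("A", "C", "G", "T"), 1)
      substr(fam$rseq[row], at, at) <- sample(c("A", "C", "G", "T"), 1)
    }
    cases[[i]] <- fam
  }
  for (trim in c(0L, 5L)) {
    for (fam in cases) {
      got <- build_strand_consensus(fam, consensus_config(),
                                    end_trim = trim)
      exp <- oracle_family_consensus(fam, 5, 0.8, end_trim = trim)
      expect_identical(got$status, exp$status)
      expect_identical(as.data.frame(got$calls[order(off), .(off, tok)]),
                       as.data.frame(exp$calls[order(off), .(off, tok)]))
    }
  }
  ## duplex merge equivalence on paired orientations of the same cases
  for (i in c(1, 4, 8, 12, 19)) {
    fam_t <- copy(cases[[i]]); fam_t[, orient := "top"]
    fam_b <- copy(cases[[min(i + 1, 20)]])
    fam_b[, `:=`(orient = "bottom", start = fam_t$start[1],
                 end = fam_t$end[1])]
    if (nrow(fam_b) >= 1) {
      fam_b[, `:=`(lpos = fam_t$lpos[1], rpos = fam_t$rpos[1])]
      got <- merge_duplex(
        build_strand_consensus(fam_t, consensus_config()),
        build_strand_consensus(fam_b, consensus_config()))
      exp <- oracle_merge(oracle_family_consensus(fam_t, 5, 0.8),
                          oracle_family_consensus(fam_b, 5, 0.8))
      expect_identical(as.data.frame(got$calls[order(off), .(off, tok)]),
                       as.data.frame(exp[order(off), .(off, tok)]))
    }
  }
})

test_that("duplex_fraction covers ideal, rejected and empty cases", {
  ## ideal: both strands, 5 copies each
  fam_t <- make_family(ref, 50, 200, 5, orient = "top")
  fam_b <- make_family(ref, 50, 200, 5, orient = "bottom", qprefix = "b")
  g <- group_templates(rbind(fam_t, fam_b))
  cs <- duplexffpe:::build_consensus_all(g, ref, consensus_config())
  d <- duplexffpe:::merge_duplexes(cs, g)
  expect_equal(duplex_fraction(g, d)$fraction, 1)
  ## no family reaches 5 copies -> fraction 0
  g2 <- group_templates(rbind(make_family(ref, 50, 200, 3),
                              make_family(ref, 50, 200, 3,
                                          orient = "bottom", qprefix = "b")))
  cs2 <- duplexffpe:::build_consensus_all(g2, ref, consensus_config())
  d2 <- duplexffpe:::merge_duplexes(cs2, g2)
  expect_equal(duplex_fraction(g2, d2)$fraction, 0)
  ## zero templates: flagged undefined, no division error
  g0 <- group_templates(make_family(ref, 1, 2, 1)[0])
  df0 <- duplex_fraction(g0, d2)
  expect_true(df0$undefined)
  expect_true(is.na(df0$fraction))
})

test_that("raising min_copies never increases duplex template count", {
  s <- run_quick_sim(n_templates = 200, pcr_copies_mean = 5, seed = 77)
  fl <- filter_pairs(s$lib$pairs, filter_config(), s$ref)
  g <- group_templates(fl$pass)
  counts <- vapply(c(1L, 3L, 5L, 7L), function(mc) {
    cs <- duplexffpe:::build_consensus_all(
      g, s$ref, consensus_config(min_copies = mc), end_trim = 5L)
    d <- duplexffpe:::merge_duplexes(cs, g)
    nrow(d$templates)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unique template count matches the truth ledger", {
  s <- run_quick_sim(n_templates = 400, strand_dropout_prob = 0,
                     pcr_copies_mean = 8, seed = 55)
  fl <- filter_pairs(s$lib$pairs, filter_config(), s$ref)
  g <- group_templates(fl$pass)
  truth_keys <- s$lib$truth$fragments[, uniqueN(paste0(start, "-", end))]
  expect_equal(nrow(g$templates), truth_keys)
  ## collisions are a known, small error mode
  expect_gt(truth_keys / 400, 0.98)
})
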