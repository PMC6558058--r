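test_that("Wallace rule melting temperatures", {
  expect_equal(wallace_tm(paste(rep(c("G", "A"), 10), collapse = "")), 60)
  expect_equal(wallace_tm(strrep("A", 10)), 20)
  set.seed(51)
  s <- random_dna(1, 25)
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_equal(wallace_tm(s),
               4 * (counts[["G"]] + counts[["C"]]) +
                 2 * (counts[["A"]] + counts[["T"]]))
  expect_error(wallace_tm("ACGN"), "ambiguity")
})

test_that("candidate enumeration slides windows over conserved regions", {
  set.seed(52)
  target <- random_dna(1, 100)
  cand <- enumerate_candidates(target, lengths = 20, step = 1)
  expect_equal(nrow(cand), 81)  # 100 - 20 + 1
  expect_equal(cand$target_start, 0:80)
  expect_equal(cand$sequence[1],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(target, 1, 20)))))
  # identical targets enumerate the same candidates as one
  expect_equal(enumerate_candidates(c(target, target), lengths = 20), cand)
  # one mismatching position excludes every window overlapping it
  variant <- target
  pos <- 50
  substr(variant, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(target, pos, pos))[1]
  cand2 <- enumerate_candidates(c(target, variant), lengths = 20)
  overlapping <- (pos - 20):(pos - 1)  # 0-based starts covering position 50
  expect_true(all(!cand2$target_start %in% overlapping))
  expect_setequal(cand2$target_start, setdiff(0:80, overlapping))
  expect_warning(enumerate_candidates(c("AAAAA", "CCCCC"), lengths = 5),
                 "no conserved window")
  expect_error(enumerate_candidates(c("ACGT", "ACGTA"), lengths = 4),
               "equal length")
})

test_that("off-target counting matches a brute-force Hamming scan", {
  set.seed(53)
  # planted verbatim occurrences count sequences, not sites
  probe <- random_dna(1, 10)
  db <- random_dna(10, 60)
  db[2] <- paste0(substr(db[2], 1, 10), probe, probe, substr(db[2], 31, 60))
  db[5] <- paste0(probe, substr(db[5], 11, 60))
  db[8] <- paste0(substr(db[8], 1, 25), probe, substr(db[8], 36, 60))
  expect_gte(count_offtarget(probe, db, 0), 3)
  expect_equal(count_offtarget(probe, db, 0), hamming_hits(probe, db, 0))
  expect_equal(count_offtarget(probe, character(0), 0), 0L)

  # a 2-substitution variant is found at budget 2 but not 0
  p2 <- random_dna(1, 12)
  v <- p2
  substr(v, 3, 3) <- setdiff(c("A","C","G","T"), substr(p2, 3, 3))[1]
  substr(v, 9, 9) <- setdiff(c("A","C","G","T"), substr(p2, 9, 9))[1]
  one <- paste0(random_dna(1, 20), v, random_dna(1, 20))
  expect_equal(count_offtarget(p2, one, 2), 1L)
  expect_equal(count_offtarget(p2, one, 0), 0L)

  # random probe/database pairs against the independent scanner
  for (i in 1:60) {
    pl <- sample(6:12, 1)
    probe <- random_dna(1, pl)
    db <- random_dna(sample(3:12, 1), sample(pl:40, 1))
    for (mm in c(0L, 2L)) {
      expect_equal(count_offtarget(probe, db, mm),
                   hamming_hits(probe, db, mm))
    }
  }
  expect_error(count_offtarget("ACGTN", db, 0), "ambiguity")
})

test_that("mismatch budget and strand symmetry behave as set operations imply", {
  set.seed(54)
  for (i in 1:20) {
    probe <- random_dna(1, 9)
    db <- random_dna(8, 30)
    h0 <- count_offtarget(probe, db, 0)
    h2 <- count_offtarget(probe, db, 2)
    expect_gte(h2, h0)
    rc_db <- vapply(db, revcomp_chr, character(1), USE.NAMES = FALSE)
    expect_equal(count_offtarget(probe, rc_db, 2), h2)
  }
  # sequences shorter than the probe cannot be hit
  expect_equal(count_offtarget("ACGTACGTACGT", "ACGT", 2), 0L)
})

test_that("specificity screen enforces <5 perfect and <=100 two-mismatch hits", {
  set.seed(55)
  probe <- random_dna(1, 18)
  plant <- function(n_exact, n_total) {
    # n_exact sequences contain the probe verbatim; the rest a 2-mismatch copy
    v <- probe
    substr(v, 4, 4) <- setdiff(c("A","C","G","T"), substr(probe, 4, 4))[1]
    substr(v, 11, 11) <- setdiff(c("A","C","G","T"), substr(probe, 11, 11))[1]
    c(vapply(seq_len(n_exact), function(i)
        paste0(random_dna(1, 5), probe, random_dna(1, 5)), character(1)),
      vapply(seq_len(n_total - n_exact), function(i)
        paste0(random_dna(1, 5), v, random_dna(1, 5)), character(1)))
  }
  cand <- data.frame(target_start = 0L, length = 18L, sequence = probe,
                     target_window = revcomp_chr(probe),
                     tm = wallace_tm(probe))
  for (case in list(list(exact = 4, total = 50, ok = TRUE),
                    list(exact = 5, total = 50, ok = FALSE),
                    list(exact = 0, total = 100, ok = TRUE),
                    list(exact = 0, total = 101, ok = FALSE))) {
    scr <- screen_candidates(cand, plant(case$exact, case$total))
    expect_equal(scr$perfect_hits, case$exact)
    expect_equal(scr$twomm_hits, case$total)
    expect_equal(scr$accepted, case$ok)
  }
})

test_that("probe-set selection spreads starts evenly and is deterministic", {
  set.seed(56)
  target <- random_dna(1, 400)
  cand <- enumerate_candidates(target, lengths = 20, step = 1)
  cand$accepted <- TRUE
  sel <- select_probe_set(cand, k = 25)
  expect_equal(nrow(sel), 25)
  ideal <- (max(cand$target_start) - min(cand$target_start)) / 24
  expect_lte(max(diff(sort(sel$target_start))), 2 * ideal)
  expect_identical(sel, select_probe_set(cand, k = 25))
  # fewer accepted candidates than k returns all with a warning
  expect_warning(all10 <- select_probe_set(cand[1:10, ], k = 25), "only 10")
  expect_equal(nrow(all10), 10)
  expect_equal(nrow(select_probe_set(cand[1:30, ], k = 25)), 25)
})

test_that("design_probes yields a screened, spread manifest per OTU", {
  set.seed(57)
  t1 <- random_dna(1, 200)
  t2 <- random_dna(1, 200)
  bg <- random_dna(20, 200)
  man <- design_probes(list(otuA = t1, otuB = t2), bg, k = 10,
                       lengths = 20, step = 2)
  expect_setequal(unique(man$otu_id), c("otuA", "otuB"))
  expect_true(all(man$accepted))
  expect_true(all(man$perfect_hits < 5 & man$twomm_hits <= 100))
  expect_true(all(table(man$otu_id) <= 10))
  fa <- tempfile(fileext = ".fasta")
  write_probe_fasta(man, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), setNames(man$sequence, man$probe_id))
})
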