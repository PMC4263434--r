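test_that("mismatch counting against the degenerate CArG rules is exact", {
  # hand-verified position-by-position comparisons
  expect_identical(mismatch_count("CCATTAATGG", carg_core()), 0L)
  expect_identical(mismatch_count("CCCTAAATGG", carg_core()), 1L)
  expect_identical(mismatch_count("CTATATTAAG", carg_relaxed()), 0L)

  expect_true(pattern_matches("GCTTAATTGG", carg_core()))   # one mismatch
  expect_false(pattern_matches("CTATATTAAG", carg_core()))  # two mismatches
  expect_false(pattern_matches("CCATTAATGG", carg_relaxed()))  # inner G

  # a perfect 10/10 window also passes the 9-of-10 standard
  expect_true(pattern_matches("CCATTAATGG", carg_core()))

  # N in the window is conservative: mismatch unless the pattern says N
  expect_identical(mismatch_count("CCNTTAATGG", carg_core()), 1L)

  expect_error(mismatch_count("CCATT", carg_core()), "length")
  expect_error(consensus_pattern("CCWWGG", max_mismatches = 6),
               "max_mismatches")
})

test_that("scanning equals a naive every-window oracle on random sequences", {
  set.seed(101)
  rules <- list(core = carg_core(), relaxed = carg_relaxed())
  for (rep in 1:20) {
    p <- promoter_record(sprintf("s%d", rep), random_dna(300))
    for (r in rules) {
      for (mode in c("forward", "both")) {
        got <- scan_carg(p, r, strands = mode)
        want <- oracle_scan(p$sequence, r$symbols, r$max_mismatches, mode)
        expect_identical(got$start, as.integer(want$start))
        expect_identical(got$mismatches, as.integer(want$mismatches))
        expect_identical(got$strand, as.character(want$strand))
      }
    }
  }
})

test_that("a planted decamer is recovered at its planted TSS position", {
  set.seed(7)
  bg <- random_dna(200)
  p0 <- promoter_record("bg", bg)
  base <- scan_carg(p0, carg_core())
  # overwrite a window well away from any existing hit
  pos <- 40L
  seq <- paste0(substr(bg, 1, pos - 1), "CCATTAATGG", substr(bg, pos + 10, 200))
  p <- promoter_record("planted", seq)
  hits <- scan_carg(p, carg_core())
  expect_true(pos %in% hits$start)
  expect_identical(
    hits$tss_position[hits$start == pos],
    to_tss_coordinate(pos, p))
  # short sequences yield an empty table, not an error
  expect_identical(nrow(scan_carg(promoter_record("tiny", "ACGT"),
                                  carg_core())), 0L)
})

test_that("both CArG patterns are their own reverse complements", {
  expect_identical(revcomp("CCWWWWWWGG"), "CCWWWWWWGG")
  expect_identical(revcomp("CWWWWWWWWG"), "CWWWWWWWWG")
  set.seed(11)
  for (i in 1:1000) {
    w <- random_dna(10)
    expect_identical(mismatch_count(w, carg_core()),
                     mismatch_count(revcomp(w), carg_core()))
    expect_identical(mismatch_count(w, carg_relaxed()),
                     mismatch_count(revcomp(w), carg_relaxed()))
  }
})

test_that("both-strand scanning adds nothing for the palindromic rules", {
  set.seed(13)
  for (i in 1:10) {
    p <- promoter_record("s", random_dna(400))
    for (r in list(carg_core(), carg_relaxed())) {
      fwd <- scan_carg(p, r, strands = "forward")
      both <- scan_carg(p, r, strands = "both")
      expect_identical(both$start, fwd$start)
      expect_true(all(both$strand == "+"))
    }
  }
})

test_that("hit counts are invariant under input case", {
  set.seed(17)
  s <- random_dna(500)
  up <- scan_carg(promoter_record("u", s), carg_core())
  lo <- scan_carg(promoter_record("l", tolower(s)), carg_core())
  expect_identical(up$start, lo$start)
})

test_that("TSS coordinates skip zero and round-trip with local indices", {
  p <- promoter_record("p", random_dna(500), tss_pos = 301L)
  expect_identical(to_tss_coordinate(301L, p), 1L)
  expect_identical(to_tss_coordinate(300L, p), -1L)
  expect_identical(p$upstream_length, 300L)
  set.seed(19)
  idx <- sample(500L, 1000L, replace = TRUE)
  tssp <- to_tss_coordinate(idx, p)
  expect_true(all(tssp != 0L))
  expect_identical(from_tss_coordinate(tssp, p), idx)
  expect_error(to_tss_coordinate(501L, p), "range")
  expect_error(from_tss_coordinate(0L, p), "never 0")
})

test_that("the published decamer catalog classifies to the reported counts", {
  tab <- pemads_carg_decamers()
  expect_identical(nrow(tab), 28L)
  core_counts <- c(PeMADS2 = 4L, PeMADS3 = 0L, PeMADS4 = 3L,
                   PeMADS5 = 3L, PeMADS6 = 2L)
  relaxed_counts <- c(PeMADS2 = 5L, PeMADS3 = 2L, PeMADS4 = 6L,
                      PeMADS5 = 2L, PeMADS6 = 1L)
  for (prom in names(core_counts)) {
    entries <- data.frame(label = as.character(tab$location),
                          decamer = tab$decamer)[tab$promoter == prom, ]
    got <- classify_decamers(entries, list(carg_core(), carg_relaxed()))
    expect_identical(got$n_matching[got$rule == "CCW6GG"],
                     core_counts[[prom]])
    expect_identical(got$n_matching[got$rule == "CW8G"],
                     relaxed_counts[[prom]])
  }
  # duplicate rows count separately
  dup <- tab[tab$promoter == "PeMADS4" & tab$decamer == "CAAAATTTTG", ]
  expect_identical(nrow(dup), 2L)
})

test_that("no published decamer satisfies both consensus rules", {
  tab <- pemads_carg_decamers()
  both <- vapply(tab$decamer, function(d) {
    pattern_matches(d, carg_core()) && pattern_matches(d, carg_relaxed())
  }, logical(1))
  expect_false(any(both))
  # and every row satisfies exactly the rule it was printed under
  for (i in seq_len(nrow(tab))) {
    pat <- if (tab$rule[i] == "core") carg_core() else carg_relaxed()
    expect_true(pattern_matches(tab$decamer[i], pat))
  }
})

test_that("classify_decamers rejects malformed entries by label", {
  entries <- data.frame(label = c("ok", "bad"),
                        decamer = c("CCATTAATGG", "CCATT"))
  expect_error(classify_decamers(entries, carg_core()), "bad")
})

test_that("BED export uses 0-based half-open coordinates", {
  p <- promoter_record("p", paste0("TTTT", "CCATTAATGG", "TTTT"))
  hits <- scan_carg(p, carg_core())
  path <- tempfile(fileext = ".bed")
  hits_to_bed(hits, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, 4L)
  expect_identical(bed$V3, 14L)
})
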