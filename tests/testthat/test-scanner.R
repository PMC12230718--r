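# The hand-built perfect core used throughout: N7=G, N8=C, 5' arm GUUCG,
# loop CAGUGC (motif 1), 3' arm CGAAC, N25=C.
PERFECT_CORE <- "GCGUUCGCAGUGCCGAACC"

strict_params <- scan_params(max_mismatches = 0, max_stem_bulges = 0,
                             allow_3prime_bulge = FALSE)

test_that("normalization uppercases, converts T to U and keeps positions", {
  n <- normalize_sequence("acgt")
  expect_equal(n$seq, "ACGU")
  expect_equal(n$offset_map, 1:4)
  expect_equal(normalize_sequence("ACGN")$seq, "ACGN")
  expect_error(normalize_sequence(""), "empty")
  expect_error(normalize_sequence(strrep("A", 50001)), "50000")
  expect_error(normalize_sequence("ACG!"), "non-nucleotide")
})

test_that("pair classification follows Watson-Crick and wobble rules", {
  expect_equal(pair_type("G", "C"), "watson_crick")
  expect_equal(pair_type("A", "U"), "watson_crick")
  expect_equal(pair_type("G", "U"), "wobble")
  expect_equal(pair_type("U", "G", allow_wobble = FALSE), "mismatch")
  expect_equal(pair_type("A", "G"), "mismatch")
})

test_that("the 19-nt perfect core is found whole and not one nt shorter", {
  cands <- scan_sequence(PERFECT_CORE)
  expect_length(cands, 1)
  c1 <- cands[[1]]
  expect_equal(c1$motif_id, "1")
  expect_equal(c1$loop_start, 8)
  expect_false(c1$has_3prime_bulge)
  expect_equal(irescan:::n_defects(c1), 0)
  expect_equal(unname(c1$positions[c("N7", "N16", "N25")]), c(1L, 10L, 19L))
  expect_length(scan_sequence(substr(PERFECT_CORE, 1, 18)), 0)
  expect_length(scan_sequence(substr(PERFECT_CORE, 2, 19)), 0)
})

test_that("a 3' bulged nucleotide before N25 is modelled at exactly 20 nt", {
  # insert A between N24 and N25 of the perfect core
  bulged <- paste0(substr(PERFECT_CORE, 1, 18), "A",
                   substr(PERFECT_CORE, 19, 19))
  expect_equal(nchar(bulged), 20)
  cands <- scan_sequence(bulged, params = scan_params(max_mismatches = 0,
                                                      max_stem_bulges = 0))
  b3p <- Filter(function(c) c$has_3prime_bulge, cands)
  expect_length(b3p, 1)
  c1 <- b3p[[1]]
  expect_equal(irescan:::n_defects(c1), 0)
  expect_equal(c1$core_end - c1$core_start + 1L, 20L)
  expect_equal(unname(c1$positions[["B3p"]]), 19L)
  # truncating away N25 removes the bulged interpretation
  short <- substr(bulged, 1, 19)
  expect_length(Filter(function(c) c$has_3prime_bulge,
                       scan_sequence(short, params = strict_params)), 0)
})

test_that("defect-free scanning equals the brute-force enumerator", {
  set.seed(401)
  reg <- ire_motifs()
  for (rep in 1:20) {
    len <- sample(60:200, 1)
    seq <- paste0(sample(ACGU, len, replace = TRUE), collapse = "")
    if (rep %% 2 == 0) {  # plant a core so hits are not vanishingly rare
      fx <- build_core(sample(reg$motif_id, 1), seed = NULL)
      at <- sample.int(len - nchar(fx$seq) + 1L, 1)
      seq <- paste0(substr(seq, 1, at - 1), fx$seq,
                    substr(seq, at + nchar(fx$seq), len))
    }
    got <- scan_sequence(seq, reg, strict_params)
    got_keys <- sort(vapply(got, function(c)
      paste(c$loop_start, c$motif_id), character(1)))
    want <- oracle_scan(seq)
    want_keys <- sort(paste(want$loop_start, want$motif_id))
    expect_equal(got_keys, want_keys, info = paste("seq:", seq))
  }
})

test_that("candidate position bookkeeping is consistent", {
  set.seed(402)
  reg <- ire_motifs()
  for (m in c("1", "9b", "18", "22")) {
    for (spec in list(list(0, 0, FALSE), list(1, 0, FALSE),
                      list(0, 1, FALSE), list(0, 0, TRUE))) {
      fx <- build_core(m, mismatches = spec[[1]], stem_bulges = spec[[2]],
                       with_3prime_bulge = spec[[3]], seed = NULL)
      cands <- scan_sequence(fx$seq, reg)
      expect_gt(length(cands), 0)
      for (c1 in cands) {
        expect_true(all(diff(c1$positions) > 0))
        span <- c1$core_end - c1$core_start + 1L
        d <- c1$defects
        expect_equal(span,
                     19L + (c1$loop_len - 6L) + length(d$stem_bulges) +
                       c1$has_3prime_bulge)
      }
    }
  }
})

test_that("tightening defect limits only removes candidates", {
  set.seed(403)
  for (rep in 1:10) {
    seq <- paste0(sample(ACGU, 150, replace = TRUE), collapse = "")
    key <- function(cands) vapply(cands, function(c)
      paste(c$loop_start, c$motif_id, c$core_start, c$core_end,
            c$has_3prime_bulge), character(1))
    strict <- scan_sequence(seq, params = scan_params(max_mismatches = 0))
    loose <- scan_sequence(seq, params = scan_params(max_mismatches = 1))
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("interpretations sharing a loop offset form one site group", {
  # CAGUGA satisfies motifs 1, 17? no: 17 needs GAGUG; it matches 1 and 18
  # only with the right N8; use motif-1 core so alternatives come from
  # defect-tolerant reassembly
  seq <- PERFECT_CORE
  cands <- scan_sequence(seq, params = scan_params())
  groups <- site_groups(cands)
  expect_length(groups, 1)
  expect_equal(names(groups), "8")
  expect_length(site_groups(list()), 0)
  # two planted cores give two groups
  fx <- build_core("1", seed = 9)
  two <- paste0(fx$seq, strrep("A", 12), fx$seq)
  groups2 <- site_groups(scan_sequence(two, params = strict_params))
  expect_length(groups2, 2)
})
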