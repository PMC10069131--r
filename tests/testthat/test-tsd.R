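test_that("Boyer-Moore finds all occurrences, including overlapping ones", {
  expect_equal(boyer_moore_search("ATAT", "GATATATG"), c(1, 3))
  expect_equal(boyer_moore_search("AAA", "AAAAA"), c(0, 1, 2))
  expect_equal(boyer_moore_search("ACGT", "TTTT"), integer(0))
  expect_equal(boyer_moore_search("ACGT", "ACG"), integer(0))
  expect_equal(boyer_moore_search("G", "GAG"), c(0, 2))
})

test_that("Boyer-Moore agrees with a fixed-string regex oracle on random
           inputs", {
  withr::with_seed(40, {
    for (i in 1:150) {
      t <- rand_dna(sample(10:60, 1))
      p <- if (runif(1) < 0.5) rand_dna(sample(2:6, 1)) else {
        s <- sample(nchar(t) - 3, 1); substr(t, s, s + sample(1:4, 1))
      }
      hits <- boyer_moore_search(p, t)
      # oracle: scan every window
      n <- nchar(t); m <- nchar(p)
      expected <- which(vapply(seq_len(n - m + 1), function(s) {
        substr(t, s, s + m - 1) == p
      }, logical(1))) - 1L
      expect_equal(hits, as.integer(expected))
    }
  })
})

test_that("find_tsd recovers planted junction motifs with and without
           mismatches", {
  left <- paste0(rand_dna(25, seed = 41), "ACGTA")
  right <- paste0("ACGTA", rand_dna(25, seed = 42))
  tsd <- find_tsd(left, right, max_mismatch = 0)
  expect_equal(tsd$motif, "ACGTA")
  expect_equal(tsd$mismatches, 0L)
  expect_equal(tsd$left_pos + tsd$length, 30)  # flush with the 5' junction
  expect_equal(tsd$right_pos, 0)

  right_mut <- paste0("ACTTA", rand_dna(25, seed = 42))
  tsd1 <- find_tsd(left, right_mut, max_mismatch = 1, max_offset = 0)
  expect_equal(tsd1$length, 5)
  expect_equal(tsd1$mismatches, 1L)
  expect_null(find_tsd(left, right_mut, max_mismatch = 0,
                       max_offset = 0))
  expect_null(find_tsd("A", "ACGT"))
})

test_that("exact-mode find_tsd equals the brute-force all-substring-pairs
           oracle, and random flanks rarely share long motifs", {
  lens <- integer(0)
  withr::with_seed(43, {
    for (i in 1:100) {
      l <- rand_dna(30); r <- rand_dna(30)
      got <- find_tsd(l, r, max_mismatch = 0)
      want <- brute_tsd(l, r, max_mm = 0)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$length, want$len)
        expect_equal(got$left_pos, want$i)
        expect_equal(got$right_pos, want$j)
      }
      lens <- c(lens, if (is.null(got)) 0L else got$length)
    }
  })
  expect_lte(median(lens), 4)
})

test_that("mismatch-mode find_tsd equals the brute-force oracle", {
  withr::with_seed(44, {
    for (i in 1:50) {
      l <- rand_dna(20); r <- rand_dna(20)
      got <- find_tsd(l, r, max_mismatch = 1)
      want <- brute_tsd(l, r, max_mm = 1)
      expect_equal(got$length, want$len)
      expect_equal(got$mismatches, want$mm)
    }
  })
})

test_that("TSDs far from the junction are filtered; tolerance is inclusive", {
  tsd <- tibble::tibble(motif = "ACGTA", left_pos = 25L, right_pos = 0L,
                        mismatches = 0L, length = 5L)
  expect_equal(filter_tsd(tsd, c(0, 0)), tsd)
  expect_null(filter_tsd(tsd, c(3, 0)))
  expect_equal(filter_tsd(tsd, c(2, 2)), tsd)
  expect_null(filter_tsd(NULL, c(0, 0)))
})

test_that("TSD uniqueness requires exactly one occurrence in the locus
           window", {
  expect_true(check_tsd_uniqueness("ACGTA",
                                   paste0(rand_dna(20, seed = 45), "ACGTA",
                                          rand_dna(20, seed = 46))))
  expect_false(check_tsd_uniqueness("AT", "ATATATATAT"))
  expect_false(check_tsd_uniqueness("ACGTA", "GGGGGGGGGG"))
})

test_that("position correction moves junctions by the TSD offsets only", {
  call <- tibble::tibble(start = 1003, end = 1500)
  fixed <- correct_position(call, c(3, 0))
  expect_equal(fixed$start, 1000)
  expect_equal(fixed$end, 1500)
  same <- correct_position(call, c(0, 0))
  expect_equal(same, call)
})

test_that("on error-free reads, planted TSDs are recovered and corrected
           outsider calls sit within 2 bp of the planted junction", {
  sim <- small_sim(error_rate = 0)
  cfg <- te_config()
  out <- call_outsider(sim$assembly, sim$reads, sim$library,
                       sim$alignments, cfg) |>
    annotate_tsd(sim$assembly, reads = sim$reads, config = cfg)
  truth <- sim$truth[sim$truth$class_label == "OUTSIDER", ]
  m <- match_calls(out, truth, tolerance = 30)
  det <- m$events[m$events$detected, ]
  expect_gte(nrow(det), 9)  # 10 planted at this scale
  dist <- abs(det$call_start - det$position)
  expect_gte(mean(dist <= 2), 0.9)
  with_tsd <- out[!is.na(out$tsd_motif), ]
  expect_gte(nrow(with_tsd), 0.7 * nrow(out))
  idx <- m$events$call_idx[m$events$detected]
  # among calls where a TSD was reported, the motif must agree with the
  # planted one up to the search's own contract: it may extend the planted
  # motif when neighbouring bases happen to match, and may carry the one
  # tolerated mismatch
  called <- out$tsd_motif[idx]
  planted <- truth$tsd_motif[m$events$detected]
  has <- !is.na(called)
  agrees <- mapply(function(p, ca) {
    nrow(telltale:::hamming_hits(p, ca, 1)) > 0
  }, planted[has], called[has])
  expect_gte(mean(agrees), 0.9)
})

test_that("insider calls get exact-mode TSDs from the assembly flanks", {
  sim <- small_sim(error_rate = 0)
  cfg <- te_config()
  ins <- call_insider(sim$reference, sim$assembly, sim$library,
                      sim$contig_alignment, cfg) |>
    annotate_tsd(sim$assembly, config = cfg)
  truth <- sim$truth[sim$truth$class_label == "INSIDER", ]
  expect_equal(ins$tsd_motif, truth$tsd_motif)
  expect_equal(ins$tsd_mismatches, rep(0L, nrow(ins)))
  # never moved by more than the flank width
  expect_lte(max(abs(ins$start - truth$position)), cfg$tsd_flank)
})
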