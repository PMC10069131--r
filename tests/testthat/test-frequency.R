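test_that("local depth averages the two 30 bp flank windows", {
  aln <- uniform_cov_aln(glen = 12000, depth = 60, len = 2000)
  d <- local_depth(aln, "sim1", 6000, 6000)
  expect_equal(d, 60L)

  # asymmetric depth: 50x left of the junction, 70x right
  left <- make_aln(sprintf("l%02d", 1:50), rep(4000, 50), rep("2000M", 50))
  right <- make_aln(sprintf("r%02d", 1:70), rep(6000, 70), rep("2000M", 70))
  d2 <- local_depth(dplyr::bind_rows(left, right), "sim1", 6000, 6000)
  expect_equal(d2, 60L)

  # supplementary records are excluded; reads ending at the junction only
  # count on their own side
  supp <- make_aln("s1", 4000, "2000M", flag = 2048L)
  expect_equal(local_depth(dplyr::bind_rows(left, supp), "sim1", 6000, 6000),
               25L)

  expect_warning(local_depth(left, "sim1", 10, 10, contig_length = 12000),
                 "truncated")
})

test_that("window depth agrees with an independent point-count pileup at
           random loci and averages near the nominal library depth", {
  sim <- small_sim(error_rate = 0.02)
  glen <- Biostrings::width(sim$assembly)[1]
  pos <- withr::with_seed(50, sort(sample(seq(20000, glen - 20000), 25)))
  tr <- sim$truth
  pos <- pos[vapply(pos, function(p) min(abs(tr$position - p)) > 5000,
                    logical(1))]
  expect_gte(length(pos), 5)
  d <- vapply(pos, function(p) local_depth(sim$alignments, "sim1", p, p),
              integer(1))
  # independent pileup oracle: count primary reads whose reference span
  # contains the point
  aln <- sim$alignments |> dplyr::filter(primary)
  cnt <- vapply(pos, function(p) sum(aln$pos < p & aln$ref_end > p),
                double(1))
  expect_lt(max(abs(d - cnt) / cnt), 0.1)
  # and the per-locus mean sits near the nominal 60x mix
  expect_lt(abs(mean(d) - sum(sim$recipe$depth_mix)) /
              sum(sim$recipe$depth_mix), 0.1)
})

test_that("insider frequency counts junction-clean reads over flank depth", {
  # carriers align straight through [5000, 6000); non-carriers jump it with
  # a structural deletion
  carriers <- make_aln(sprintf("c%02d", 1:50), rep(3000, 50),
                       rep("5000M", 50))
  jumpers <- make_aln(sprintf("j%02d", 1:10), rep(3000, 10),
                      rep("2000M1000D2000M", 10))
  aln <- dplyr::bind_rows(carriers, jumpers)
  call <- tibble::tibble(contig = "sim1", start = 5000, end = 6000,
                         call_class = "INSIDER", kind = "insertion")
  fe <- insider_frequency(aln, call)
  expect_equal(fe$supporting, 50L)
  expect_equal(fe$spanning_total, 60L)
  expect_equal(fe$frequency, 50 / 60, tolerance = 1e-9)

  # no carriers: frequency 0, not NA
  fe0 <- insider_frequency(jumpers, call)
  expect_equal(fe0$supporting, 0L)
  expect_equal(fe0$frequency, 0)

  # clipped-at-junction reads are not supporters
  clipped <- make_aln(sprintf("x%02d", 1:10), rep(3000, 10),
                      rep("2000M3000S", 10),
                      seq = replicate(10, rand_dna(5000)))
  fec <- insider_frequency(dplyr::bind_rows(jumpers, clipped), call)
  expect_equal(fec$supporting, 0L)
})

test_that("zero local depth yields an absent frequency with a warning", {
  far <- make_aln("f1", 100000, "1000M")
  call <- tibble::tibble(contig = "sim1", start = 5000, end = 6000,
                         call_class = "INSIDER", kind = "insertion")
  expect_warning(fe <- insider_frequency(far, call), "depth")
  expect_true(is.na(fe$frequency))
})

test_that("clip rewriting produces a length-consistent insertion record", {
  seq <- rand_dna(9000, seed = 51)
  aln <- make_aln("r1", 0, "6000M3000S", seq = seq,
                  qual = strrep("I", 9000))
  call <- tibble::tibble(contig = "sim1", start = 6000)
  rw <- rewrite_clips_as_insertions(aln, call, te_length = 4990)
  expect_equal(rw$cigar, "6000M5000I")
  expect_equal(nchar(rw$seq), 11000)
  expect_equal(substr(rw$seq, 6001, 11000), strrep("N", 5000))
  expect_equal(substr(rw$qual, 6001, 6001),
               rawToChar(as.raw(33 + 8)))   # fake quality 8
  # SAM validity: query-consuming ops match the sequence length
  expect_equal(telltale:::cigar_query_width(rw$cigar), nchar(rw$seq))

  # no clip at the junction: untouched
  full <- make_aln("r2", 0, "4000M5000I4000M", seq = rand_dna(13000, seed = 52))
  expect_equal(rewrite_clips_as_insertions(full, call, 4990), full)
  # clip far from the junction: untouched
  wrong <- make_aln("r3", 8000, "3000S6000M", seq = seq,
                    qual = strrep("I", 9000))
  rw3 <- rewrite_clips_as_insertions(wrong, call, 4990)
  expect_equal(rw3$cigar, wrong$cigar)
  # a left clip anchored at the junction is a carrier and is rewritten
  lc <- make_aln("r4", 6000, "3000S6000M", seq = seq,
                 qual = strrep("I", 9000))
  expect_equal(rewrite_clips_as_insertions(lc, call, 4990)$cigar,
               "5000I6000M")
})

test_that("outsider frequency counts each supporting read once and clamps
           to [0, 1]", {
  asm_len <- 20000
  p <- 10000
  # 3 reads with the full insertion, 2 clipped at the junction, depth ~10
  ins_reads <- make_aln(sprintf("i%d", 1:3), rep(p - 4000, 3),
                        rep("4000M1000I4000M", 3),
                        seq = replicate(3, rand_dna(9000)))
  clip_reads <- make_aln(sprintf("k%d", 1:2), rep(p - 4000, 2),
                         rep("4000M600S", 2),
                         seq = replicate(2, rand_dna(4600)))
  plain <- make_aln(sprintf("p%d", 1:5), rep(p - 4000, 5), rep("8000M", 5),
                    seq = replicate(5, rand_dna(8000)))
  aln <- dplyr::bind_rows(ins_reads, clip_reads, plain)
  call <- tibble::tibble(contig = "sim1", start = p, end = p + 1,
                         call_class = "OUTSIDER", kind = "insertion")
  fe <- outsider_frequency(aln, call, te_length = 1000)
  expect_equal(fe$supporting, 4L)  # 3 spanning + mean(2 left-only, 3+2)
  expect_equal(fe$spanning_total, 9L)
  expect_equal(fe$frequency, 4 / 9, tolerance = 1e-9)
  expect_true(fe$frequency >= 0 && fe$frequency <= 1)

  # a read contributing both a clip and an insertion op still counts once
  both <- make_aln("dual", p - 4000, "4000M1000I2000M500S",
                   seq = rand_dna(7500, seed = 53))
  fe2 <- outsider_frequency(dplyr::bind_rows(both, plain), call, 1000)
  expect_equal(fe2$supporting, 1L)

  # no supporting reads at all: absent frequency
  expect_warning(
    fe3 <- outsider_frequency(make_aln("x", 0, "100M",
                                       seq = rand_dna(100, seed = 54)),
                              call, 1000),
    "depth")
  expect_true(is.na(fe3$frequency))
})

test_that("whole-call-set estimation matches the planted mixture and stays
           in [0, 1]; deletions get no frequency", {
  sim <- small_sim(error_rate = 0.02)
  cfg <- te_config()
  out <- call_outsider(sim$assembly, sim$reads, sim$library,
                       sim$alignments, cfg) |>
    estimate_frequencies(sim$alignments, sim$library, cfg)
  expect_true(all(out$frequency >= 0 & out$frequency <= 1, na.rm = TRUE))
  f_out <- unname(sim$recipe$depth_mix["outsider"] /
                    sum(sim$recipe$depth_mix))
  expect_lt(abs(mean(out$frequency, na.rm = TRUE) - f_out), 0.05)

  del <- tibble::tibble(contig = "sim1", start = 100, end = 400,
                        family = "alpha", call_class = "INSIDER",
                        kind = "deletion")
  del_fe <- estimate_frequencies(del, sim$alignments, sim$library, cfg)
  expect_true(is.na(del_fe$frequency))
})
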