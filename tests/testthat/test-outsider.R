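test_that("insertion ops and long soft clips become positioned signals", {
  seq1 <- rand_dna(13000, seed = 31)
  aln <- make_aln("r1", 100000, "4000M5000I4000M", seq = seq1)
  sig <- collect_candidate_reads(aln)
  expect_equal(nrow(sig), 1)
  expect_equal(sig$position, 104000)
  expect_equal(sig$size, 5000)
  expect_equal(sig$sequence, substr(seq1, 4001, 9000))
  expect_equal(sig$read_offset, 4000)

  seq2 <- rand_dna(9000, seed = 32)
  aln2 <- make_aln("r2", 50000, "6000M3000S", seq = seq2)
  sig2 <- collect_candidate_reads(aln2)
  expect_equal(sig2$kind, "clip_right")
  expect_equal(sig2$position, 56000)        # M/S boundary on the target
  expect_equal(sig2$sequence, substr(seq2, 6001, 9000))

  # sub-threshold signals are ignored; secondary records skipped
  aln3 <- make_aln("r3", 0, "100M20I100M100S", seq = rand_dna(320, seed = 33))
  expect_equal(nrow(collect_candidate_reads(aln3)), 0)
  aln4 <- make_aln("r4", 0, "100M", flag = 256L)
  expect_equal(nrow(collect_candidate_reads(aln4)), 0)
})

test_that("signals cluster by anchor window with median position and size", {
  sig <- tibble::tibble(
    read_id = c("a", "b", "c"), contig = "sim1",
    position = c(1000, 1010, 1025), size = c(400, 500, 450),
    kind = "ins", sequence = "ACGT", read_offset = 0)
  cl <- cluster_signals(sig, te_config())
  expect_equal(nrow(cl), 1)
  expect_equal(cl$position, 1010)   # median, computed by hand
  expect_equal(cl$size, 450)
  expect_equal(cl$n_reads, 3L)

  far <- sig |> dplyr::mutate(position = c(1000, 1000, 1100))
  expect_equal(nrow(cluster_signals(far, te_config())), 2)
})

test_that("cluster order and membership ignore input row order", {
  sig <- withr::with_seed(34, tibble::tibble(
    read_id = sprintf("r%02d", 1:20), contig = "sim1",
    position = sort(sample(1:50000, 20)), size = 300, kind = "ins",
    sequence = "ACGT", read_offset = 0))
  a <- cluster_signals(sig, te_config())
  b <- cluster_signals(sig[sample(nrow(sig)), ], te_config())
  expect_equal(a |> dplyr::select(-members), b |> dplyr::select(-members))
})

test_that("the highest-scoring read represents the cluster; non-TE clusters
           are dropped; score ties break to the smaller read id", {
  lib <- tiny_library()
  cons <- lib$sequence[1]
  mut_copy <- function(seq, n_sub, seed) {
    withr::with_seed(seed, {
      ch <- strsplit(seq, "")[[1]]
      idx <- sample(length(ch), n_sub)
      ch[idx] <- vapply(ch[idx], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(ch, collapse = "")
    })
  }
  sig <- tibble::tibble(
    read_id = c("read1", "read2", "read3"), contig = "sim1",
    position = c(5000, 5003, 5006), size = 1000, kind = "ins",
    sequence = c(mut_copy(cons, 80, 1), mut_copy(cons, 50, 2),
                 mut_copy(cons, 100, 3)),
    read_offset = 0)
  cl <- cluster_signals(sig, te_config())
  best <- select_best_read(cl, lib, te_config())
  expect_equal(nrow(best), 1)
  expect_equal(best$best_read_id, "read2")   # fewest substitutions
  expect_equal(best$family, "alpha")

  # all member sequences non-TE: cluster dropped
  junk <- sig |> dplyr::mutate(sequence = c(rand_dna(1000, seed = 4),
                                            rand_dna(1000, seed = 5),
                                            rand_dna(1000, seed = 6)))
  expect_equal(nrow(select_best_read(cluster_signals(junk, te_config()),
                                     lib, te_config())), 0)

  # identical sequences tie on score: lexicographically smaller id wins
  tie <- sig |> dplyr::mutate(sequence = cons,
                              read_id = c("zed", "abc", "mid"))
  best_tie <- select_best_read(cluster_signals(tie, te_config()),
                               lib, te_config())
  expect_equal(best_tie$best_read_id, "abc")
})

test_that("clip reads from the two sides jointly establish full-length TE
           evidence for one cluster", {
  lib <- tiny_library()
  cons <- lib$sequence[1]  # 1000 bp
  sig <- tibble::tibble(
    read_id = c("left", "right"), contig = "sim1",
    position = c(8000, 8000), size = c(600, 600),
    kind = c("clip_right", "clip_left"),
    sequence = c(substr(cons, 1, 600), substr(cons, 401, 1000)),
    read_offset = 0)
  cl <- cluster_signals(sig, te_config())
  best <- select_best_read(cl, lib, te_config())
  expect_equal(nrow(best), 1)
  expect_gte(best$te_coverage_pct, 80)
  # neither fragment alone reaches the coverage floor
  single <- search_te_library(c(x = substr(cons, 1, 600)), lib) |>
    group_fragments()
  expect_lt(max(single$te_coverage_pct), 80)
})

test_that("a single read carrying a full TE with flanks gives exactly one
           call, and TE-free reads give none", {
  lib <- tiny_library()
  asm_seq <- rand_dna(20000, seed = 35)
  asm <- Biostrings::DNAStringSet(c(sim1 = asm_seq))
  p <- 10000
  read_seq <- paste0(substr(asm_seq, p - 1500 + 1, p), lib$sequence[1],
                     substr(asm_seq, p + 1, p + 1500))
  aln <- make_aln("lone", p - 1500, "1500M1000I1500M", seq = read_seq)
  calls <- call_outsider(asm, NULL, lib, aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, p)
  expect_equal(calls$family, "alpha")
  expect_equal(calls$kind, "insertion")
  expect_equal(calls$supporting, 1L)
  expect_equal(calls$best_read_id, "lone")

  plain <- make_aln(c("a", "b"), c(0, 3000), c("5000M", "5000M"),
                    seq = c(substr(asm_seq, 1, 5000),
                            substr(asm_seq, 3001, 8000)))
  expect_equal(nrow(call_outsider(asm, NULL, lib, plain)), 0)
})

test_that("error-free simulated reads put every spanning-read signal within
           a few bp of the planted position", {
  sim <- small_sim(error_rate = 0)
  truth <- sim$truth[sim$truth$class_label == "OUTSIDER", ]
  sig <- collect_candidate_reads(sim$alignments) |>
    dplyr::filter(kind == "ins")
  near <- vapply(sig$position, function(p) {
    min(abs(truth$position - p))
  }, double(1))
  expect_lte(max(near), 5)
  # every planted event is hit by at least one insertion-op signal cluster
  cl <- cluster_signals(sig, te_config())
  hit <- vapply(truth$position, function(p) {
    any(abs(cl$position - p) <= 30)
  }, logical(1))
  expect_true(all(hit))
})

test_that("the outsider track is deterministic under read-order permutation", {
  sim <- small_sim(error_rate = 0.02)
  aln <- sim$alignments
  a <- call_outsider(sim$assembly, sim$reads, sim$library, aln)
  perm <- withr::with_seed(36, aln[sample(nrow(aln)), ])
  b <- call_outsider(sim$assembly, sim$reads, sim$library, perm)
  expect_equal(a, b)
})
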