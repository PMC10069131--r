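test_that("library search finds exact and partial self-matches", {
  lib <- tiny_library()
  full <- lib$sequence[1]
  half <- substr(lib$sequence[1], 1, 500)
  m <- search_te_library(c(full = full, half = half), lib)
  best_full <- m[m$candidate_id == "full", ][1, ]
  expect_equal(best_full$family, "alpha")
  expect_equal(best_full$identity_pct, 100)
  expect_equal(best_full$te_coverage_pct, 100)
  best_half <- m[m$candidate_id == "half", ][1, ]
  expect_equal(best_half$te_coverage_pct, 50, tolerance = 0.02)
})

test_that("reverse-complement candidates are found on the minus strand", {
  lib <- tiny_library()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lib$sequence[2])))
  m <- search_te_library(c(rc = rc), lib)
  expect_equal(m$strand[1], "-")
  expect_equal(m$family[1], "beta")
  expect_equal(m$te_coverage_pct[1], 100)
})

test_that("reported identity agrees with an independent pairwise-alignment
           oracle on a mutated copy", {
  lib <- tiny_library()
  cons <- lib$sequence[1]
  mutated <- withr::with_seed(42, {
    ch <- strsplit(cons, "")[[1]]
    idx <- sample(length(ch), round(0.1 * length(ch)))
    sub <- vapply(ch[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    ch[idx] <- sub
    paste(ch, collapse = "")
  })
  m <- search_te_library(c(mut = mutated), lib) |>
    group_fragments() |>
    dplyr::filter(family == "alpha")
  expect_gte(m$identity_pct[1], 88)
  expect_lte(m$identity_pct[1], 92)
  # independent oracle: global pairwise alignment percent identity,
  # agreement within 2 percentage points
  pw <- Biostrings::pairwiseAlignment(mutated, cons, type = "global")
  expect_lt(abs(m$identity_pct[1] - Biostrings::pid(pw)), 2)
})

test_that("the identity/coverage filter is inclusive and configurable", {
  base <- tibble::tibble(candidate_id = "c", family = "alpha",
                         cand_start = 0, cand_end = 100, cons_start = 0,
                         cons_end = 100, consensus_length = 100L,
                         strand = "+", score = 100)
  m <- dplyr::bind_rows(
    base |> dplyr::mutate(identity_pct = 85, te_coverage_pct = 85),
    base |> dplyr::mutate(identity_pct = 79.9, te_coverage_pct = 95),
    base |> dplyr::mutate(identity_pct = 90, te_coverage_pct = 12))
  kept <- filter_matches(m, te_config())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$identity_pct, 85)
  # boundary is inclusive: exactly 80/80 passes
  at <- base |> dplyr::mutate(identity_pct = 80, te_coverage_pct = 80)
  expect_equal(nrow(filter_matches(at, te_config())), 1)
  # relaxing the coverage floor to 10% recovers truncated copies
  kept10 <- filter_matches(m, te_config(min_te_coverage_pct = 10))
  expect_equal(nrow(kept10), 2)
})

test_that("raising a threshold never enlarges the kept set", {
  m <- withr::with_seed(7, tibble::tibble(
    candidate_id = "c", family = "alpha",
    identity_pct = runif(200, 50, 100), te_coverage_pct = runif(200, 0, 100),
    cand_start = 0, cand_end = 100, cons_start = 0, cons_end = 100,
    consensus_length = 100L, strand = "+", score = 1))
  for (thr in seq(10, 90, by = 20)) {
    lo <- filter_matches(m, te_config(min_identity_pct = thr,
                                      min_te_coverage_pct = thr))
    hi <- filter_matches(m, te_config(min_identity_pct = thr + 10,
                                      min_te_coverage_pct = thr + 10))
    expect_lte(nrow(hi), nrow(lo))
    expect_true(all(paste(hi$identity_pct, hi$te_coverage_pct) %in%
                      paste(lo$identity_pct, lo$te_coverage_pct)))
  }
})

test_that("collinear fragments merge into a composite with union coverage", {
  frag <- function(cs, ce, qs, qe, id = 95) {
    tibble::tibble(candidate_id = "c", family = "alpha", identity_pct = id,
                   te_coverage_pct = 100 * (ce - cs) / 1000,
                   cand_start = qs, cand_end = qe, cons_start = cs,
                   cons_end = ce, consensus_length = 1000L, strand = "+",
                   score = (ce - cs) / 10)
  }
  # consensus [0,400) + [450,1000): union 950 of 1000 -> 95% coverage
  m <- dplyr::bind_rows(frag(0, 400, 0, 400), frag(450, 1000, 420, 970))
  g <- group_fragments(m, gap_tolerance = 100)
  expect_equal(nrow(g), 1)
  expect_equal(g$te_coverage_pct, 95)
  expect_equal(g$identity_pct, 95)
  expect_equal(g$cand_start, 0)
  expect_equal(g$cand_end, 970)

  # opposite strands never merge
  m2 <- dplyr::bind_rows(frag(0, 400, 0, 400),
                         frag(450, 1000, 420, 970) |>
                           dplyr::mutate(strand = "-"))
  expect_equal(nrow(group_fragments(m2, 100)), 2)

  # a single hit passes through unchanged
  single <- frag(0, 800, 10, 810)
  expect_equal(group_fragments(single, 100)$te_coverage_pct,
               single$te_coverage_pct)

  # grouping never lowers a family's best coverage
  expect_gte(max(g$te_coverage_pct), max(m$te_coverage_pct))
})

test_that("insertion size bounds are inclusive at both ends", {
  cands <- tibble::tibble(size = c(150, 200, 5000, 15000, 16000))
  kept <- apply_length_bounds(cands, te_config())
  expect_equal(kept$size, c(200, 5000, 15000))
})
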