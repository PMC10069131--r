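# Shared fixtures, all built in code. Simulations are memoised so several
# test files can reuse the same object without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- get0(key, envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_env)
  val
}

rand_dna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# finalized alignment tibble from minimal fields
make_aln <- function(read_id, pos, cigar, seq = NA_character_, flag = 0L,
                     contig = "sim1", qual = NA_character_) {
  telltale:::finalize_alignments(tibble::tibble(
    read_id = read_id, flag = as.integer(flag), contig = contig,
    pos = as.double(pos), mapq = 60L, cigar = cigar, seq = seq, qual = qual))
}

# uniform-coverage synthetic alignments: `depth` reads of length `len`
# tiled so every base of [0, glen) is covered `depth` times
uniform_cov_aln <- function(glen = 10000, depth = 60, len = 2000) {
  starts <- rep(seq(0, glen - len, by = len / depth), each = 1)
  starts <- starts[starts + len <= glen]
  make_aln(sprintf("u%04d", seq_along(starts)), starts,
           sprintf("%dM", len))
}

# a small two-family library with conveniently short consensuses
tiny_library <- function() {
  memo("tiny_library", {
    tibble::tibble(
      family = c("alpha", "beta"),
      sequence = c(rand_dna(1000, seed = 101), rand_dna(700, seed = 102)),
      length = c(1000L, 700L))
  })
}

# memoised small simulations (200 kb genome, 1 insider + 10 outsider)
small_sim <- function(error_rate = 0.02, seed = 301) {
  memo(sprintf("small_sim_%g_%d", error_rate, seed), {
    simulate_te_benchmark(scale_recipe(
      simulation_recipe(seed = seed, error_rate = error_rate), 0.01))
  })
}

# brute-force longest-common-substring-with-mismatches oracle for find_tsd:
# enumerates every substring pair of the two flanks
brute_tsd <- function(left, right, max_mm = 0, min_len = 2) {
  nl <- nchar(left); nr <- nchar(right)
  best <- NULL
  lc <- strsplit(left, "")[[1]]
  rc <- strsplit(right, "")[[1]]
  for (len in seq(min(nl, nr), min_len)) {
    found <- NULL
    for (i in seq_len(nl - len + 1)) {
      for (j in seq_len(nr - len + 1)) {
        mm <- sum(lc[i:(i + len - 1)] != rc[j:(j + len - 1)])
        if (mm <= max_mm) {
          o5 <- nl - (i - 1 + len)
          tot <- o5 + (j - 1)
          cand <- list(len = len, i = i - 1, j = j - 1, mm = mm, tot = tot)
          if (is.null(found) || tot < found$tot ||
              (tot == found$tot && cand$i < found$i)) {
            found <- cand
          }
        }
      }
    }
    if (!is.null(found)) return(found)
  }
  NULL
}
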