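# Target-site-duplication detection. TE integration via staggered
# double-strand breaks leaves a short direct repeat (the TSD) immediately
# flanking both TE ends; finding the same motif at the end of the 5' flank
# and the start of the 3' flank both confirms a genuine integration event and
# pins the junction to within a couple of bases. Exact motif search uses
# Boyer-Moore (bad-character + good-suffix rules); mismatch tolerance is a
# Hamming-distance sliding scan on top (mismatches, not edits).

#' Boyer-Moore exact string search
#'
#' Classic Boyer-Moore with both the bad-character and (strong) good-suffix
#' shift rules. Finds all, including overlapping, occurrences.
#'
#' @param pattern,text DNA strings (any characters work; comparison is
#'   exact).
#' @return Integer vector of 0-based start positions of `pattern` in `text`.
#' @examples
#' boyer_moore_search("ATAT", "GATATATG")
#' @export
boyer_moore_search <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p)
  n <- length(t)
  if (m == 0 || m > n) return(integer(0))

  # bad-character rule: rightmost position (1-based) of each character
  bad <- new.env(parent = emptyenv())
  for (i in seq_len(m)) assign(p[i], i, envir = bad)
  bad_shift <- function(ch, j) {
    r <- get0(ch, envir = bad, ifnotfound = 0L)
    j - r
  }

  # good-suffix rule (strong), border-based preprocessing; arrays are
  # 1-based over positions 0..m (stored at +1)
  f <- integer(m + 1)
  s <- integer(m + 1)
  i <- m; j <- m + 1
  f[i + 1] <- j
  while (i > 0) {
    while (j <= m && p[i] != p[j]) {
      if (s[j + 1] == 0) s[j + 1] <- j - i
      j <- f[j + 1]
    }
    i <- i - 1; j <- j - 1
    f[i + 1] <- j
  }
  j <- f[1]
  for (i in 0:m) {
    if (s[i + 1] == 0) s[i + 1] <- j
    if (i == j) j <- f[j + 1]
  }

  hits <- integer(0)
  shift <- 0L
  while (shift <= n - m) {
    j <- m
    while (j >= 1 && p[j] == t[shift + j]) j <- j - 1
    if (j == 0) {
      hits <- c(hits, shift)
      shift <- shift + s[1]
    } else {
      shift <- shift + max(s[j + 1], bad_shift(t[shift + j], j))
    }
  }
  hits
}

hamming_hits <- function(pattern, text, max_mismatch) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p); n <- length(t)
  if (m > n) return(tibble(pos = integer(0), mismatches = integer(0)))
  pos <- integer(0); mm <- integer(0)
  for (s in 0:(n - m)) {
    d <- sum(p != t[s + seq_len(m)])
    if (d <= max_mismatch) {
      pos <- c(pos, s); mm <- c(mm, d)
    }
  }
  tibble(pos = pos, mismatches = mm)
}

#' Find a target-site-duplication motif between two junction flanks
#'
#' Finds the longest motif occurring in both the 5' flank (the bases
#' immediately upstream of the insertion's 5' junction) and the 3' flank
#' (immediately downstream of the 3' junction), allowing up to
#' `max_mismatch` mismatches in the 3' occurrence. Exact mode
#' (`max_mismatch = 0`) uses Boyer-Moore search; mismatch mode adds a
#' Hamming-distance scan (no indels inside the motif). Ties between
#' equal-length motifs are broken by the smallest summed distance of the two
#' occurrences from their junctions, then by the leftmost 5'-flank position,
#' so output is deterministic.
#'
#' @param left_flank DNA string ending at the 5' junction.
#' @param right_flank DNA string starting at the 3' junction.
#' @param max_mismatch Mismatches tolerated (default 1, the read-derived
#'   setting; assembly-derived junctions use 0).
#' @param min_len Minimum motif length reported (shorter shared strings are
#'   noise).
#' @param max_offset Only consider occurrences within this many bases of the
#'   junctions (`Inf` searches the whole flanks). Constraining the search to
#'   the junction neighbourhood prevents a longer repeat elsewhere in the
#'   flanks from shadowing a genuine at-junction duplication.
#' @return One-row tibble (`motif`, `left_pos`, `right_pos` 0-based offsets
#'   within the flanks, `mismatches`, `length`), or `NULL` when no motif of
#'   at least `min_len` exists.
#' @examples
#' find_tsd("TTTTTTTTTTACGTA", "ACGTATTTTTTTTTT", max_mismatch = 0)
#' @export
find_tsd <- function(left_flank, right_flank, max_mismatch = 1,
                     min_len = 2, max_offset = Inf) {
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  if (nl < min_len || nr < min_len) return(NULL)
  for (len in seq(min(nl, nr), min_len)) {
    best <- NULL
    i_min <- max(1, ceiling(nl - len - max_offset + 1))
    for (i in i_min:(nl - len + 1)) {
      motif <- substr(left_flank, i, i + len - 1)
      occ <- if (max_mismatch == 0) {
        hits <- boyer_moore_search(motif, right_flank)
        tibble(pos = hits, mismatches = rep(0L, length(hits)))
      } else {
        hamming_hits(motif, right_flank, max_mismatch)
      }
      occ <- occ[occ$pos <= max_offset, , drop = FALSE]
      if (!nrow(occ)) next
      left_pos <- i - 1L
      o5 <- nl - (left_pos + len)  # motif end to 5' junction
      occ$total_offset <- o5 + occ$pos
      occ <- occ[order(occ$total_offset, occ$pos), , drop = FALSE]
      cand <- tibble(motif = motif, left_pos = left_pos,
                     right_pos = occ$pos[1], mismatches = occ$mismatches[1],
                     length = len, total_offset = occ$total_offset[1])
      if (is.null(best) || cand$total_offset < best$total_offset ||
          (cand$total_offset == best$total_offset &&
           cand$left_pos < best$left_pos)) {
        best <- cand
      }
    }
    if (!is.null(best)) return(best |> select(-"total_offset"))
  }
  NULL
}

#' Filter TSDs too far from the detected junctions
#'
#' A motif found on both sides but offset from the junctions is more likely a
#' pre-existing duplication in the locus than a genuine TSD; occurrences more
#' than `tsd_junction_tolerance` bp (inclusive tolerance: 2 bp passes by
#' default) from either junction are rejected.
#'
#' @param tsd One-row tibble from [find_tsd()] (or `NULL`).
#' @param junction_offsets Length-2 numeric: distance of the motif from the
#'   5' and 3' junctions.
#' @param config A [te_config()].
#' @return `tsd`, or `NULL` when rejected.
#' @export
filter_tsd <- function(tsd, junction_offsets, config = te_config()) {
  if (is.null(tsd)) return(NULL)
  config <- as_te_config(config)
  if (any(junction_offsets > config$tsd_junction_tolerance)) return(NULL)
  tsd
}

#' Check that a TSD motif is unique at the insertion locus
#'
#' For read-derived (outsider) calls the putative TSD must occur exactly once
#' in the empty-site window of the assembly; zero occurrences mean the motif
#' is not the empty-site sequence at all, several mean it cannot anchor the
#' junction.
#'
#' @param motif TSD motif string.
#' @param locus_window Assembly sequence of the insertion locus (position
#'   +/- `tsd_flank`).
#' @return `TRUE` iff the motif occurs exactly once (overlapping occurrences
#'   counted).
#' @export
check_tsd_uniqueness <- function(motif, locus_window) {
  length(boyer_moore_search(motif, locus_window)) == 1
}

#' Correct call junctions from a retained TSD
#'
#' Moves the call's 5' end back by the motif's distance from the detected 5'
#' junction and its 3' end forward by the distance from the 3' junction, so
#' the reported interval ends exactly at the duplication. A call is never
#' moved by more than the flank width.
#'
#' @param call One-or-more-row calls tibble with `start`/`end`.
#' @param junction_offsets Length-2 numeric (5' and 3' offsets, bp).
#' @return The calls tibble with corrected coordinates.
#' @export
correct_position <- function(call, junction_offsets) {
  call |>
    mutate(start = .data$start - junction_offsets[1],
           end = .data$end + junction_offsets[2])
}

#' Detect, filter and apply TSDs for a call set
#'
#' For insider insertions the two flanks are read from the assembly around
#' the annotated TE span and compared exactly; for outsider insertions they
#' are read from the best supporting read around its insertion operation,
#' with mismatch tolerance, and the motif must additionally be unique in the
#' assembly's empty-site window. Retained TSDs refine the junctions via
#' [correct_position()] (outsider point calls shift by the 5' offset).
#' Deletion calls and clip-only outsider calls (only one junction visible in
#' the read) get `NA` TSD fields.
#'
#' @param calls Calls tibble from [call_insider()] / [call_outsider()].
#' @param assembly Named `DNAStringSet`.
#' @param reads Tibble with `read_id`/`sequence` for outsider best reads (may
#'   be `NULL` when `calls` has no outsider rows).
#' @param config A [te_config()].
#' @return `calls` with `tsd_motif`, `tsd_len`, `tsd_mismatches` columns and
#'   TSD-corrected coordinates.
#' @export
annotate_tsd <- function(calls, assembly, reads = NULL,
                         config = te_config()) {
  config <- as_te_config(config)
  calls$tsd_motif <- NA_character_
  calls$tsd_len <- NA_integer_
  calls$tsd_mismatches <- NA_integer_
  if (!nrow(calls)) return(calls)
  fl <- config$tsd_flank
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$kind != "insertion") next
    if (cl$call_class == "INSIDER") {
      ctg <- assembly[[cl$contig]]
      js <- cl$start + cl$cand_start
      je <- cl$start + cl$cand_end
      if (js - fl < 0 || je + fl > length(ctg)) next
      left <- as.character(Biostrings::subseq(ctg, js - fl + 1, js))
      right <- as.character(Biostrings::subseq(ctg, je + 1, je + fl))
      tsd <- find_tsd(left, right, config$tsd_max_mismatch_insider,
                      config$tsd_min_len,
                      max_offset = config$tsd_junction_tolerance)
    } else {
      if (is.na(cl$best_kind) || cl$best_kind != "ins" || is.null(reads)) next
      rseq <- reads$sequence[match(cl$best_read_id, reads$read_id)]
      if (is.na(rseq)) next
      js <- cl$best_read_offset + cl$cand_start
      je <- cl$best_read_offset + cl$cand_end
      if (js - fl < 0 || je + fl > nchar(rseq)) next
      left <- substr(rseq, js - fl + 1, js)
      right <- substr(rseq, je + 1, je + fl)
      tsd <- find_tsd(left, right, config$tsd_max_mismatch_outsider,
                      config$tsd_min_len,
                      max_offset = config$tsd_junction_tolerance)
    }
    if (is.null(tsd)) next
    o5 <- fl - (tsd$left_pos + tsd$length)
    o3 <- tsd$right_pos
    tsd <- filter_tsd(tsd, c(o5, o3), config)
    if (is.null(tsd)) next
    if (cl$call_class == "OUTSIDER") {
      ctg <- assembly[[cl$contig]]
      w_s <- max(0, cl$start - fl)
      w_e <- min(length(ctg), cl$start + fl)
      window <- as.character(Biostrings::subseq(ctg, w_s + 1, w_e))
      if (!check_tsd_uniqueness(tsd$motif, window)) next
      calls$start[i] <- cl$start - o5
      calls$end[i] <- calls$start[i] + 1
    } else {
      calls$start[i] <- js - o5
      calls$end[i] <- je + o3
    }
    calls$tsd_motif[i] <- tsd$motif
    calls$tsd_len[i] <- tsd$length
    calls$tsd_mismatches[i] <- tsd$mismatches
  }
  calls
}
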