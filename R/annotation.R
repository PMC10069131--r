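# Shared TE annotation engine: decide whether a candidate sequence is a TE.
# The similarity search is delegated to BLASTN (the standard local-alignment
# tool for nucleotide-vs-consensus comparison); filtering, fragment grouping
# and family assignment happen here. Identity is percent identical columns of
# the local alignment; coverage is the percentage of the *consensus* length
# covered (the "80% in length of the reference TE sequence" convention).

.blast_cache <- new.env(parent = emptyenv())

blast_db_for <- function(library) {
  key <- rlang::hash(list(library$family, library$sequence))
  hit <- get0(key, envir = .blast_cache)
  if (!is.null(hit) && file.exists(paste0(hit, ".nsq"))) return(hit)
  if (Sys.which("makeblastdb") == "" || Sys.which("blastn") == "") {
    abort("BLAST+ (makeblastdb/blastn) not found on PATH")
  }
  dir <- tempfile("telib")
  dir.create(dir)
  fa <- file.path(dir, "library.fa")
  write_te_library(library, fa)
  db <- file.path(dir, "tedb")
  status <- system2("makeblastdb",
                    c("-in", fa, "-dbtype", "nucl", "-out", db,
                      "-logfile", file.path(dir, "makeblastdb.log")))
  if (status != 0) abort("makeblastdb failed")
  assign(key, db, envir = .blast_cache)
  db
}

#' Search candidate sequences against a TE consensus library
#'
#' Runs a local nucleotide alignment (BLASTN) of each candidate against every
#' consensus, both strands, and reports one row per local hit with percent
#' identity, the percentage of the consensus covered by the hit, the matched
#' spans on candidate and consensus (0-based half-open), strand and bit
#' score, sorted by descending score.
#'
#' @param candidates Either a named character vector of DNA sequences or a
#'   tibble with `candidate_id` and `sequence` columns.
#' @param library TE library tibble ([load_te_library()] /
#'   [synthetic_te_library()]).
#' @param config A [te_config()] (unused here beyond validation; thresholds
#'   are applied by [filter_matches()]).
#' @return Tibble of matches: `candidate_id`, `family`, `identity_pct`,
#'   `te_coverage_pct`, `cand_start`, `cand_end`, `cons_start`, `cons_end`,
#'   `consensus_length`, `strand`, `score`.
#' @export
search_te_library <- function(candidates, library, config = te_config()) {
  if (is.character(candidates)) {
    ids <- names(candidates) %||% paste0("cand", seq_along(candidates))
    candidates <- tibble(candidate_id = ids, sequence = unname(candidates))
  }
  empty <- tibble(candidate_id = character(), family = character(),
                  identity_pct = double(), te_coverage_pct = double(),
                  cand_start = double(), cand_end = double(),
                  cons_start = double(), cons_end = double(),
                  consensus_length = integer(), strand = character(),
                  score = double())
  if (!nrow(candidates)) return(empty)
  stopifnot(nrow(library) > 0)
  db <- blast_db_for(library)
  qfa <- tempfile(fileext = ".fa")
  safe_id <- paste0("q", seq_len(nrow(candidates)))
  writeLines(paste0(">", safe_id, "\n", candidates$sequence), qfa)
  out <- tempfile(fileext = ".tsv")
  status <- system2("blastn",
                    c("-task", "blastn", "-query", qfa, "-db", db,
                      "-outfmt",
                      shQuote(paste("6 qseqid sseqid pident length qstart",
                                    "qend sstart send bitscore slen")),
                      "-evalue", "1e-10", "-dust", "no",
                      "-soft_masking", "false", "-num_threads", "1",
                      "-out", out))
  if (status != 0) abort("blastn failed")
  lines <- readLines(out)
  unlink(c(qfa, out))
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[[`, character(1), i)
  sstart <- as.double(col(7))
  send <- as.double(col(8))
  minus <- send < sstart
  m <- tibble(
    candidate_id = candidates$candidate_id[match(col(1), safe_id)],
    family = col(2),
    identity_pct = as.double(col(3)),
    cand_start = as.double(col(5)) - 1,
    cand_end = as.double(col(6)),
    cons_start = ifelse(minus, send, sstart) - 1,
    cons_end = ifelse(minus, sstart, send),
    consensus_length = as.integer(col(10)),
    strand = ifelse(minus, "-", "+"),
    score = as.double(col(9))
  )
  m$te_coverage_pct <- 100 * (m$cons_end - m$cons_start) / m$consensus_length
  m |>
    select("candidate_id", "family", "identity_pct", "te_coverage_pct",
           "cand_start", "cand_end", "cons_start", "cons_end",
           "consensus_length", "strand", "score") |>
    arrange(dplyr::desc(.data$score))
}

# total length of the union of [start, end) intervals
interval_union_len <- function(starts, ends) {
  if (!length(starts)) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  tot + (cur_e - cur_s)
}

#' Group collinear fragment matches of one family into composite matches
#'
#' A TE that BLAST reports as several local fragments (e.g. split by an
#' internal deletion or an error cluster) is reassembled here: within each
#' (candidate, family, strand) group, hits that are collinear on candidate
#' and consensus and separated by at most `gap_tolerance` on both are merged.
#' The composite's identity is the length-weighted mean of its parts, its
#' coverage the union of consensus spans over the consensus length, and its
#' score the sum.
#'
#' @param matches Match tibble from [search_te_library()].
#' @param gap_tolerance Maximum gap (bp) bridged on candidate and consensus.
#' @return Match tibble with fragments merged; never lowers any
#'   (candidate, family) pair's best coverage.
#' @export
group_fragments <- function(matches, gap_tolerance = 100) {
  if (!nrow(matches)) return(matches)
  keep_cols <- names(matches)
  grouped <- matches |>
    group_by(.data$candidate_id, .data$family, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      merge_fragment_chain(d, key$strand, gap_tolerance)
    }) |>
    ungroup()
  grouped |>
    select(dplyr::all_of(keep_cols)) |>
    arrange(dplyr::desc(.data$score))
}

merge_fragment_chain <- function(d, strand, gap_tolerance) {
  if (nrow(d) == 1) return(d)
  d <- d[order(d$cand_start), , drop = FALSE]
  # chain assignment: a hit extends the current chain when near-collinear on
  # both axes (gaps within +/- gap_tolerance; consensus direction follows
  # strand)
  chain <- integer(nrow(d))
  chain[1] <- 1L
  for (i in 2:nrow(d)) {
    prev <- i - 1L
    cand_gap <- d$cand_start[i] - d$cand_end[prev]
    cons_gap <- if (strand == "+") d$cons_start[i] - d$cons_end[prev]
                else d$cons_start[prev] - d$cons_end[i]
    collinear <- cand_gap <= gap_tolerance && cand_gap >= -gap_tolerance &&
      cons_gap <= gap_tolerance && cons_gap >= -gap_tolerance
    chain[i] <- if (collinear) chain[prev] else chain[prev] + 1L
  }
  d$chain <- chain
  d |>
    group_by(.data$chain) |>
    summarise(
      identity_pct = sum(.data$identity_pct *
                           (.data$cand_end - .data$cand_start)) /
        sum(.data$cand_end - .data$cand_start),
      te_coverage_pct = 100 * interval_union_len(.data$cons_start,
                                                 .data$cons_end) /
        .data$consensus_length[1],
      cand_start = min(.data$cand_start),
      cand_end = max(.data$cand_end),
      cons_start = min(.data$cons_start),
      cons_end = max(.data$cons_end),
      consensus_length = .data$consensus_length[1],
      score = sum(.data$score),
      .groups = "drop"
    ) |>
    select(-"chain")
}

#' Apply the identity/coverage annotation thresholds
#'
#' Keeps matches with `identity_pct >= min_identity_pct` and
#' `te_coverage_pct >= min_te_coverage_pct` (both inclusive: the thresholds
#' are minima). Monotone: raising either threshold never enlarges the kept
#' set.
#'
#' @param matches Match tibble.
#' @param config A [te_config()].
#' @return Filtered match tibble.
#' @export
filter_matches <- function(matches, config = te_config()) {
  config <- as_te_config(config)
  matches |>
    filter(.data$identity_pct >= config$min_identity_pct,
           .data$te_coverage_pct >= config$min_te_coverage_pct)
}

#' Apply insertion-size bounds to SV candidates
#'
#' @param candidates Tibble with a `size` column (bp).
#' @param config A [te_config()]; bounds are inclusive.
#' @return Candidates with `min_te_len <= size <= max_te_len`.
#' @export
apply_length_bounds <- function(candidates, config = te_config()) {
  config <- as_te_config(config)
  candidates |>
    filter(.data$size >= config$min_te_len, .data$size <= config$max_te_len)
}

# One best family per candidate from grouped+filtered matches. Ties broken by
# higher coverage then lexicographic family name, so output is deterministic.
best_family_per_candidate <- function(matches) {
  if (!nrow(matches)) {
    return(matches |> mutate(.rank = integer(0)) |> select(-".rank"))
  }
  matches |>
    group_by(.data$candidate_id) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$te_coverage_pct),
            .data$family, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Annotate candidate sequences with their best TE family
#'
#' Convenience wrapper chaining [search_te_library()], [group_fragments()]
#' and [filter_matches()], then assigning each surviving candidate its single
#' best family (highest score; ties by coverage, then family name). When
#' several families pass the filter for one candidate, the alternatives are
#' reported in the `n_alt_families` column.
#'
#' @inheritParams search_te_library
#' @return One row per annotated candidate.
#' @export
annotate_candidates <- function(candidates, library, config = te_config()) {
  config <- as_te_config(config)
  m <- search_te_library(candidates, library, config) |>
    group_fragments(config$group_gap_tolerance) |>
    filter_matches(config)
  n_fam <- m |>
    distinct(.data$candidate_id, .data$family) |>
    dplyr::count(.data$candidate_id, name = "n_fam")
  best_family_per_candidate(m) |>
    left_join(n_fam, by = "candidate_id") |>
    mutate(n_alt_families = .data$n_fam - 1L) |>
    select(-"n_fam")
}
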