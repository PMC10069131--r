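# Outsider track: low-frequency TE insertions absent from the assembly,
# recovered from reads that map partially (large soft clips) or carry large
# insertion operations relative to the assembly. Signals are clustered around
# an anchor position, the cluster's sequences are annotated against the TE
# library, and the most informative read (highest alignment score) represents
# the call.

#' Collect raw insertion/clip signals from read alignments
#'
#' Per primary mapped read, emits one signal for every CIGAR `I` operation of
#' at least `min_ins_signal` bp (with its inserted sequence and the 0-based
#' target position it occurs at) and for every terminal soft clip of at least
#' `min_clip_signal` bp (anchored at the clip boundary). Records without
#' sequence are skipped with a warning; fully unmapped reads carry no anchor
#' and are handled separately by [call_outsider()].
#'
#' @param alignments Read-to-assembly alignment tibble.
#' @param config A [te_config()].
#' @return Signal tibble: `read_id`, `contig`, `position`, `size`, `kind`
#'   (`"ins"`, `"clip_left"`, `"clip_right"`), `sequence`, `read_offset`
#'   (0-based offset of the signal sequence within the read).
#' @export
collect_candidate_reads <- function(alignments, config = te_config()) {
  config <- as_te_config(config)
  aln <- alignments |> filter(.data$primary)
  no_seq <- is.na(aln$seq) | aln$seq == "*"
  if (any(no_seq)) {
    warn(sprintf("skipping %d alignment(s) without sequence", sum(no_seq)))
    aln <- aln[!no_seq, , drop = FALSE]
  }
  empty <- tibble(read_id = character(), contig = character(),
                  position = double(), size = double(), kind = character(),
                  sequence = character(), read_offset = double())
  if (!nrow(aln)) return(empty)
  ops <- alignment_ops(aln)
  ins <- ops |>
    filter(.data$op == "I", .data$len >= config$min_ins_signal) |>
    mutate(kind = "ins", position = .data$ref_start)
  nops <- ops |> group_by(.data$aln_idx) |> summarise(n = n())
  first_last <- ops |>
    group_by(.data$aln_idx) |>
    dplyr::slice(c(1, n())) |>
    mutate(terminal = if_else(row_number() == 1, "first", "last")) |>
    ungroup()
  clip_l <- first_last |>
    filter(.data$terminal == "first", .data$op == "S",
           .data$len >= config$min_clip_signal) |>
    mutate(kind = "clip_left", position = .data$ref_start)
  clip_r <- first_last |>
    filter(.data$terminal == "last", .data$op == "S",
           .data$len >= config$min_clip_signal) |>
    mutate(kind = "clip_right", position = .data$ref_start)
  sig <- bind_rows(ins, clip_l, clip_r)
  if (!nrow(sig)) return(empty)
  sig |>
    mutate(sequence = substr(aln$seq[.data$aln_idx], .data$qry_start + 1,
                             .data$qry_end),
           size = as.double(.data$len),
           read_offset = .data$qry_start) |>
    select("read_id", "contig", "position", "size", "kind", "sequence",
           "read_offset") |>
    arrange(.data$contig, .data$position, .data$read_id, .data$kind)
}

#' Cluster insertion/clip signals around anchor positions
#'
#' Signals on one contig within `cluster_window` bp of a growing cluster's
#' anchor (the running median of member positions) are merged. Insertion-op
#' and clip signals mix freely in one cluster; the cluster position and size
#' are the medians of its members' positions and sizes, and support is the
#' set of distinct member reads. Input order does not matter: signals are
#' re-sorted, so permuted input yields identical clusters.
#'
#' @param signals Signal tibble from [collect_candidate_reads()].
#' @param config A [te_config()].
#' @return Cluster tibble: `cluster_id`, `contig`, `position`, `size`,
#'   `n_reads`, `read_ids` (list column), `members` (list column of member
#'   signal rows).
#' @export
cluster_signals <- function(signals, config = te_config()) {
  config <- as_te_config(config)
  empty <- tibble(cluster_id = character(), contig = character(),
                  position = double(), size = double(), n_reads = integer(),
                  read_ids = list(), members = list())
  if (!nrow(signals)) return(empty)
  signals <- signals |>
    arrange(.data$contig, .data$position, .data$read_id, .data$kind)
  cl <- integer(nrow(signals))
  cur <- 1L
  cur_pos <- signals$position[1]
  cl[1] <- cur
  members_pos <- signals$position[1]
  for (i in seq_len(nrow(signals))[-1]) {
    same_contig <- signals$contig[i] == signals$contig[i - 1]
    if (same_contig &&
        abs(signals$position[i] - median(members_pos)) <=
          config$cluster_window) {
      members_pos <- c(members_pos, signals$position[i])
    } else {
      cur <- cur + 1L
      members_pos <- signals$position[i]
    }
    cl[i] <- cur
  }
  signals$cluster <- cl
  signals |>
    tidyr::nest(members = -"cluster") |>
    mutate(
      contig = purrr::map_chr(.data$members, ~ .x$contig[1]),
      position = purrr::map_dbl(.data$members, ~ round(median(.x$position))),
      size = purrr::map_dbl(.data$members, ~ round(median(.x$size))),
      read_ids = purrr::map(.data$members,
                            ~ sort(unique(.x$read_id), method = "radix")),
      n_reads = lengths(.data$read_ids),
      cluster_id = sprintf("%s:%d", .data$contig, as.integer(.data$position))
    ) |>
    select("cluster_id", "contig", "position", "size", "n_reads",
           "read_ids", "members") |>
    arrange(.data$contig, .data$position)
}

# Pool the matches of one cluster's member sequences per family: union of
# consensus coverage across reads, length-weighted identity, summed score.
# A 5' clip read and a 3' clip read jointly establish full-length TE
# evidence even when neither alone covers 80% of the consensus.
pool_cluster_matches <- function(matches) {
  matches |>
    group_by(.data$family, .data$strand) |>
    summarise(
      identity_pct = sum(.data$identity_pct *
                           (.data$cand_end - .data$cand_start)) /
        sum(.data$cand_end - .data$cand_start),
      te_coverage_pct = 100 * interval_union_len(.data$cons_start,
                                                 .data$cons_end) /
        .data$consensus_length[1],
      score = sum(.data$score),
      .groups = "drop"
    )
}

#' Select the most informative read of a signal cluster
#'
#' Searches every member signal sequence against the TE library, pools the
#' per-family evidence across members (union of consensus coverage), applies
#' the identity/coverage thresholds at cluster level, and picks the family
#' with the highest pooled score. The returned best read is the member whose
#' own match to that family scores highest (ties broken by lexicographically
#' smaller read id); clusters with no family passing the filter are dropped.
#'
#' @param clusters Cluster tibble from [cluster_signals()].
#' @param library TE library tibble.
#' @param config A [te_config()].
#' @return Annotated cluster tibble with `family`, `strand`, `identity_pct`,
#'   `te_coverage_pct` (pooled), `score`, `best_read_id`, and the best
#'   read's signal/match geometry (`best_kind`, `best_read_offset`,
#'   `best_signal_size`, `best_sequence`, `cand_start`, `cand_end`,
#'   `match_te_len`).
#' @export
select_best_read <- function(clusters, library, config = te_config()) {
  config <- as_te_config(config)
  empty <- clusters[0, ] |>
    mutate(family = character(0), strand = character(0),
           identity_pct = double(0), te_coverage_pct = double(0),
           score = double(0), best_read_id = character(0),
           best_kind = character(0), best_read_offset = double(0),
           best_signal_size = double(0), best_sequence = character(0),
           cand_start = double(0), cand_end = double(0),
           match_te_len = integer(0))
  if (!nrow(clusters)) return(empty)
  member_tbl <- clusters |>
    select("cluster_id", "members") |>
    tidyr::unnest("members") |>
    mutate(candidate_id = paste0(.data$cluster_id, "|", .data$read_id, "|",
                                 .data$kind, "|", .data$read_offset))
  m <- search_te_library(
    member_tbl |> select("candidate_id", sequence = "sequence"),
    library, config) |>
    group_fragments(config$group_gap_tolerance)
  if (!nrow(m)) return(empty)
  m <- m |>
    left_join(member_tbl |>
                select("candidate_id", "cluster_id", "read_id", "kind",
                       "read_offset", signal_size = "size",
                       signal_seq = "sequence"),
              by = "candidate_id")
  pooled <- m |>
    group_by(.data$cluster_id) |>
    dplyr::group_modify(~ pool_cluster_matches(.x)) |>
    ungroup() |>
    filter(.data$identity_pct >= config$min_identity_pct,
           .data$te_coverage_pct >= config$min_te_coverage_pct) |>
    group_by(.data$cluster_id) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$te_coverage_pct),
            .data$family, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  if (!nrow(pooled)) return(empty)
  best_member <- m |>
    dplyr::semi_join(pooled, by = c("cluster_id", "family")) |>
    group_by(.data$cluster_id) |>
    arrange(dplyr::desc(.data$score), .data$read_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster_id", best_read_id = "read_id", best_kind = "kind",
           best_read_offset = "read_offset",
           best_signal_size = "signal_size", best_sequence = "signal_seq",
           "cand_start", "cand_end", "consensus_length")
  clusters |>
    dplyr::inner_join(pooled, by = "cluster_id") |>
    dplyr::inner_join(best_member, by = "cluster_id") |>
    rename(match_te_len = "consensus_length")
}

#' Call outsider TE insertions
#'
#' Full outsider track: signal collection from read alignments, positional
#' clustering, insertion-size bounds on the cluster size, cluster-level TE
#' annotation with best-read selection, and conversion to point calls
#' (`[position, position + 1)` on the assembly). Fully unmapped reads are
#' searched against the library and their TE content logged, but produce no
#' positioned call. A single informative read is sufficient support by
#' default (`min_support`).
#'
#' @param assembly Named `DNAStringSet` (used only for bounds checking; may
#'   be `NULL`).
#' @param reads Read tibble ([load_reads()]) used to recover sequences for
#'   unmapped-read logging; may be `NULL`.
#' @param library TE library tibble.
#' @param alignments Read-to-assembly alignment tibble (with sequences).
#' @param config A [te_config()].
#' @return Calls tibble with the same core columns as [call_insider()] plus
#'   `supporting` (distinct supporting reads) and the best-read geometry
#'   used for TSD detection.
#' @export
call_outsider <- function(assembly, reads, library, alignments,
                          config = te_config()) {
  config <- as_te_config(config)
  unmapped <- alignments |> filter(.data$unmapped)
  if (nrow(unmapped)) {
    useq <- unmapped$seq
    if (all(is.na(useq)) && !is.null(reads)) {
      useq <- reads$sequence[match(unmapped$read_id, reads$read_id)]
    }
    useq <- useq[!is.na(useq)]
    if (length(useq)) {
      um <- search_te_library(setNames(useq, paste0("unmapped", seq_along(useq))),
                              library, config) |>
        filter_matches(config)
      inform(sprintf(
        "%d unmapped read(s); %d with TE hits (no positioned call emitted)",
        nrow(unmapped), length(unique(um$candidate_id))))
    }
  }
  clusters <- collect_candidate_reads(alignments, config) |>
    cluster_signals(config) |>
    filter(.data$n_reads >= config$min_support) |>
    apply_length_bounds(config)
  ann <- select_best_read(clusters, library, config)
  empty <- tibble(contig = character(), start = double(), end = double(),
                  family = character(), call_class = character(),
                  kind = character(), strand = character(),
                  identity_pct = double(), te_coverage_pct = double(),
                  score = double(), supporting = integer(),
                  best_read_id = character(), best_kind = character(),
                  best_read_offset = double(), best_signal_size = double(),
                  best_sequence = character(), cand_start = double(),
                  cand_end = double(), match_te_len = integer(),
                  ref_pos = double())
  if (!nrow(ann)) return(empty)
  ann |>
    mutate(start = .data$position, end = .data$position + 1,
           call_class = "OUTSIDER", kind = "insertion",
           supporting = .data$n_reads, ref_pos = NA_real_) |>
    select("contig", "start", "end", "family", "call_class", "kind",
           "strand", "identity_pct", "te_coverage_pct", "score",
           "supporting", "best_read_id", "best_kind", "best_read_offset",
           "best_signal_size", "best_sequence", "cand_start", "cand_end",
           "match_te_len", "ref_pos") |>
    arrange(.data$contig, .data$start)
}
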