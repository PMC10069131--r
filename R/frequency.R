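# Allele-frequency estimation: how many of the pooled haplotypes carry each
# insertion. The numerator counts reads showing the insertion, the
# denominator is the local read depth averaged over two 30 bp windows
# flanking the junction(s). Insider and outsider calls need different
# numerators: an insider TE is part of the assembly, so carrier reads align
# straight through its junctions while non-carrier reads show a TE-sized
# deletion or a clip there; an outsider TE is absent from the assembly, so
# carrier reads show a large insertion operation or a terminal clip at the
# insertion point.

#' Local read depth around a junction pair
#'
#' Mean per-base depth over `[junction5 - depth_window, junction5)` and
#' `[junction3, junction3 + depth_window)`, averaged and rounded. Secondary,
#' supplementary and unmapped records are excluded. Windows are truncated
#' (with a warning) at contig bounds when `contig_length` is supplied.
#'
#' @param alignments Read alignment tibble.
#' @param contig Contig name.
#' @param junction5,junction3 0-based junction coordinates (equal for a
#'   point insertion).
#' @param config A [te_config()].
#' @param contig_length Optional contig length for bounds truncation.
#' @return Rounded mean depth (integer).
#' @export
local_depth <- function(alignments, contig, junction5, junction3,
                        config = te_config(), contig_length = NULL) {
  config <- as_te_config(config)
  w <- config$depth_window
  win <- rbind(c(junction5 - w, junction5), c(junction3, junction3 + w))
  if (!is.null(contig_length)) {
    clipped <- pmax(pmin(win, contig_length), 0)
    if (!identical(clipped, win)) {
      warn("depth window truncated at contig bounds")
      win <- clipped
    }
  }
  aln <- alignments |>
    filter(.data$primary, .data$contig == !!contig)
  mean_depth <- vapply(seq_len(nrow(win)), function(k) {
    lo <- win[k, 1]; hi <- win[k, 2]
    if (hi <= lo) return(NA_real_)
    ov <- pmax(0, pmin(aln$ref_end, hi) - pmax(aln$pos, lo))
    sum(ov) / (hi - lo)
  }, double(1))
  as.integer(round(mean(mean_depth, na.rm = TRUE)))
}

# Reads that cleanly cover junction +/- jw: alignment spans the window, and
# no structural-size indel op (>= min_ins_signal) touches it. Small
# sequencing-error indels inside the window do not disqualify a read.
clean_junction_readers <- function(aln, ops, junction, jw, min_struct) {
  covers <- aln$pos <= junction - jw & aln$ref_end >= junction + jw
  if (!any(covers)) return(character(0))
  bad <- ops |>
    filter(.data$op %in% c("I", "D"), .data$len >= min_struct,
           .data$ref_end >= junction - jw, .data$ref_start <= junction + jw)
  setdiff(unique(aln$read_id[covers]), unique(bad$read_id))
}

#' Estimate the allele frequency of an insider insertion
#'
#' Reads overlapping the call within `insider_fetch_window` are fetched
#' (supplementary and secondary records excluded, the SAM flag-2048
#' convention). A read supports the insertion when it cleanly covers a
#' junction `+/- insider_junction_window`: clipped-there reads and reads
#' whose alignment jumps the TE with a structural-size deletion are
#' non-carriers and do not count. The supporting count is the rounded mean
#' over the two junctions; the denominator is [local_depth()] at the same
#' junctions.
#'
#' @param alignments Read alignment tibble.
#' @param call One-row insider insertion call.
#' @param config A [te_config()].
#' @return Tibble `supporting`, `spanning_total`, `frequency` (clamped to
#'   \[0, 1\]; `NA` with a warning when the local depth is zero).
#' @export
insider_frequency <- function(alignments, call, config = te_config()) {
  config <- as_te_config(config)
  fw <- config$insider_fetch_window
  jw <- config$insider_junction_window
  aln <- alignments |>
    filter(.data$primary, .data$contig == call$contig,
           .data$pos < call$end + fw, .data$ref_end > call$start - fw)
  ops <- alignment_ops(aln) |>
    filter(.data$op %in% c("I", "D"), .data$len >= config$min_ins_signal)
  n5 <- length(clean_junction_readers(aln, ops, call$start, jw,
                                      config$min_ins_signal))
  n3 <- length(clean_junction_readers(aln, ops, call$end, jw,
                                      config$min_ins_signal))
  supporting <- as.integer(round(mean(c(n5, n3))))
  total <- local_depth(aln, call$contig, call$start, call$end, config)
  freq <- if (is.na(total) || total == 0) {
    warn("zero local depth: frequency reported as NA")
    NA_real_
  } else {
    min(1, max(0, supporting / total))
  }
  tibble(supporting = supporting, spanning_total = total, frequency = freq)
}

#' Rewrite junction clips as insertion operations
#'
#' For outsider frequency estimation, a read clipped at the insertion point
#' carries the TE but no insertion operation. Its terminal soft clip is
#' rewritten as an `I` operation of the TE length plus `cigar_rewrite_pad`
#' bp, the read sequence receives that many `N` bases at the corresponding
#' position with phred quality `fake_quality`, and the clipped bases beyond
#' the insertion are dropped, so the rewritten record counts like a read
#' containing the full insertion. Records whose clip is on the wrong side of
#' (or not at) the junction are left untouched.
#'
#' @param alignments Read alignment tibble.
#' @param call One-row outsider call (`start` is the insertion point).
#' @param te_length TE length (bp) to rewrite the clip as.
#' @param config A [te_config()].
#' @return `alignments` with qualifying records rewritten (CIGARs stay
#'   length-consistent with the sequences).
#' @export
rewrite_clips_as_insertions <- function(alignments, call, te_length,
                                        config = te_config()) {
  config <- as_te_config(config)
  win <- config$cluster_window
  ins_len <- te_length + config$cigar_rewrite_pad
  n_block <- strrep("N", ins_len)
  q_block <- strrep(rawToChar(as.raw(33 + config$fake_quality)), ins_len)
  aln <- alignments
  for (i in seq_len(nrow(aln))) {
    if (!aln$primary[i] || aln$contig[i] != call$contig) next
    right_at <- aln$right_clip[i] > 0 &&
      abs(aln$ref_end[i] - call$start) <= win
    left_at <- aln$left_clip[i] > 0 && abs(aln$pos[i] - call$start) <= win
    if (!right_at && !left_at) next
    m <- merge_ops(
      GenomicAlignments::explodeCigarOps(aln$cigar[i])[[1]],
      GenomicAlignments::explodeCigarOpLengths(aln$cigar[i])[[1]])
    op <- m$op; len <- m$len
    seq <- aln$seq[i]; qual <- aln$qual[i]
    if (right_at && op[length(op)] == "S") {
      keep <- nchar(seq) - len[length(len)]
      op <- c(op[-length(op)], "I")
      len <- c(len[-length(len)], ins_len)
      seq <- paste0(substr(seq, 1, keep), n_block)
      if (!is.na(qual)) qual <- paste0(substr(qual, 1, keep), q_block)
    } else if (left_at && op[1] == "S") {
      drop <- len[1]
      op <- c("I", op[-1])
      len <- c(ins_len, len[-1])
      seq <- paste0(n_block, substr(seq, drop + 1, nchar(seq)))
      if (!is.na(qual)) qual <- paste0(q_block, substr(qual, drop + 1,
                                                       nchar(qual)))
    } else {
      next
    }
    aln$cigar[i] <- ops_to_cigar(op, len)
    aln$seq[i] <- seq
    aln$qual[i] <- qual
    aln$left_clip[i] <- if (left_at) 0L else aln$left_clip[i]
    aln$right_clip[i] <- if (right_at) 0L else aln$right_clip[i]
  }
  aln
}

#' Estimate the allele frequency of an outsider insertion
#'
#' Restricts to reads near the call, rewrites junction clips as insertion
#' operations ([rewrite_clips_as_insertions()]), re-runs signal collection
#' and clustering on the rewritten records, and counts the distinct reads in
#' the cluster at the call position (a read contributing both a clip and an
#' insertion op counts once). The denominator is [local_depth()] with both
#' windows adjacent to the insertion point.
#'
#' @param alignments Read alignment tibble.
#' @param call One-row outsider call.
#' @param te_length Matched TE consensus length (bp), used for the clip
#'   rewrite.
#' @param config A [te_config()].
#' @return Tibble `supporting`, `spanning_total`, `frequency` (`NA`
#'   frequency when no reads span the site).
#' @export
outsider_frequency <- function(alignments, call, te_length,
                               config = te_config()) {
  config <- as_te_config(config)
  fw <- config$insider_fetch_window
  aln <- alignments |>
    filter(.data$primary, .data$contig == call$contig,
           .data$pos < call$start + fw, .data$ref_end > call$start - fw)
  aln <- rewrite_clips_as_insertions(aln, call, te_length, config)
  clusters <- collect_candidate_reads(aln, config) |>
    cluster_signals(config)
  supporting <- 0L
  if (nrow(clusters)) {
    near <- clusters |>
      mutate(dist = abs(.data$position - call$start)) |>
      filter(.data$dist <= config$cluster_window) |>
      arrange(.data$dist)
    if (nrow(near)) {
      # Count carriers per flank side and average, mirroring the two-window
      # depth denominator: a read that only grazes the TE (clip anchored at
      # the junction but alignment ending there) covers just one flank
      # window, so counting it once against both windows would inflate the
      # estimate for long TEs.
      ids <- near$read_ids[[1]]
      sub <- aln |> filter(.data$read_id %in% ids, .data$primary)
      w <- config$depth_window
      n5 <- length(unique(sub$read_id[sub$pos <= call$start - w &
                                        sub$ref_end >= call$start]))
      n3 <- length(unique(sub$read_id[sub$ref_end >= call$start + w &
                                        sub$pos <= call$start]))
      supporting <- round(mean(c(n5, n3)))
    }
  }
  total <- local_depth(aln, call$contig, call$start, call$start, config)
  freq <- if (is.na(total) || total == 0) {
    warn("zero local depth: frequency reported as NA")
    NA_real_
  } else {
    min(1, max(0, supporting / total))
  }
  tibble(supporting = as.integer(supporting), spanning_total = total,
         frequency = freq)
}

#' Estimate allele frequencies for a whole call set
#'
#' Dispatches each call to [insider_frequency()] or [outsider_frequency()];
#' deletion calls receive no frequency (reads cannot "support" an absence
#' the same way, and no procedure is defined for them).
#'
#' @param calls Calls tibble.
#' @param alignments Read-to-assembly alignment tibble.
#' @param library TE library tibble (for consensus lengths in the clip
#'   rewrite).
#' @param config A [te_config()].
#' @return `calls` with `supporting`, `spanning_total`, `frequency` columns.
#' @export
estimate_frequencies <- function(calls, alignments, library,
                                 config = te_config()) {
  config <- as_te_config(config)
  calls$supporting <- NA_integer_
  calls$spanning_total <- NA_integer_
  calls$frequency <- NA_real_
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$kind != "insertion") next
    fe <- if (cl$call_class == "INSIDER") {
      insider_frequency(alignments, cl, config)
    } else {
      te_len <- library$length[match(cl$family, library$family)]
      if (is.na(te_len)) te_len <- cl$best_signal_size
      outsider_frequency(alignments, cl, te_len, config)
    }
    calls$supporting[i] <- fe$supporting
    calls$spanning_total[i] <- fe$spanning_total
    calls$frequency[i] <- fe$frequency
  }
  calls
}
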