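# Insider track: TE insertions/deletions already incorporated in the sample
# assembly, recovered from a whole-genome pairwise alignment of the assembly
# (query) against the reference (target). SV signals come from two places:
# large I/D operations inside one alignment, and length discrepancies between
# consecutive alignments of the same contig.

INSERTION_TYPES <- c("INSERTION", "Repeat_expansion", "Tandem_expansion")
DELETION_TYPES <- c("DELETION", "Repeat_contraction", "Tandem_contraction")

#' Extract structural-variant candidates from genome-to-genome alignments
#'
#' Within-alignment signals: CIGAR `I` operations of at least `min_te_len`
#' become `INSERTION` candidates (positioned on the assembly/query), `D`
#' operations become `DELETION` candidates (positioned on the reference).
#' Between-alignment signals: for consecutive anchor alignments of one contig
#' on one reference contig, a query gap exceeding the reference gap by
#' `min_te_len` is insertion-like (and vice versa for deletions); events
#' whose flanking anchors overlap on the other genome are classified as
#' `Tandem_*` expansions/contractions. Anchors are alignments with at least
#' `anchor_min_len` aligned bases, or the contig's primary alignment.
#'
#' @param alignments Contig-to-reference alignment tibble
#'   ([parse_alignments()] on a PAF, or simulator truth).
#' @param config A [te_config()].
#' @return SV candidate tibble: `sv_type`, `contig` (genome the candidate
#'   sequence lives on: assembly contig for insertion-like, reference contig
#'   for deletion-like), `position`, `size`, `ref_pos` (homologous reference
#'   anchor), `query_id`, `target_id`, `source`.
#' @export
extract_svs <- function(alignments, config = te_config()) {
  config <- as_te_config(config)
  aln <- alignments |> filter(!.data$unmapped)
  empty <- tibble(sv_type = character(), contig = character(),
                  position = double(), size = double(), ref_pos = double(),
                  query_id = character(), target_id = character(),
                  source = character())
  if (!nrow(aln)) return(empty)

  ops <- alignment_ops(aln)
  big <- ops |>
    filter(.data$op %in% c("I", "D"), .data$len >= config$min_te_len)
  within_sv <- empty
  if (nrow(big)) {
    minus <- bitwAnd(aln$flag[big$aln_idx], 16L) > 0L
    qlen <- cigar_query_width(aln$cigar[big$aln_idx])
    qpos <- ifelse(minus, qlen - big$qry_end, big$qry_start)
    within_sv <- tibble(
      sv_type = ifelse(big$op == "I", "INSERTION", "DELETION"),
      contig = ifelse(big$op == "I", aln$read_id[big$aln_idx],
                      aln$contig[big$aln_idx]),
      position = ifelse(big$op == "I", qpos, big$ref_start),
      size = as.double(big$len),
      ref_pos = big$ref_start,
      query_id = aln$read_id[big$aln_idx],
      target_id = aln$contig[big$aln_idx],
      source = "assembly_pair"
    )
  }

  between_sv <- between_alignment_svs(aln, config)
  bind_rows(within_sv, between_sv) |>
    arrange(.data$contig, .data$position)
}

between_alignment_svs <- function(aln, config) {
  anchors <- aln |>
    mutate(aligned_len = .data$ref_end - .data$pos,
           qlen = cigar_query_width(.data$cigar),
           q_from = ifelse(bitwAnd(.data$flag, 16L) > 0L,
                           .data$right_clip, .data$left_clip),
           q_to = .data$qlen - ifelse(bitwAnd(.data$flag, 16L) > 0L,
                                      .data$left_clip, .data$right_clip)) |>
    filter(.data$aligned_len >= config$anchor_min_len | .data$primary) |>
    arrange(.data$read_id, .data$q_from)
  out <- list()
  if (nrow(anchors) < 2) return(bind_rows(out))
  for (i in seq_len(nrow(anchors) - 1)) {
    a <- anchors[i, ]; b <- anchors[i + 1, ]
    if (a$read_id != b$read_id || a$contig != b$contig) next
    if (bitwAnd(a$flag, 16L) != bitwAnd(b$flag, 16L)) next
    q_gap <- b$q_from - a$q_to
    r_gap <- b$pos - a$ref_end
    ins_size <- q_gap - r_gap
    del_size <- r_gap - q_gap
    if (ins_size >= config$min_te_len && ins_size >= del_size) {
      out[[length(out) + 1]] <- tibble(
        sv_type = if (r_gap < 0) "Tandem_expansion" else "INSERTION",
        contig = a$read_id, position = as.double(a$q_to),
        size = as.double(ins_size), ref_pos = as.double(a$ref_end),
        query_id = a$read_id, target_id = a$contig, source = "assembly_pair")
    } else if (del_size >= config$min_te_len) {
      out[[length(out) + 1]] <- tibble(
        sv_type = if (q_gap < 0) "Tandem_contraction" else "DELETION",
        contig = a$contig, position = as.double(a$ref_end),
        size = as.double(del_size), ref_pos = as.double(a$ref_end),
        query_id = a$read_id, target_id = a$contig, source = "assembly_pair")
    }
  }
  bind_rows(out)
}

#' Retrieve the DNA sequence of an SV candidate
#'
#' Insertion-like candidates (`INSERTION`, `Repeat_expansion`,
#' `Tandem_expansion`) physically live on the assembly, so their sequence is
#' taken from the query genome; deletion-like candidates are recovered from
#' the reference.
#'
#' @param svs SV candidate tibble from [extract_svs()].
#' @param reference,assembly Named `DNAStringSet` genomes.
#' @return `svs` with a `sequence` column (`nchar(sequence) == size`).
#' @export
retrieve_sv_sequence <- function(svs, reference, assembly) {
  if (!nrow(svs)) return(svs |> mutate(sequence = character(0)))
  seqs <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    genome <- if (svs$sv_type[i] %in% INSERTION_TYPES) assembly else reference
    ctg <- svs$contig[i]
    if (!ctg %in% names(genome)) {
      abort(paste0("contig not found in genome FASTA: ", ctg))
    }
    glen <- Biostrings::width(genome[ctg])
    s <- svs$position[i]; e <- s + svs$size[i]
    if (s < 0 || e > glen) {
      abort(sprintf("SV coordinates [%d,%d) out of bounds for %s (%d bp)",
                    s, e, ctg, glen))
    }
    seqs[i] <- as.character(Biostrings::subseq(genome[[ctg]], s + 1, e))
  }
  svs$sequence <- seqs
  svs
}

#' Call insider TE insertions/deletions
#'
#' Full insider track: SV extraction from the assembly-vs-reference
#' alignment, size bounds, sequence retrieval, TE-library annotation under
#' the identity/coverage rule, and conversion of surviving candidates to
#' calls. Insertion calls are reported on assembly coordinates (where the TE
#' physically is), with the homologous reference position kept in `ref_pos`;
#' deletion calls are reported on reference coordinates.
#'
#' @param reference,assembly Named `DNAStringSet` genomes.
#' @param library TE library tibble.
#' @param alignments Contig-to-reference alignment tibble.
#' @param config A [te_config()].
#' @return Calls tibble: `contig`, `start`, `end`, `family`, `call_class`
#'   (`"INSIDER"`), `kind` (`"insertion"`/`"deletion"`), `strand`,
#'   `identity_pct`, `te_coverage_pct`, `score`, `cand_start`, `cand_end`
#'   (matched span on the candidate, used downstream for TSD flanks),
#'   `ref_pos`, `best_read_id` (`NA` for insider calls).
#' @export
call_insider <- function(reference, assembly, library, alignments,
                         config = te_config()) {
  config <- as_te_config(config)
  svs <- extract_svs(alignments, config) |>
    apply_length_bounds(config)
  empty <- tibble(contig = character(), start = double(), end = double(),
                  family = character(), call_class = character(),
                  kind = character(), strand = character(),
                  identity_pct = double(), te_coverage_pct = double(),
                  score = double(), cand_start = double(),
                  cand_end = double(), ref_pos = double(),
                  best_read_id = character())
  if (!nrow(svs)) return(empty)
  svs <- retrieve_sv_sequence(svs, reference, assembly) |>
    mutate(candidate_id = paste0("sv", row_number()))
  ann <- annotate_candidates(
    svs |> select("candidate_id", sequence = "sequence"), library, config)
  if (!nrow(ann)) return(empty)
  svs |>
    dplyr::inner_join(ann, by = "candidate_id") |>
    mutate(
      start = .data$position,
      end = .data$position + .data$size,
      call_class = "INSIDER",
      kind = if_else(.data$sv_type %in% INSERTION_TYPES,
                     "insertion", "deletion"),
      best_read_id = NA_character_
    ) |>
    select("contig", "start", "end", "family", "call_class", "kind",
           "strand", "identity_pct", "te_coverage_pct", "score",
           "cand_start", "cand_end", "ref_pos", "best_read_id") |>
    arrange(.data$contig, .data$start)
}
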