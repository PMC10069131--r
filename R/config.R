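#' Pipeline configuration
#'
#' Collects every tunable numeric parameter of the caller in one list, with
#' defaults matching the method's standard settings: the 80/80
#' identity/length-coverage annotation rule, 200 bp--15 kb insertion size
#' bounds, 30 bp flanks for target-site-duplication (TSD) search, a 30 bp
#' clustering window for read signals, and the depth windows used by the
#' frequency estimator.
#'
#' @param min_identity_pct Minimum percent identity of a candidate sequence to
#'   a TE consensus for the candidate to be annotated as that family.
#' @param min_te_coverage_pct Minimum percentage of the TE consensus length
#'   that must be covered by the (grouped) alignment. Lowering this (the
#'   method tolerates values down to 10) recovers truncated or internally
#'   deleted copies at some cost in specificity.
#' @param min_te_len,max_te_len Size bounds (bp) applied to candidate
#'   insertions/deletions before annotation.
#' @param tsd_flank Width (bp) of the junction flanks searched for TSDs.
#' @param tsd_max_mismatch_insider,tsd_max_mismatch_outsider Mismatches
#'   tolerated in the TSD motif match; exact for assembly-derived (insider)
#'   junctions, 1 by default for read-derived (outsider) junctions to absorb
#'   long-read errors.
#' @param tsd_min_len Minimum reported TSD motif length (bp).
#' @param tsd_junction_tolerance Maximum distance (bp) between a TSD motif
#'   occurrence and the detected insertion junction; motifs farther away are
#'   treated as pre-existing duplications and discarded.
#' @param cluster_window Window (bp) used to cluster read signals around an
#'   insertion anchor point, and to score calls against planted truth.
#' @param min_ins_signal Minimum CIGAR insertion-operation length (bp) that
#'   counts as a raw insertion signal; also the size from which an indel is
#'   considered "structural" when judging whether a read cleanly spans a
#'   junction.
#' @param min_clip_signal Minimum soft-clip length (bp) that counts as a raw
#'   clip signal.
#' @param min_support Minimum number of distinct supporting reads for an
#'   outsider call (a single informative long read suffices by default).
#' @param insider_fetch_window Window (bp) around an insider call within which
#'   reads are fetched for frequency estimation.
#' @param insider_junction_window Half-width (bp) of the junction window a
#'   read must cover cleanly (no clip boundary, no structural indel) to count
#'   as supporting an insider insertion.
#' @param depth_window Width (bp) of the two flanking windows over which local
#'   read depth is averaged to obtain the frequency denominator.
#' @param cigar_rewrite_pad Extra bases added to the TE length when a terminal
#'   soft clip is rewritten as an insertion operation during outsider
#'   frequency estimation.
#' @param fake_quality Phred quality assigned to the `N` bases introduced by
#'   the clip rewrite.
#' @param group_gap_tolerance Maximum gap (bp), on both the candidate and the
#'   consensus, across which collinear fragment matches of one family are
#'   grouped into a composite match.
#' @param anchor_min_len Minimum aligned length (bp) for a genome-to-genome
#'   alignment to serve as an anchor for between-alignment SV signals (primary
#'   alignments always qualify).
#'
#' @return A named list of class `te_config`.
#' @examples
#' cfg <- te_config(min_te_coverage_pct = 10)
#' cfg$min_te_coverage_pct
#' @export
te_config <- function(min_identity_pct = 80,
                      min_te_coverage_pct = 80,
                      min_te_len = 200,
                      max_te_len = 15000,
                      tsd_flank = 30,
                      tsd_max_mismatch_insider = 0,
                      tsd_max_mismatch_outsider = 1,
                      tsd_min_len = 2,
                      tsd_junction_tolerance = 2,
                      cluster_window = 30,
                      min_ins_signal = 30,
                      min_clip_signal = 200,
                      min_support = 1,
                      insider_fetch_window = 100,
                      insider_junction_window = 5,
                      depth_window = 30,
                      cigar_rewrite_pad = 10,
                      fake_quality = 8,
                      group_gap_tolerance = 100,
                      anchor_min_len = 10000) {
  cfg <- list(
    min_identity_pct = min_identity_pct,
    min_te_coverage_pct = min_te_coverage_pct,
    min_te_len = min_te_len,
    max_te_len = max_te_len,
    tsd_flank = tsd_flank,
    tsd_max_mismatch_insider = tsd_max_mismatch_insider,
    tsd_max_mismatch_outsider = tsd_max_mismatch_outsider,
    tsd_min_len = tsd_min_len,
    tsd_junction_tolerance = tsd_junction_tolerance,
    cluster_window = cluster_window,
    min_ins_signal = min_ins_signal,
    min_clip_signal = min_clip_signal,
    min_support = min_support,
    insider_fetch_window = insider_fetch_window,
    insider_junction_window = insider_junction_window,
    depth_window = depth_window,
    cigar_rewrite_pad = cigar_rewrite_pad,
    fake_quality = fake_quality,
    group_gap_tolerance = group_gap_tolerance,
    anchor_min_len = anchor_min_len
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) abort("all te_config() parameters must be numeric")
  if (any(unlist(cfg[setdiff(names(cfg), c("tsd_max_mismatch_insider",
                                           "tsd_max_mismatch_outsider",
                                           "fake_quality"))]) <= 0)) {
    abort("te_config() parameters must be positive")
  }
  if (min_te_len >= max_te_len) abort("min_te_len must be < max_te_len")
  structure(cfg, class = c("te_config", "list"))
}

as_te_config <- function(config) {
  if (inherits(config, "te_config")) return(config)
  if (is.null(config)) return(te_config())
  do.call(te_config, as.list(config))
}

#' Depth of coverage per pooled haplotype
#'
#' For a library sequenced from a pool of haploid genomes, the chance that a
#' given haplotype contributed a read covering a locus is the total depth
#' divided by the number of pooled haplotypes. A 183x library over 200
#' haploid genomes (100 diploid individuals) therefore probes each haplotype
#' at about 0.91x, which bounds how rare an insertion can be and still leave
#' supporting reads.
#'
#' @param total_depth Mean depth of the pooled library (x).
#' @param n_haplotypes Number of haploid genomes in the pool.
#' @return Depth per haplotype (x).
#' @examples
#' depth_per_haplotype(183, 200)
#' @export
depth_per_haplotype <- function(total_depth, n_haplotypes) {
  stopifnot(total_depth > 0, n_haplotypes >= 1)
  total_depth / n_haplotypes
}
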