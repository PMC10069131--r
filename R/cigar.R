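# CIGAR arithmetic. All coordinates are 0-based half-open; GenomicAlignments
# does the heavy exploding/width work, this file adds the bookkeeping the
# caller needs (clip lengths, per-op genome/read offsets, run merging).

REF_OPS <- c("M", "D", "=", "X", "N")
QRY_OPS <- c("M", "I", "S", "=", "X")

cigar_ref_width <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  out
}

cigar_query_width <- function(cigar, with_clips = TRUE) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    out[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
      cigar[ok], after.soft.clipping = !with_clips)
  }
  out
}

# terminal S/H lengths; H carries no sequence but still counts for clip
# bookkeeping (soft-only lengths are available via `soft_only`)
cigar_clips <- function(cigar, soft_only = FALSE) {
  n <- length(cigar)
  left <- integer(n)
  right <- integer(n)
  ok <- which(!is.na(cigar) & cigar != "*")
  if (length(ok)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[ok])
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[ok])
    keep <- if (soft_only) "S" else c("S", "H")
    left[ok] <- vapply(seq_along(ops), function(i) {
      o <- ops[[i]]; l <- lens[[i]]
      tot <- 0L
      for (j in seq_along(o)) {
        if (o[j] %in% keep) tot <- tot + l[j]
        else if (!(o[j] %in% c("S", "H"))) break
      }
      tot
    }, integer(1))
    right[ok] <- vapply(seq_along(ops), function(i) {
      o <- rev(ops[[i]]); l <- rev(lens[[i]])
      tot <- 0L
      for (j in seq_along(o)) {
        if (o[j] %in% keep) tot <- tot + l[j]
        else if (!(o[j] %in% c("S", "H"))) break
      }
      tot
    }, integer(1))
  }
  tibble(left_clip = left, right_clip = right)
}

# Explode the CIGARs of an alignment tibble into one long tibble with per-op
# genome and read offsets:
#   ref_start/ref_end : 0-based half-open target interval the op consumes
#   qry_start/qry_end : 0-based half-open interval on the stored SEQ (soft
#                       clips included, hard clips absent)
alignment_ops <- function(aln) {
  ok <- which(!is.na(aln$cigar) & aln$cigar != "*")
  if (!length(ok)) {
    return(tibble(aln_idx = integer(), read_id = character(),
                  contig = character(), op = character(), len = integer(),
                  ref_start = double(), ref_end = double(),
                  qry_start = double(), qry_end = double()))
  }
  ops_l <- GenomicAlignments::explodeCigarOps(aln$cigar[ok])
  lens_l <- GenomicAlignments::explodeCigarOpLengths(aln$cigar[ok])
  nops <- lengths(ops_l)
  idx <- rep(ok, nops)
  op <- unlist(ops_l, use.names = FALSE)
  len <- unlist(lens_l, use.names = FALSE)
  ref_adv <- ifelse(op %in% REF_OPS, len, 0L)
  qry_adv <- ifelse(op %in% QRY_OPS, len, 0L)
  # per-alignment cumulative offsets without grouping: subtract the running
  # total at each alignment's first row
  cs_r <- cumsum(as.double(ref_adv))
  cs_q <- cumsum(as.double(qry_adv))
  first <- cumsum(c(1L, head(nops, -1L)))
  start_r <- cs_r - ref_adv
  start_q <- cs_q - qry_adv
  grp_base_r <- rep(start_r[first], nops)
  grp_base_q <- rep(start_q[first], nops)
  ref_start <- rep(aln$pos[ok], nops) + (start_r - grp_base_r)
  qry_start <- start_q - grp_base_q
  tibble(
    aln_idx = idx,
    read_id = rep(aln$read_id[ok], nops),
    contig = rep(aln$contig[ok], nops),
    op = op,
    len = len,
    ref_start = ref_start,
    ref_end = ref_start + ref_adv,
    qry_start = qry_start,
    qry_end = qry_start + qry_adv
  )
}

# collapse zero-length ops and merge adjacent runs of the same op
merge_ops <- function(op, len) {
  keep <- len > 0
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return(list(op = character(), len = integer()))
  same <- c(FALSE, op[-1] == op[-length(op)])
  grp <- cumsum(!same)
  list(op = op[!same],
       len = as.integer(tapply(len, grp, sum)[as.character(unique(grp))]))
}

ops_to_cigar <- function(op, len) {
  m <- merge_ops(op, len)
  if (!length(m$op)) return("*")
  paste0(m$len, m$op, collapse = "")
}

# Derive the standard per-record columns (flag bits, clips, reference end)
# from raw SAM-like fields. Kept idempotent so readers and the simulator can
# both funnel through it.
finalize_alignments <- function(aln) {
  aln <- as_tibble(aln)
  needed <- c("read_id", "flag", "contig", "pos", "cigar", "seq")
  missing_cols <- setdiff(needed, names(aln))
  if (length(missing_cols)) {
    abort(paste0("alignment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"mapq" %in% names(aln)) aln$mapq <- 60L
  if (!"qual" %in% names(aln)) aln$qual <- NA_character_
  flag <- as.integer(aln$flag)
  aln$unmapped <- bitwAnd(flag, 4L) > 0L
  aln$secondary <- bitwAnd(flag, 256L) > 0L
  aln$supplementary <- bitwAnd(flag, 2048L) > 0L
  aln$primary <- !aln$unmapped & !aln$secondary & !aln$supplementary
  clips <- cigar_clips(aln$cigar)
  aln$left_clip <- clips$left_clip
  aln$right_clip <- clips$right_clip
  aln$ref_end <- aln$pos + cigar_ref_width(aln$cigar)
  # sanity: query-consuming ops must match the stored sequence
  has_seq <- !is.na(aln$seq) & aln$seq != "*" & !aln$unmapped
  qw <- cigar_query_width(aln$cigar)
  bad <- has_seq & !is.na(qw) & qw != nchar(aln$seq)
  if (any(bad)) {
    warn(sprintf("dropping %d alignment(s) with CIGAR/sequence length mismatch",
                 sum(bad)))
    aln <- aln[!bad, , drop = FALSE]
  }
  aln
}
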