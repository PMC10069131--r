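# Synthetic benchmark generator. The design mirrors the standard three-pool
# simulation for this problem: a base genome; an "assembly" haplotype
# carrying ~100 high-frequency (insider) TE insertions; a third haplotype
# carrying 1000 additional low-frequency (outsider) insertions on top of the
# insider ones. Long reads are drawn from the three haplotypes at a chosen
# depth mix (default 10x/45x/5x, 60x total), so each insertion's population
# frequency is encoded purely by the depth ratios: insiders ride in pools 2+3
# (50/60 ~ 0.83), outsiders only in pool 3 (5/60 ~ 0.083). Ground-truth
# alignments of every read against the assembly haplotype are emitted
# alongside, so the detection and frequency modules can be exercised without
# an external aligner.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic TE consensus library
#'
#' Twelve families named after classic *Drosophila* TE families, with
#' consensus lengths spanning the realistic 1.3-11.7 kb range (mean ~5 kb)
#' and random uniform-composition sequences. The library is deterministic
#' for a given seed and independent of the caller's RNG state.
#'
#' @param seed Seed for the library sequences.
#' @return TE library tibble (`family`, `sequence`, `length`).
#' @export
synthetic_te_library <- function(seed = 7202) {
  lens <- c(ZAM = 8400, gtwin = 7400, Doc = 4700, roo = 9100, copia = 5100,
            `F-element` = 4700, hopper = 1400, Helena = 1300, HB = 1600,
            `TART-A` = 11700, gypsy = 7400, Idefix = 7400)
  with_seed(seed, {
    tibble(
      family = names(lens),
      sequence = vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
      }, character(1), USE.NAMES = FALSE),
      length = as.integer(unname(lens))
    )
  })
}

insider_default_counts <- function() {
  c(ZAM = 5, gtwin = 5, Doc = 10, roo = 10, copia = 10, `F-element` = 10,
    hopper = 10, Helena = 10, HB = 10, `TART-A` = 10, gypsy = 10)
}

outsider_default_counts <- function() {
  c(ZAM = 200, gtwin = 200, Doc = 50, roo = 50, copia = 50,
    `F-element` = 50, hopper = 50, Helena = 50, HB = 50, `TART-A` = 50,
    gypsy = 100, Idefix = 100)
}

#' Simulation recipe
#'
#' Bundles every knob of the synthetic benchmark. The defaults are the full
#' benchmark design: 100 insider insertions (5 each for ZAM and gtwin, 10
#' each for nine further families) and 1000 outsider insertions
#' (200/200/50x8/100/100 across twelve families), reads with a 20 kb mean
#' length mixed at 10x/45x/5x. Use [scale_recipe()] for a proportionally
#' reduced desk-scale run.
#'
#' @param genome_length Base genome length (bp).
#' @param gc GC content of the base genome.
#' @param insider_counts,outsider_counts Named integer vectors
#'   (family -> insertion count).
#' @param depth_mix Named depths (x) for the `base`, `insider` and
#'   `outsider` read pools.
#' @param read_mean_len Mean read length (bp); lengths are lognormal.
#' @param read_sdlog Lognormal sdlog of read lengths (0.6 gives the strong
#'   right skew of long-read libraries).
#' @param min_read_len Minimum read length (bp).
#' @param error_rate Per-base read error rate (< 0.3; 0 gives error-free
#'   reads for oracle tests).
#' @param error_mix Relative weights of substitution/insertion/deletion
#'   errors.
#' @param tsd_len_range Target-site-duplication lengths planted (uniform
#'   over the range; 4-6 bp, typical of LTR retroelements).
#' @param min_end_dist Minimum distance (bp) of planted events from contig
#'   ends.
#' @param min_event_gap Minimum distance (bp) between planted events.
#' @param seed Master seed; every random choice in the simulation derives
#'   from it.
#' @return A list of class `te_recipe`.
#' @export
simulation_recipe <- function(genome_length = 20e6,
                              gc = 0.42,
                              insider_counts = insider_default_counts(),
                              outsider_counts = outsider_default_counts(),
                              depth_mix = c(base = 10, insider = 45,
                                            outsider = 5),
                              read_mean_len = 20000,
                              read_sdlog = 0.6,
                              min_read_len = 500,
                              error_rate = 0.05,
                              error_mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                              tsd_len_range = c(4, 6),
                              min_end_dist = 2000,
                              min_event_gap = 1000,
                              seed = 1) {
  stopifnot(genome_length > 0, all(depth_mix > 0),
            all(insider_counts >= 0), all(outsider_counts >= 0),
            error_rate >= 0, error_rate < 0.3,
            length(tsd_len_range) == 2, tsd_len_range[1] >= 2)
  structure(list(
    genome_length = genome_length, gc = gc,
    insider_counts = insider_counts, outsider_counts = outsider_counts,
    depth_mix = depth_mix, read_mean_len = read_mean_len,
    read_sdlog = read_sdlog, min_read_len = min_read_len,
    error_rate = error_rate, error_mix = error_mix,
    tsd_len_range = tsd_len_range, min_end_dist = min_end_dist,
    min_event_gap = min_event_gap, seed = seed
  ), class = c("te_recipe", "list"))
}

# largest-remainder apportionment keeping the scaled total exact
apportion_counts <- function(counts, factor) {
  target <- round(sum(counts) * factor)
  raw <- counts * factor
  base <- floor(raw)
  rem <- target - sum(base)
  if (rem > 0) {
    # radix method: C-locale byte order, independent of the session locale
    o <- order(-(raw - base), names(counts), method = "radix")
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Scale a recipe down (or up) proportionally
#'
#' Genome length and per-family event counts are scaled by `factor`; counts
#' use largest-remainder apportionment so the scaled totals are exact (e.g.
#' factor 0.1 turns 100/1000 events into 10/100). Depths, read lengths and
#' error rates are left untouched: they are per-locus properties.
#'
#' @param recipe A [simulation_recipe()].
#' @param factor Scaling factor.
#' @return A scaled `te_recipe`.
#' @export
scale_recipe <- function(recipe, factor) {
  stopifnot(inherits(recipe, "te_recipe"), factor > 0)
  recipe$genome_length <- round(recipe$genome_length * factor)
  recipe$insider_counts <- apportion_counts(recipe$insider_counts, factor)
  recipe$outsider_counts <- apportion_counts(recipe$outsider_counts, factor)
  recipe
}

#' Generate a random base genome
#'
#' Uniform random sequence at the requested GC content, with optional
#' low-complexity dinucleotide-repeat patches. Reproducible per seed.
#'
#' @param length Genome length (bp, > 0).
#' @param seed Optional seed (uses the current RNG state when `NULL`).
#' @param gc GC fraction.
#' @param n_low_complexity,patch_len Number and length of dinucleotide
#'   repeat patches to embed.
#' @param contig Contig name.
#' @return A named `DNAStringSet` of one contig.
#' @export
generate_base_genome <- function(length, seed = NULL, gc = 0.42,
                                 n_low_complexity = 0, patch_len = 500,
                                 contig = "sim1") {
  if (length <= 0) abort("genome length must be positive")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(p), length, replace = TRUE, prob = p)
    if (n_low_complexity > 0) {
      for (k in seq_len(n_low_complexity)) {
        at <- sample.int(length - patch_len, 1)
        di <- sample(c("A", "C", "G", "T"), 2)
        s[at:(at + patch_len - 1)] <- rep(di, length.out = patch_len)
      }
    }
    Biostrings::DNAStringSet(setNames(paste(s, collapse = ""), contig))
  })
}

#' Plant TE insertions (with TSDs) into a genome
#'
#' Positions are uniform, at least `min_end_dist` from the contig ends and
#' `min_event_gap` from each other and from any previously planted event
#' (`existing_truth`); strand is random; each insertion duplicates the
#' `tsd_len` bases immediately 5' of the insertion point, so the mutated
#' genome reads `...[motif] TE [motif]...`. The truth ledger records both
#' the host coordinate (pre-insertion genome) and the interval on the
#' mutated genome.
#'
#' @param genome Named `DNAStringSet` of one contig.
#' @param library TE library tibble.
#' @param counts Named vector, family -> number of insertions.
#' @param class_label `"INSIDER"` or `"OUTSIDER"` truth label.
#' @param tsd_len_range Length-2 vector of planted TSD lengths.
#' @param min_end_dist,min_event_gap Placement constraints (bp).
#' @param existing_truth Optional truth tibble of events already present on
#'   `genome` (their intervals are avoided).
#' @param seed Optional seed.
#' @return List with `genome` (mutated `DNAStringSet`) and `truth` tibble:
#'   `contig`, `host_pos` (insertion point on the input genome), `start`,
#'   `end` (physical interval on the mutated genome), `family`,
#'   `te_length`, `insert_size` (TE + TSD), `tsd_motif`, `strand`,
#'   `class_label`.
#' @export
plant_insertions <- function(genome, library, counts,
                             class_label = "INSIDER",
                             tsd_len_range = c(4, 6),
                             min_end_dist = 2000, min_event_gap = 1000,
                             existing_truth = NULL, seed = NULL) {
  stopifnot(length(genome) == 1)
  counts <- counts[counts > 0]
  n <- sum(counts)
  contig <- names(genome)
  empty_truth <- tibble(contig = character(), host_pos = double(),
                        start = double(), end = double(),
                        family = character(), te_length = integer(),
                        insert_size = integer(), tsd_motif = character(),
                        strand = character(), class_label = character())
  if (n == 0) return(list(genome = genome, truth = empty_truth))
  host <- as.character(genome[[1]])
  L <- nchar(host)
  if (L < 2 * min_end_dist + (n + 1) * min_event_gap) {
    abort("genome too small for the requested number of spaced insertions")
  }
  missing_fams <- setdiff(names(counts), library$family)
  if (length(missing_fams)) {
    abort(paste0("families absent from library: ",
                 paste(missing_fams, collapse = ", ")))
  }
  with_seed(seed, {
    avoid <- if (!is.null(existing_truth) && nrow(existing_truth)) {
      existing_truth |> select("start", "end")
    } else tibble(start = double(0), end = double(0))
    pos <- double(0)
    tries <- 0
    while (length(pos) < n) {
      tries <- tries + 1
      if (tries > 1000) {
        abort("could not place insertions with the requested spacing")
      }
      cand <- floor(runif(2 * (n - length(pos)),
                          min_end_dist, L - min_end_dist))
      for (p in cand) {
        if (length(pos) >= n) break
        if (length(pos) && min(abs(pos - p)) < min_event_gap) next
        if (nrow(avoid) &&
            any(p > avoid$start - min_event_gap &
                p < avoid$end + min_event_gap)) next
        pos <- c(pos, p)
      }
    }
    pos <- sort(pos)
    fams <- sample(rep(names(counts), counts))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tsd_len <- sample(seq(tsd_len_range[1], tsd_len_range[2]), n,
                      replace = TRUE)
    te_seq <- library$sequence[match(fams, library$family)]
    te_len <- library$length[match(fams, library$family)]
    te_oriented <- ifelse(
      strand == "-",
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(te_seq))),
      te_seq)
    motif <- substring(host, pos - tsd_len + 1, pos)
    block <- paste0(te_oriented, motif)
    block_len <- nchar(block)
    # stitch: host segments between insertion points, block after each
    seg_start <- c(1, pos + 1)
    seg_end <- c(pos, L)
    segs <- substring(host, seg_start, seg_end)
    mutated <- paste0(paste0(segs[seq_len(n)], block, collapse = ""),
                      segs[n + 1])
    offset <- c(0, cumsum(block_len))[seq_len(n)]
    truth <- tibble(
      contig = contig,
      host_pos = pos,
      start = pos + offset,
      end = pos + offset + block_len,
      family = fams,
      te_length = te_len,
      insert_size = as.integer(block_len),
      tsd_motif = motif,
      strand = strand,
      class_label = class_label
    )
    list(genome = Biostrings::DNAStringSet(setNames(mutated, contig)),
         truth = truth)
  })
}

# --- error model -----------------------------------------------------------

BASES <- c("A", "C", "G", "T")

# Apply the parametric error model to one sequence. Returns the observed
# sequence plus (op, len) vectors describing observed -> template: M runs,
# I for inserted bases, D for dropped bases. Substitutions stay M.
mutate_seq <- function(seq, rate, mix) {
  n <- nchar(seq)
  if (rate == 0 || n == 0) {
    return(list(seq = seq, op = "M", len = n))
  }
  k <- rbinom(1, n, rate)
  if (k == 0) return(list(seq = seq, op = "M", len = n))
  pos <- sort(sample.int(n, k))
  typ <- sample(c("s", "i", "d"), k, replace = TRUE, prob = mix)
  prev <- c(0L, pos[-k])
  gap_len <- pos - prev - 1L
  gap_piece <- substring(seq, prev + 1L, pos - 1L)
  ch <- substring(seq, pos, pos)
  idx <- match(ch, BASES)
  idx[is.na(idx)] <- 1L
  alt <- BASES[((idx - 1L + sample.int(3, k, replace = TRUE)) %% 4L) + 1L]
  rand_ins <- BASES[sample.int(4, k, replace = TRUE)]
  piece <- ifelse(typ == "s", alt,
                  ifelse(typ == "i", paste0(ch, rand_ins), ""))
  tail_piece <- substring(seq, pos[k] + 1L, n)
  obs <- paste0(paste0(gap_piece, piece, collapse = ""), tail_piece)
  # ops: M(gap), then per event: s -> M1; i -> M1,I1; d -> D1
  op1 <- ifelse(typ == "d", "D", "M")
  op2 <- ifelse(typ == "i", "I", "M")
  len2 <- ifelse(typ == "i", 1L, 0L)
  ops <- as.vector(rbind("M", op1, op2))
  lens <- as.vector(rbind(gap_len, 1L, len2))
  ops <- c(ops, "M")
  lens <- c(lens, n - pos[k])
  m <- merge_ops(ops, lens)
  list(seq = obs, op = m$op, len = m$len)
}

# --- read simulation -------------------------------------------------------

# Structural segments of a read interval [s, e) on its haplotype, relative
# to the assembly. Returns NULL for a read wholly inside an extra block
# (unmappable), otherwise a list of segments (type M/I/S with haplotype
# interval) plus the 0-based assembly position of the first aligned base and
# any deletion ops to interleave.
read_segments <- function(s, e, rel) {
  if (is.null(rel)) {
    return(list(pos = s, segs = list(list(type = "M", from = s, to = e))))
  }
  if (rel$type == "extra") {
    b <- rel$blocks  # hap coords: start, end; asm_pos; cum_before
    segs <- list()
    cur <- s
    # block containing s?
    inside <- which(b$start <= s & b$end > s)
    if (length(inside)) {
      bl <- b[inside, ]
      if (e <= bl$end) return(NULL)  # read entirely within the insertion
      segs[[1]] <- list(type = "S", from = s, to = bl$end)
      cur <- bl$end
    }
    repeat {
      nxt <- which(b$start >= cur & b$start < e)
      if (!length(nxt)) break
      bl <- b[nxt[1], ]
      if (bl$start > cur) {
        segs[[length(segs) + 1]] <- list(type = "M", from = cur,
                                         to = bl$start)
      }
      if (bl$end <= e) {
        segs[[length(segs) + 1]] <- list(type = "I", from = bl$start,
                                         to = bl$end)
        cur <- bl$end
      } else {
        segs[[length(segs) + 1]] <- list(type = "S", from = bl$start, to = e)
        cur <- e
        break
      }
    }
    if (cur < e) {
      segs[[length(segs) + 1]] <- list(type = "M", from = cur, to = e)
    }
    first_m <- Find(function(x) x$type == "M", segs)
    if (is.null(first_m)) return(NULL)
    # assembly position of first aligned base: hap coord minus extra bases
    # before it
    x <- first_m$from
    before <- sum(pmin(b$end, x) - pmin(b$start, x))
    list(pos = x - before, segs = segs)
  } else {  # missing: assembly has blocks the haplotype lacks
    b <- rel$blocks  # base_pos (insertion point, hap coords), len
    rel_pts <- which(b$base_pos > s & b$base_pos < e)
    pos <- s + sum(b$len[b$base_pos <= s])
    segs <- list()
    cur <- s
    for (j in rel_pts) {
      segs[[length(segs) + 1]] <- list(type = "M", from = cur,
                                       to = b$base_pos[j])
      segs[[length(segs) + 1]] <- list(type = "D", dlen = b$len[j])
      cur <- b$base_pos[j]
    }
    segs[[length(segs) + 1]] <- list(type = "M", from = cur, to = e)
    list(pos = pos, segs = segs)
  }
}

#' Simulate long reads from depth-weighted haplotypes
#'
#' Draws reads (lognormal lengths, uniform starts, forward strand) from each
#' haplotype until its target depth is reached, applies the parametric error
#' model (substitutions/insertions/deletions at `error_mix` ratios), and
#' emits ground-truth alignments of every read against the designated
#' assembly haplotype: insertions private to a haplotype appear as `I`
#' operations or terminal soft clips exactly as an aligner would report
#' them, insertions private to the assembly as `D` operations. Reads falling
#' entirely inside a non-assembly insertion are emitted as unmapped records.
#'
#' @param haplotypes List of haplotype descriptions: each a list with
#'   `name`, `sequence` (character), `depth` (x), and optionally `rel`
#'   describing its structural relation to the assembly (`NULL` = identical;
#'   `list(type = "extra", blocks = ...)` for private insertions with
#'   haplotype-coordinate `start`/`end` and `asm_pos`;
#'   `list(type = "missing", blocks = ...)` with assembly-private insertion
#'   points `base_pos` and lengths `len`).
#' @param recipe A [simulation_recipe()] (read-length and error parameters).
#' @param assembly_contig Contig name used in the truth alignments.
#' @param seed Optional seed.
#' @return List with `reads` (tibble: `read_id`, `sequence`, `quality`,
#'   `haplotype`) and `alignments` (alignment tibble against the assembly).
#' @export
simulate_reads <- function(haplotypes, recipe, assembly_contig = "sim1",
                           seed = NULL) {
  meanlog <- log(recipe$read_mean_len) - recipe$read_sdlog^2 / 2
  with_seed(seed, {
    all_aln <- list()
    for (h in haplotypes) {
      L <- nchar(h$sequence)
      target <- h$depth * L
      # molecule start anywhere (including hanging off the contig start) and
      # truncate at the contig bounds: coverage is then uniform along the
      # contig at the nominal depth instead of piling up mid-contig
      starts <- integer(0); lens <- integer(0)
      while (sum(lens) < target) {
        need <- max(20, ceiling((target - sum(lens)) / recipe$read_mean_len))
        mol <- pmin(pmax(round(rlnorm(need, meanlog, recipe$read_sdlog)),
                         recipe$min_read_len), L)
        s0 <- floor(runif(need, -(mol - 1), L))
        s <- pmax(0, s0)
        e <- pmin(L, s0 + mol)
        keep <- (e - s) >= min(recipe$min_read_len, L)
        s <- s[keep]; e <- e[keep]
        starts <- c(starts, s)
        lens <- c(lens, e - s)
        if (sum(lens) >= target) {
          k <- which(cumsum(lens) >= target)[1]
          starts <- starts[seq_len(k)]
          lens <- lens[seq_len(k)]
          break
        }
      }
      recs <- vector("list", length(lens))
      for (i in seq_along(lens)) {
        s <- starts[i]; e <- s + lens[i]
        sg <- read_segments(s, e, h$rel)
        rid <- sprintf("%s_read%06d", h$name, i)
        if (is.null(sg)) {
          raw <- substr(h$sequence, s + 1, e)
          mut <- mutate_seq(raw, recipe$error_rate, recipe$error_mix)
          recs[[i]] <- list(read_id = rid, flag = 4L, contig = NA_character_,
                            pos = NA_real_, cigar = NA_character_,
                            seq = mut$seq, hap = h$name)
          next
        }
        ops <- character(0); lens_o <- integer(0); pieces <- character(0)
        for (seg in sg$segs) {
          if (seg$type == "D") {
            ops <- c(ops, "D"); lens_o <- c(lens_o, seg$dlen)
            next
          }
          raw <- substr(h$sequence, seg$from + 1, seg$to)
          if (seg$type == "M") {
            mut <- mutate_seq(raw, recipe$error_rate, recipe$error_mix)
            ops <- c(ops, mut$op); lens_o <- c(lens_o, mut$len)
            pieces <- c(pieces, mut$seq)
          } else {
            mut <- mutate_seq(raw, recipe$error_rate, recipe$error_mix)
            ops <- c(ops, seg$type); lens_o <- c(lens_o, nchar(mut$seq))
            pieces <- c(pieces, mut$seq)
          }
        }
        recs[[i]] <- list(read_id = rid, flag = 0L, contig = assembly_contig,
                          pos = sg$pos, cigar = ops_to_cigar(ops, lens_o),
                          seq = paste0(pieces, collapse = ""), hap = h$name)
      }
      all_aln[[h$name]] <- dplyr::bind_rows(recs)
    }
    aln <- bind_rows(all_aln)
    aln$qual <- strrep("?", nchar(aln$seq))
    aln$mapq <- ifelse(aln$flag == 4L, 0L, 60L)
    reads <- tibble(read_id = aln$read_id, sequence = aln$seq,
                    quality = aln$qual, haplotype = aln$hap)
    aln <- finalize_alignments(aln |> select(-"hap"))
    list(reads = reads, alignments = aln)
  })
}

#' Subsample a read set
#'
#' Keeps each read independently with probability `fraction`; reproducible
#' per seed. Stands in for depth-titration experiments.
#'
#' @param reads Reads tibble ([load_reads()] / [simulate_reads()]).
#' @param fraction Keep probability in (0, 1].
#' @param seed Optional seed.
#' @return Subset of `reads`.
#' @export
subsample_reads <- function(reads, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  if (fraction == 1) return(reads)
  with_seed(seed, reads[runif(nrow(reads)) < fraction, , drop = FALSE])
}

# truth CIGAR of the assembly contig against the reference: M runs broken by
# an I of each insider insertion's size
contig_alignment <- function(insider_truth, base_len, contig = "sim1") {
  t <- insider_truth |> arrange(.data$host_pos)
  ops <- character(0); lens <- integer(0)
  cur <- 0
  if (!nrow(t)) {
    return(finalize_alignments(tibble(
      read_id = contig, flag = 0L, contig = contig, pos = 0, mapq = 60L,
      cigar = paste0(base_len, "M"), seq = NA_character_,
      qual = NA_character_)))
  }
  for (i in seq_len(nrow(t))) {
    ops <- c(ops, "M", "I")
    lens <- c(lens, t$host_pos[i] - cur, t$insert_size[i])
    cur <- t$host_pos[i]
  }
  ops <- c(ops, "M"); lens <- c(lens, base_len - cur)
  finalize_alignments(tibble(
    read_id = contig, flag = 0L, contig = contig, pos = 0,
    mapq = 60L, cigar = ops_to_cigar(ops, lens), seq = NA_character_,
    qual = NA_character_))
}

#' Run the full synthetic benchmark generator
#'
#' Builds the base genome, plants insider insertions to form the "assembly"
#' haplotype, plants outsider insertions on top of it to form the third
#' haplotype, simulates the depth-mixed read pools, and emits ground-truth
#' read and contig alignments plus a unified truth ledger. Population
#' frequencies follow from the depth mix: insiders are carried by the
#' insider and outsider pools, outsiders only by the outsider pool.
#'
#' @param recipe A [simulation_recipe()].
#' @return A list of class `te_simulation`: `recipe`, `library`,
#'   `reference`, `assembly` (both `DNAStringSet`), `reads`, `alignments`
#'   (reads vs assembly), `contig_alignment` (assembly vs reference), and
#'   `truth` (with `position` = assembly-coordinate scoring position).
#' @examples
#' \donttest{
#' sim <- simulate_te_benchmark(scale_recipe(simulation_recipe(seed = 1), 0.02))
#' dplyr::count(sim$truth, class_label)
#' }
#' @export
simulate_te_benchmark <- function(recipe = simulation_recipe()) {
  stopifnot(inherits(recipe, "te_recipe"))
  set.seed(recipe$seed)
  lib <- synthetic_te_library()
  base <- generate_base_genome(recipe$genome_length, gc = recipe$gc)
  ins <- plant_insertions(base, lib, recipe$insider_counts,
                          class_label = "INSIDER",
                          tsd_len_range = recipe$tsd_len_range,
                          min_end_dist = recipe$min_end_dist,
                          min_event_gap = recipe$min_event_gap)
  out <- plant_insertions(ins$genome, lib, recipe$outsider_counts,
                          class_label = "OUTSIDER",
                          tsd_len_range = recipe$tsd_len_range,
                          min_end_dist = recipe$min_end_dist,
                          min_event_gap = recipe$min_event_gap,
                          existing_truth = ins$truth)
  d <- recipe$depth_mix
  f_ins <- unname((d["insider"] + d["outsider"]) / sum(d))
  f_out <- unname(d["outsider"] / sum(d))
  truth <- bind_rows(
    ins$truth |> mutate(position = .data$start,
                        population_frequency = f_ins),
    out$truth |> mutate(position = .data$host_pos,
                        population_frequency = f_out)
  ) |> arrange(.data$position)
  haps <- list(
    list(name = "base", sequence = as.character(base[[1]]),
         depth = unname(d["base"]),
         rel = list(type = "missing",
                    blocks = tibble(base_pos = ins$truth$host_pos,
                                    len = ins$truth$insert_size))),
    list(name = "insider", sequence = as.character(ins$genome[[1]]),
         depth = unname(d["insider"]), rel = NULL),
    list(name = "outsider", sequence = as.character(out$genome[[1]]),
         depth = unname(d["outsider"]),
         rel = list(type = "extra",
                    blocks = tibble(start = out$truth$start,
                                    end = out$truth$end,
                                    asm_pos = out$truth$host_pos)))
  )
  rd <- simulate_reads(haps, recipe, assembly_contig = names(base))
  structure(list(
    recipe = recipe,
    library = lib,
    reference = base,
    assembly = ins$genome,
    reads = rd$reads,
    alignments = rd$alignments,
    contig_alignment = contig_alignment(ins$truth,
                                        nchar(as.character(base[[1]])),
                                        names(base)),
    truth = truth
  ), class = c("te_simulation", "list"))
}
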