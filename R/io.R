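# Readers/writers for the standard formats the pipeline touches. Sequence
# containers are Biostrings objects at the boundary; everything tabular is a
# tibble. Internal coordinates are uniformly 0-based half-open: SAM POS is
# converted at parse time, BED is native.

#' Load a genome FASTA
#'
#' @param path FASTA file.
#' @return A named `Biostrings::DNAStringSet`, uppercased; IUPAC ambiguity
#'   codes outside `A/C/G/T/N` are replaced by `N` with a warning (downstream
#'   exact matching needs a closed alphabet).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) abort(paste0("empty FASTA: ", path))
  names(x) <- sub("\\s.*$", "", names(x))
  clean_dna(x)
}

clean_dna <- function(x) {
  chars <- as.character(x)
  chars <- toupper(chars)
  n_odd <- sum(vapply(chars, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, numeric(1)))
  if (n_odd > 0) {
    warn(sprintf("replacing %d non-ACGTN base(s) with N", n_odd))
    chars <- vapply(chars, function(s) gsub("[^ACGTN]", "N", s), character(1),
                    USE.NAMES = FALSE)
  }
  Biostrings::DNAStringSet(setNames(chars, names(x)))
}

#' Load a TE consensus library
#'
#' One consensus sequence per TE family. Duplicate family names are rejected:
#' every candidate is annotated with the single best family, so the library
#' must key families uniquely.
#'
#' @param path FASTA file of consensus sequences.
#' @return A tibble with columns `family`, `sequence`, `length`.
#' @examples
#' lib <- synthetic_te_library(seed = 1)
#' tf <- tempfile(fileext = ".fa")
#' write_te_library(lib, tf)
#' identical(load_te_library(tf)$family, lib$family)
#' @export
load_te_library <- function(path) {
  x <- load_genome(path)
  fam <- names(x)
  if (anyDuplicated(fam)) {
    abort(paste0("duplicate family name(s) in TE library: ",
                 paste(unique(fam[duplicated(fam)]), collapse = ", ")))
  }
  lib <- tibble(family = fam,
                sequence = unname(as.character(x)),
                length = Biostrings::width(x))
  inform(sprintf("TE library: %d families, mean length %.0f bp",
                 nrow(lib), mean(lib$length)))
  lib
}

#' Write a TE consensus library to FASTA
#' @param library Tibble with `family` and `sequence` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_te_library <- function(library, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(library$sequence, library$family)), path)
  invisible(path)
}

#' Load long reads from FASTQ
#'
#' @param path FASTQ file.
#' @return Tibble with `read_id`, `sequence` and `quality` (phred+33 string).
#' @export
load_reads <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns here; benign
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(toupper(as.character(x))),
         quality = unname(as.character(Biostrings::quality(x))))
}

#' Write reads to FASTQ
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Parse read or contig alignments (SAM/BAM or PAF)
#'
#' Normalizes SAM/BAM records or PAF lines (with `cg:Z` CIGAR tags) to the
#' package's alignment tibble: one row per record, 0-based half-open target
#' coordinates, clip lengths and flag bits populated, unmapped records
#' retained. SAM text is converted through `Rsamtools::asBam()`.
#'
#' @param path A `.sam`, `.bam` or `.paf` file.
#' @return An alignment tibble with columns `read_id`, `flag`, `contig`,
#'   `pos` (0-based), `mapq`, `cigar`, `seq`, `qual` plus derived columns
#'   `ref_end`, `left_clip`, `right_clip`, `unmapped`, `secondary`,
#'   `supplementary`, `primary`.
#' @export
parse_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "paf") return(parse_paf(path))
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  aln <- tibble(
    read_id = r$qname,
    flag = as.integer(r$flag),
    contig = as.character(r$rname),
    pos = as.double(r$pos) - 1,  # SAM is 1-based
    mapq = as.integer(r$mapq),
    cigar = r$cigar,
    seq = as.character(r$seq),
    qual = as.character(r$qual)
  )
  finalize_alignments(aln)
}

parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(finalize_alignments(tibble(
      read_id = character(), flag = integer(), contig = character(),
      pos = double(), mapq = integer(), cigar = character(),
      seq = character(), qual = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cg <- vapply(fields, function(f) {
    tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(tag)) sub("^cg:Z:", "", tag[1]) else NA_character_
  }, character(1))
  if (anyNA(cg)) warn("PAF record(s) without cg:Z tag: CIGAR set to *")
  strand <- vapply(fields, `[[`, character(1), 5)
  qlen <- as.double(vapply(fields, `[[`, character(1), 2))
  qstart <- as.double(vapply(fields, `[[`, character(1), 3))
  qend <- as.double(vapply(fields, `[[`, character(1), 4))
  # encode query end overhangs as soft clips so downstream CIGAR walking sees
  # the standard picture
  lc <- ifelse(strand == "+", qstart, qlen - qend)
  rc <- ifelse(strand == "+", qlen - qend, qstart)
  cigar <- ifelse(is.na(cg), "*",
                  paste0(ifelse(lc > 0, paste0(lc, "S"), ""), cg,
                         ifelse(rc > 0, paste0(rc, "S"), "")))
  aln <- tibble(
    read_id = vapply(fields, `[[`, character(1), 1),
    flag = ifelse(strand == "-", 16L, 0L),
    contig = vapply(fields, `[[`, character(1), 6),
    pos = as.double(vapply(fields, `[[`, character(1), 8)),  # already 0-based
    mapq = as.integer(vapply(fields, `[[`, character(1), 12)),
    cigar = cigar,
    seq = NA_character_,
    qual = NA_character_
  )
  finalize_alignments(aln)
}

#' Write alignments to SAM text
#'
#' @param aln Alignment tibble (see [parse_alignments()]).
#' @param contig_lengths Named vector of target sequence lengths for the
#'   `@SQ` header lines.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(aln, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths))), con)
  if (nrow(aln)) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     aln$read_id, aln$flag,
                     ifelse(aln$unmapped, "*", aln$contig),
                     ifelse(aln$unmapped, 0L, as.integer(aln$pos) + 1L),
                     ifelse(is.na(aln$mapq), 255L, aln$mapq),
                     ifelse(aln$unmapped | is.na(aln$cigar), "*", aln$cigar),
                     ifelse(is.na(aln$seq), "*", aln$seq),
                     ifelse(is.na(aln$qual), "*", aln$qual))
    writeLines(lines, con)
  }
  invisible(path)
}

bed_call_columns <- c("contig", "start", "end", "family", "score", "strand",
                      "call_class", "kind", "tsd_motif", "tsd_mismatches",
                      "supporting", "spanning_total", "frequency",
                      "best_read_id", "ref_pos")

#' Write TE calls to BED6+
#'
#' BED columns: contig, start, end, name (TE family), score (rounded
#' frequency x 100), strand, then extra columns for call class, kind, TSD
#' motif and mismatch count, supporting/spanning read counts, frequency (4
#' decimals), best supporting read and the homologous reference position of
#' insider calls. Missing values are written as `.`.
#'
#' @param calls Calls tibble (as produced by [call_insider()] /
#'   [call_outsider()] and downstream annotators).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  calls <- as_tibble(calls)
  if (nrow(calls)) {
    o <- order(calls$contig, calls$start)
    if (!identical(o, seq_len(nrow(calls)))) {
      inform("sorting calls by (contig, start) before writing BED")
      calls <- calls[o, , drop = FALSE]
    }
  }
  for (col in bed_call_columns) {
    if (!col %in% names(calls)) calls[[col]] <- NA
  }
  fmt <- function(x, digits = NULL) {
    out <- if (!is.null(digits)) {
      ifelse(is.na(x), ".", formatC(x, format = "f", digits = digits))
    } else as.character(x)
    out[is.na(out)] <- "."
    out
  }
  score <- ifelse(is.na(calls$frequency), 0L,
                  as.integer(round(calls$frequency * 100)))
  lines <- paste(calls$contig, as.integer(calls$start), as.integer(calls$end),
                 fmt(calls$family), score, fmt(calls$strand),
                 fmt(calls$call_class), fmt(calls$kind), fmt(calls$tsd_motif),
                 fmt(calls$tsd_mismatches), fmt(calls$supporting),
                 fmt(calls$spanning_total), fmt(calls$frequency, 4),
                 fmt(calls$best_read_id),
                 fmt(calls$ref_pos), sep = "\t")
  writeLines(c(paste0("#", paste(bed_call_columns, collapse = "\t")), lines),
             path)
  invisible(path)
}

#' Read a TE call BED written by [write_calls_bed()]
#' @param path BED path.
#' @return Calls tibble.
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(contig = character(), start = double(), end = double(),
                  family = character(), score = integer(), strand = character(),
                  call_class = character(), kind = character(),
                  tsd_motif = character(), tsd_mismatches = integer(),
                  supporting = integer(), spanning_total = integer(),
                  frequency = double(), best_read_id = character(),
                  ref_pos = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[[`, character(1), i)
  na_dot <- function(x) ifelse(x == ".", NA, x)
  tibble(
    contig = col(1),
    start = as.double(col(2)),
    end = as.double(col(3)),
    family = na_dot(col(4)),
    score = as.integer(col(5)),
    strand = na_dot(col(6)),
    call_class = na_dot(col(7)),
    kind = na_dot(col(8)),
    tsd_motif = na_dot(col(9)),
    tsd_mismatches = as.integer(na_dot(col(10))),
    supporting = as.integer(na_dot(col(11))),
    spanning_total = as.integer(na_dot(col(12))),
    frequency = as.double(na_dot(col(13))),
    best_read_id = na_dot(col(14)),
    ref_pos = as.double(na_dot(col(15)))
  )
}

#' Write a planted-truth ledger to BED
#' @param truth Truth tibble from [plant_insertions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- paste(truth$contig, as.integer(truth$start),
                 as.integer(truth$end), truth$family,
                 as.integer(round(truth$population_frequency * 100)),
                 truth$strand, truth$class_label, truth$te_length,
                 truth$insert_size, truth$tsd_motif,
                 as.integer(truth$host_pos),
                 formatC(truth$population_frequency, format = "f", digits = 4),
                 sep = "\t")
  hdr <- paste0("#", paste(c("contig", "start", "end", "family", "score",
                             "strand", "class_label", "te_length",
                             "insert_size", "tsd_motif", "host_pos",
                             "population_frequency"), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a truth ledger BED written by [write_truth_bed()]
#' @param path BED path.
#' @return Truth tibble.
#' @export
read_truth_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[[`, character(1), i)
  tibble(
    contig = col(1), start = as.double(col(2)), end = as.double(col(3)),
    family = col(4), strand = col(6), class_label = col(7),
    te_length = as.integer(col(8)), insert_size = as.integer(col(9)),
    tsd_motif = col(10), host_pos = as.double(col(11)),
    population_frequency = as.double(col(12))
  )
}
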