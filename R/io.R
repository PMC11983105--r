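#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet;
#' duplicate contig names and empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (one uppercase string per contig) of
#'   class `"ref_genome"`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(ss) == 0) stop("FASTA contains no sequences: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  ref_genome(seqs)
}

#' Construct a reference genome object from named sequences
#'
#' @param seqs Named character vector of DNA sequences.
#' @return A `"ref_genome"` (named uppercase character vector).
#' @export
ref_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) stop("empty contig sequence")
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence alphabet must be A/C/G/T/N")
  }
  structure(seqs, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome>", length(x), "contig(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Contig lengths of a reference genome
#' @param genome A `ref_genome`.
#' @return Named integer vector of contig lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Extract genome subsequence (0-based half-open)
#'
#' @param genome A `ref_genome`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval, clipped to contig bounds.
#' @return DNA string.
#' @export
genome_substr <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  start <- max(0L, start)
  end <- min(len, end)
  if (end <= start) return("")
  substr(genome[[contig]], start + 1L, end)
}

#' Write a reference genome to FASTA
#' @param genome A `ref_genome`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' sgRNA specification
#'
#' @param protospacer 20-nt protospacer (nontarget-strand sequence, written
#'   5'->3' with position 1 PAM-distal and position 20 PAM-proximal).
#' @param pam 3-nt PAM pattern over IUPAC codes (default `"NRG"`, the
#'   canonical SpCas9-family motif).
#' @param editing_window Inclusive protospacer position range where the
#'   deaminase acts most efficiently (default 3:9).
#' @return A list of class `"sgrna_spec"` with `protospacer`, `pam`,
#'   `editing_window` and the concatenated `target` (protospacer + PAM)
#'   used for binding-site alignment.
#' @export
sgrna_spec <- function(protospacer, pam = "NRG", editing_window = 3:9) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  if (grepl("[^ACGT]", protospacer)) stop("protospacer must be A/C/G/T")
  if (nchar(pam) != 3L) stop("PAM pattern must be 3 nt")
  if (!all(chars(pam) %in% names(IUPAC_SETS))) stop("PAM must use IUPAC codes")
  ew <- as.integer(editing_window)
  if (any(ew < 1L | ew > 20L)) stop("editing window must lie in 1..20")
  structure(list(protospacer = protospacer, pam = pam,
                 editing_window = ew,
                 target = paste0(protospacer, pam)),
            class = "sgrna_spec")
}

#' @export
print.sgrna_spec <- function(x, ...) {
  cat("<sgrna_spec>", x$protospacer, "+", x$pam,
      sprintf("(editing window %d-%d)\n",
              min(x$editing_window), max(x$editing_window)))
  invisible(x)
}

# ---- aligned reads -------------------------------------------------------

read_tibble_cols <- c("name", "contig", "start", "strand", "mapq", "cigar",
                      "seq", "is_r1", "is_proper_pair", "is_primary",
                      "is_duplicate", "sample")

#' Read aligned reads from SAM or BAM
#'
#' Decodes flags into logical columns and, by default, drops reads that are
#' not primary, not proper-pair, or marked duplicate — mirroring the
#' preprocessing contract of the upstream alignment workflow. Single-end
#' records (paired flag unset) are treated as proper-pair R1 by convention.
#'
#' @param path SAM or BAM file (SAM is converted via [Rsamtools::asBam()]).
#' @param sample Sample label attached to every read, one of
#'   `"sgrna_pos_rep1"`, `"sgrna_pos_rep2"`, `"sgrna_neg"`, `"untreated"`
#'   (other labels are allowed for ad hoc use).
#' @param keep_filtered Keep secondary/supplementary, improper-pair and
#'   duplicate reads (flagged, not dropped). Default `FALSE`.
#' @return Tibble with columns `name, contig, start` (0-based leftmost
#'   aligned position), `strand, mapq, cigar, seq, is_r1, is_proper_pair,
#'   is_primary, is_duplicate, sample`.
#' @export
read_alignments <- function(path, sample = "sample", keep_filtered = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  paired <- bitwAnd(flag, 0x1) > 0
  reads <- tibble::tibble(
    name = res$qname,
    contig = as.character(res$rname),
    start = res$pos - 1L,
    strand = ifelse(bitwAnd(flag, 0x10) > 0, "-", "+"),
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq),
    is_r1 = !paired | bitwAnd(flag, 0x40) > 0,
    is_proper_pair = !paired | bitwAnd(flag, 0x2) > 0,
    is_primary = bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0,
    is_duplicate = bitwAnd(flag, 0x400) > 0,
    sample = sample
  )
  reads <- dplyr::filter(reads, !is.na(.data$contig), !is.na(.data$start))
  if (!keep_filtered) {
    reads <- dplyr::filter(reads, .data$is_primary, .data$is_proper_pair,
                           !.data$is_duplicate)
  }
  reads
}

#' Write aligned reads as SAM
#'
#' Emits an unsorted single-end SAM with `@SQ` lines taken from the genome.
#'
#' @param reads Read tibble (see [read_alignments()]).
#' @param genome A `ref_genome` providing the header contigs.
#' @param path Output path (`.sam`).
#' @export
write_sam <- function(reads, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$is_duplicate, 1024L, 0L) +
    ifelse(reads$is_primary, 0L, 256L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 reads$name, flag, reads$contig, reads$start + 1L,
                 reads$mapq, reads$cigar, reads$seq,
                 strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# ---- exclusion list ------------------------------------------------------

#' Read a known-variant exclusion list (BED or VCF)
#'
#' Only CHROM/POS are consumed; a BED interval contributes every position it
#' covers.
#'
#' @param path `.bed`, `.vcf` or `.vcf.gz` file.
#' @return Tibble with columns `contig`, `pos` (0-based).
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) {
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    }
    tb <- tibble::tibble(contig = as.character(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]) - 1L)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    tb <- tibble::tibble(
      contig = rep(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::width(gr)),
      pos = unlist(purrr::map2(GenomicRanges::start(gr) - 1L,
                               GenomicRanges::end(gr) - 1L, seq),
                   use.names = FALSE)
    )
  }
  dplyr::distinct(tb)
}

#' Write an exclusion list as BED
#' @param excl Tibble with `contig`, `pos` (0-based).
#' @param path Output `.bed` path.
#' @export
write_exclusion_bed <- function(excl, path) {
  if (nrow(excl) == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d", excl$contig, excl$pos, excl$pos + 1L),
               path)
  }
  invisible(path)
}

# ---- site reports --------------------------------------------------------

#' Write site calls as BED
#'
#' 0-based half-open single-base intervals; the BED score column is the
#' Selict score scaled by 1000 and clamped to 0..1000.
#'
#' @param calls Tibble with at least `contig`, `pos`, `strand`,
#'   `selict_score`; a `classification` column, when present, becomes the
#'   feature name.
#' @param path Output `.bed` path.
#' @export
write_sites_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("classification" %in% names(calls)) calls$classification else "site"
  score <- pmin(1000L, pmax(0L, as.integer(round(calls$selict_score * 1000))))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     calls$contig, calls$pos, calls$pos + 1L,
                     name, score, calls$strand),
             path)
  invisible(path)
}

#' Write / read the full site audit report (TSV)
#'
#' The TSV carries every count, filter verdict and annotation column so each
#' cascade rule can be recomputed from the report alone. A 1-based position
#' column (`pos1`) is added alongside the 0-based `pos`. Numeric fields
#' round-trip exactly.
#'
#' @param calls Site/call tibble.
#' @param path TSV path.
#' @export
write_report_tsv <- function(calls, path) {
  out <- dplyr::mutate(calls, pos1 = .data$pos + 1L, .after = "pos")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dplyr::select(tb, -dplyr::any_of("pos1"))
}
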