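# Strand-resolved pileups over reference-consuming (M) bases. Soft-clipped
# and inserted bases never touch the reference; deletions contribute no
# call. The "second aligned base" of a read is the second reference-
# consuming query base counted from the read's 5' end in sequencing
# orientation: second from the left edge for plus-strand reads, second from
# the right edge (in reference coordinates) for minus-strand reads.

# vectorised reference-base lookup (0-based positions)
ref_at <- function(genome, ct, p) {
  out <- character(length(p))
  for (u in unique(ct)) {
    i <- ct == u
    out[i] <- substring(unclass(genome)[[u]], p[i] + 1L, p[i] + 1L)
  }
  out
}

# decompose reads into M blocks; coordinates: rstart/rend 0-based half-open
# on the reference, qstart 1-based within the stored (reference-
# orientation) seq string
read_blocks <- function(reads) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$start + 1L, ops = "M")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar, ops = "M")
  nb <- lengths(rr)
  tibble::tibble(
    read = rep(seq_len(nrow(reads)), nb),
    rstart = unlist(IRanges::start(rr), use.names = FALSE) - 1L,
    rend = unlist(IRanges::end(rr), use.names = FALSE),
    qstart = unlist(IRanges::start(qr), use.names = FALSE)
  )
}

# one row per read: the reference position and called base of the read's
# second aligned base (NA when the read has fewer than two aligned bases)
second_base_records <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(read = integer(0), contig = character(0),
                          strand = character(0), pos2 = integer(0),
                          base2 = character(0)))
  }
  b <- read_blocks(reads)
  b$w <- b$rend - b$rstart
  first <- which(!duplicated(b$read))
  last <- which(!duplicated(b$read, fromLast = TRUE))
  n <- nrow(reads)
  pos2 <- rep(NA_integer_, n)
  q2 <- rep(NA_integer_, n)
  plus <- reads$strand == "+"
  rid_f <- b$read[first]
  # plus strand: second ref-consuming base from the left
  f1 <- first[plus[rid_f]]
  ok <- b$w[f1] >= 2L
  pos2[b$read[f1][ok]] <- b$rstart[f1][ok] + 1L
  q2[b$read[f1][ok]] <- b$qstart[f1][ok] + 1L
  nxt <- f1[!ok] + 1L
  valid <- nxt <= nrow(b) & b$read[nxt] == b$read[f1][!ok]
  pos2[b$read[nxt][valid]] <- b$rstart[nxt][valid]
  q2[b$read[nxt][valid]] <- b$qstart[nxt][valid]
  # minus strand: second ref-consuming base from the right
  rid_l <- b$read[last]
  l1 <- last[!plus[rid_l]]
  ok <- b$w[l1] >= 2L
  pos2[b$read[l1][ok]] <- b$rend[l1][ok] - 2L
  q2[b$read[l1][ok]] <- b$qstart[l1][ok] + b$w[l1][ok] - 2L
  prv <- l1[!ok] - 1L
  valid <- prv >= 1L & b$read[prv] == b$read[l1][!ok]
  pos2[b$read[prv][valid]] <- b$rend[prv][valid] - 1L
  q2[b$read[prv][valid]] <- b$qstart[prv][valid] + b$w[prv][valid] - 1L

  keep <- !is.na(pos2)
  tibble::tibble(
    read = which(keep),
    contig = reads$contig[keep],
    strand = reads$strand[keep],
    pos2 = pos2[keep],
    base2 = substr(reads$seq[keep], q2[keep], q2[keep])
  )
}

# per-(contig, pos, strand, base) counts of covering calls, optionally
# restricted to a position set (tibble contig/pos); 0-based positions
base_call_counts <- function(reads, positions = NULL) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(contig = character(0), pos = integer(0),
                          strand = character(0), base = character(0),
                          n = integer(0)))
  }
  b <- read_blocks(reads)
  b$contig <- reads$contig[b$read]
  parts <- list()
  for (ct in unique(b$contig)) {
    bc <- b[b$contig == ct, ]
    if (is.null(positions)) {
      w <- bc$rend - bc$rstart
      parts[[ct]] <- list(pos = rep(bc$rstart, w) + sequence(w) - 1L,
                          qpos = rep(bc$qstart, w) + sequence(w) - 1L,
                          rd = rep(bc$read, w))
    } else {
      pset <- positions$pos[positions$contig == ct]
      if (length(pset) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(pset + 1L, width = 1L),
        IRanges::IRanges(bc$rstart + 1L, bc$rend))
      pi <- S4Vectors::queryHits(hits)
      bi <- S4Vectors::subjectHits(hits)
      parts[[ct]] <- list(pos = pset[pi],
                          qpos = bc$qstart[bi] + (pset[pi] - bc$rstart[bi]),
                          rd = bc$read[bi])
    }
  }
  if (length(parts) == 0) {
    return(tibble::tibble(contig = character(0), pos = integer(0),
                          strand = character(0), base = character(0),
                          n = integer(0)))
  }
  # split only the sequences that contribute calls
  used <- sort(unique(unlist(lapply(parts, `[[`, "rd"), use.names = FALSE)))
  lens <- nchar(reads$seq[used])
  offs_used <- cumsum(c(0L, lens[-length(lens)]))
  flat <- unlist(strsplit(reads$seq[used], "", fixed = TRUE),
                 use.names = FALSE)
  out <- lapply(names(parts), function(ct) {
    pp <- parts[[ct]]
    base <- flat[offs_used[match(pp$rd, used)] + pp$qpos]
    dplyr::count(
      tibble::tibble(contig = ct, pos = pp$pos,
                     strand = reads$strand[pp$rd], base = base),
      .data$contig, .data$pos, .data$strand, .data$base, name = "n")
  })
  dplyr::bind_rows(out)
}

#' Build strand-resolved pileup columns
#'
#' Tallies per-position, per-strand depth, base calls, and truncated-read
#' counts (reads whose second aligned base lands on the position). Reads
#' below `min_mapq` are excluded entirely; only R1, primary, proper-pair,
#' non-duplicate reads should be supplied (as produced by
#' [read_alignments()] or [simulate_reads()]).
#'
#' @param reads Read tibble for one sample.
#' @param genome A `ref_genome` (supplies reference bases).
#' @param min_mapq Mapping-quality threshold (default 5).
#' @param positions Optional tibble (`contig`, `pos`, 0-based) restricting
#'   the pileup to those positions; `NULL` tallies every covered position.
#' @return Tibble with columns `contig`, `pos` (0-based), `ref`, `strand`,
#'   `depth`, `n_A`, `n_C`, `n_G`, `n_T`, `n_N`, `trunc_total`,
#'   `trunc_mut`. `trunc_mut` counts truncated reads whose call is the
#'   strand-appropriate mutant base (G over reference A on `+`, C over
#'   reference T on `-`).
#' @export
build_pileup <- function(reads, genome, min_mapq = 5L, positions = NULL) {
  bad <- setdiff(unique(reads$contig), names(genome))
  if (length(bad)) stop("read references unknown contig: ",
                        paste(bad, collapse = ", "))
  reads <- dplyr::filter(reads, .data$mapq >= min_mapq, .data$is_r1)
  counts <- base_call_counts(reads, positions)
  if (nrow(counts) == 0) {
    return(tibble::tibble(contig = character(0), pos = integer(0),
                          ref = character(0), strand = character(0),
                          depth = integer(0), n_A = integer(0),
                          n_C = integer(0), n_G = integer(0),
                          n_T = integer(0), n_N = integer(0),
                          trunc_total = integer(0), trunc_mut = integer(0)))
  }
  wide <- tidyr::pivot_wider(counts, names_from = "base",
                             values_from = "n", values_fill = 0L,
                             names_prefix = "n_")
  for (col in c("n_A", "n_C", "n_G", "n_T", "n_N")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  wide$depth <- wide$n_A + wide$n_C + wide$n_G + wide$n_T + wide$n_N

  sb <- second_base_records(reads)
  if (!is.null(positions)) {
    sb <- dplyr::semi_join(sb,
                           dplyr::rename(positions, pos2 = "pos"),
                           by = c("contig", "pos2"))
  }
  sb$ref <- ref_at(genome, sb$contig, sb$pos2)
  sb$mut <- (sb$strand == "+" & sb$ref == "A" & sb$base2 == "G") |
            (sb$strand == "-" & sb$ref == "T" & sb$base2 == "C")
  trunc <- sb %>%
    dplyr::group_by(.data$contig, pos = .data$pos2, .data$strand) %>%
    dplyr::summarise(trunc_total = dplyr::n(),
                     trunc_mut = sum(.data$mut), .groups = "drop")

  out <- dplyr::left_join(wide, trunc, by = c("contig", "pos", "strand"))
  out$trunc_total <- dplyr::coalesce(out$trunc_total, 0L)
  out$trunc_mut <- as.integer(dplyr::coalesce(out$trunc_mut, 0L))
  out$ref <- ref_at(genome, out$contig, out$pos)
  dplyr::select(out, "contig", "pos", "ref", "strand", "depth",
                "n_A", "n_C", "n_G", "n_T", "n_N",
                "trunc_total", "trunc_mut") %>%
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
}
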