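# UMI-tagged targeted amplicon quantification: exact-UMI grouping,
# per-position majority consensus (one molecule per UMI), editing rates
# with matched-control background subtraction and a coverage gate.

#' Read paired amplicon FASTQ files
#'
#' @param r1_path,r2_path FASTQ paths (R1 carries the forward UMI then the
#'   amplicon sequence; R2 the reverse UMI then the reverse-complemented
#'   amplicon).
#' @return Tibble with `name`, `r1`, `r2`.
#' @export
read_amplicon_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) stop("R1/R2 read counts differ")
  tibble::tibble(name = sub("\\s.*$", "", names(r1)),
                 r1 = unname(as.character(r1)),
                 r2 = unname(as.character(r2)))
}

#' Group amplicon read pairs by combined UMI and collapse to consensus
#'
#' The combined UMI is the concatenation of the first `umi_len` bases of
#' R1 and R2; pairs whose UMI contains N are discarded (count logged).
#' Within a UMI group the consensus takes the per-position majority base of
#' the R1 insert; positions whose majority fraction falls below
#' `min_agreement` become N. One consensus molecule is emitted per UMI, so
#' PCR duplicates collapse and isolated sequencing errors are corrected.
#'
#' @param pairs Tibble from [read_amplicon_pairs()] (or the simulator).
#' @param umi_len UMI length on each mate (default 5).
#' @param min_agreement Minimum majority fraction for a consensus call
#'   (default 0.6).
#' @return Tibble with `umi`, `n_reads`, `consensus`.
#' @export
umi_collapse <- function(pairs, umi_len = 5L, min_agreement = 0.6) {
  umi <- paste0(substr(pairs$r1, 1L, umi_len),
                substr(pairs$r2, 1L, umi_len))
  insert <- substr(pairs$r1, umi_len + 1L, nchar(pairs$r1))
  keep <- !grepl("N", umi, fixed = TRUE)
  if (any(!keep)) {
    abescan_log(sum(!keep), " read pair(s) discarded: N in UMI")
  }
  umi <- umi[keep]; insert <- insert[keep]
  if (length(insert) == 0) {
    return(tibble::tibble(umi = character(0), n_reads = integer(0),
                          consensus = character(0)))
  }
  len <- min(nchar(insert))
  insert <- substr(insert, 1L, len)
  grp <- match(umi, unique(umi))
  ng <- max(grp)
  m <- do.call(rbind, strsplit(insert, "", fixed = TRUE))
  bases <- c(DNA_BASES, "N")
  counts <- lapply(bases, function(b) {
    rowsum((m == b) + 0L, grp)
  })
  tot <- Reduce(`+`, counts)
  best <- counts[[1]]
  best_base <- matrix(bases[1], ng, len)
  for (bi in 2:length(bases)) {
    better <- counts[[bi]] > best
    best[better] <- counts[[bi]][better]
    best_base[better] <- bases[bi]
  }
  agree <- best / pmax(tot, 1L)
  best_base[agree < min_agreement] <- "N"
  tibble::tibble(
    umi = unique(umi),
    n_reads = as.integer(tabulate(grp, ng)),
    consensus = apply(best_base, 1, paste, collapse = "")
  )
}

#' Per-position editing rates with background subtraction
#'
#' For every amplicon position, the raw rate is edited consensus molecules
#' over molecules with a call there, times 100; the net rate subtracts the
#' matched untreated control and floors at zero. Positions with fewer than
#' `min_cov` consensus molecules in either sample are reported but flagged
#' unqualified.
#'
#' @param test_molecules,control_molecules Consensus tibbles from
#'   [umi_collapse()].
#' @param reference Amplicon reference sequence (insert only, no UMI).
#' @param min_cov Coverage gate applied to both samples (default 500).
#' @param edit_from,edit_to The substitution counted as an edit
#'   (default A to G; use T/C for a minus-strand amplicon design).
#' @return Tibble with `offset` (1-based), `ref`, `edited`, `total`,
#'   `control_edited`, `control_total`, `raw_rate`, `control_rate`,
#'   `net_rate` (percent), `passes_coverage`.
#' @export
editing_rates <- function(test_molecules, control_molecules, reference,
                          min_cov = 500L, edit_from = "A", edit_to = "G") {
  reference <- toupper(reference)
  len <- nchar(reference)
  tally <- function(mol) {
    if (nrow(mol) == 0) {
      return(list(edited = integer(len), total = integer(len)))
    }
    if (any(nchar(mol$consensus) != len)) {
      stop("consensus length does not match the amplicon reference")
    }
    m <- do.call(rbind, strsplit(mol$consensus, "", fixed = TRUE))
    refc <- chars(reference)
    total <- colSums(m != "N")
    edited <- integer(len)
    isfrom <- refc == edit_from
    edited[isfrom] <- colSums(m[, isfrom, drop = FALSE] == edit_to)
    list(edited = edited, total = total)
  }
  tt <- tally(test_molecules)
  cc <- tally(control_molecules)
  raw <- ifelse(tt$total > 0, tt$edited / tt$total * 100, NA_real_)
  ctl <- ifelse(cc$total > 0, cc$edited / cc$total * 100, NA_real_)
  tibble::tibble(
    offset = seq_len(len),
    ref = chars(reference),
    edited = tt$edited, total = as.integer(tt$total),
    control_edited = cc$edited, control_total = as.integer(cc$total),
    raw_rate = raw, control_rate = ctl,
    net_rate = pmax(raw - dplyr::coalesce(ctl, 0), 0),
    passes_coverage = tt$total >= min_cov & cc$total >= min_cov
  )
}

#' Simulate UMI-tagged amplicon read pairs
#'
#' Each molecule draws forward and reverse UMIs and a fixed edited or
#' unedited state per profiled position; `reads_per_molecule` PCR copies
#' share the UMI and state but carry independent sequencing errors on the
#' insert. R1 is `umi_f + insert`; R2 is `umi_r + revcomp(insert)`.
#'
#' @param reference Amplicon insert sequence.
#' @param edit_profile Named numeric vector: 1-based offset ->
#'   per-molecule edit probability (A-to-G at that offset).
#' @param n_molecules Number of molecules.
#' @param reads_per_molecule PCR copies per molecule.
#' @param umi_len UMI length per mate (default 5).
#' @param error_rate Per-base insert sequencing error rate.
#' @param seed Seed.
#' @return List: `pairs` (tibble `name`, `r1`, `r2`), `truth` (tibble
#'   `offset`, `edit_probability`, `edited_molecules`).
#' @export
simulate_amplicon <- function(reference, edit_profile, n_molecules,
                              reads_per_molecule = 5L, umi_len = 5L,
                              error_rate = 0.001, seed = 1L) {
  set.seed(seed)
  reference <- toupper(reference)
  offs <- as.integer(names(edit_profile))
  stopifnot(all(offs >= 1L), all(offs <= nchar(reference)),
            all(substr(rep(reference, length(offs)), offs, offs) == "A"))
  rand_umi <- function(n) {
    vapply(seq_len(n),
           function(i) paste(sample(DNA_BASES, umi_len, replace = TRUE),
                             collapse = ""), character(1))
  }
  umi_f <- rand_umi(n_molecules)
  umi_r <- rand_umi(n_molecules)
  mol_seq <- rep(reference, n_molecules)
  edited_count <- setNames(integer(length(offs)), names(edit_profile))
  for (k in seq_along(offs)) {
    hit <- runif(n_molecules) < edit_profile[k]
    edited_count[k] <- sum(hit)
    substr(mol_seq[hit], offs[k], offs[k]) <- "G"
  }
  idx <- rep(seq_len(n_molecules), each = reads_per_molecule)
  ins1 <- inject_errors(mol_seq[idx], error_rate)
  ins2 <- inject_errors(revcomp(mol_seq[idx]), error_rate)
  pairs <- tibble::tibble(
    name = sprintf("mol%06d_r%02d", idx,
                   rep(seq_len(reads_per_molecule), n_molecules)),
    r1 = paste0(umi_f[idx], ins1),
    r2 = paste0(umi_r[idx], ins2)
  )
  truth <- tibble::tibble(offset = offs,
                          edit_probability = unname(edit_profile),
                          edited_molecules = unname(edited_count))
  list(pairs = pairs, truth = truth)
}

#' Write amplicon read pairs as FASTQ
#' @param pairs Tibble with `name`, `r1`, `r2`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @export
write_amplicon_fastq <- function(pairs, r1_path, r2_path) {
  w <- function(seqs, names, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- names
    Biostrings::writeXStringSet(
      ss, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  }
  w(pairs$r1, pairs$name, r1_path)
  w(pairs$r2, pairs$name, r2_path)
  invisible(c(r1_path, r2_path))
}
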