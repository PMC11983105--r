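#' Find the best sgRNA binding site around a candidate position
#'
#' Extracts the window of `window_flank` nt on each side of the site
#' (clipped at contig ends) and aligns the on-target sequence (protospacer
#' + PAM pattern) against both window strands with [semiglobal_align()].
#' The better-scoring strand wins (ties go to `+`). The binding site is
#' reported only when its alignment penalty is below `max_penalty`.
#'
#' @param contig,pos Candidate coordinates (0-based).
#' @param sgrna An [sgrna_spec()].
#' @param genome A `ref_genome`.
#' @param config A [pipeline_config()].
#' @return `NULL`, or a list: `contig`, `ref_start`, `ref_end` (0-based
#'   half-open genomic span of the aligned target), `strand` (protospacer
#'   orientation on the reference), `score`, `penalty`, `aligned_target`,
#'   `aligned_window`, `pam_observed`, `pam_canonical`,
#'   `mismatch_positions`, `target_bulges` (gap in window / sgRNA bulge),
#'   `dna_bulges` (gap in target) in protospacer coordinates
#'   (1 = PAM-distal), `n_mismatch`, `n_gap`, and `columns` with a
#'   `genome_pos` for every alignment column.
#' @export
find_binding_site <- function(contig, pos, sgrna, genome,
                              config = pipeline_config()) {
  glen <- genome_lengths(genome)[[contig]]
  wstart <- max(0L, pos - config$window_flank)
  wend <- min(glen, pos + config$window_flank + 1L)
  window <- genome_substr(genome, contig, wstart, wend)
  target <- sgrna$target
  if (nchar(window) < nchar(target)) return(NULL)

  aln_p <- semiglobal_align(target, window, config)
  aln_m <- semiglobal_align(target, revcomp(window), config)
  strand <- if (aln_m$score > aln_p$score) "-" else "+"
  aln <- if (strand == "+") aln_p else aln_m
  if (aln$penalty >= config$max_penalty) return(NULL)

  L <- nchar(window)
  cols <- aln$columns
  # genomic position of each window-consuming column
  cols$genome_pos <- if (strand == "+") {
    wstart + cols$window_index - 1L
  } else {
    wstart + (L - cols$window_index)
  }
  ref_start <- wstart + if (strand == "+") aln$window_start else
    L - aln$window_end
  ref_end <- wstart + if (strand == "+") aln$window_end else
    L - aln$window_start

  # protospacer-coordinate annotations (positions 1..20; PAM = 21..23)
  mism <- cols$target_index[cols$state == "M" & cols$mismatch &
                              !is.na(cols$target_index) &
                              cols$target_index <= 20L]
  tb <- cols$target_index[cols$state == "X" & !is.na(cols$target_index) &
                            cols$target_index <= 20L]
  last_ti <- 0L
  db <- integer(0)
  for (k in seq_len(nrow(cols))) {
    if (!is.na(cols$target_index[k])) {
      last_ti <- cols$target_index[k]
    } else if (cols$state[k] == "Y") {
      db <- c(db, last_ti)
    }
  }
  db <- db[db >= 1L & db <= 20L]
  pam_cols <- cols[!is.na(cols$target_index) & cols$target_index >= 21L, ]
  pam_obs <- paste(pam_cols$window_char, collapse = "")
  pam_canon <- nchar(gsub("-", "", pam_obs)) == 3L &&
    all(iupac_compatible(chars("NRG"), chars(pam_obs)))

  list(contig = contig, ref_start = as.integer(ref_start),
       ref_end = as.integer(ref_end), strand = strand,
       score = aln$score, penalty = aln$penalty,
       aligned_target = aln$aligned_target,
       aligned_window = aln$aligned_window,
       pam_observed = pam_obs, pam_canonical = pam_canon,
       mismatch_positions = mism, target_bulges = tb, dna_bulges = db,
       n_mismatch = aln$n_mismatch, n_gap = aln$n_gap,
       columns = cols)
}

# protospacer coordinate of a genomic position, projected through the
# alignment columns (extrapolated linearly outside the aligned span)
protospacer_position_of <- function(binding, pos) {
  cols <- binding$columns
  consumed <- cols[!is.na(cols$genome_pos), ]
  hit <- which(consumed$genome_pos == pos)
  if (length(hit) == 1L) {
    ti <- consumed$target_index[hit]
    if (!is.na(ti)) return(ti)
    # inside a DNA bulge: report the preceding protospacer position
    before <- consumed$target_index[seq_len(hit - 1L)]
    before <- before[!is.na(before)]
    return(if (length(before)) max(before) else 0L)
  }
  tis <- cols$target_index[!is.na(cols$target_index)]
  t_first <- min(tis); t_last <- max(tis)
  if (binding$strand == "+") {
    if (pos < binding$ref_start) {
      t_first - (binding$ref_start - pos)
    } else {
      t_last + (pos - binding$ref_end + 1L)
    }
  } else {
    if (pos >= binding$ref_end) {
      t_first - (pos - binding$ref_end + 1L)
    } else {
      t_last + (binding$ref_start - pos)
    }
  }
}

binding_as_row <- function(binding) {
  if (is.null(binding)) {
    return(tibble::tibble(
      binding_found = FALSE, binding_start = NA_integer_,
      binding_end = NA_integer_, binding_strand = NA_character_,
      align_score = NA_real_, align_penalty = NA_real_,
      aligned_target = NA_character_, aligned_window = NA_character_,
      pam_observed = NA_character_, pam_canonical = NA,
      mismatch_positions = NA_character_, target_bulges = NA_character_,
      dna_bulges = NA_character_, n_mismatch = NA_integer_,
      n_gap = NA_integer_))
  }
  tibble::tibble(
    binding_found = TRUE, binding_start = binding$ref_start,
    binding_end = binding$ref_end, binding_strand = binding$strand,
    align_score = binding$score, align_penalty = binding$penalty,
    aligned_target = binding$aligned_target,
    aligned_window = binding$aligned_window,
    pam_observed = binding$pam_observed,
    pam_canonical = binding$pam_canonical,
    mismatch_positions = paste(binding$mismatch_positions, collapse = ","),
    target_bulges = paste(binding$target_bulges, collapse = ","),
    dna_bulges = paste(binding$dna_bulges, collapse = ","),
    n_mismatch = binding$n_mismatch, n_gap = binding$n_gap)
}

#' Classify candidate sites and annotate their binding-site geometry
#'
#' Applies the off-target classification to every candidate row:
#' \describe{
#'   \item{cas9_dependent}{Selict score >= `min_score`, edited ratio >=
#'     `min_edited_ratio`, sgRNA(-) mutant reads <= `max_neg_reads`, the
#'     cascade passed, and a binding site with penalty < `max_penalty`
#'     containing the edit (within `oop_flank` bp of the aligned span);}
#'   \item{cas9_independent}{cascade passed, sgRNA(-) mutant reads >=
#'     `indep_min_neg_reads` and no mutant reads in the untreated sample;}
#'   \item{endogenous_dI}{present in both sgRNA(-) (>=
#'     `indep_min_neg_reads` mutant reads) and untreated (more than
#'     `max_background_reads` mutant reads) — not induced by the editor;}
#'   \item{unclassified}{anything else.}
#' }
#' Dependent calls are annotated with the protospacer position of the edit
#' (1 = PAM-distal, 20 = PAM-proximal), editing-window and
#' out-of-protospacer flags, the signed distance to the protospacer
#' (negative = PAM-distal side) and the edited strand (nontarget = same
#' strand as the protospacer).
#'
#' @param candidates Candidate tibble from [call_candidates()].
#' @param sgrna An [sgrna_spec()].
#' @param genome A `ref_genome`.
#' @param config A [pipeline_config()].
#' @return The candidate tibble with binding columns
#'   (`binding_found..n_gap`), `classification`, `protospacer_position`,
#'   `in_protospacer`, `in_editing_window`, `out_of_protospacer`,
#'   `edit_strand`, `distance_to_protospacer`.
#' @export
classify_sites <- function(candidates, sgrna, genome,
                           config = pipeline_config()) {
  n <- nrow(candidates)
  bindings <- vector("list", n)
  rows <- vector("list", max(n, 1L))
  if (n == 0) {
    out <- dplyr::bind_cols(candidates, binding_as_row(NULL)[0, ])
    out$classification <- character(0)
    return(out)
  }
  for (k in seq_len(n)) {
    bindings[k] <- list(find_binding_site(candidates$contig[k],
                                          candidates$pos[k], sgrna, genome,
                                          config))
    rows[[k]] <- binding_as_row(bindings[[k]])
  }
  out <- dplyr::bind_cols(candidates, dplyr::bind_rows(rows))

  contains_edit <- purrr::map_lgl(seq_len(n), function(k) {
    b <- bindings[[k]]
    !is.null(b) &&
      candidates$pos[k] >= b$ref_start - config$oop_flank &&
      candidates$pos[k] < b$ref_end + config$oop_flank
  })

  endo <- out$neg_mut >= config$indep_min_neg_reads &
    out$untreated_mut > config$max_background_reads
  dep <- !endo & out$pass &
    !is.na(out$selict_score) & out$selict_score >= config$min_score &
    out$edited_ratio >= config$min_edited_ratio &
    out$neg_mut <= config$max_neg_reads &
    out$binding_found & contains_edit
  indep <- !endo & !dep & out$pass &
    out$neg_mut >= config$indep_min_neg_reads & out$untreated_mut == 0L
  out$classification <- dplyr::case_when(
    endo ~ "endogenous_dI",
    dep ~ "cas9_dependent",
    indep ~ "cas9_independent",
    TRUE ~ "unclassified")

  # geometric annotations for sites with a binding alignment
  pp <- rep(NA_integer_, n)
  es <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    b <- bindings[[k]]
    if (is.null(b)) next
    pp[k] <- as.integer(protospacer_position_of(b, candidates$pos[k]))
    es[k] <- if (candidates$strand[k] == b$strand) "nontarget_strand" else
      "target_strand"
  }
  out$protospacer_position <- pp
  out$in_protospacer <- !is.na(pp) & pp >= 1L & pp <= 20L
  out$in_editing_window <- !is.na(pp) & pp %in% sgrna$editing_window
  out$out_of_protospacer <- !is.na(pp) & !(pp >= 1L & pp <= 20L)
  out$edit_strand <- es
  out$distance_to_protospacer <- dplyr::case_when(
    is.na(pp) ~ NA_integer_,
    pp < 1L ~ pp - 1L,
    pp > 20L ~ pp - 20L,
    TRUE ~ 0L)
  out
}
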