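#' Extract binding-site features for edit-determinant regression
#'
#' Mismatch and gap counts of the sgRNA binding alignment, tallied in
#' protospacer coordinates (1 = PAM-distal): over the first 5 bp, first
#' 8 bp, the seed region (PAM-proximal positions 11-20 by default) and the
#' whole protospacer, plus the PAM type (1 = canonical NRG). Two outcome
#' columns are carried: whether the site shows an out-of-protospacer edit
#' and whether it shows a target-strand edit.
#'
#' @param calls Classified calls from [classify_sites()]; rows without a
#'   binding alignment are dropped.
#' @param seed_region Protospacer positions forming the seed
#'   (default 11:20).
#' @return Tibble with `contig`, `pos`, the nine feature columns
#'   (`first5_mismatch`, `first8_mismatch`, `first5_gap`, `first8_gap`,
#'   `align_mismatch`, `align_gap`, `seed_mismatch`, `seed_gap`,
#'   `pam_type`) and the outcomes `outcome_out_of_protospacer`,
#'   `outcome_target_strand`.
#' @export
extract_features <- function(calls, seed_region = 11:20) {
  calls <- dplyr::filter(calls, .data$binding_found)
  if (nrow(calls) == 0) stop("no calls with a binding site")
  parse_pos <- function(x) {
    purrr::map(x, function(s) {
      if (is.na(s) || s == "") integer(0) else
        as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  mm <- parse_pos(calls$mismatch_positions)
  gp <- purrr::map2(parse_pos(calls$target_bulges),
                    parse_pos(calls$dna_bulges), c)
  count_in <- function(lst, range) {
    purrr::map_int(lst, ~ sum(.x %in% range))
  }
  tibble::tibble(
    contig = calls$contig, pos = calls$pos,
    first5_mismatch = count_in(mm, 1:5),
    first8_mismatch = count_in(mm, 1:8),
    first5_gap = count_in(gp, 1:5),
    first8_gap = count_in(gp, 1:8),
    align_mismatch = count_in(mm, 1:20),
    align_gap = count_in(gp, 1:20),
    seed_mismatch = count_in(mm, seed_region),
    seed_gap = count_in(gp, seed_region),
    pam_type = as.integer(calls$pam_canonical),
    outcome_out_of_protospacer = as.integer(calls$out_of_protospacer),
    outcome_target_strand =
      as.integer(!is.na(calls$edit_strand) &
                   calls$edit_strand == "target_strand")
  )
}
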