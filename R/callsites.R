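#' Selict score of a candidate site
#'
#' The fraction of all strand-depth reads at the site that are truncated
#' and mutant (second aligned base on the position, called as the mutant
#' base), pooled over the sgRNA(+) replicates. Quantifies how strongly the
#' endonuclease-V truncation signature supports the site.
#'
#' @param trunc_mut Pooled truncated-mutant read count.
#' @param depth Pooled strand depth.
#' @return Score in `[0, 1]`; `NA` when depth is 0.
#' @export
selict_score <- function(trunc_mut, depth) {
  ifelse(depth > 0, pmin(1, pmax(0, trunc_mut / depth)), NA_real_)
}

# mutation-rate/type table used by the consecutive-mutation artifact rule:
# per position (strands pooled), overall non-reference rate and the modal
# substitution type
mutation_rate_table <- function(pileup) {
  pooled <- pileup %>%
    dplyr::group_by(.data$contig, .data$pos, .data$ref) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c("n_A", "n_C", "n_G", "n_T", "depth")), sum), .groups = "drop")
  cnt <- as.matrix(pooled[, c("n_A", "n_C", "n_G", "n_T")])
  ridx <- match(pooled$ref, DNA_BASES)
  refn <- ifelse(is.na(ridx), 0L, cnt[cbind(seq_len(nrow(cnt)),
                                            pmax(ridx, 1L))])
  alt <- cnt
  alt[cbind(which(!is.na(ridx)), ridx[!is.na(ridx)])] <- -1L
  modal <- DNA_BASES[max.col(alt, ties.method = "first")]
  tibble::tibble(
    contig = pooled$contig, pos = pooled$pos, ref = pooled$ref,
    depth = pooled$depth,
    mut_rate = ifelse(pooled$depth > 0,
                      (pooled$depth - refn) / pooled$depth, 0),
    mut_type = paste0(pooled$ref, ">", modal)
  )
}

# does position p sit inside a run of `win` consecutive positions all with
# mutation rate > rate_thr and >= 2 distinct substitution types among them?
in_consecutive_artifact <- function(contig, p, rates, win, rate_thr) {
  sub <- rates[rates$contig == contig &
                 rates$pos >= p - (win - 1L) & rates$pos <= p + (win - 1L), ]
  hot <- sub$pos[sub$mut_rate > rate_thr]
  for (s in (p - win + 1L):p) {
    run <- s:(s + win - 1L)
    if (all(run %in% hot)) {
      types <- sub$mut_type[match(run, sub$pos)]
      if (length(unique(types)) >= 2L) return(TRUE)
    }
  }
  FALSE
}

#' Call candidate dA-to-dI sites through the seven-rule filter cascade
#'
#' Candidate positions are seeded wherever a strand-appropriate truncated
#' mutant signature (A-to-G at the second base of plus-strand reads,
#' T-to-C for minus-strand reads) reaches the minimum mutant-read count in
#' at least one sgRNA(+) replicate; each is then audited against all seven
#' rules:
#' \describe{
#'   \item{i}{contributing reads have mapping quality at least `min_mapq`
#'     (enforced at pileup construction);}
#'   \item{ii}{strand depth at least `min_depth` in each sgRNA(+)
#'     replicate;}
#'   \item{iii}{truncated-mutant reads at least `min_mut_reads` with
#'     proportion at least `min_mut_prop` of strand depth (in the
#'     best-supported replicate);}
#'   \item{iv}{at most `max_background_reads` mutant reads in the untreated
#'     sample;}
#'   \item{v}{the site satisfies (ii)+(iii) in every replicate;}
#'   \item{vi}{not inside a run of `consec_window` consecutive positions
#'     with mutation rate above `consec_rate` and two or more distinct
#'     substitution types (sequencing/alignment artifact);}
#'   \item{vii}{not on the known-variant exclusion list.}
#' }
#'
#' @param reads_by_sample Named list of read tibbles; names must include
#'   `sgrna_pos_rep1`, `sgrna_pos_rep2` (or more replicates), `sgrna_neg`
#'   and `untreated`.
#' @param genome A `ref_genome`.
#' @param exclusion Tibble (`contig`, `pos`) of known variant positions, or
#'   `NULL`.
#' @param config A [pipeline_config()].
#' @return Tibble of candidate sites: coordinates and edit strand,
#'   per-replicate and control counts, pooled `edited_ratio` and
#'   `selict_score`, the seven audit columns `filter_i`..`filter_vii`, and
#'   `pass` (all rules). Includes every seeded candidate, so failures carry
#'   their audit trail.
#' @export
call_candidates <- function(reads_by_sample, genome, exclusion = NULL,
                            config = pipeline_config()) {
  reps <- grep("^sgrna_pos_rep", names(reads_by_sample), value = TRUE)
  need <- c("sgrna_neg", "untreated")
  if (length(reps) < 2L || !all(need %in% names(reads_by_sample))) {
    stop("reads_by_sample must contain >=2 'sgrna_pos_rep*' replicates, ",
         "'sgrna_neg' and 'untreated'")
  }
  reps <- sort(reps)

  # seed candidates from truncated-mutant records of the replicates
  seed_tbl <- purrr::map(reps, function(s) {
    rd <- dplyr::filter(reads_by_sample[[s]],
                        .data$mapq >= config$min_mapq, .data$is_r1)
    sb <- second_base_records(rd)
    if (nrow(sb) == 0) {
      return(tibble::tibble(contig = character(0), pos = integer(0),
                            strand = character(0)))
    }
    ref <- ref_at(genome, sb$contig, sb$pos2)
    mut <- (sb$strand == "+" & ref == "A" & sb$base2 == "G") |
           (sb$strand == "-" & ref == "T" & sb$base2 == "C")
    sb[mut, ] %>%
      dplyr::count(.data$contig, pos = .data$pos2, .data$strand,
                   name = "n") %>%
      dplyr::filter(.data$n >= config$min_mut_reads) %>%
      dplyr::select("contig", "pos", "strand")
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::distinct()
  if (nrow(seed_tbl) == 0) {
    return(empty_candidates())
  }

  # pileups restricted to candidates +/- the artifact window
  win <- config$consec_window - 1L
  positions <- seed_tbl %>%
    dplyr::select("contig", "pos") %>%
    tidyr::expand_grid(off = -win:win) %>%
    dplyr::transmute(contig = .data$contig, pos = .data$pos + .data$off) %>%
    dplyr::distinct()
  piles <- purrr::map(reads_by_sample[c(reps, need)], function(rd) {
    build_pileup(rd, genome, min_mapq = config$min_mapq,
                 positions = positions)
  })

  strand_counts <- function(pile, contig, pos, strand) {
    i <- match(paste(contig, pos, strand),
               paste(pile$contig, pile$pos, pile$strand))
    depth <- ifelse(is.na(i), 0L, pile$depth[i])
    mut <- ifelse(is.na(i), 0L,
                  ifelse(strand == "+", pile$n_G[i], pile$n_C[i]))
    tibble::tibble(depth = depth, mut = as.integer(mut),
                   trunc_mut = ifelse(is.na(i), 0L, pile$trunc_mut[i]),
                   trunc_total = ifelse(is.na(i), 0L, pile$trunc_total[i]))
  }

  cand <- seed_tbl
  for (r in seq_along(reps)) {
    sc <- strand_counts(piles[[reps[r]]], cand$contig, cand$pos, cand$strand)
    cand[[paste0("depth_rep", r)]] <- sc$depth
    cand[[paste0("mut_rep", r)]] <- sc$mut
    cand[[paste0("trunc_mut_rep", r)]] <- sc$trunc_mut
  }
  neg <- strand_counts(piles$sgrna_neg, cand$contig, cand$pos, cand$strand)
  unt <- strand_counts(piles$untreated, cand$contig, cand$pos, cand$strand)
  cand$neg_depth <- neg$depth
  cand$neg_mut <- neg$mut
  cand$untreated_depth <- unt$depth
  cand$untreated_mut <- unt$mut

  depth_cols <- paste0("depth_rep", seq_along(reps))
  trunc_cols <- paste0("trunc_mut_rep", seq_along(reps))
  mut_cols <- paste0("mut_rep", seq_along(reps))
  dmat <- as.matrix(cand[depth_cols])
  tmat <- as.matrix(cand[trunc_cols])
  mmat <- as.matrix(cand[mut_cols])
  cand$depth_pool <- rowSums(dmat)
  cand$mut_pool <- rowSums(mmat)
  cand$trunc_mut_pool <- rowSums(tmat)
  cand$edited_ratio <- ifelse(cand$depth_pool > 0,
                              cand$mut_pool / cand$depth_pool, NA_real_)
  cand$selict_score <- selict_score(cand$trunc_mut_pool, cand$depth_pool)

  prop <- tmat / pmax(dmat, 1L)
  rep_present <- dmat >= config$min_depth &
    tmat >= config$min_mut_reads & prop >= config$min_mut_prop

  cand$filter_i <- TRUE
  cand$filter_ii <- rowSums(dmat >= config$min_depth) == length(reps)
  cand$filter_iii <- apply(tmat >= config$min_mut_reads &
                             prop >= config$min_mut_prop, 1, any)
  cand$filter_iv <- cand$untreated_mut <= config$max_background_reads
  cand$filter_v <- rowSums(rep_present) == length(reps)

  pooled_pos <- dplyr::bind_rows(piles[reps])
  rates <- mutation_rate_table(pooled_pos)
  cand$filter_vi <- !purrr::map2_lgl(cand$contig, cand$pos, function(ct, p) {
    in_consecutive_artifact(ct, p, rates, config$consec_window,
                            config$consec_rate)
  })

  if (is.null(exclusion) || nrow(exclusion) == 0) {
    cand$filter_vii <- TRUE
  } else {
    key <- paste(exclusion$contig, exclusion$pos)
    cand$filter_vii <- !(paste(cand$contig, cand$pos) %in% key)
  }

  cand$pass <- cand$filter_i & cand$filter_ii & cand$filter_iii &
    cand$filter_iv & cand$filter_v & cand$filter_vi & cand$filter_vii
  cand$ref <- ref_at(genome, cand$contig, cand$pos)
  dplyr::relocate(cand, "contig", "pos", "strand", "ref") %>%
    dplyr::arrange(.data$contig, .data$pos)
}

empty_candidates <- function() {
  tibble::tibble(
    contig = character(0), pos = integer(0), strand = character(0),
    ref = character(0),
    depth_rep1 = integer(0), mut_rep1 = integer(0),
    trunc_mut_rep1 = integer(0),
    depth_rep2 = integer(0), mut_rep2 = integer(0),
    trunc_mut_rep2 = integer(0),
    neg_depth = integer(0), neg_mut = integer(0),
    untreated_depth = integer(0), untreated_mut = integer(0),
    depth_pool = numeric(0), mut_pool = numeric(0),
    trunc_mut_pool = numeric(0),
    edited_ratio = numeric(0), selict_score = numeric(0),
    filter_i = logical(0), filter_ii = logical(0), filter_iii = logical(0),
    filter_iv = logical(0), filter_v = logical(0), filter_vi = logical(0),
    filter_vii = logical(0), pass = logical(0)
  )
}
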