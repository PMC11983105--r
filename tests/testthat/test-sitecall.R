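# Filter-cascade boundary behaviour, built from handcrafted reads on the
# tiling genome (A at positions divisible by 4; candidate site at 100).

cascade <- function(samples, genome = tiling_genome(400), excl = NULL,
                    config = pipeline_config()) {
  call_candidates(samples, genome, excl, config)
}

test_that("the reference configuration passes a minimal bona fide site", {
  g <- tiling_genome(400)
  cand <- cascade(passing_sample_set(g))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 100L)
  expect_true(cand$pass)
  expect_true(all(unlist(cand[paste0("filter_",
                                     c("i", "ii", "iii", "iv", "v",
                                       "vi", "vii"))])))
  # depth 5 per replicate, 3 truncated mutants: score 6/10
  expect_equal(cand$depth_rep1, 5L)
  expect_equal(cand$trunc_mut_rep1, 3L)
  expect_equal(cand$selict_score, 0.6)
  expect_equal(cand$edited_ratio, 0.6)
})

test_that("selict_score is the truncated-mutant fraction of depth", {
  expect_equal(selict_score(6, 10), 0.6)
  expect_equal(selict_score(0, 10), 0)
  expect_equal(selict_score(10, 10), 1)
  expect_true(is.na(selict_score(0, 0)))
})

test_that("each cascade rule flips at its printed threshold", {
  g <- tiling_genome(400)

  # (i) mapq 4 reads are invisible: the site disappears entirely when both
  # replicates fall below the floor, and fails depth when one does
  low <- passing_sample_set(g)
  low$sgrna_pos_rep1$mapq <- 4L
  cand_one <- cascade(low)
  expect_false(cand_one$filter_ii)   # rep1 contributes nothing
  expect_false(cand_one$pass)
  low$sgrna_pos_rep2$mapq <- 4L
  expect_equal(nrow(cascade(low)), 0L)

  # (ii) depth 4 in one replicate fails; mut 3 of depth 4 still satisfies iii
  thin <- passing_sample_set(g)
  thin$sgrna_pos_rep1 <- site_reads(g, 100L, n_trunc_mut = 3L,
                                    n_cover = 1L,
                                    sample = "sgrna_pos_rep1")
  cand <- cascade(thin)
  expect_equal(cand$depth_rep1, 4L)
  expect_false(cand$filter_ii)
  expect_true(cand$filter_iii)
  expect_false(cand$pass)

  # (iii) mutant count 2 never seeds a candidate
  few <- passing_sample_set(g)
  few$sgrna_pos_rep1 <- site_reads(g, 100L, n_trunc_mut = 2L,
                                   n_cover = 3L, sample = "sgrna_pos_rep1")
  few$sgrna_pos_rep2 <- site_reads(g, 100L, n_trunc_mut = 2L,
                                   n_cover = 3L, sample = "sgrna_pos_rep2")
  expect_equal(nrow(cascade(few)), 0L)

  # (iii) 3 mutants of depth 20 is 15% < 20%: proportion arm fails
  dilute <- passing_sample_set(g)
  dilute$sgrna_pos_rep1 <- site_reads(g, 100L, n_trunc_mut = 3L,
                                      n_cover = 17L,
                                      sample = "sgrna_pos_rep1")
  dilute$sgrna_pos_rep2 <- site_reads(g, 100L, n_trunc_mut = 3L,
                                      n_cover = 17L,
                                      sample = "sgrna_pos_rep2")
  cand <- cascade(dilute)
  expect_false(cand$filter_iii)
  expect_false(cand$pass)
  # 3 of 15 is exactly 20%: passes
  exact <- passing_sample_set(g)
  exact$sgrna_pos_rep1 <- site_reads(g, 100L, n_trunc_mut = 3L,
                                     n_cover = 12L,
                                     sample = "sgrna_pos_rep1")
  exact$sgrna_pos_rep2 <- site_reads(g, 100L, n_trunc_mut = 3L,
                                     n_cover = 12L,
                                     sample = "sgrna_pos_rep2")
  expect_true(cascade(exact)$pass)

  # (iv) one untreated mutant read is tolerated, two are not
  bg1 <- passing_sample_set(g)
  bg1$untreated <- site_reads(g, 100L, n_trunc_mut = 0L, n_cover = 10L,
                              n_cover_mut = 1L, sample = "untreated")
  expect_true(cascade(bg1)$filter_iv)
  bg2 <- passing_sample_set(g)
  bg2$untreated <- site_reads(g, 100L, n_trunc_mut = 0L, n_cover = 10L,
                              n_cover_mut = 2L, sample = "untreated")
  cand <- cascade(bg2)
  expect_false(cand$filter_iv)
  expect_false(cand$pass)

  # (v) signal in one replicate only
  solo <- passing_sample_set(g)
  solo$sgrna_pos_rep2 <- site_reads(g, 100L, n_trunc_mut = 0L,
                                    n_cover = 5L,
                                    sample = "sgrna_pos_rep2")
  cand <- cascade(solo)
  expect_true(cand$filter_ii)
  expect_true(cand$filter_iii)
  expect_false(cand$filter_v)
  expect_false(cand$pass)

  # (vii) exclusion list removes the exact position
  excl <- tibble::tibble(contig = "chr1", pos = 100L)
  cand <- cascade(passing_sample_set(g), excl = excl)
  expect_false(cand$filter_vii)
  expect_false(cand$pass)
  other <- tibble::tibble(contig = "chr1", pos = 101L)
  expect_true(cascade(passing_sample_set(g), excl = other)$pass)
})

test_that("three consecutive high-rate mixed-type positions are excluded", {
  g <- tiling_genome(400)
  # candidate at 100; add >20% non-reference calls of other types at 99
  # (T->A) and 101 (C->A) in both replicates
  noisy <- passing_sample_set(g)
  for (s in c("sgrna_pos_rep1", "sgrna_pos_rep2")) {
    noisy[[s]] <- dplyr::bind_rows(
      noisy[[s]],
      rep_rows(mk_read(g, 90L, mutations = list(`10` = "A", `12` = "A"),
                       sample = s, name = "art"), 3L))
  }
  cand <- cascade(noisy)
  expect_false(cand$filter_vi)
  expect_false(cand$pass)

  # same extra reads but with only one distinct neighbouring type and a
  # low-rate third position: rule vi keeps the site
  calm <- passing_sample_set(g)
  for (s in c("sgrna_pos_rep1", "sgrna_pos_rep2")) {
    calm[[s]] <- dplyr::bind_rows(
      calm[[s]],
      rep_rows(mk_read(g, 90L, mutations = list(`10` = "A"),
                       sample = s, name = "art"), 1L))
  }
  expect_true(cascade(calm)$filter_vi)
})

test_that("window-scan oracle agrees with the artifact rule on random tracks", {
  # independent oracle: brute-force scan of every 3-window
  oracle <- function(hot, types, p) {
    for (s in (p - 2):p) {
      run <- s:(s + 2)
      if (all(run %in% hot) &&
          length(unique(types[as.character(run)])) >= 2) return(TRUE)
    }
    FALSE
  }
  set.seed(99)
  for (trial in 1:25) {
    hot <- sort(sample(95:105, sample(3:8, 1)))
    types <- setNames(sample(c("A>G", "C>T", "G>A"), length(hot),
                             replace = TRUE), hot)
    rates <- tibble::tibble(contig = "chr1", pos = hot, ref = "A",
                            depth = 10L, mut_rate = 0.5,
                            mut_type = unname(types))
    got <- abescan:::in_consecutive_artifact("chr1", 100L, rates, 3L, 0.2)
    expect_equal(got, oracle(hot, types, 100L), info = paste(hot, collapse = ","))
  }
})

test_that("every stored verdict can be recomputed from the reported counts", {
  g <- tiling_genome(400)
  cfg <- pipeline_config()
  mixed <- passing_sample_set(g)
  mixed$untreated <- site_reads(g, 100L, n_trunc_mut = 0L, n_cover = 10L,
                                n_cover_mut = 2L, sample = "untreated")
  cand <- cascade(mixed)
  expect_equal(cand$filter_ii,
               cand$depth_rep1 >= cfg$min_depth &
                 cand$depth_rep2 >= cfg$min_depth)
  expect_equal(cand$filter_iii,
               (cand$trunc_mut_rep1 >= cfg$min_mut_reads &
                  cand$trunc_mut_rep1 / cand$depth_rep1 >= cfg$min_mut_prop) |
                 (cand$trunc_mut_rep2 >= cfg$min_mut_reads &
                    cand$trunc_mut_rep2 / cand$depth_rep2 >= cfg$min_mut_prop))
  expect_equal(cand$filter_iv,
               cand$untreated_mut <= cfg$max_background_reads)
  expect_equal(cand$selict_score,
               cand$trunc_mut_pool / cand$depth_pool)
  expect_equal(cand$edited_ratio, cand$mut_pool / cand$depth_pool)
  expect_equal(cand$pass,
               cand$filter_i & cand$filter_ii & cand$filter_iii &
                 cand$filter_iv & cand$filter_v & cand$filter_vi &
                 cand$filter_vii)
})

test_that("strand symmetry: mirrored reads give mirrored minus-strand calls", {
  g <- tiling_genome(400)
  glen <- 400L
  flip_reads <- function(rd) {
    len <- nchar(rd$seq)
    tibble::tibble(name = rd$name, contig = rd$contig,
                   start = glen - (rd$start + len),
                   strand = ifelse(rd$strand == "+", "-", "+"),
                   mapq = rd$mapq, cigar = rd$cigar,
                   seq = revcomp(rd$seq),
                   is_r1 = rd$is_r1, is_proper_pair = rd$is_proper_pair,
                   is_primary = rd$is_primary,
                   is_duplicate = rd$is_duplicate, sample = rd$sample)
  }
  g_rc <- ref_genome(setNames(revcomp(unclass(g)[["chr1"]]), "chr1"))
  fwd <- cascade(passing_sample_set(g))
  rev <- cascade(lapply(passing_sample_set(g), flip_reads), genome = g_rc)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$pos, glen - 1L - fwd$pos)
  expect_equal(rev$strand, "-")
  expect_equal(rev$selict_score, fwd$selict_score)
  expect_equal(rev$pass, fwd$pass)
})

test_that("missing control samples raise a configuration error", {
  g <- tiling_genome(400)
  broken <- passing_sample_set(g)
  broken$untreated <- NULL
  expect_error(call_candidates(broken, g, NULL), "untreated")
})
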