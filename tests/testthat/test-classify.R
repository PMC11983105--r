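# classification thresholds exercised on synthetic candidate rows over a
# genome carrying a perfect planted protospacer

synthetic_candidate <- function(pos, score, ratio, neg_mut,
                                untreated_mut = 0L, pass = TRUE,
                                strand = "+") {
  tibble::tibble(
    contig = "chr1", pos = as.integer(pos), strand = strand, ref = "A",
    depth_rep1 = 10L, mut_rep1 = 6L, trunc_mut_rep1 = 6L,
    depth_rep2 = 10L, mut_rep2 = 6L, trunc_mut_rep2 = 6L,
    neg_depth = 10L, neg_mut = as.integer(neg_mut),
    untreated_depth = 10L, untreated_mut = as.integer(untreated_mut),
    depth_pool = 20, mut_pool = ratio * 20, trunc_mut_pool = score * 20,
    edited_ratio = ratio, selict_score = score,
    filter_i = TRUE, filter_ii = pass, filter_iii = pass, filter_iv = pass,
    filter_v = pass, filter_vi = TRUE, filter_vii = TRUE, pass = pass)
}

planted_genome <- function(seed = 71) {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 20000L), seed = seed)
  planted <- plant_sites(g, sg, site_spec("cas9_dependent",
                                          edit_fraction = 1), seed = seed)
  list(genome = planted$genome, site = planted$sites[1, ], sgrna = sg)
}

test_that("dependent calls flip exactly at the score/ratio/control thresholds", {
  px <- planted_genome()
  pos <- px$site$position
  cases <- list(
    list(0.60, 0.20, 0L, "cas9_dependent"),
    list(0.60, 0.20, 1L, "cas9_dependent"),
    list(0.59, 0.20, 1L, "unclassified"),
    list(0.60, 0.19, 1L, "unclassified"),
    list(0.60, 0.20, 2L, "unclassified"),
    list(0.70, 0.25, 0L, "cas9_dependent")
  )
  for (cs in cases) {
    cand <- synthetic_candidate(pos, cs[[1]], cs[[2]], cs[[3]],
                                strand = px$site$strand_of_edit)
    out <- classify_sites(cand, px$sgrna, px$genome)
    expect_equal(out$classification, cs[[4]],
                 info = sprintf("score=%.2f ratio=%.2f neg=%d",
                                cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("a high-scoring site without sgRNA homology is never dependent", {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 20000L), seed = 72)
  # no planted homology anywhere: classification cannot be cas9_dependent
  cand <- synthetic_candidate(10000L, 0.9, 0.9, 0L)
  out <- classify_sites(cand, sg, g)
  expect_false(out$binding_found)
  expect_equal(out$classification, "unclassified")
})

test_that("independent and endogenous thresholds follow the control counts", {
  px <- planted_genome(73)
  pos <- px$site$position
  # neg >= 3 and clean untreated: independent
  out <- classify_sites(
    synthetic_candidate(pos, 0.3, 0.3, neg_mut = 3L, untreated_mut = 0L),
    px$sgrna, px$genome)
  expect_equal(out$classification, "cas9_independent")
  # neg 2 falls short
  out <- classify_sites(
    synthetic_candidate(pos, 0.3, 0.3, neg_mut = 2L, untreated_mut = 0L),
    px$sgrna, px$genome)
  expect_equal(out$classification, "unclassified")
  # present in both controls: endogenous, never an off-target class
  out <- classify_sites(
    synthetic_candidate(pos, 0.9, 0.9, neg_mut = 5L, untreated_mut = 4L,
                        pass = FALSE),
    px$sgrna, px$genome)
  expect_equal(out$classification, "endogenous_dI")
})

test_that("random windows rarely admit a binding site under the penalty cap", {
  sg <- test_sgrna()
  cfg <- pipeline_config()
  set.seed(74)
  hits <- 0L
  for (k in 1:100) {
    g <- ref_genome(setNames(random_seq(300), "chr1"))
    b <- find_binding_site("chr1", 150L, sg, g, cfg)
    if (!is.null(b)) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("binding-site annotations resolve protospacer geometry", {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 30000L), seed = 75)
  planted <- plant_sites(g, sg, site_spec("cas9_dependent",
                                          edit_fraction = 1), seed = 75)
  st <- planted$sites[1, ]
  cand <- synthetic_candidate(st$position, 0.8, 0.8, 0L,
                              strand = st$strand_of_edit)
  out <- classify_sites(cand, sg, planted$genome)
  expect_equal(out$classification, "cas9_dependent")
  expect_equal(out$protospacer_position, 7L)
  expect_true(out$in_protospacer)
  expect_true(out$in_editing_window)       # default window 3..9
  expect_false(out$out_of_protospacer)
  expect_equal(out$distance_to_protospacer, 0L)
  expect_equal(out$edit_strand, "nontarget_strand")
  expect_true(out$pam_canonical)

  # an edit 7 bp PAM-distal of position 1 is out-of-protospacer
  b <- find_binding_site(st$contig, st$position, sg, planted$genome,
                         pipeline_config())
  oop_pos <- if (b$strand == "+") b$ref_start - 7L else b$ref_end + 6L
  pp <- abescan:::protospacer_position_of(b, oop_pos)
  expect_equal(pp, -6L)                     # position 1 minus 7
  # the edited strand opposite to the protospacer is the target strand
  flipped <- synthetic_candidate(st$position, 0.8, 0.8, 0L,
                                 strand = ifelse(st$strand_of_edit == "+",
                                                 "-", "+"))
  out2 <- classify_sites(flipped, sg, planted$genome)
  expect_equal(out2$edit_strand, "target_strand")
})

test_that("context motif fixes the edited A at the centre and finds TAT", {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 30000L), seed = 76)
  specs <- dplyr::bind_rows(lapply(1:6, function(i) {
    site_spec("cas9_independent", strand = c("+", "-")[i %% 2 + 1])
  }))
  planted <- plant_sites(g, sg, specs, seed = 76)
  calls <- tibble::tibble(contig = planted$sites$contig,
                          pos = planted$sites$position,
                          strand = planted$sites$strand_of_edit)
  pfm <- motif_pfm(calls, planted$genome, flank = 2L)
  expect_equal(pfm$n, 6L)
  expect_equal(unname(pfm$freq["A", 3]), 1)          # centre fixed at A
  expect_equal(names(which.max(pfm$freq[, 2])), "T") # -1 preference
  expect_equal(names(which.max(pfm$freq[, 4])), "T") # +1 preference
  expect_equal(unname(pfm$info[3]), 2)               # fully determined
  expect_error(motif_pfm(calls[0, ], planted$genome), "no calls")
})
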