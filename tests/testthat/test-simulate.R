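test_that("genome generation is deterministic with controlled composition", {
  p <- sim_params(genome_length = 100000L, gc_content = 0.5)
  g1 <- make_genome(p, seed = 1)
  g2 <- make_genome(p, seed = 1)
  expect_identical(unclass(g1), unclass(g2))
  gc <- sum(strsplit(unclass(g1)[["chr1"]], "")[[1]] %in% c("G", "C")) /
    100000
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_error(make_genome(sim_params(genome_length = 1000L),
                           seed = 1), NA)
  expect_error(sim_params(genome_length = 0L) |> make_genome(),
               "at least 1000")
})

test_that("planted protospacers align back with the requested degeneracy", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 20000L)
  g <- make_genome(p, seed = 5)
  specs <- dplyr::bind_rows(
    site_spec("cas9_dependent", mm = c(1L, 3L), pam = "AGG"),
    site_spec("cas9_dependent", mm = integer(0), pam = "TGG",
              strand = "-"),
    site_spec("cas9_dependent", dna_bulge = 14L, pam = "CGG"),
    site_spec("cas9_dependent", rna_bulge = 16L, pam = "AGG")
  )
  planted <- plant_sites(g, sg, specs, seed = 6)
  cfg <- pipeline_config()
  for (k in seq_len(nrow(planted$sites))) {
    st <- planted$sites[k, ]
    b <- find_binding_site(st$contig, st$position, sg, planted$genome, cfg)
    expect_false(is.null(b), info = paste("site", k))
    expect_equal(b$strand, st$strand_of_edit)
    expect_equal(b$n_mismatch, length(specs$mm[[k]]), info = paste("site", k))
    expect_equal(length(b$dna_bulges), length(specs$dna_bulge[[k]]))
    expect_equal(length(b$target_bulges), length(specs$rna_bulge[[k]]))
    # the edit lies at the requested protospacer position
    expect_equal(abescan:::protospacer_position_of(b, st$position),
                 st$protospacer_pos)
  }
})

test_that("independent sites carry a TAT context and edited bases are adenosines", {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 20000L), seed = 7)
  specs <- dplyr::bind_rows(
    site_spec("cas9_independent", strand = "+"),
    site_spec("cas9_independent", strand = "-"),
    site_spec("endogenous_dI"),
    site_spec("snp")
  )
  planted <- plant_sites(g, sg, specs, seed = 8)
  gs <- unclass(planted$genome)[["chr1"]]
  for (k in 1:2) {
    st <- planted$sites[k, ]
    ctx <- substr(gs, st$position, st$position + 2L)
    if (st$strand_of_edit == "-") ctx <- revcomp(ctx)
    expect_equal(ctx, "TAT")
  }
  refb <- substr(rep(gs, 4), planted$sites$position + 1L,
                 planted$sites$position + 1L)
  expect_equal(refb,
               ifelse(planted$sites$strand_of_edit == "+", "A", "T"))
  # snp positions populate the exclusion list
  expect_equal(planted$exclusion$pos,
               planted$sites$position[planted$sites$site_class == "snp"])
})

test_that("overlapping explicit placements are rejected", {
  sg <- test_sgrna()
  g <- make_genome(sim_params(genome_length = 20000L), seed = 9)
  specs <- dplyr::bind_rows(
    site_spec("cas9_independent", position = 5000L),
    site_spec("cas9_independent", position = 5000L)
  )
  expect_error(plant_sites(g, sg, specs, seed = 1), "overlapping")
})

test_that("signal reads obey the second-base convention (independent SAM check)", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 30000L, depth = 15,
                  sequencing_error_rate = 0)
  sim <- simulate_run(sg, dplyr::bind_rows(
    site_spec("cas9_dependent", edit_fraction = 1, strand = "+"),
    site_spec("cas9_dependent", edit_fraction = 1, strand = "-",
              mm = 2L)), params = p, seed = 21)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads$sgrna_pos_rep1, sim$genome, sam)
  gs <- unclass(sim$genome)[["chr1"]]
  # re-read the SAM text directly, independent of the package reader
  rec <- strsplit(grep("^[^@]", readLines(sam), value = TRUE), "\t")
  sig <- Filter(function(f) grepl("_sig_", f[1]), rec)
  expect_gt(length(sig), 10)
  truth_pos <- sim$sites$position
  names(truth_pos) <- sim$sites$strand_of_edit
  for (f in sig) {
    flag <- as.integer(f[2]); pos1 <- as.integer(f[4]); seq <- f[10]
    if (bitwAnd(flag, 16L) == 0L) {
      # plus strand: second base of the read sits on the edited A, read G
      p0 <- pos1 - 1L + 1L
      expect_equal(substr(gs, p0 + 1L, p0 + 1L), "A")
      expect_equal(substr(seq, 2L, 2L), "G")
      expect_true(p0 %in% truth_pos)
    } else {
      # minus strand: second base from the right edge, T read as C
      endp <- pos1 - 1L + nchar(seq) - 1L
      p0 <- endp - 1L
      expect_equal(substr(gs, p0 + 1L, p0 + 1L), "T")
      expect_equal(substr(seq, nchar(seq) - 1L, nchar(seq) - 1L), "C")
      expect_true(p0 %in% truth_pos)
    }
  }
})

test_that("edit fraction scales signal read counts as a binomial", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 30000L, depth = 20)
  none <- simulate_run(sg, site_spec("cas9_dependent", edit_fraction = 0),
                       params = p, seed = 31)
  expect_equal(sum(grepl("_sig_", none$reads$sgrna_pos_rep1$name)), 0L)
  full <- simulate_run(sg, site_spec("cas9_dependent", edit_fraction = 1),
                       params = p, seed = 31)
  n_sig <- sum(grepl("_sig_", full$reads$sgrna_pos_rep1$name))
  expect_equal(n_sig, round(20 * p$signal_read_multiplier))
})

test_that("control samples receive signal only from the classes they should", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 40000L, depth = 15)
  sim <- simulate_run(sg, dplyr::bind_rows(
    site_spec("cas9_dependent", edit_fraction = 1),
    site_spec("cas9_independent", edit_fraction = 1),
    site_spec("endogenous_dI", edit_fraction = 1)), params = p, seed = 41)
  sig_positions <- function(reads) {
    sig <- reads[grepl("_sig_", reads$name), ]
    unique(ifelse(sig$strand == "+", sig$start + 1L,
                  sig$start + nchar(sig$seq) - 2L))
  }
  truth <- setNames(sim$sites$position, sim$sites$site_class)
  expect_setequal(sig_positions(sim$reads$sgrna_pos_rep1), unname(truth))
  expect_setequal(sig_positions(sim$reads$sgrna_neg),
                  unname(truth[c("cas9_independent", "endogenous_dI")]))
  expect_setequal(sig_positions(sim$reads$untreated),
                  unname(truth["endogenous_dI"]))
})

test_that("background coverage matches the n*L/G expectation", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 50000L, depth = 10)
  g <- make_genome(p, seed = 51)
  no_sites <- plant_sites(g, sg, site_spec("endogenous_dI"),
                          seed = 53)$sites[0, ]
  reads <- simulate_reads(g, no_sites, p, "untreated", seed = 52)
  cov <- sum(nchar(reads$seq)) / 50000
  expect_gt(cov, 9.5)
  expect_lt(cov, 10.5)
})

test_that("identical parameters and seed give byte-identical SAM output", {
  sg <- test_sgrna()
  p <- sim_params(genome_length = 20000L, depth = 10)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  s1 <- simulate_run(sg, default_site_specs(), p, seed = 61)
  s2 <- simulate_run(sg, default_site_specs(), p, seed = 61)
  write_sam(s1$reads$sgrna_pos_rep1, s1$genome, f1)
  write_sam(s2$reads$sgrna_pos_rep1, s2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})
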