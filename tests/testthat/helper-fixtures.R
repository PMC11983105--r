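# Shared fixtures: handcrafted genomes and reads, plus an independent
# brute-force alignment oracle used to validate the affine-gap DP.

test_sgrna <- function() sgrna_spec("GAACACAAAGCATAGACTGC")

# deterministic genome without accidental structure: fixed 4-base tiling so
# every position's reference base is known (pos %% 4: 0=A, 1=C, 2=G, 3=T)
tiling_genome <- function(len = 400L, contig = "chr1") {
  ref_genome(setNames(strrep("ACGT", ceiling(len / 4))|> substr(1, len),
                      contig))
}

# one aligned single-end read over the genome, with optional substitutions
# given as read offsets (1-based) -> base
mk_read <- function(genome, start, len = 50L, strand = "+",
                    mutations = NULL, mapq = 60L, contig = "chr1",
                    sample = "s", name = "r") {
  seq <- genome_substr(genome, contig, start, start + len)
  for (off in names(mutations)) {
    o <- as.integer(off)
    substr(seq, o, o) <- mutations[[off]]
  }
  tibble::tibble(name = name, contig = contig, start = start,
                 strand = strand, mapq = mapq,
                 cigar = paste0(nchar(seq), "M"), seq = seq,
                 is_r1 = TRUE, is_proper_pair = TRUE, is_primary = TRUE,
                 is_duplicate = FALSE, sample = sample)
}

rep_rows <- function(tb, n) {
  if (n == 0) return(tb[0, ])
  out <- tb[rep(1, n), ]
  out$name <- paste0(out$name, "_", seq_len(n))
  out
}

# reads for one edited site at 0-based position p (reference A, plus
# strand): n_trunc_mut truncated reads calling G, n_trunc_ref truncated
# reads calling A, n_cover ordinary covering reads (n_cover_mut of them
# calling G at p without the truncation signature)
site_reads <- function(genome, p, n_trunc_mut, n_trunc_ref = 0L,
                       n_cover = 0L, n_cover_mut = 0L, mapq = 60L,
                       sample = "s") {
  dplyr::bind_rows(
    rep_rows(mk_read(genome, p - 1L, mutations = list(`2` = "G"),
                     mapq = mapq, sample = sample, name = "tm"),
             n_trunc_mut),
    rep_rows(mk_read(genome, p - 1L, mapq = mapq, sample = sample,
                     name = "tr"), n_trunc_ref),
    rep_rows(mk_read(genome, p - 10L, mapq = mapq, sample = sample,
                     name = "cv"), n_cover - n_cover_mut),
    rep_rows(mk_read(genome, p - 10L, mutations = list(`11` = "G"),
                     mapq = mapq, sample = sample, name = "cm"),
             n_cover_mut)
  )
}

empty_sample <- function(genome, n_cover = 10L, p = 100L) {
  rep_rows(mk_read(genome, p - 10L, name = "bg"), n_cover)
}

# sample set where the site at p passes the full cascade
passing_sample_set <- function(genome, p = 100L) {
  list(
    sgrna_pos_rep1 = site_reads(genome, p, n_trunc_mut = 3L,
                                n_trunc_ref = 0L, n_cover = 2L,
                                sample = "sgrna_pos_rep1"),
    sgrna_pos_rep2 = site_reads(genome, p, n_trunc_mut = 3L,
                                n_trunc_ref = 0L, n_cover = 2L,
                                sample = "sgrna_pos_rep2"),
    sgrna_neg = empty_sample(genome, p = p),
    untreated = empty_sample(genome, p = p)
  )
}

# Independent cubic-time alignment oracle: enumerates whole gap runs
# (a length-L run costs open + (L-1) * ext), free window skip at both
# ends, full target consumption. Scores only.
oracle_align_score <- function(target, window, match = 5, mismatch = -4,
                               open = -24, ext = -8) {
  n <- nchar(target); m <- nchar(window)
  tc <- strsplit(target, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  B <- matrix(-Inf, n + 1, m + 1)
  B[1, ] <- 0
  for (i in 1:n) {
    ii <- i + 1
    for (j in 0:m) {
      jj <- j + 1
      best <- -Inf
      if (j >= 1) {
        s <- if (tc[i] == wc[j]) match else mismatch
        best <- max(best, B[ii - 1, jj - 1] + s)
      }
      # gap in window: run of L target chars ending at i
      best <- max(best, max(B[ii - (1:i), jj] + open + (0:(i - 1)) * ext))
      # gap in target: run of L window chars ending at j
      if (j >= 1) {
        best <- max(best, max(B[ii, jj - (1:j)] + open + (0:(j - 1)) * ext))
      }
      B[ii, jj] <- best
    }
  }
  max(B[n + 1, ])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
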