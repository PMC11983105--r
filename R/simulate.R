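#' Simulation parameters
#'
#' Conditions for the synthetic sequencing experiment the simulator
#' emulates: a uniformly fragmented background over a pseudo-random genome,
#' plus enriched truncated signal reads at planted edit sites.
#'
#' @param genome_length Toy genome length in bp (single contig `chr1`;
#'   minimum 1000).
#' @param gc_content GC fraction of the random genome (default 0.41,
#'   human-like).
#' @param depth Mean background coverage (default 30).
#' @param read_length Read length in bp (default 100).
#' @param signal_read_multiplier Enrichment factor for truncated signal
#'   reads relative to background sampling (default 5). Emulates the
#'   endonuclease-V / streptavidin capture step, which strongly enriches
#'   dI-containing fragments over bulk genomic background; without
#'   enrichment the truncated-read fraction of depth could never reach the
#'   dependent-call score threshold.
#' @param sequencing_error_rate Per-base substitution error rate
#'   (default 0.001; must be at most 0.05).
#' @param mapq_high,mapq_high_prob Mapping qualities are `mapq_high` with
#'   probability `mapq_high_prob` and uniform on 0..`mapq_high` otherwise,
#'   so the mapping-quality filter is exercised (defaults 60 and 0.9).
#' @param n_replicates Number of sgRNA(+) replicates (default 2).
#' @param seed Default seed.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(genome_length = 200000L,
                       gc_content = 0.41,
                       depth = 30,
                       read_length = 100L,
                       signal_read_multiplier = 5,
                       sequencing_error_rate = 0.001,
                       mapq_high = 60L,
                       mapq_high_prob = 0.9,
                       n_replicates = 2L,
                       seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            gc_content = gc_content, depth = depth,
            read_length = as.integer(read_length),
            signal_read_multiplier = signal_read_multiplier,
            sequencing_error_rate = sequencing_error_rate,
            mapq_high = as.integer(mapq_high),
            mapq_high_prob = mapq_high_prob,
            n_replicates = as.integer(n_replicates),
            seed = as.integer(seed))
  stopifnot(p$depth > 0, p$sequencing_error_rate >= 0,
            p$sequencing_error_rate <= 0.05,
            p$gc_content > 0, p$gc_content < 1, p$read_length >= 10)
  structure(p, class = "sim_params")
}

#' Generate a pseudo-random toy genome
#'
#' @param params A [sim_params()].
#' @param contig Contig name (default `"chr1"`).
#' @param seed Seed (defaults to `params$seed`).
#' @return A `ref_genome` with one contig.
#' @export
make_genome <- function(params = sim_params(), contig = "chr1",
                        seed = params$seed) {
  if (params$genome_length < 1000L) {
    stop("genome_length must be at least 1000 bp")
  }
  set.seed(seed)
  ref_genome(setNames(random_dna(params$genome_length, params$gc_content),
                      contig))
}

#' Describe one planted site
#'
#' @param class One of `"on_target"`, `"cas9_dependent"`,
#'   `"cas9_independent"`, `"endogenous_dI"`, `"snp"`.
#' @param edit_fraction Per-read probability that a sampled signal read
#'   carries the edit (for `snp`, the allele is always heterozygous 50%).
#' @param strand Strand carrying the deaminated adenosine (`"+"` or `"-"`;
#'   `NA` = choose at random).
#' @param position Explicit 0-based genome position of the edited base
#'   (`NA` = place at random without overlap).
#' @param mm Integer protospacer positions (1 = PAM-distal) to mutate when
#'   planting a degenerate protospacer (cas9_dependent only).
#' @param dna_bulge Protospacer positions after which an extra genomic base
#'   is inserted (DNA bulge).
#' @param rna_bulge Protospacer positions deleted from the genomic copy
#'   (sgRNA bulge).
#' @param pam Concrete 3-mer PAM to plant (default `"AGG"`).
#' @param edit_pos Protospacer position of the edited adenosine
#'   (default 7, inside the editing window; must be an A of the
#'   protospacer and not mutated).
#' @return One-row tibble usable in a `spec_list` for [plant_sites()].
#' @export
site_spec <- function(class, edit_fraction = 0.5, strand = NA_character_,
                      position = NA_integer_, mm = integer(0),
                      dna_bulge = integer(0), rna_bulge = integer(0),
                      pam = "AGG", edit_pos = 7L) {
  class <- match.arg(class, c("on_target", "cas9_dependent",
                              "cas9_independent", "endogenous_dI", "snp"))
  tibble::tibble(class = class, edit_fraction = edit_fraction,
                 strand = strand, position = as.integer(position),
                 mm = list(as.integer(mm)),
                 dna_bulge = list(as.integer(dna_bulge)),
                 rna_bulge = list(as.integer(rna_bulge)),
                 pam = toupper(pam), edit_pos = as.integer(edit_pos))
}

#' Default planted-site panel used by [run_all()]
#'
#' One on-target, six Cas9-dependent sites spanning 0-4 mismatches, DNA and
#' sgRNA bulges and a noncanonical PAM, five TAT-context Cas9-independent
#' sites, two endogenous-dI sites and two heterozygous SNPs.
#'
#' @return Tibble of site specifications.
#' @export
default_site_specs <- function() {
  dplyr::bind_rows(
    site_spec("on_target", edit_fraction = 0.8),
    site_spec("cas9_dependent", mm = integer(0), pam = "TGG"),
    site_spec("cas9_dependent", mm = c(1L), pam = "AGG", strand = "-"),
    site_spec("cas9_dependent", mm = c(1L, 3L), pam = "CGG"),
    site_spec("cas9_dependent", mm = c(2L, 12L, 20L), pam = "GGG",
              strand = "-"),
    site_spec("cas9_dependent", mm = c(1L, 4L), dna_bulge = 14L,
              pam = "AGG"),
    site_spec("cas9_dependent", mm = c(3L), rna_bulge = 16L, pam = "TCA"),
    site_spec("cas9_independent", edit_fraction = 0.4),
    site_spec("cas9_independent", edit_fraction = 0.4, strand = "-"),
    site_spec("cas9_independent", edit_fraction = 0.4),
    site_spec("cas9_independent", edit_fraction = 0.4, strand = "-"),
    site_spec("cas9_independent", edit_fraction = 0.4),
    site_spec("endogenous_dI", edit_fraction = 0.4),
    site_spec("endogenous_dI", edit_fraction = 0.4, strand = "-"),
    site_spec("snp"),
    site_spec("snp")
  )
}

# build the degenerate genomic copy of protospacer+PAM for one spec;
# returns list(seq, edit_offset) where edit_offset is the 1-based index of
# the edited adenosine within seq (protospacer orientation)
build_planted_target <- function(sgrna, spec_row) {
  proto <- chars(sgrna$protospacer)
  mm <- spec_row$mm[[1]]
  rna_b <- sort(spec_row$rna_bulge[[1]])
  dna_b <- sort(spec_row$dna_bulge[[1]])
  edit_pos <- spec_row$edit_pos
  if (proto[edit_pos] != "A") {
    stop("protospacer position ", edit_pos, " is not an adenosine")
  }
  if (edit_pos %in% mm || edit_pos %in% rna_b) {
    stop("edited position cannot be mutated or deleted in the planted site")
  }
  for (k in mm) {
    alt <- setdiff(DNA_BASES, proto[k])
    # deterministic substitution; avoid creating a spurious A run
    proto[k] <- alt[1L + (match(sgrna_base <- proto[k], DNA_BASES) %% 3L)]
  }
  # apply bulges from the right so earlier indices stay valid
  seq <- proto
  for (k in rev(rna_b)) seq <- seq[-k]
  for (k in rev(dna_b)) {
    ins <- sample(DNA_BASES, 1)
    seq <- append(seq, ins, after = k - sum(rna_b < k))
  }
  edit_offset <- edit_pos - sum(rna_b < edit_pos) + sum(dna_b < edit_pos)
  list(seq = paste0(paste(seq, collapse = ""), spec_row$pam),
       edit_offset = edit_offset)
}

#' Plant ground-truth edit sites into a genome
#'
#' Rewrites the genome so each requested site exists: Cas9-dependent sites
#' get a degenerate protospacer+PAM copy (with the requested mismatches and
#' bulges) flanking the edited adenosine; Cas9-independent sites get a TAT
#' trinucleotide context centred on the edited adenosine; endogenous-dI and
#' SNP sites get an adenosine at the edited position. SNP positions are
#' returned as the exclusion list.
#'
#' @param genome A `ref_genome` (single- or multi-contig; sites are planted
#'   on the first contig).
#' @param sgrna An [sgrna_spec()].
#' @param spec_list Tibble of [site_spec()] rows.
#' @param seed Seed controlling placement and degenerate-base choices.
#' @param min_sep Minimum separation between planted loci in bp
#'   (default 300).
#' @return List with `genome` (rewritten), `sites` (truth tibble: `contig`,
#'   `position` 0-based, `strand_of_edit`, `site_class`, `edit_fraction`,
#'   `protospacer_pos`, `locus_start`, `locus_end`, `planted_seq`) and
#'   `exclusion` (tibble of SNP positions).
#' @export
plant_sites <- function(genome, sgrna, spec_list, seed = 1L,
                        min_sep = 300L) {
  set.seed(seed)
  contig <- names(genome)[1]
  gseq <- unclass(genome)[[contig]]
  glen <- nchar(gseq)
  explicit <- spec_list$position[!is.na(spec_list$position)]
  if (anyDuplicated(explicit)) stop("overlapping site specifications")
  occupied <- integer(0)
  margin <- 150L

  place <- function(len, want_pos = NA_integer_) {
    for (try in 1:500) {
      start <- if (!is.na(want_pos)) want_pos else {
        sample.int(glen - len - 2L * margin, 1) + margin
      }
      if (start < margin || start + len + margin > glen) {
        if (!is.na(want_pos)) stop("requested position out of bounds")
        next
      }
      if (!any(abs(occupied - start) < min_sep)) return(start)
      if (!is.na(want_pos)) stop("overlapping site specifications")
    }
    stop("could not place site after bounded retries")
  }

  rows <- vector("list", nrow(spec_list))
  for (r in seq_len(nrow(spec_list))) {
    sp <- spec_list[r, ]
    strand <- sp$strand
    if (is.na(strand)) strand <- sample(c("+", "-"), 1)
    cls <- sp$class
    if (cls %in% c("on_target", "cas9_dependent")) {
      bt <- build_planted_target(sgrna, sp)
      plen <- nchar(bt$seq)
      L <- place(plen, sp$position)
      planted <- if (strand == "+") bt$seq else revcomp(bt$seq)
      substr(gseq, L + 1L, L + plen) <- planted
      pos <- if (strand == "+") L + bt$edit_offset - 1L
             else L + plen - bt$edit_offset
      occupied <- c(occupied, L)
      rows[[r]] <- tibble::tibble(
        contig = contig, position = pos, strand_of_edit = strand,
        site_class = cls, edit_fraction = sp$edit_fraction,
        protospacer_pos = sp$edit_pos, locus_start = L,
        locus_end = L + plen, planted_seq = bt$seq)
    } else {
      L <- place(5L, sp$position)
      pos <- L + 2L
      ctx <- if (cls == "cas9_independent") "TAT" else {
        paste0(substr(gseq, L + 2L, L + 2L), "A", substr(gseq, L + 4L, L + 4L))
      }
      plant <- if (strand == "+") ctx else revcomp(ctx)
      substr(gseq, L + 2L, L + 4L) <- plant
      occupied <- c(occupied, L)
      rows[[r]] <- tibble::tibble(
        contig = contig, position = pos, strand_of_edit = strand,
        site_class = cls, edit_fraction = sp$edit_fraction,
        protospacer_pos = NA_integer_, locus_start = L, locus_end = L + 5L,
        planted_seq = ctx)
    }
  }
  sites <- dplyr::bind_rows(rows)
  # sanity: edited base must be A on its strand
  refb <- substr(rep(gseq, nrow(sites)), sites$position + 1L,
                 sites$position + 1L)
  want <- ifelse(sites$strand_of_edit == "+", "A", "T")
  stopifnot(all(refb == want))
  g2 <- unclass(genome)
  g2[[contig]] <- gseq
  list(genome = ref_genome(g2),
       sites = sites,
       exclusion = dplyr::filter(sites, .data$site_class == "snp") %>%
         dplyr::transmute(contig = .data$contig, pos = .data$position))
}

# inject uniform substitution errors into reference-orientation sequences
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1, total, error_rate)
  if (n_err == 0) return(seqs)
  flat <- sample.int(total, n_err)
  offs <- cumsum(c(0, lens[-length(lens)]))
  ridx <- findInterval(flat, offs + 1)
  within <- flat - offs[ridx]
  for (k in seq_len(n_err)) {
    old <- substr(seqs[ridx[k]], within[k], within[k])
    new <- sample(setdiff(DNA_BASES, old), 1)
    substr(seqs[ridx[k]], within[k], within[k]) <- new
  }
  seqs
}

sample_mapq <- function(n, params) {
  hi <- runif(n) < params$mapq_high_prob
  out <- integer(n)
  out[hi] <- params$mapq_high
  out[!hi] <- sample.int(params$mapq_high + 1L, sum(!hi),
                         replace = TRUE) - 1L
  out
}

# which planted classes emit truncated signal reads into which sample
signal_classes_for <- function(sample) {
  base <- sub("_rep[0-9]+$", "", sample)
  switch(base,
    sgrna_pos = c("on_target", "cas9_dependent", "cas9_independent",
                  "endogenous_dI"),
    sgrna_neg = c("cas9_independent", "endogenous_dI"),
    untreated = "endogenous_dI",
    character(0))
}

#' Simulate aligned reads for one sample
#'
#' Background reads fragment the genome uniformly; every planted site whose
#' class emits signal in this sample adds `Binomial(depth *
#' signal_read_multiplier, edit_fraction)` truncated signal reads whose
#' alignment places the edited base at the second position from the read's
#' 5' end: a plus-strand read starting one base before the site with G over
#' the reference A, or a minus-strand read whose 5' (rightmost reference)
#' end is one base past the site, observed as T-to-C on the plus reference.
#' SNP sites appear in the background of every sample as an ordinary
#' heterozygous allele. Sequences are stored in reference orientation (SAM
#' convention).
#'
#' @param genome A `ref_genome` (after [plant_sites()]).
#' @param sites Truth tibble from [plant_sites()].
#' @param params A [sim_params()].
#' @param sample Sample label (`sgrna_pos_rep1`, `sgrna_pos_rep2`,
#'   `sgrna_neg`, `untreated`).
#' @param seed Seed for this sample's draws.
#' @return Read tibble in the [read_alignments()] layout.
#' @export
simulate_reads <- function(genome, sites, params, sample,
                           seed = params$seed) {
  set.seed(seed)
  contig <- names(genome)[1]
  gseq <- unclass(genome)[[contig]]
  glen <- nchar(gseq)
  L <- params$read_length

  n_bg <- round(params$depth * glen / L)
  start <- sample.int(glen - L + 1L, n_bg, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n_bg, replace = TRUE)
  seqs <- substring(gseq, start + 1L, start + L)
  # heterozygous SNP alleles live in the background of every sample
  snps <- dplyr::filter(sites, .data$site_class == "snp")
  if (nrow(snps) > 0) {
    for (k in seq_len(nrow(snps))) {
      p <- snps$position[k]
      alt <- if (snps$strand_of_edit[k] == "+") "G" else "C"
      cov <- which(start <= p & start + L > p)
      carrier <- cov[runif(length(cov)) < 0.5]
      off <- p - start[carrier] + 1L
      for (z in seq_along(carrier)) {
        substr(seqs[carrier[z]], off[z], off[z]) <- alt
      }
    }
  }
  bg <- tibble::tibble(start = start, strand = strand, seq = seqs,
                       kind = "bg")

  sig_rows <- list()
  emit <- dplyr::filter(sites,
                        .data$site_class %in% signal_classes_for(sample))
  for (k in seq_len(nrow(emit))) {
    st <- emit[k, ]
    n_sig <- rbinom(1, round(params$depth * params$signal_read_multiplier),
                    st$edit_fraction)
    if (n_sig == 0) next
    if (st$strand_of_edit == "+") {
      s0 <- st$position - 1L
      width <- min(L, glen - s0)
      sq <- substring(gseq, s0 + 1L, s0 + width)
      substr(sq, 2L, 2L) <- "G"
      sig_rows[[length(sig_rows) + 1L]] <-
        tibble::tibble(start = rep(s0, n_sig), strand = "+",
                       seq = rep(sq, n_sig), kind = "sig")
    } else {
      endp <- st$position + 1L            # rightmost reference base
      s0 <- max(0L, endp - L + 1L)
      sq <- substring(gseq, s0 + 1L, endp + 1L)
      off <- st$position - s0 + 1L
      substr(sq, off, off) <- "C"
      sig_rows[[length(sig_rows) + 1L]] <-
        tibble::tibble(start = rep(s0, n_sig), strand = "-",
                       seq = rep(sq, n_sig), kind = "sig")
    }
  }
  reads <- dplyr::bind_rows(bg, sig_rows)
  reads$seq <- inject_errors(reads$seq, params$sequencing_error_rate)
  n <- nrow(reads)
  tibble::tibble(
    name = sprintf("%s_%s_%06d", sample, reads$kind, seq_len(n)),
    contig = contig,
    start = reads$start,
    strand = reads$strand,
    mapq = sample_mapq(n, params),
    cigar = paste0(nchar(reads$seq), "M"),
    seq = reads$seq,
    is_r1 = TRUE, is_proper_pair = TRUE, is_primary = TRUE,
    is_duplicate = FALSE,
    sample = sample
  )
}

#' Simulate a complete experiment (all four samples)
#'
#' @inheritParams simulate_reads
#' @param sgrna An [sgrna_spec()].
#' @param spec_list Tibble of [site_spec()] rows
#'   (default [default_site_specs()]).
#' @param seed Master seed; per-sample seeds are derived from it.
#' @return List with `genome`, `sites`, `exclusion`, and `reads` — a named
#'   list of read tibbles for `sgrna_pos_rep1..repN`, `sgrna_neg`,
#'   `untreated`.
#' @export
simulate_run <- function(sgrna, spec_list = default_site_specs(),
                         params = sim_params(), seed = params$seed) {
  base_genome <- make_genome(params, seed = derive_seed(seed, 1L))
  planted <- plant_sites(base_genome, sgrna, spec_list,
                         seed = derive_seed(seed, 2L))
  samples <- c(paste0("sgrna_pos_rep", seq_len(params$n_replicates)),
               "sgrna_neg", "untreated")
  reads <- lapply(seq_along(samples), function(i) {
    simulate_reads(planted$genome, planted$sites, params, samples[i],
                   seed = derive_seed(seed, 10L + i))
  })
  names(reads) <- samples
  list(genome = planted$genome, sites = planted$sites,
       exclusion = planted$exclusion, reads = reads)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
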