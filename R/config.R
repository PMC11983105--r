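#' Pipeline configuration
#'
#' All thresholds of the candidate filter cascade, the off-target classifier,
#' the binding-site aligner and the amplicon quantifier. Defaults are the
#' published values of the protocol, so an empty configuration file reproduces
#' the reference pipeline.
#'
#' @param min_mapq Minimum mapping quality for a read to enter the pileup
#'   (filter i; default 5).
#' @param min_depth Minimum strand depth per sgRNA(+) replicate at a
#'   candidate site (filter ii; default 5).
#' @param min_mut_reads Minimum truncated-mutant read count per replicate
#'   (filter iii; default 3).
#' @param min_mut_prop Minimum truncated-mutant proportion of strand depth per
#'   replicate (filter iii; default 0.20).
#' @param max_background_reads Maximum mutant reads allowed in the untreated
#'   background sample (filter iv; default 1).
#' @param min_score Minimum Selict score for a Cas9-dependent call
#'   (default 0.6).
#' @param min_edited_ratio Minimum edited ratio (all mutant reads / depth,
#'   pooled replicates) for a Cas9-dependent call (default 0.2).
#' @param max_neg_reads Maximum sgRNA(-) mutant reads for a Cas9-dependent
#'   call (default 1).
#' @param indep_min_neg_reads Minimum sgRNA(-) mutant reads for a
#'   Cas9-independent call (default 3).
#' @param window_flank Half-width in bp of the genomic window searched for an
#'   sgRNA binding site around a candidate (default 100).
#' @param match,mismatch,gap_open,gap_extend Alignment scores for the
#'   semiglobal protospacer search (defaults +5, -4, -24, -8). `gap_open` is
#'   the cost of the first gapped position, `gap_extend` of each additional
#'   one, so a length-L gap costs `-(24 + 8*(L-1))` under the defaults.
#' @param max_penalty Binding sites with alignment penalty (5 x target length
#'   minus score) at or above this are rejected (default 70).
#' @param oop_flank Distance in bp beyond the aligned binding span within
#'   which an edit still counts as belonging to that binding site
#'   (out-of-protospacer annotation span; default 20).
#' @param consec_window,consec_rate Parameters of the alignment-artifact
#'   exclusion (filter vi): a site is excluded when it lies in a run of
#'   `consec_window` consecutive positions whose mutation rate all exceed
#'   `consec_rate` with at least two distinct substitution types among them
#'   (defaults 3 and 0.20).
#' @param amplicon_min_cov Minimum consensus-molecule coverage required in
#'   both test and control for an amplicon position to be qualified
#'   (default 500).
#' @param umi_len Length of each of the forward and reverse UMIs (default 5).
#' @param seed Default random seed used where a function draws random numbers
#'   and no seed is given.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_mapq = 5L,
                            min_depth = 5L,
                            min_mut_reads = 3L,
                            min_mut_prop = 0.20,
                            max_background_reads = 1L,
                            min_score = 0.6,
                            min_edited_ratio = 0.2,
                            max_neg_reads = 1L,
                            indep_min_neg_reads = 3L,
                            window_flank = 100L,
                            match = 5,
                            mismatch = -4,
                            gap_open = -24,
                            gap_extend = -8,
                            max_penalty = 70,
                            oop_flank = 20L,
                            consec_window = 3L,
                            consec_rate = 0.20,
                            amplicon_min_cov = 500L,
                            umi_len = 5L,
                            seed = 1L) {
  cfg <- list(
    min_mapq = as.integer(min_mapq), min_depth = as.integer(min_depth),
    min_mut_reads = as.integer(min_mut_reads), min_mut_prop = min_mut_prop,
    max_background_reads = as.integer(max_background_reads),
    min_score = min_score, min_edited_ratio = min_edited_ratio,
    max_neg_reads = as.integer(max_neg_reads),
    indep_min_neg_reads = as.integer(indep_min_neg_reads),
    window_flank = as.integer(window_flank),
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    max_penalty = max_penalty, oop_flank = as.integer(oop_flank),
    consec_window = as.integer(consec_window), consec_rate = consec_rate,
    amplicon_min_cov = as.integer(amplicon_min_cov),
    umi_len = as.integer(umi_len), seed = as.integer(seed)
  )
  stopifnot(
    cfg$min_mapq >= 0, cfg$min_depth >= 0, cfg$min_mut_reads >= 0,
    cfg$min_mut_prop >= 0, cfg$min_mut_prop <= 1,
    cfg$min_score >= 0, cfg$min_score <= 1,
    cfg$min_edited_ratio >= 0, cfg$min_edited_ratio <= 1,
    cfg$match > 0, cfg$mismatch < 0, cfg$gap_open <= cfg$gap_extend,
    cfg$gap_extend < 0, cfg$max_penalty >= 0, cfg$window_flank > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Flat `key: value` text (YAML subset). Keys absent from the file keep their
#' default, so an empty file yields the reference configuration.
#'
#' @param path File path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- if (file.exists(path) && file.size(path) > 0) {
    yaml::read_yaml(path)
  } else {
    list()
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
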