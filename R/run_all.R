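#' Run the full synthetic pipeline end to end
#'
#' Simulates a complete experiment (genome, planted truth, aligned reads
#' for both sgRNA(+) replicates, the sgRNA(-) control and the untreated
#' control), calls candidate dA-to-dI sites through the filter cascade,
#' classifies them, extracts binding-site features (with ridge fits when
#' the outcomes vary), derives the Cas9-independent context motif, and
#' scores recall/precision against the planted truth. All stage outputs
#' are written under `out_dir` with stage-prefixed filenames; the manifest
#' is written last.
#'
#' @param out_dir Output directory (created if missing).
#' @param sgrna An [sgrna_spec()] (default: an A-rich 20-mer with NRG PAM).
#' @param spec_list Planted-site panel (default [default_site_specs()]).
#' @param params A [sim_params()].
#' @param config A [pipeline_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param write_sam_files Also write per-sample SAM files (default TRUE;
#'   candidate calling itself runs on the in-memory reads).
#' @return Invisibly, a list with `candidates`, `calls`, `features`,
#'   `ridge` (possibly NULL), `pfm` (possibly NULL), `truth`, `metrics`
#'   and `manifest`.
#' @export
run_all <- function(out_dir,
                    sgrna = sgrna_spec("GAACACAAAGCATAGACTGC"),
                    spec_list = default_site_specs(),
                    params = sim_params(),
                    config = pipeline_config(),
                    seed = config$seed,
                    write_sam_files = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, paste0(...))

  abescan_log("simulating reads (genome ", params$genome_length, " bp)")
  sim <- simulate_run(sgrna, spec_list, params, seed = seed)
  write_genome(sim$genome, pth("sim_genome.fa"))
  readr::write_tsv(sim$sites, pth("sim_truth.tsv"))
  write_exclusion_bed(sim$exclusion, pth("sim_exclusion.bed"))
  if (write_sam_files) {
    for (s in names(sim$reads)) {
      write_sam(sim$reads[[s]], sim$genome, pth("sim_", s, ".sam"))
    }
  }

  abescan_log("calling candidate sites")
  cand <- call_candidates(sim$reads, sim$genome, sim$exclusion, config)
  write_report_tsv(cand, pth("call_candidates.tsv"))
  write_sites_bed(dplyr::filter(cand, .data$pass), pth("call_sites.bed"))

  abescan_log("classifying ", nrow(cand), " candidate site(s)")
  calls <- classify_sites(cand, sgrna, sim$genome, config)
  write_report_tsv(calls, pth("classify_calls.tsv"))
  write_sites_bed(calls, pth("classify_calls.bed"))

  feats <- NULL
  fits <- list()
  if (any(calls$binding_found)) {
    feats <- extract_features(calls)
    readr::write_tsv(feats, pth("features_matrix.tsv"))
    xmat <- as.matrix(feats[, c("first5_mismatch", "first8_mismatch",
                                "first5_gap", "first8_gap",
                                "align_mismatch", "align_gap",
                                "seed_mismatch", "seed_gap", "pam_type")])
    for (out_col in c("outcome_out_of_protospacer",
                      "outcome_target_strand")) {
      yv <- feats[[out_col]]
      if (nrow(feats) > 2L * ncol(xmat) && dplyr::n_distinct(yv) > 1L) {
        fit <- suppressWarnings(ridge_fit(xmat, yv))
        fits[[out_col]] <- fit
        readr::write_tsv(tidy(fit),
                         pth("features_ridge_", sub("outcome_", "", out_col),
                             ".tsv"))
      }
    }
  }

  pfm <- NULL
  indep <- dplyr::filter(calls, .data$classification == "cas9_independent")
  if (nrow(indep) > 0) {
    pfm <- motif_pfm(indep, sim$genome)
    write_pfm_tsv(pfm, pth("classify_motif_pfm.tsv"))
  }

  metrics <- score_against_truth(calls, sim$sites)
  readr::write_tsv(metrics, pth("report_metrics.tsv"))

  manifest <- list(
    seed = seed,
    config = unclass(config),
    params = unclass(params),
    n_reads = purrr::map_int(sim$reads, nrow),
    n_candidates = nrow(cand),
    n_pass = sum(cand$pass),
    n_classified = table(calls$classification),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(list(candidates = cand, calls = calls, features = feats,
                 ridge = fits, pfm = pfm, truth = sim$sites,
                 metrics = metrics, manifest = manifest, sim = sim))
}

#' Score classified calls against planted truth
#'
#' @param calls Output of [classify_sites()].
#' @param truth Planted-site tibble from [plant_sites()]/[simulate_run()].
#' @return Tibble with one row per planted class (recall) plus dependent-
#'   and independent-call precision.
#' @export
score_against_truth <- function(calls, truth) {
  key <- function(ct, p) paste(ct, p)
  dep_truth <- dplyr::filter(truth, .data$site_class %in%
                               c("on_target", "cas9_dependent"))
  ind_truth <- dplyr::filter(truth, .data$site_class == "cas9_independent")
  dep_calls <- dplyr::filter(calls, .data$classification == "cas9_dependent")
  ind_calls <- dplyr::filter(calls,
                             .data$classification == "cas9_independent")
  dep_hit <- key(dep_truth$contig, dep_truth$position) %in%
    key(dep_calls$contig, dep_calls$pos)
  ind_hit <- key(ind_truth$contig, ind_truth$position) %in%
    key(ind_calls$contig, ind_calls$pos)
  dep_tp <- key(dep_calls$contig, dep_calls$pos) %in%
    key(dep_truth$contig, dep_truth$position)
  ind_tp <- key(ind_calls$contig, ind_calls$pos) %in%
    key(ind_truth$contig, ind_truth$position)
  tibble::tibble(
    metric = c("recall_cas9_dependent", "recall_cas9_independent",
               "precision_cas9_dependent", "precision_cas9_independent"),
    numerator = c(sum(dep_hit), sum(ind_hit), sum(dep_tp), sum(ind_tp)),
    denominator = c(nrow(dep_truth), nrow(ind_truth),
                    nrow(dep_calls), nrow(ind_calls)),
    value = c(
      ifelse(nrow(dep_truth) > 0, mean(dep_hit), NA_real_),
      ifelse(nrow(ind_truth) > 0, mean(ind_hit), NA_real_),
      ifelse(nrow(dep_calls) > 0, mean(dep_tp), NA_real_),
      ifelse(nrow(ind_calls) > 0, mean(ind_tp), NA_real_))
  )
}
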