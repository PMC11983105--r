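#' Position frequency matrix of the sequence context around edited sites
#'
#' Extracts the `2*flank + 1`-mer centred on each edited adenosine
#' (reverse-complemented for minus-strand edits so the edited base is
#' always A, fixed at the centre — position 3 for the default 2-bp flank),
#' tallies a 4 x width base-count matrix and computes per-column
#' information content in bits. Intended for Cas9-independent calls, whose
#' deaminase-only mechanism shows a TAT context preference.
#'
#' @param calls Tibble with `contig`, `pos`, `strand` (strand of the edited
#'   adenosine).
#' @param genome A `ref_genome`.
#' @param flank Bases on each side of the edited A (default 2).
#' @return List of class `"motif_pfm"`: `counts` (4 x width), `freq`,
#'   `info` (bits per column), `n` (sites used), `flank`.
#' @export
motif_pfm <- function(calls, genome, flank = 2L) {
  if (nrow(calls) == 0) stop("no calls supplied to motif_pfm()")
  width <- 2L * flank + 1L
  kmers <- character(0)
  for (k in seq_len(nrow(calls))) {
    ct <- calls$contig[k]; p <- calls$pos[k]
    s <- genome_substr(genome, ct, p - flank, p + flank + 1L)
    if (nchar(s) < width) {
      warning("site ", ct, ":", p, " too close to contig end; skipped")
      next
    }
    if (calls$strand[k] == "-") s <- revcomp(s)
    kmers <- c(kmers, s)
  }
  if (length(kmers) == 0) stop("no usable sites for motif_pfm()")
  mat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  counts <- sapply(seq_len(width), function(j) {
    table(factor(mat[, j], levels = DNA_BASES))
  })
  rownames(counts) <- DNA_BASES
  colnames(counts) <- as.character(seq_len(width))
  freq <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  info <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(counts = counts, freq = freq, info = info,
                 n = length(kmers), flank = flank),
            class = "motif_pfm")
}

#' @export
print.motif_pfm <- function(x, ...) {
  cat("<motif_pfm>", x$n, "sites, width", ncol(x$counts), "\n")
  print(round(x$freq, 3))
  cat("information (bits):", paste(round(x$info, 2), collapse = " "), "\n")
  invisible(x)
}

#' Write a position frequency matrix as TSV
#' @param pfm A `motif_pfm`.
#' @param path Output path.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- as.data.frame(pfm$counts)
  df <- cbind(base = rownames(df), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' @rdname motif_pfm
#' @param object A `motif_pfm`.
#' @param ... Ignored.
#' @method autoplot motif_pfm
#' @export
autoplot.motif_pfm <- function(object, ...) {
  width <- ncol(object$freq)
  df <- tidyr::expand_grid(base = DNA_BASES,
                           position = seq_len(width)) %>%
    dplyr::mutate(freq = purrr::map2_dbl(.data$base, .data$position,
                                         ~ object$freq[.x, .y]))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position - object$flank - 1),
                                   y = .data$freq, fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position relative to edited A", y = "base frequency",
                  fill = NULL,
                  title = sprintf("Edited-site context (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}
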