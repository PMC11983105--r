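# Semiglobal ("fitting") alignment of a short target (protospacer + PAM
# pattern) against a genomic window: the target is consumed in full, gaps at
# the window's ends are free, internal gaps use affine costs (gap_open for
# the first gapped position, gap_extend for each additional one). IUPAC
# codes in the target (PAM pattern) score as a match for any compatible
# window base.

NEG_INF <- -1e9

#' Semiglobal affine-gap alignment of an sgRNA target against a window
#'
#' Dynamic programming over three states (substitution, gap-in-window,
#' gap-in-target) with affine gap costs; the full target must be aligned
#' while any number of window bases may be skipped for free at either end.
#' Among equal-score alignments the tie-break is deterministic: leftmost
#' window start, then fewest gap columns, then fewest mismatches.
#'
#' @param target DNA string (IUPAC allowed; e.g. protospacer + PAM pattern).
#' @param window Plain DNA window (A/C/G/T/N).
#' @param config A [pipeline_config()] supplying `match`, `mismatch`,
#'   `gap_open`, `gap_extend`.
#' @return List with `score`, `penalty` (`match * nchar(target) - score`),
#'   `aligned_target`, `aligned_window` (equal-length gapped strings),
#'   `window_start`, `window_end` (0-based half-open aligned span within
#'   `window`), `n_mismatch`, `n_gap`, and per-column detail
#'   `columns` (tibble: `state`, `target_index`, `window_index`,
#'   `target_char`, `window_char`, `mismatch`).
#' @export
semiglobal_align <- function(target, window, config = pipeline_config()) {
  target <- toupper(target)
  window <- toupper(window)
  n <- nchar(target)
  m <- nchar(window)
  if (n < 1L || m < 1L) stop("empty sequence in alignment")
  if (n > m) stop("target longer than window")
  tc <- chars(target)
  wc <- chars(window)
  if (!all(tc %in% rownames(COMPAT_MAT))) stop("invalid target character")
  if (!all(wc %in% rownames(COMPAT_MAT))) stop("invalid window character")
  compat <- COMPAT_MAT[tc, , drop = FALSE][, wc, drop = FALSE]

  ma <- config$match; mi <- config$mismatch
  go <- config$gap_open; ge <- config$gap_extend

  # state matrices: score S, tie keys (start column, gap columns,
  # mismatches), predecessor state P (1=M, 2=X, 3=Y) for traceback
  dimr <- n + 1L; dimc <- m + 1L
  newm <- function(fill) matrix(fill, dimr, dimc)
  SM <- newm(NEG_INF); SX <- newm(NEG_INF); SY <- newm(NEG_INF)
  TM <- newm(0L); TX <- newm(0L); TY <- newm(0L)          # start column
  GM <- newm(0L); GX <- newm(0L); GY <- newm(0L)          # gap columns
  MM <- newm(0L); MX <- newm(0L); MY <- newm(0L)          # mismatches
  PM <- newm(0L); PX <- newm(0L); PY <- newm(0L)

  SM[1L, ] <- 0
  TM[1L, ] <- 0:m  # free leading skip: alignment starts after this column
  # left edge: target bases before the window (never optimal, kept for
  # completeness)
  for (i in seq_len(n)) {
    SX[i + 1L, 1L] <- go + (i - 1L) * ge
    TX[i + 1L, 1L] <- 0L
    GX[i + 1L, 1L] <- i
    PX[i + 1L, 1L] <- if (i == 1L) 1L else 2L
  }

  pick <- function(s, st, g, mm) {
    best <- 1L
    for (k in 2:3) {
      if (s[k] > s[best] ||
          (s[k] == s[best] && (st[k] < st[best] ||
            (st[k] == st[best] && (g[k] < g[best] ||
              (g[k] == g[best] && mm[k] < mm[best])))))) {
        best <- k
      }
    }
    best
  }

  for (i in seq_len(n)) {
    ii <- i + 1L
    cmp_i <- compat[i, ]
    for (j in seq_len(m)) {
      jj <- j + 1L
      # M: target i aligned to window j
      s <- c(SM[ii - 1L, jj - 1L], SX[ii - 1L, jj - 1L], SY[ii - 1L, jj - 1L])
      st <- c(TM[ii - 1L, jj - 1L], TX[ii - 1L, jj - 1L], TY[ii - 1L, jj - 1L])
      g <- c(GM[ii - 1L, jj - 1L], GX[ii - 1L, jj - 1L], GY[ii - 1L, jj - 1L])
      mm <- c(MM[ii - 1L, jj - 1L], MX[ii - 1L, jj - 1L], MY[ii - 1L, jj - 1L])
      k <- pick(s, st, g, mm)
      sub <- if (cmp_i[j]) ma else mi
      SM[ii, jj] <- s[k] + sub
      TM[ii, jj] <- st[k]; GM[ii, jj] <- g[k]
      MM[ii, jj] <- mm[k] + (!cmp_i[j])
      PM[ii, jj] <- k
      # X: target i aligned to a gap (sgRNA/target bulge)
      s <- c(SM[ii - 1L, jj] + go, SX[ii - 1L, jj] + ge, SY[ii - 1L, jj] + go)
      st <- c(TM[ii - 1L, jj], TX[ii - 1L, jj], TY[ii - 1L, jj])
      g <- c(GM[ii - 1L, jj], GX[ii - 1L, jj], GY[ii - 1L, jj])
      mm <- c(MM[ii - 1L, jj], MX[ii - 1L, jj], MY[ii - 1L, jj])
      k <- pick(s, st, g, mm)
      SX[ii, jj] <- s[k]
      TX[ii, jj] <- st[k]; GX[ii, jj] <- g[k] + 1L; MX[ii, jj] <- mm[k]
      PX[ii, jj] <- k
      # Y: window j aligned to a gap (DNA bulge), only after target started
      s <- c(SM[ii, jj - 1L] + go, SX[ii, jj - 1L] + go, SY[ii, jj - 1L] + ge)
      st <- c(TM[ii, jj - 1L], TX[ii, jj - 1L], TY[ii, jj - 1L])
      g <- c(GM[ii, jj - 1L], GX[ii, jj - 1L], GY[ii, jj - 1L])
      mm <- c(MM[ii, jj - 1L], MX[ii, jj - 1L], MY[ii, jj - 1L])
      k <- pick(c(s[1L], s[2L], s[3L]), st, g, mm)
      # note preference order here is M, X, Y mapped to pred codes 1,2,3
      SY[ii, jj] <- s[k]
      TY[ii, jj] <- st[k]; GY[ii, jj] <- g[k] + 1L; MY[ii, jj] <- mm[k]
      PY[ii, jj] <- k
    }
  }

  # best end: any window column, state M or X (trailing window skip free)
  best <- NULL
  for (j in 0:m) {
    jj <- j + 1L
    for (state in 1:2) {
      s <- if (state == 1L) SM[n + 1L, jj] else SX[n + 1L, jj]
      if (s <= NEG_INF / 2) next
      key <- list(
        score = s,
        start = if (state == 1L) TM[n + 1L, jj] else TX[n + 1L, jj],
        gaps = if (state == 1L) GM[n + 1L, jj] else GX[n + 1L, jj],
        mism = if (state == 1L) MM[n + 1L, jj] else MX[n + 1L, jj],
        state = state, j = j
      )
      if (is.null(best) ||
          key$score > best$score ||
          (key$score == best$score && (key$start < best$start ||
            (key$start == best$start && (key$gaps < best$gaps ||
              (key$gaps == best$gaps && key$mism < best$mism)))))) {
        best <- key
      }
    }
  }

  # traceback
  cols <- list()
  i <- n; j <- best$j; state <- best$state
  while (i > 0L || (state == 3L)) {
    ii <- i + 1L; jj <- j + 1L
    if (state == 1L) {
      cols[[length(cols) + 1L]] <- list(state = "M", ti = i, wi = j,
                                        tch = tc[i], wch = wc[j],
                                        mis = !compat[i, j])
      p <- PM[ii, jj]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      cols[[length(cols) + 1L]] <- list(state = "X", ti = i, wi = NA_integer_,
                                        tch = tc[i], wch = "-", mis = FALSE)
      p <- PX[ii, jj]; i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- list(state = "Y", ti = NA_integer_, wi = j,
                                        tch = "-", wch = wc[j], mis = FALSE)
      p <- PY[ii, jj]; j <- j - 1L
    }
    if (i == 0L && p == 1L) break  # reached the free-start pseudo row
    state <- p
  }
  cols <- rev(cols)
  columns <- tibble::tibble(
    state = purrr::map_chr(cols, "state"),
    target_index = purrr::map_int(cols, ~ as.integer(.x$ti)),
    window_index = purrr::map_int(cols, ~ as.integer(.x$wi)),
    target_char = purrr::map_chr(cols, "tch"),
    window_char = purrr::map_chr(cols, "wch"),
    mismatch = purrr::map_lgl(cols, "mis")
  )

  list(
    score = best$score,
    penalty = ma * n - best$score,
    aligned_target = paste(columns$target_char, collapse = ""),
    aligned_window = paste(columns$window_char, collapse = ""),
    window_start = as.integer(best$start),
    window_end = as.integer(best$j),
    n_mismatch = as.integer(best$mism),
    n_gap = as.integer(best$gaps),
    columns = columns
  )
}
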