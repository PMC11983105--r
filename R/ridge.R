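#' Ridge linear regression with analytic coefficient significance
#'
#' Linear-probability ridge fit of a binary (or numeric) outcome on
#' standardized features: `beta = (X'X + lambda I)^-1 X'y` with columns of
#' `X` centred and scaled to unit variance and `y` centred (the intercept
#' is the outcome mean). Coefficient variances use the sandwich form
#' `Var(beta) = sigma^2 (X'X+lI)^-1 X'X (X'X+lI)^-1`, with `sigma^2`
#' estimated from the residuals on `n - tr(H)` effective degrees of
#' freedom (`H` the ridge hat matrix); two-sided p-values come from a
#' Student t on those degrees of freedom, or optionally from a permutation
#' null. `lambda` is chosen by generalized cross-validation unless fixed.
#'
#' @param x Numeric matrix or data frame of features (n x p).
#' @param y Numeric outcome (binary outcomes are treated as 0/1 numeric).
#' @param lambda `"gcv"` (default) to choose by generalized
#'   cross-validation over `lambda_grid`, or a fixed non-negative number.
#' @param lambda_grid Candidate penalties for GCV.
#' @param p_method `"t"` (analytic, default) or `"permutation"`.
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return Object of class `"ridge_fit"`: `lambda`, `coefficients` (on the
#'   standardized scale), `std_error`, `statistic`, `p_value`, `edf_model`
#'   (trace of the hat matrix), `df_residual` (`n - tr(H)`), `sigma2`,
#'   `intercept`, `r_squared`, `n`, `terms`, `gcv` (the GCV path when
#'   used), `dropped` (constant columns removed).
#' @export
ridge_fit <- function(x, y, lambda = "gcv",
                      lambda_grid = 10^seq(-3, 5, length.out = 121),
                      p_method = c("t", "permutation"),
                      n_perm = 999L, seed = 1L) {
  p_method <- match.arg(p_method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  p <- ncol(x)
  if (p == 0) stop("no non-constant features")
  if (n <= p) stop("need more observations than features")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  xs <- scale(x, center = ctr, scale = scl)
  ybar <- mean(y)
  yc <- y - ybar

  sv <- svd(xs)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)

  fit_for <- function(lam) {
    shrink <- sv$d / (d2 + lam)
    beta <- sv$v %*% (shrink * uty)
    fitted <- sv$u %*% ((d2 / (d2 + lam)) * uty)
    trH <- sum(d2 / (d2 + lam))
    rss <- sum((yc - fitted)^2)
    list(beta = drop(beta), rss = rss, trH = trH, fitted = drop(fitted))
  }

  gcv_path <- NULL
  if (identical(lambda, "gcv")) {
    gcv_path <- vapply(lambda_grid, function(lam) {
      f <- fit_for(lam)
      n * f$rss / (n - f$trH)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv_path)]
  } else {
    lambda <- as.numeric(lambda)
    if (lambda < 0) stop("lambda must be non-negative")
  }
  f <- fit_for(lambda)
  df_resid <- n - f$trH
  sigma2 <- f$rss / df_resid
  # Var(beta) = sigma2 * V diag(d^2/(d^2+l)^2) V'
  vb <- sv$v %*% (t(sv$v) * (d2 / (d2 + lambda)^2))
  se <- sqrt(sigma2 * diag(vb))
  tstat <- f$beta / se
  if (p_method == "t") {
    pval <- 2 * pt(-abs(tstat), df = df_resid)
  } else {
    set.seed(seed)
    exceed <- rep(1L, p)
    for (b in seq_len(n_perm)) {
      yp <- sample(yc)
      shrink <- sv$d / (d2 + lambda)
      utyp <- crossprod(sv$u, yp)
      bp <- drop(sv$v %*% (shrink * utyp))
      fitp <- drop(sv$u %*% ((d2 / (d2 + lambda)) * utyp))
      s2p <- sum((yp - fitp)^2) / df_resid
      tp <- bp / sqrt(s2p * diag(vb))
      exceed <- exceed + (abs(tp) >= abs(tstat))
    }
    pval <- exceed / (n_perm + 1)
  }
  terms <- colnames(x) %||% paste0("x", seq_len(p))
  structure(list(
    lambda = lambda, coefficients = setNames(f$beta, terms),
    std_error = setNames(se, terms), statistic = setNames(tstat, terms),
    p_value = setNames(pval, terms),
    edf_model = f$trH, df_residual = df_resid, sigma2 = sigma2,
    intercept = ybar,
    r_squared = 1 - f$rss / sum(yc^2),
    n = n, terms = terms, gcv = gcv_path, dropped = dropped,
    p_method = p_method,
    center = ctr, scale = scl), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> n = %d, lambda = %.4g, edf = %.2f\n",
              x$n, x$lambda, x$edf_model))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a ridge fit
#'
#' @param x A `ridge_fit`.
#' @param ... Ignored.
#' @return Tibble with `term`, `estimate` (standardized scale),
#'   `std.error`, `statistic`, `p.value` and `significant`
#'   (p below 0.01, the conventional reporting threshold for this
#'   analysis).
#' @method tidy ridge_fit
#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble::tibble(term = x$terms,
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_error),
                 statistic = unname(x$statistic),
                 p.value = unname(x$p_value),
                 significant = unname(x$p_value) < 0.01)
}

#' @rdname tidy.ridge_fit
#' @method glance ridge_fit
#' @export
glance.ridge_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, edf = x$edf_model,
                 df.residual = x$df_residual,
                 sigma = sqrt(x$sigma2), r.squared = x$r_squared,
                 nobs = x$n)
}

#' @rdname tidy.ridge_fit
#' @param object A `ridge_fit`.
#' @method autoplot ridge_fit
#' @export
autoplot.ridge_fit <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std.error,
      xmax = .data$estimate + 2 * .data$std.error)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D62839",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "standardized ridge coefficient", y = NULL,
                  colour = "p < .01",
                  title = sprintf("Ridge fit (lambda = %.3g, n = %d)",
                                  object$lambda, object$n)) +
    ggplot2::theme_minimal()
}
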