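#' Wilcoxon signed-rank test with exact tie-aware enumeration
#'
#' Paired two-sided signed-rank test. Missing and zero differences are
#' dropped (Wilcoxon convention); absolute differences are midranked. For n <= 25
#' the null distribution of the rank sum is enumerated exactly by dynamic
#' programming over the 2^n sign assignments (doubled midranks keep the
#' convolution on integers, so ties are handled exactly); above that, the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is
#'   enumerated.
#' @return List with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided), `n` (non-zero pairs) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25) {
  d <- differences[!is.na(differences) & differences != 0]
  n <- length(d)
  if (n == 0)
    stop(structure(class = c("afcn_degenerate_test", "error", "condition"),
                   list(message = "all paired differences are zero",
                        call = sys.call())))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    d2 <- as.integer(round(2 * r))            # doubled midranks are integers
    S <- sum(d2)
    f <- numeric(S + 1)                       # counts over rank sums 0..S
    f[1] <- 1
    for (v in d2) {
      g <- f
      g[(v + 1):(S + 1)] <- g[(v + 1):(S + 1)] + f[1:(S + 1 - v)]
      f <- g
    }
    w2 <- as.integer(round(2 * W))
    total <- 2^n
    p_le <- sum(f[1:(w2 + 1)]) / total
    p_ge <- sum(f[(w2 + 1):(S + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    E <- n * (n + 1) / 4
    ties <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

safe_signed_rank_p <- function(d) {
  tryCatch(wilcoxon_signed_rank(d)$p_value,
           afcn_degenerate_test = function(e) NA_real_)
}

#' Mean and 95\% confidence band of a group of metric curves
#'
#' @param curves `data.frame` with columns `subject`, `density`, `value`
#'   (one metric, one condition).
#' @return `data.frame` with `density`, `n`, `mean`, `lo`, `hi` (t-based
#'   95\% CI; `NA` bounds when only one subject is available).
#' @export
summarize_group <- function(curves) {
  stopifnot(all(c("subject", "density", "value") %in% names(curves)))
  out <- do.call(rbind, lapply(split(curves, curves$density), function(g) {
    n <- nrow(g)
    m <- mean(g$value)
    half <- if (n >= 2) qt(0.975, n - 1) * sd(g$value) / sqrt(n) else NA_real_
    data.frame(density = g$density[1], n = n, mean = m,
               lo = m - half, hi = m + half)
  }))
  out[order(out$density), , drop = FALSE]
}

#' Compare density-resolved metric curves between two conditions
#'
#' Wilcoxon signed-rank comparison of one network parameter between paired
#' conditions (e.g. baseline vs post-ablation). A test is run at each
#' density point, and a pooled test on the per-subject density-averaged
#' metric provides the headline p-value. Self-comparisons and other
#' all-zero-difference cases yield `NA` p-values (degenerate test).
#'
#' @param a,b `data.frame`s with columns `subject`, `density`, `value`; in
#'   paired mode subjects are matched by `subject` across conditions.
#' @param paired logical; unpaired comparisons use the rank-sum test.
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` (default, matching the convention of reporting
#'   raw p-values) or `"BH"` for Benjamini-Hochberg over the density grid.
#' @return Object of class `paired_comparison`: list with `per_density`
#'   (`data.frame` of `density`, `p`, `p_adj`), `pooled_p`, `n_pairs`,
#'   `significant` (pooled p below `alpha`), `summary_a`, `summary_b`.
#' @export
compare_conditions <- function(a, b, paired = TRUE, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  dens <- sort(unique(a$density))
  if (!setequal(dens, unique(b$density)))
    stop_invalid("conditions use different density grids")
  if (paired) {
    subj <- intersect(unique(a$subject), unique(b$subject))
    if (length(subj) == 0)
      stop(structure(class = c("afcn_pairing_error", "error", "condition"),
                     list(message = "no overlapping subjects in paired mode",
                          call = sys.call())))
    wide <- function(df) {
      df <- df[df$subject %in% subj, ]
      tapply(df$value, list(df$subject, df$density), mean)[as.character(subj),
                                                           as.character(dens),
                                                           drop = FALSE]
    }
    A <- wide(a); B <- wide(b)
    per_p <- vapply(seq_along(dens),
                    function(j) safe_signed_rank_p(A[, j] - B[, j]), 0)
    pooled <- safe_signed_rank_p(rowMeans(A, na.rm = TRUE) -
                                   rowMeans(B, na.rm = TRUE))
    n_pairs <- length(subj)
  } else {
    per_p <- vapply(dens, function(d)
      stats::wilcox.test(a$value[a$density == d],
                         b$value[b$density == d])$p.value, 0)
    pa <- tapply(a$value, a$subject, mean)
    pb <- tapply(b$value, b$subject, mean)
    pooled <- stats::wilcox.test(pa, pb)$p.value
    n_pairs <- min(length(pa), length(pb))
  }
  p_adj <- if (adjust == "BH") stats::p.adjust(per_p, "BH") else per_p
  structure(list(per_density = data.frame(density = dens, p = per_p,
                                          p_adj = p_adj),
                 pooled_p = pooled, n_pairs = n_pairs,
                 significant = !is.na(pooled) && pooled < alpha,
                 alpha = alpha,
                 summary_a = summarize_group(a), summary_b = summarize_group(b)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison over %d density points, %d pairs\n",
              nrow(x$per_density), x$n_pairs))
  cat(sprintf("  pooled p = %s%s\n",
              format.pval(x$pooled_p, digits = 3),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
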