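#' KSG estimator parameters
#'
#' @param k neighbour order of the Kraskov-Stoegbauer-Grassberger estimator
#'   (default 4, following Kraskov's bias/variance analysis).
#' @param tie_noise_scale relative amplitude of the seeded tie-breaking
#'   jitter added before the neighbour search (times the series SD). The
#'   estimator assumes continuous marginals; exact ties otherwise corrupt
#'   the neighbour counts.
#' @param seed integer seed for the jitter; fixed seed gives bit-identical
#'   estimates.
#' @return Object of class `ksg_params`.
#' @export
ksg_params <- function(k = 4, tie_noise_scale = 1e-10, seed = 1) {
  if (k < 1 || k != round(k)) stop_invalid("k must be a positive integer")
  structure(list(k = as.integer(k), tie_noise_scale = tie_noise_scale,
                 seed = as.integer(seed)),
            class = "ksg_params")
}

#' Digamma function on the positive integers
#'
#' `psi(n) = -gamma + sum_{j=1}^{n-1} 1/j`, the harmonic-series form of the
#' digamma function, where `gamma` is the Euler-Mascheroni constant. The KSG
#' estimator only ever evaluates the digamma at integer neighbour counts, so
#' this closed form is all that is needed.
#'
#' @param n positive integer (vectorized).
#' @return `psi(n)` as a double.
#' @examples
#' digamma_int(1)  # -0.5772157 = -gamma
#' @export
digamma_int <- function(n) {
  if (any(n < 1) || any(n != round(n)))
    stop_invalid("n must be a positive integer")
  h <- c(0, cumsum(1 / seq_len(max(n))))   # h[m+1] = sum_{j<=m} 1/j
  -EULER_GAMMA + h[n]
}

jitter_series <- function(x, rel) {
  s <- sd(x)
  x + rnorm(length(x), 0, if (s > 0) rel * s else rel)
}

#' Pairwise mutual information by k-nearest-neighbor statistics
#'
#' Estimates `I(X; Y)` in nats with the second Kraskov-Stoegbauer-Grassberger
#' algorithm: in the joint space `Z = (X, Y)` the k-th nearest neighbour of
#' each sample is located under the max norm; `eps_x(i)` and `eps_y(i)` are
#' the marginal projections of that neighbourhood; `n_x(i)` and `n_y(i)`
#' count the samples within and on the boundary of each marginal
#' neighbourhood (`|x_i - x_j| <= eps_x(i)/2`); and
#' `I = psi(k) - 1/k - mean(psi(n_x) + psi(n_y)) + psi(N)`.
#'
#' A tiny seeded jitter (see [ksg_params()]) is added before the neighbour
#' search to break ties. Estimates near independence may be slightly
#' negative and are returned unclipped: clipping would bias the edge ranking
#' used downstream.
#'
#' @param x,y numeric series of equal length `N > k`, finite values.
#' @param params a `ksg_params`.
#' @return Mutual information estimate in nats.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(2000), ncol = 2) %*% chol(matrix(c(1, .9, .9, 1), 2))
#' ksg_mutual_information(z[, 1], z[, 2], ksg_params())  # about 0.83 nats
#' @export
ksg_mutual_information <- function(x, y, params = ksg_params()) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) <= params$k)
    stop_invalid("need N > k samples (N = ", length(x), ", k = ", params$k, ")")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_invalid("series must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    warning("constant series: estimate reflects tie-breaking noise only")
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  ksg_mi_cpp(jitter_series(x, params$tie_noise_scale),
             jitter_series(y, params$tie_noise_scale), params$k)
}

#' All-to-all mutual information matrix for one window
#'
#' Evaluates [ksg_mutual_information()] for every unordered channel pair of
#' a samples x channels window, yielding a symmetric matrix in nats with the
#' diagonal forced to zero (self-edges are excluded). Tie-breaking jitter is
#' drawn once per channel so that the matrix is exactly symmetric.
#'
#' @param window numeric matrix, samples x channels (>= 2 channels).
#' @param params a `ksg_params`.
#' @return Object of class `mi_matrix`: list with `values` (channels x
#'   channels, nats), `n_channels`, `labels` and `window_index`.
#' @export
all_to_all_mi <- function(window, params = ksg_params()) {
  window <- as.matrix(window)
  nch <- ncol(window)
  if (nch < 2) stop_invalid("need at least 2 channels")
  if (nrow(window) <= params$k)
    stop_invalid("window has fewer samples than k + 1")
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  jit <- apply(window, 2, jitter_series, rel = params$tie_noise_scale)
  vals <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      mi <- tryCatch(ksg_mi_cpp(jit[, i], jit[, j], params$k),
                     error = function(e)
                       stop("pair (", i, ", ", j, "): ", conditionMessage(e)))
      vals[i, j] <- vals[j, i] <- mi
    }
  }
  labels <- colnames(window) %||% paste0("ch", seq_len(nch))
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, n_channels = nch, labels = labels,
                 window_index = NA_integer_),
            class = "mi_matrix")
}

#' Average mutual-information matrices across windows
#'
#' Elementwise arithmetic mean of per-window MI matrices; the result is
#' tagged `"averaged"`.
#'
#' @param matrices list of `mi_matrix` objects of identical shape.
#' @return The averaged `mi_matrix`.
#' @export
average_mi <- function(matrices) {
  if (length(matrices) == 0) stop_invalid("empty list of MI matrices")
  dims <- vapply(matrices, function(m) m$n_channels, 0L)
  if (length(unique(dims)) != 1) stop_invalid("matrices differ in shape")
  out <- matrices[[1]]
  out$values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  out$window_index <- "averaged"
  out
}

#' Windowed MI analysis of a recording
#'
#' Runs [all_to_all_mi()] on each window of a [segment_windows()] result and
#' averages with [average_mi()].
#'
#' @param ws a `window_set`.
#' @param params a `ksg_params`; the jitter seed is offset per window.
#' @return List with `per_window` (list of `mi_matrix`) and `averaged`.
#' @export
windowed_mi <- function(ws, params = ksg_params()) {
  stopifnot(inherits(ws, "window_set"))
  per <- vector("list", ws$n_windows)
  for (i in seq_len(ws$n_windows)) {
    pw <- params
    pw$seed <- params$seed + i - 1L
    per[[i]] <- all_to_all_mi(ws$windows[[i]], pw)
    per[[i]]$window_index <- i
  }
  list(per_window = per, averaged = average_mi(per))
}

#' @export
print.mi_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("MI matrix (%s): %d channels, off-diagonal %.4f-%.4f nats\n",
              ifelse(identical(x$window_index, "averaged"), "averaged",
                     paste("window", x$window_index)),
              x$n_channels, min(off), max(off)))
  invisible(x)
}
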