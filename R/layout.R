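#' Electrode layout of a multi-spline basket catheter
#'
#' Builds the channel labelling of a basket mapping catheter: `n_splines`
#' splines named `a`, `b`, ... counterclockwise, each carrying
#' `per_spline` electrodes numbered 1 (distal) to `per_spline` (proximal).
#' The standard clinical basket is 8 x 8 = 64 electrodes with 9-11 mm
#' inter-electrode spacing.
#'
#' @param n_splines number of splines (>= 1).
#' @param per_spline electrodes per spline (>= 1).
#' @param spacing_mm nominal inter-electrode spacing in millimetres
#'   (metadata only; no geometry is computed from it).
#' @return An object of class `basket_layout`: a list with `n_splines`,
#'   `electrodes_per_spline`, `labels` (spline-major order, `a1` first) and
#'   `inter_electrode_spacing_mm`.
#' @examples
#' lay <- generate_basket_layout(8, 8)
#' head(lay$labels)   # "a1" "a2" ...
#' @export
generate_basket_layout <- function(n_splines = 8, per_spline = 8,
                                   spacing_mm = 10) {
  if (!is.numeric(n_splines) || length(n_splines) != 1 || n_splines < 1 ||
      n_splines != round(n_splines))
    stop_invalid("n_splines must be a positive integer")
  if (!is.numeric(per_spline) || length(per_spline) != 1 || per_spline < 1 ||
      per_spline != round(per_spline))
    stop_invalid("per_spline must be a positive integer")
  if (n_splines > 26)
    stop_invalid("at most 26 splines (single-letter names)")
  splines <- letters[seq_len(n_splines)]
  labels <- as.vector(t(outer(splines, seq_len(per_spline), paste0)))
  structure(list(n_splines = as.integer(n_splines),
                 electrodes_per_spline = as.integer(per_spline),
                 labels = labels,
                 inter_electrode_spacing_mm = spacing_mm),
            class = "basket_layout")
}

#' @export
print.basket_layout <- function(x, ...) {
  cat(sprintf("Basket layout: %d splines x %d electrodes = %d channels (%s..%s)\n",
              x$n_splines, x$electrodes_per_spline, length(x$labels),
              x$labels[1], x$labels[length(x$labels)]))
  invisible(x)
}

n_channels <- function(layout) length(layout$labels)
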