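#' Tidy a fitted network
#'
#' Returns the per-neuron receptive-field characterization of the
#' multisensory layer (see [rf_profile()]).
#'
#' @param x a `pps_fit`.
#' @param ... unused.
#' @return A tibble, one row per multisensory neuron.
#' @export
tidy.pps_fit <- function(x, ...) rf_profile(x)

#' One-row summary of a fitted network
#'
#' @param x a `pps_fit`.
#' @param ... unused.
#' @return A tibble with the variant, layer sizes, training extent, final
#'   reconstruction error, excitatory percentage and overlap index.
#' @export
glance.pps_fit <- function(x, ...) {
  prof <- rf_profile(x)
  tibble(
    variant = x$config$variant,
    scale = x$config$scale,
    n_multi = nrow(x$params$W),
    n_low = ncol(x$params$W),
    epochs = if (is.null(x$metrics)) NA_integer_ else max(x$metrics$epoch),
    recon_error = if (is.null(x$metrics)) NA_real_
                  else tail(x$metrics$recon_error, 1),
    pct_excitatory = excitatory_fraction(prof),
    overlap_index = overlap_index(prof)
  )
}
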