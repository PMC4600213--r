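#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROH scan
#'
#' `tidy()` returns the segment table (one row per detected run of
#' homozygosity); `glance()` returns a one-row panel-level summary with the
#' mean per-sample ROH count and mean F_ROH.
#'
#' @param x A `roh_scan` object from [scan_all()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy roh_scan
#' @export
tidy.roh_scan <- function(x, ...) {
  x$segments
}

#' @rdname tidy.roh_scan
#' @method glance roh_scan
#' @export
glance.roh_scan <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$summary),
    n_segments = nrow(x$segments),
    mean_n_roh = mean(x$summary$n_roh),
    mean_total_bp = mean(x$summary$total_bp),
    mean_f_roh = mean(x$summary$f_roh),
    window_snps = x$settings$window_snps,
    min_length_bp = x$settings$min_length_bp)
}
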