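#' Double-exponential calcium indicator kernel
#'
#' Impulse response used to turn event-locked drive into GCaMP-like
#' fluorescence transients: a difference of exponentials with a fast rise
#' and a slow decay, normalized so its peak equals `amplitude`.
#'
#' @param t Numeric vector of times in seconds (values < 0 return 0).
#' @param rise_tau_s Rise time constant in seconds (> 0).
#' @param decay_tau_s Decay time constant in seconds (> `rise_tau_s`).
#' @param amplitude Peak height of the kernel (dF/F units).
#' @return Numeric vector, same length as `t`.
#' @seealso [kernel_peak_time()]
#' @export
#' @examples
#' tt <- seq(0, 8, by = 0.1)
#' k <- calcium_kernel(tt, 0.2, 1.2)
#' max(k)  # 1
calcium_kernel <- function(t, rise_tau_s = 0.2, decay_tau_s = 1.2,
                           amplitude = 1) {
  stopifnot(rise_tau_s > 0, decay_tau_s > rise_tau_s)
  tp <- kernel_peak_time(rise_tau_s, decay_tau_s)
  peak <- exp(-tp / decay_tau_s) - exp(-tp / rise_tau_s)
  out <- ifelse(t < 0, 0, exp(-t / decay_tau_s) - exp(-t / rise_tau_s))
  amplitude * out / peak
}

#' Analytic peak time of the double-exponential kernel
#'
#' @inheritParams calcium_kernel
#' @return Time of the kernel maximum in seconds.
#' @export
kernel_peak_time <- function(rise_tau_s = 0.2, decay_tau_s = 1.2) {
  stopifnot(rise_tau_s > 0, decay_tau_s > rise_tau_s)
  (rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s)) *
    log(decay_tau_s / rise_tau_s)
}
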