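#' Parametric PPG pulse template
#'
#' A single PPG pulse is modelled as the sum of Gaussian lobes: a narrow
#' systolic lobe, a wider "decay shoulder" that slows the falling limb (so the
#' pulse rises faster than it falls, as real PPG pulses do), and a delayed
#' diastolic lobe that plays the role of the dicrotic/diastolic limb. The
#' template is causal: it is identically zero before the pulse onset (the beat
#' time), so that in a rendered pulse train the local minimum between beats
#' coincides with the next beat's onset. On its support the waveform is a sum
#' of plain Gaussians, hence infinitely differentiable with derivatives
#' available in closed form, which makes it usable as a symbolic oracle for
#' the fiducial-point detectors.
#'
#' The systolic lobe peaks at `2 * systolic_width` seconds after onset with
#' standard deviation `2/3 * systolic_width`; the shoulder (45% of the
#' systolic amplitude) sits one `systolic_width` later with twice the
#' standard deviation. The diastolic lobe is a Gaussian centred
#' `diastolic_delay` seconds after the systolic peak with standard deviation
#' `diastolic_width`.
#'
#' @param systolic_amplitude peak amplitude of the systolic lobe (arbitrary
#'   PPG units, > 0).
#' @param systolic_width time-scale of the systolic lobe in seconds (> 0); the
#'   systolic peak sits at twice this value after onset.
#' @param diastolic_amplitude peak amplitude of the diastolic lobe (>= 0 and
#'   less than `systolic_amplitude`).
#' @param diastolic_delay delay of the diastolic lobe centre after the systolic
#'   peak, seconds (>= 0).
#' @param diastolic_width standard deviation of the diastolic lobe, seconds.
#' @return an object of class `pulse_template`.
#' @examples
#' tpl <- pulse_template()
#' tau <- seq(0, 1.2, by = 1 / 32)
#' y <- eval_pulse(tpl, tau)
#' @export
pulse_template <- function(systolic_amplitude = 1.0,
                           systolic_width = 0.09,
                           diastolic_amplitude = 0.35,
                           diastolic_delay = 0.25,
                           diastolic_width = 0.12) {
  stopifnot_scalar(systolic_amplitude, "systolic_amplitude", lower = 1e-12)
  stopifnot_scalar(systolic_width, "systolic_width", lower = 1e-6, upper = 1)
  stopifnot_scalar(diastolic_amplitude, "diastolic_amplitude", lower = 0)
  stopifnot_scalar(diastolic_delay, "diastolic_delay", lower = 0)
  stopifnot_scalar(diastolic_width, "diastolic_width", lower = 1e-6, upper = 1)
  if (diastolic_amplitude >= systolic_amplitude) {
    stop("`diastolic_amplitude` must be smaller than `systolic_amplitude`",
         call. = FALSE)
  }
  structure(
    list(systolic_amplitude = systolic_amplitude,
         systolic_width = systolic_width,
         diastolic_amplitude = diastolic_amplitude,
         diastolic_delay = diastolic_delay,
         diastolic_width = diastolic_width),
    class = "pulse_template"
  )
}

# lobe helpers: value and first two derivatives of A * exp(-(x-c)^2 / (2 s^2))
.gauss <- function(x, c, s) exp(-0.5 * ((x - c) / s)^2)
.gauss_d1 <- function(x, c, s) -(x - c) / s^2 * .gauss(x, c, s)
.gauss_d2 <- function(x, c, s) ((x - c)^2 / s^4 - 1 / s^2) * .gauss(x, c, s)

.template_params <- function(template) {
  t_sp <- 2 * template$systolic_width
  list(
    t_sp = t_sp,
    s_sys = 2 / 3 * template$systolic_width,
    t_shoulder = t_sp + template$systolic_width,
    s_shoulder = 4 / 3 * template$systolic_width,
    a_shoulder = 0.45,
    t_dia = t_sp + template$diastolic_delay
  )
}

#' Evaluate a pulse template (and derivatives) at offsets from onset
#'
#' @param template a [pulse_template()].
#' @param tau numeric vector of times in seconds relative to the pulse onset.
#' @param deriv 0, 1 or 2: evaluate the template, its first (velocity) or
#'   second (acceleration) time derivative. Derivatives are analytic, not
#'   numeric.
#' @return numeric vector, zero wherever `tau < 0` (the template is causal).
#' @export
eval_pulse <- function(template, tau, deriv = 0L) {
  stopifnot(inherits(template, "pulse_template"))
  p <- .template_params(template)
  f <- switch(as.character(deriv),
    "0" = .gauss, "1" = .gauss_d1, "2" = .gauss_d2,
    stop("`deriv` must be 0, 1 or 2", call. = FALSE))
  out <- template$systolic_amplitude *
    (f(tau, p$t_sp, p$s_sys) +
       p$a_shoulder * f(tau, p$t_shoulder, p$s_shoulder)) +
    template$diastolic_amplitude * f(tau, p$t_dia, template$diastolic_width)
  out[tau < 0] <- 0
  out
}

# Effective support of the template past which lobes are negligible (< 1e-8
# of peak); used by the renderer to bound per-beat work.
.template_support <- function(template) {
  p <- .template_params(template)
  max(p$t_shoulder + 6.1 * p$s_shoulder,
      p$t_dia + 6.1 * template$diastolic_width)
}

#' @export
print.pulse_template <- function(x, ...) {
  p <- .template_params(x)
  cat(sprintf(
    "<pulse_template> systolic peak %.0f ms after onset (amp %.3g), diastolic lobe at %.0f ms (amp %.3g)\n",
    1000 * p$t_sp, x$systolic_amplitude, 1000 * p$t_dia, x$diastolic_amplitude))
  invisible(x)
}
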