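#' Piezoelectric sensor and amplifier parameters
#'
#' Bundles the constants of the sensor/readout transfer model: the
#' piezoelectric charge constant `d33`, the amplifier gain `beta`, and the
#' equivalent input resistance `RM` and capacitance `CM` of the amplifying
#' circuit, plus the sampling rate.
#'
#' Defaults are chosen for a normalized-voltage simulator: `d33 = 200e-12` C/N
#' (well below the ~600 pC/N ceiling of common piezoceramics), `beta = 100`,
#' `RM = 1e7` ohm, `CM = 1e-8` F. With these values `omega * RM * CM = 0.63 *
#' (f / 1 Hz)`, so the high-frequency regime `(omega*RM*CM)^2 >> 1` holds for
#' cardiac frequencies but is only marginal at respiratory frequencies; the
#' linear transfer form is applied throughout.
#'
#' @param d33 Piezoelectric charge constant (C/N), `0 < d33 <= 600e-12`.
#' @param beta Amplifier gain (dimensionless, > 0).
#' @param RM Equivalent input resistance (ohm, > 0).
#' @param CM Equivalent input capacitance (F, > 0).
#' @param fs Sampling rate (Hz). One minute is `60 * fs` samples.
#' @return An object of class `piezo_params` (a named list incl. `dt = 1/fs`).
#' @examples
#' p <- piezo_params()
#' sensor_transfer(1, 2 * pi * 1.2, p)
#' @export
piezo_params <- function(d33 = 200e-12, beta = 100, RM = 1e7, CM = 1e-8,
                         fs = 100) {
  if (!is.numeric(d33) || d33 <= 0 || d33 > 600e-12)
    abort_bad_arg("`d33` must be in (0, 600e-12] C/N")
  if (beta <= 0 || RM <= 0 || CM <= 0) abort_bad_arg("`beta`, `RM`, `CM` must be positive")
  if (fs <= 0) abort_bad_arg("`fs` must be positive")
  structure(list(d33 = d33, beta = beta, RM = RM, CM = CM,
                 fs = fs, dt = 1 / fs),
            class = "piezo_params")
}

#' Sensor transfer: force amplitude to output voltage amplitude
#'
#' Amplitude of the amplified output voltage for a sinusoidal normal force of
#' amplitude `Fm` at angular frequency `omega`:
#' `Uim = d33 * Fm * omega * RM * beta / sqrt(1 + (omega*RM*CM)^2)`.
#' In the high-frequency limit this tends to `beta * d33 * Fm / CM`, i.e. the
#' piezoelectric sensitivity becomes frequency-independent.
#'
#' @param Fm Force amplitude (N), `>= 0`. Vectorized.
#' @param omega Angular frequency (rad/s), `> 0`. Vectorized.
#' @param params A [piezo_params()] object.
#' @return Voltage amplitude(s), same length as the broadcast of `Fm`/`omega`.
#' @export
sensor_transfer <- function(Fm, omega, params = piezo_params()) {
  stopifnot(inherits(params, "piezo_params"))
  if (any(!is.finite(omega)) || any(omega <= 0))
    abort_bad_arg("`omega` must be positive and finite")
  if (any(Fm < 0)) abort_bad_arg("`Fm` must be non-negative")
  wrc <- omega * params$RM * params$CM
  params$d33 * Fm * omega * params$RM * params$beta / sqrt(1 + wrc^2)
}

# inverse of the high-frequency amplitude relation: voltage amplitude -> force
# intensity, U = beta*d33/CM * F  =>  F = U * CM / (beta * d33)
voltage_to_force <- function(U, params) U * params$CM / (params$beta * params$d33)
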