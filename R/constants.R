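#' Physical constants and the package unit conventions
#'
#' One table collecting every constant and unit convention used across the
#' package. Molecular-scale quantities use nm / ps (or ns) / k_BT; the droplet
#' shell model uses SI (m, s, kg). Diffusion coefficients are always reported
#' in m^2 s^-1.
#'
#' @return Named list with `k_B` (J K^-1), `h` (J s), and the unit conventions
#'   as documentation strings.
#' @examples
#' cavity_constants()$k_B
#' @export
cavity_constants <- function() {
  list(
    k_B = 1.380649e-23,            # J / K (exact, SI)
    h = 6.62607015e-34,            # J s (exact, SI)
    length_molecular = "nm",
    time_molecular = "ps (trajectories), ns (rates, timescales)",
    energy_molecular = "k_BT",
    droplet_units = "SI: m, s, kg; D in m^2 s^-1",
    nm2_per_ps_to_m2_per_s = 1e-6  # 1 nm^2/ps = 1e-6 m^2/s
  )
}

#' Thermal attempt frequency k_BT/h in ns^-1
#'
#' Default transition-state-theory prefactor. At 300 K this is about
#' 6.25e3 ns^-1.
#'
#' @param temperature Temperature in K.
#' @return Attempt frequency in ns^-1.
#' @export
kbt_over_h_ns <- function(temperature = 300) {
  cc <- cavity_constants()
  cc$k_B * temperature / cc$h * 1e-9
}
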