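# Internal unit system: lengths in mm, stresses/moduli in kPa, forces in mN.

#' Unit conversion constants
#'
#' `MMHG_TO_KPA` converts millimetres of mercury to kilopascal
#' (1 mmHg = 0.133322 kPa).
#'
#' @format Length-one numeric.
#' @export
MMHG_TO_KPA <- 0.133322

#' @rdname MMHG_TO_KPA
#' @export
UM_PER_MM <- 1000

#' Convert a radius of curvature to keratometric power
#'
#' Clinical convention: corneal power in dioptres is `(n - 1) * 1000 / r`
#' with `r` in mm and `n` the keratometric index.
#'
#' @param radius_mm radius of curvature in mm.
#' @param n_index keratometric refractive index (default 1.3375, so that
#'   `power = 337.5 / r`).
#' @return power in dioptres.
#' @export
keratometric_power <- function(radius_mm, n_index = 1.3375) {
  (n_index - 1) * 1000 / radius_mm
}

#' Read a simulation configuration file
#'
#' Reads a YAML configuration with any of the sections `geometry`, `tunnel`,
#' `materials`, `prestrain`, `design`, `solver`.  Missing sections fall back
#' to package defaults.  A template covering all fields ships in
#' `system.file("extdata", "default_config.yaml", package = "corneafem")`.
#'
#' @param path path to a YAML file.
#' @return named list of configuration sections.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
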