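#' Parameters of the electron-shuttle flux-balance estimate
#'
#' A flux balance over the flock volume: the flock's total respiratory
#' electron demand is compared with the size of the dissolved mediator pool
#' to obtain the pool turnover time, and inverted to obtain the concentration
#' required to sustain a target turnover. Geometry defaults reflect the
#' observed flock: a cylindrical shell of elevated cell density around a
#' filament segment (cells are concentrated within 20 um but remain elevated
#' to about 50 um, so the shuttle-carrying volume uses the 50 um extent), and
#' the cell count is of the order observed per tracked flock segment.
#'
#' @param flock_length Filament segment length with flocking (um).
#' @param flock_radius Radius of the flock volume (um); default 50 um, the
#'   full radial extent of elevated cell density.
#' @param n_cells Total flocking cells in the volume. Alternatively supply
#'   `cell_density`.
#' @param cell_density Cells per um^3 (used if `n_cells` is `NULL`).
#' @param per_cell_electron_rate Respiratory electron consumption per cell
#'   (e-/s); default 2.4e6, i.e. an O2 uptake of ~1e-18 mol/cell/s times 4
#'   electrons per O2.
#' @param electrons_per_mediator Electrons carried per mediator molecule
#'   (default 2, flavin-like).
#' @param shuttle_concentration Dissolved mediator concentration (mol/L);
#'   default 1e-7 (100 nM, the range reported for sediment flavins).
#' @param diffusion_coefficient Mediator diffusion coefficient (um^2/s);
#'   default 400, typical for a small organic molecule in water.
#' @param mean_travel_distance Characteristic cell-to-filament transport
#'   distance (um); default 25.
#' @return An object of class `shuttle_params`.
#' @export
shuttle_params <- function(flock_length = 200,
                           flock_radius = 50,
                           n_cells = 270,
                           cell_density = NULL,
                           per_cell_electron_rate = 2.4e6,
                           electrons_per_mediator = 2L,
                           shuttle_concentration = 1e-7,
                           diffusion_coefficient = 400,
                           mean_travel_distance = 25) {
  p <- list(flock_length = flock_length, flock_radius = flock_radius,
            n_cells = n_cells, cell_density = cell_density,
            per_cell_electron_rate = per_cell_electron_rate,
            electrons_per_mediator = as.integer(electrons_per_mediator),
            shuttle_concentration = shuttle_concentration,
            diffusion_coefficient = diffusion_coefficient,
            mean_travel_distance = mean_travel_distance)
  for (nm in c("flock_length", "flock_radius", "per_cell_electron_rate",
               "shuttle_concentration", "diffusion_coefficient",
               "mean_travel_distance"))
    .assert_positive(p[[nm]], nm)
  if (p$electrons_per_mediator < 1)
    stop("'electrons_per_mediator' must be >= 1", call. = FALSE)
  if (is.null(p$n_cells) && is.null(p$cell_density))
    stop("supply 'n_cells' or 'cell_density'", call. = FALSE)
  if (!is.null(p$n_cells) && p$n_cells < 0)
    stop("'n_cells' must be >= 0", call. = FALSE)
  class(p) <- "shuttle_params"
  p
}

#' Flock volume
#'
#' Volume of the cylindrical flock shell, `pi * r^2 * L`, converted to liters
#' (1 um^3 = 1e-15 L). The filament's own volume (radius ~1 um) is negligible
#' against the flock radius and is not subtracted.
#'
#' @param params [shuttle_params()].
#' @return Volume in liters.
#' @export
flock_volume <- function(params) {
  stopifnot(inherits(params, "shuttle_params"))
  pi * params$flock_radius^2 * params$flock_length * 1e-15
}

#' Total respiratory electron demand of the flock
#'
#' @param params [shuttle_params()].
#' @return Demand in electrons per second.
#' @export
electron_demand <- function(params) {
  stopifnot(inherits(params, "shuttle_params"))
  n <- params$n_cells
  if (is.null(n))
    n <- params$cell_density * flock_volume(params) / 1e-15
  n * params$per_cell_electron_rate
}

#' Turnover time of the mediator pool
#'
#' Time to cycle the whole dissolved mediator pool once at the flock's
#' electron demand: `tau = N * n_e / R`, with `N = C * N_A * V` molecules in
#' the flock volume, `n_e` electrons per mediator and `R` the demand.
#'
#' @param params [shuttle_params()].
#' @return Turnover time in seconds (`Inf` with a warning if the demand is 0).
#' @export
turnover_time <- function(params) {
  stopifnot(inherits(params, "shuttle_params"))
  R <- electron_demand(params)
  if (R == 0) {
    warning("zero electron demand: turnover time is undefined (Inf)")
    return(Inf)
  }
  N <- params$shuttle_concentration * .N_AVOGADRO * flock_volume(params)
  N * params$electrons_per_mediator / R
}

#' Concentration required for a target turnover time
#'
#' Algebraic inverse of [turnover_time()]:
#' `C = R * tau / (n_e * N_A * V)`.
#'
#' @param params [shuttle_params()].
#' @param tau_target Target turnover time in seconds.
#' @return Required concentration in mol/L.
#' @export
required_concentration <- function(params, tau_target) {
  stopifnot(inherits(params, "shuttle_params"))
  .assert_positive(tau_target, "tau_target")
  R <- electron_demand(params)
  R * tau_target /
    (params$electrons_per_mediator * .N_AVOGADRO * flock_volume(params))
}

#' Characteristic diffusion time over a distance
#'
#' Three-dimensional diffusion time `t = d^2 / (6 D)`.
#'
#' @param distance Distance in um.
#' @param D Diffusion coefficient in um^2/s.
#' @return Time in seconds.
#' @export
diffusion_time <- function(distance, D) {
  .assert_positive(D, "D")
  distance^2 / (6 * D)
}

#' Summary report of the shuttle estimate
#'
#' Evaluates the flux balance at the supplied parameters: flock volume,
#' electron demand, turnover time at the stated concentration, concentration
#' required for a 2 s turnover, and the diffusion time over the mean travel
#' distance.
#'
#' @param params [shuttle_params()].
#' @param tau_target Target turnover time (s) for the required-concentration
#'   inversion (default 2).
#' @return A list of class `shuttle_report`.
#' @export
shuttle_report <- function(params = shuttle_params(), tau_target = 2) {
  structure(list(
    params = params,
    volume_L = flock_volume(params),
    demand_e_per_s = electron_demand(params),
    turnover_time_s = turnover_time(params),
    required_concentration_M = required_concentration(params, tau_target),
    tau_target_s = tau_target,
    diffusion_time_s = diffusion_time(params$mean_travel_distance,
                                      params$diffusion_coefficient)
  ), class = "shuttle_report")
}

#' @export
print.shuttle_report <- function(x, ...) {
  cat("Electron shuttle flux balance\n")
  cat(sprintf("  flock volume:            %.4g L\n", x$volume_L))
  cat(sprintf("  electron demand:         %.4g e-/s\n", x$demand_e_per_s))
  cat(sprintf("  turnover time at %.3g M: %.4g s\n",
              x$params$shuttle_concentration, x$turnover_time_s))
  cat(sprintf("  concentration for tau = %g s: %.4g M (%.3g nM)\n",
              x$tau_target_s, x$required_concentration_M,
              x$required_concentration_M * 1e9))
  cat(sprintf("  diffusion time over %g um: %.4g s\n",
              x$params$mean_travel_distance, x$diffusion_time_s))
  invisible(x)
}
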