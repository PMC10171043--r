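# Evaluation of a simulated design: stress statistics, degree of opening,
# and the combined loss index used for ranking.

#' Summary statistics of a von Mises stress field
#'
#' Arithmetic mean, maximum and population standard deviation of the
#' per-element von Mises stresses.
#'
#' @param vm Non-empty numeric vector of von Mises values (MPa).
#' @return An object of class `stress_summary`: list with `mean`, `max`,
#'   `sd` (population) and `n`.
#' @examples
#' stress_summary(c(1, 2, 3)) # mean 2, max 3, sd 0.8165
#' @export
stress_summary <- function(vm) {
  vm <- as.numeric(vm)
  if (length(vm) == 0L) stop("empty stress field", call. = FALSE)
  if (!all(is.finite(vm))) stop("non-finite stress values", call. = FALSE)
  m <- mean(vm)
  structure(list(mean = m, max = max(vm),
                 sd = sqrt(mean((vm - m)^2)), n = length(vm)),
            class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf(
    "von Mises stress over %d elements: mean %.4g, max %.4g, SD %.4g MPa\n",
    x$n, x$mean, x$max, x$sd))
  invisible(x)
}

#' Degree of opening
#'
#' The uncovered fraction of the leaflet's reference orifice area in XY
#' projection, as a percentage: `DO = S / (pi*Rin^2/3) * 100`, where `S` is
#' the reference area minus the area the (deformed) leaflet still covers
#' (clamped to `[0, reference]`).  The closed, undeformed leaflet covers
#' its whole sector, so DO starts near 0 % and grows as the leaflet swings
#' open.
#'
#' @param state An `opening_sim`, or an N x 3 matrix of deformed node
#'   positions (then `mesh` must be given).
#' @param mesh The `leaflet_mesh` the positions refer to (taken from the
#'   simulation if `state` is an `opening_sim`).
#' @param Rin Prosthesis radius (mm); default from the mesh parameters.
#' @param resolution Raster resolution for the projected area (mm/pixel).
#' @return Degree of opening in percent, in `[0, 100]`.
#' @export
degree_of_opening <- function(state, mesh = NULL, Rin = NULL,
                              resolution = 0.05) {
  if (inherits(state, "opening_sim")) {
    mesh <- state$mesh
    positions <- state$positions
  } else {
    positions <- as.matrix(state)
    if (is.null(mesh)) {
      stop("mesh must be supplied with bare positions", call. = FALSE)
    }
  }
  if (is.null(Rin)) {
    if (is.null(mesh$params)) {
      stop("Rin must be given for a non-leaflet mesh", call. = FALSE)
    }
    Rin <- mesh$params$Rin
  }
  ref_area <- sector_area(Rin)
  covered <- projected_covered_area(positions, Rin, resolution,
                                    triangles = mesh$triangles)
  open_area <- min(max(ref_area - covered, 0), ref_area)
  open_area / ref_area * 100
}

#' Loss index of a leaflet design
#'
#' A "the less, the better" scalar combining the opening deficit and the
#' stress utilisation of the material:
#' `LI = sqrt(((100 - DO)/100)^2 + (sigma_max/sigma_lim)^2)`.
#' It is 0 for a fully opening, stress-free design and exceeds 1 whenever
#' the peak von Mises stress passes the ultimate strength of the tissue.
#'
#' @param do_percent Degree of opening in percent, in `[0, 100]`
#'   (vectorised; values above 100 are rejected).
#' @param sigma_max Peak von Mises stress (MPa), >= 0.
#' @param sigma_lim Ultimate strength of the leaflet material (MPa),
#'   default 11.6 (pericardium).
#' @return Dimensionless loss index, >= 0.
#' @examples
#' loss_index(100, 0)          # 0: ideal design
#' loss_index(84.48, 1.21)     # 0.19 at 2 dp
#' loss_index(88.12, 1.87)     # 0.20 at 2 dp
#' @export
loss_index <- function(do_percent, sigma_max, sigma_lim = 11.6) {
  if (!all(is.finite(do_percent)) || any(do_percent < 0) ||
      any(do_percent > 100)) {
    stop("do_percent must be in [0, 100]", call. = FALSE)
  }
  if (!all(is.finite(sigma_max)) || any(sigma_max < 0)) {
    stop("sigma_max must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma_lim) || length(sigma_lim) != 1L || sigma_lim <= 0) {
    stop("sigma_lim must be a single value > 0", call. = FALSE)
  }
  sqrt(((100 - do_percent) / 100)^2 + (sigma_max / sigma_lim)^2)
}

#' Analyze a finished opening simulation
#'
#' Convenience wrapper combining [stress_summary()], [degree_of_opening()]
#' and [loss_index()] into one record.
#'
#' @param sim An `opening_sim`.
#' @param sigma_lim Ultimate strength for the loss index (MPa).
#' @param resolution Raster resolution for the projected area (mm/pixel).
#' @return A one-row data frame with `do_percent`, `vm_mean`, `vm_max`,
#'   `vm_sd` and `li`.
#' @export
analyze_opening <- function(sim, sigma_lim = 11.6, resolution = 0.05) {
  stopifnot(inherits(sim, "opening_sim"))
  ss <- stress_summary(sim$element_vm)
  do <- degree_of_opening(sim, resolution = resolution)
  data.frame(do_percent = do, vm_mean = ss$mean, vm_max = ss$max,
             vm_sd = ss$sd, li = loss_index(do, ss$max, sigma_lim))
}
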