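#' Leaflet design parameters
#'
#' Bundle the six geometric parameters that define one leaflet design of a
#' bioprosthetic heart valve.  Lengths are in millimetres, angles in degrees.
#'
#' @param H1 Leaflet height (mm): distance from the lowest point of the
#'   attachment scallop up to the top of the commissural strut.  Must be > 0.
#' @param phi Free-edge deviation angle (degrees).  Positive values tilt the
#'   centre of the free edge toward the ventricle (below the commissure
#'   height); negative values raise it.  Must lie in (-90, 90).
#' @param R Degree of leaflet dome "sagging", in percent of the reference
#'   sag depth `0.25 * Rin`.  Must lie in \[0, 100\].
#' @param Rin Internal radius of the prosthesis (mm).  Must be > 0.
#' @param T Leaflet thickness (mm).  Must be > 0.
#' @param Sec Angular span occupied by one leaflet (degrees).  Must lie in
#'   (0, 120\].  Defaults to 119, the span of typical commercial designs
#'   (a small gap is left at the commissures).
#'
#' @return An object of class `leaflet_params` (a named list).
#' @examples
#' p <- leaflet_params(H1 = 15.22, phi = 5.17, R = 40, Rin = 9.38, T = 0.14)
#' p
#' @export
leaflet_params <- function(H1, phi = 0, R = 40, Rin, T, Sec = 119) {
  vals <- list(H1 = H1, phi = phi, R = R, Rin = Rin, T = T, Sec = Sec)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("leaflet parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (H1 <= 0) stop("H1 (leaflet height) must be > 0", call. = FALSE)
  if (Rin <= 0) stop("Rin (prosthesis radius) must be > 0", call. = FALSE)
  if (T <= 0) stop("T (leaflet thickness) must be > 0", call. = FALSE)
  if (R < 0 || R > 100) stop("R (sag degree) must be in [0, 100] %", call. = FALSE)
  if (phi <= -90 || phi >= 90) {
    stop("phi (free-edge deviation) must be in (-90, 90) degrees", call. = FALSE)
  }
  if (Sec <= 0 || Sec > 120) stop("Sec must be in (0, 120] degrees", call. = FALSE)
  structure(vals, class = "leaflet_params")
}

#' @export
print.leaflet_params <- function(x, ...) {
  cat("Leaflet design parameters\n")
  cat(sprintf("  H1  (height)        : %8.3f mm\n", x$H1))
  cat(sprintf("  phi (edge deviation): %8.3f deg\n", x$phi))
  cat(sprintf("  R   (dome sag)      : %8.3f %%\n", x$R))
  cat(sprintf("  Rin (valve radius)  : %8.3f mm\n", x$Rin))
  cat(sprintf("  T   (thickness)     : %8.3f mm\n", x$T))
  cat(sprintf("  Sec (angular span)  : %8.3f deg\n", x$Sec))
  invisible(x)
}

#' @export
as.data.frame.leaflet_params <- function(x, ...) {
  data.frame(H1 = x$H1, phi = x$phi, R = x$R, Rin = x$Rin, T = x$T,
             Sec = x$Sec)
}

#' Default design-space parameter ranges
#'
#' The ranges used for batch exploration of leaflet designs: they cover the
#' majority of existing tricuspid-layout prostheses in the aortic position.
#'
#' @return A named list of length-2 numeric vectors (`lower`, `upper`) for
#'   `H1`, `phi`, `R`, `Rin` and `T`.  `Sec` is held fixed (see
#'   [sample_designs()]).
#' @export
default_ranges <- function() {
  list(
    H1  = c(10, 25),    # mm
    phi = c(-30, 30),   # degrees
    R   = c(0, 100),    # percent
    Rin = c(7.5, 20.0), # mm
    T   = c(0.1, 1.0)   # mm
  )
}
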