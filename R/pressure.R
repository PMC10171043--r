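# Transvalvular pressure loading for the systolic opening phase.
#
# The leaflet midsurface carries the net (ventricular minus aortic)
# pressure as a follower load along the current surface normal; for a thin
# membrane this is mechanically equivalent to loading the two faces
# separately.

MMHG_TO_MPA <- 1.33322e-4

#' Transvalvular pressure waveform
#'
#' Parametric net pressure difference (ventricular minus aortic) over the
#' opening phase.  The default rises smoothly from 0 to `dp_max` over
#' `t_end` and holds the final value afterwards.
#'
#' @param shape One of `"smoothstep"` (`3x^2 - 2x^3`, zero slope at both
#'   ends), `"half-sine"` (`sin(pi x / 2)`) or `"ramp"` (linear).
#' @param dp_max Peak net pressure in mmHg (>= 0), default 30 -- a
#'   physiologically plausible peak systolic transvalvular gradient.
#' @param t_end Duration of the opening phase in seconds (> 0),
#'   default 0.2.
#' @return An object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(shape = c("smoothstep", "half-sine", "ramp"),
                              dp_max = 30, t_end = 0.2) {
  shape <- match.arg(shape)
  if (!is.numeric(dp_max) || length(dp_max) != 1L || !is.finite(dp_max) ||
      dp_max < 0) {
    stop("dp_max must be a single finite number >= 0 (mmHg)", call. = FALSE)
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    stop("t_end must be a single finite number > 0 (s)", call. = FALSE)
  }
  structure(list(shape = shape, dp_max = dp_max, t_end = t_end),
            class = "pressure_waveform")
}

#' Net transvalvular pressure at time t
#'
#' @param wf A [pressure_waveform()].
#' @param t Time(s) in seconds, >= 0.  Values beyond `t_end` hold the final
#'   pressure.
#' @return Net pressure in MPa (1 mmHg = 1.33322e-4 MPa).
#' @examples
#' wf <- pressure_waveform(dp_max = 30, t_end = 0.2)
#' net_pressure(wf, c(0, 0.1, 0.2))
#' @export
net_pressure <- function(wf, t) {
  if (!all(is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  x <- pmin(pmax(t / wf$t_end, 0), 1)
  s <- switch(wf$shape,
              smoothstep = 3 * x^2 - 2 * x^3,
              `half-sine` = sin(pi * x / 2),
              ramp = x)
  wf$dp_max * MMHG_TO_MPA * s
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(
    "Pressure waveform: %s, peak %g mmHg (%.4g MPa) over %g s, held after\n",
    x$shape, x$dp_max, x$dp_max * MMHG_TO_MPA, x$t_end))
  invisible(x)
}
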