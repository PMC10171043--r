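# Soft-tissue material model: averaging of multi-sample uniaxial tensile
# curves into a cubic stress-strain law, plus a synthetic tensile-curve
# generator standing in for wet-lab xenopericardium tests.

#' Uniaxial tensile curve
#'
#' One sample's engineering strain-stress record from a uniaxial tensile
#' test.
#'
#' @param strain Dimensionless engineering strain, non-negative and strictly
#'   increasing.
#' @param stress Engineering stress (MPa), same length as `strain`.
#' @return An object of class `tensile_curve`.
#' @export
tensile_curve <- function(strain, stress) {
  strain <- as.numeric(strain)
  stress <- as.numeric(stress)
  if (length(strain) != length(stress)) {
    stop("strain and stress must have equal length", call. = FALSE)
  }
  if (!all(is.finite(strain)) || !all(is.finite(stress))) {
    stop("strain and stress must be finite", call. = FALSE)
  }
  if (any(strain < 0)) stop("strain must be non-negative", call. = FALSE)
  if (any(diff(strain) <= 0)) {
    stop("strain must be strictly increasing", call. = FALSE)
  }
  structure(list(strain = strain, stress = stress), class = "tensile_curve")
}

#' Averaged material law
#'
#' Constructs a material description around polynomial stress-strain
#' coefficients (no constant term, so sigma(0) = 0).  Usually produced by
#' [fit_polynomial_average()]; the direct constructor serves linear
#' verification materials and deserialisation.
#'
#' @param coeffs Polynomial coefficients `c(c1, c2, ...)` of
#'   `sigma(eps) = c1*eps + c2*eps^2 + ...` in MPa.
#' @param r2 Coefficient of determination of the fit (`NA` when
#'   constructed directly).
#' @param sigma_lim Ultimate strength of the tissue (MPa), default 11.6
#'   (glutaraldehyde-stabilised pericardium).
#' @param density Mass density in tonne/mm^3, default 1.1e-9 (soft tissue).
#' @param poisson Poisson ratio, default 0.45 (nearly incompressible).
#' @param strain_max Largest fitted strain; beyond it the law extrapolates
#'   linearly with the tangent at `strain_max`.
#' @return An object of class `material_fit`.
#' @export
material_fit <- function(coeffs, r2 = NA_real_, sigma_lim = 11.6,
                         density = 1.1e-9, poisson = 0.45, strain_max = 0.4) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 1L || !all(is.finite(coeffs))) {
    stop("coeffs must be finite polynomial coefficients", call. = FALSE)
  }
  if (!is.na(r2) && r2 > 1 + 1e-12) stop("r2 cannot exceed 1", call. = FALSE)
  if (sigma_lim <= 0) stop("sigma_lim must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (poisson < 0 || poisson >= 0.5) {
    stop("poisson must be in [0, 0.5)", call. = FALSE)
  }
  if (!is.finite(strain_max) || strain_max <= 0) {
    stop("strain_max must be a finite value > 0", call. = FALSE)
  }
  names(coeffs) <- paste0("c", seq_along(coeffs))
  structure(list(coeffs = coeffs, r2 = r2, sigma_lim = sigma_lim,
                 density = density, poisson = poisson,
                 strain_max = strain_max),
            class = "material_fit")
}

#' Average tensile curves with an origin-constrained polynomial
#'
#' Pools the (strain, stress) points of all sample curves and fits a single
#' polynomial of the requested degree without a constant term (the averaged
#' law must pass through the origin), by least squares -- equivalent to
#' solving the normal equations of the pooled design matrix.  The
#' coefficient of determination is computed on the pooled points.
#'
#' @param curves A list of [tensile_curve()] objects (or a single curve).
#' @param degree Polynomial degree, default 3.
#' @param ... Passed to [material_fit()] (`sigma_lim`, `density`,
#'   `poisson`).
#' @return A [material_fit()] whose `strain_max` is the largest pooled
#'   strain.
#' @examples
#' cv <- tensile_curve(seq(0.02, 0.4, length.out = 20),
#'                     1.0 * seq(0.02, 0.4, length.out = 20) +
#'                     2.0 * seq(0.02, 0.4, length.out = 20)^3)
#' fit <- fit_polynomial_average(list(cv))
#' coef(fit)
#' @export
fit_polynomial_average <- function(curves, degree = 3, ...) {
  if (inherits(curves, "tensile_curve")) curves <- list(curves)
  if (!is.list(curves) || length(curves) < 1L) {
    stop("curves must be a non-empty list of tensile_curve objects",
         call. = FALSE)
  }
  curves <- lapply(curves, function(cv) {
    if (!inherits(cv, "tensile_curve")) do.call(tensile_curve, cv) else cv
  })
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)

  strain <- unlist(lapply(curves, `[[`, "strain"))
  stress <- unlist(lapply(curves, `[[`, "stress"))
  if (length(strain) < degree + 1L) {
    stop("need at least degree + 1 pooled points (", degree + 1L,
         "), got ", length(strain), call. = FALSE)
  }
  X <- outer(strain, seq_len(degree), `^`)
  qrX <- qr(X)
  if (qrX$rank < degree) {
    stop("rank-deficient design: too few distinct strain levels",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, stress)
  fitted <- drop(X %*% beta)
  ss_res <- sum((stress - fitted)^2)
  ss_tot <- sum((stress - mean(stress))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  material_fit(beta, r2 = r2, strain_max = max(strain), ...)
}

#' Stress at a given strain
#'
#' Evaluates the fitted polynomial law.  The compressive branch is the odd
#' extension `sigma(-eps) = -sigma(eps)`; beyond the largest fitted strain
#' the law extrapolates linearly with the tangent there.
#'
#' @param fit A [material_fit()].
#' @param strain Numeric vector of engineering strains.
#' @return Stress in MPa, same length as `strain`.
#' @export
stress_at_strain <- function(fit, strain) {
  if (!all(is.finite(strain))) stop("strain must be finite", call. = FALSE)
  s <- sign(strain)
  a <- abs(strain)
  poly_eval <- function(e) {
    acc <- 0
    for (k in rev(seq_along(fit$coeffs))) acc <- (acc + fit$coeffs[[k]]) * e
    acc
  }
  out <- poly_eval(pmin(a, fit$strain_max))
  over <- a > fit$strain_max
  if (any(over)) {
    tang <- tangent_at(fit, fit$strain_max)
    out[over] <- out[over] + tang * (a[over] - fit$strain_max)
  }
  unname(s * out)
}

# Polynomial tangent d sigma / d eps at |strain| <= strain_max.
tangent_at <- function(fit, e) {
  acc <- 0
  for (k in rev(seq_along(fit$coeffs))) {
    acc <- acc * e + k * fit$coeffs[[k]]
  }
  acc
}

#' Tangent modulus of the fitted law
#'
#' @param fit A [material_fit()].
#' @param strain Numeric vector of strains (odd extension; constant tangent
#'   beyond `strain_max`).
#' @return Tangent modulus d(sigma)/d(eps) in MPa.
#' @export
tangent_modulus <- function(fit, strain) {
  a <- pmin(abs(strain), fit$strain_max)
  out <- vapply(a, function(e) tangent_at(fit, e), numeric(1L))
  unname(out)
}

#' @export
coef.material_fit <- function(object, ...) object$coeffs

#' @export
predict.material_fit <- function(object, strain, ...) {
  stress_at_strain(object, strain)
}

#' @export
print.material_fit <- function(x, ...) {
  cat("Averaged stress-strain law (origin-constrained polynomial)\n")
  cat("  sigma(eps) =",
      paste(sprintf("%+.4g*eps^%d", x$coeffs, seq_along(x$coeffs)),
            collapse = " "), "MPa\n")
  cat(sprintf("  R^2 = %s on pooled points; valid strain range [0, %.3g]\n",
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$strain_max))
  cat(sprintf("  sigma_lim = %.3g MPa, density = %.3g tonne/mm^3, nu = %.2f\n",
              x$sigma_lim, x$density, x$poisson))
  invisible(x)
}

#' Default pericardium-like material
#'
#' A fixed cubic law emulating glutaraldehyde-treated xenopericardium: a
#' compliant toe region stiffening toward the ultimate strength of 11.6 MPa
#' near 40 % strain.  Used as the built-in material when no tensile data
#' are supplied; it is a synthetic stand-in, not a measured tissue curve.
#'
#' @return A [material_fit()] with coefficients `(1, 5, 150)` MPa on the
#'   strain range `[0, 0.4]`.
#' @export
default_material <- function() {
  material_fit(c(1, 5, 150), r2 = NA_real_, sigma_lim = 11.6,
               density = 1.1e-9, poisson = 0.45, strain_max = 0.4)
}

#' Generate synthetic uniaxial tensile curves
#'
#' Deterministic (given `seed`) stand-in for a multi-sample tensile
#' experiment: each sample is the truth polynomial evaluated on a jittered
#' strain grid, scaled by a per-sample lognormal stiffness factor (natural
#' inter-sample variability of the biomaterial) plus i.i.d. Gaussian stress
#' noise.
#'
#' @param n Number of sample curves (>= 1).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param truth_coeffs Polynomial coefficients of the underlying law
#'   (default the [default_material()] cubic).
#' @param noise_sd Gaussian stress noise SD (MPa), default 0.05.
#' @param strain_max Largest strain sampled, default 0.4.
#' @param points Points per curve, default 25.
#' @param stiffness_sdlog SD of the per-curve lognormal stiffness factor
#'   (default 0.1); 0 disables inter-sample variability.
#' @return A list of `n` [tensile_curve()] objects, with the truth
#'   coefficients attached as `attr(, "truth_coeffs")`.
#' @export
synth_tensile_curves <- function(n, seed = 1L, truth_coeffs = c(1, 5, 150),
                                 noise_sd = 0.05, strain_max = 0.4,
                                 points = 25L, stiffness_sdlog = 0.1) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  base <- seq(0, strain_max, length.out = points + 1L)[-1L]
  spacing <- strain_max / points
  truth <- function(e) {
    acc <- 0
    for (k in rev(seq_along(truth_coeffs))) acc <- (acc + truth_coeffs[k]) * e
    acc
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    jit <- stats::runif(points, -0.3, 0.3) * spacing
    strain <- sort(base + jit)
    strain <- pmax(strain, spacing * 0.05)
    # enforce strict monotonicity after jitter
    strain <- cummax(strain) + seq_len(points) * 1e-12
    fac <- if (stiffness_sdlog > 0) stats::rlnorm(1L, 0, stiffness_sdlog) else 1
    stress <- fac * truth(strain) + stats::rnorm(points, 0, noise_sd)
    out[[i]] <- tensile_curve(strain, stress)
  }
  attr(out, "truth_coeffs") <- truth_coeffs
  out
}

#' Read tensile curves from CSV
#'
#' Expects columns `sample_id`, `strain`, `stress_mpa`; one row per
#' measured point, grouped into one curve per `sample_id`.
#'
#' @param path CSV file path.
#' @return A list of [tensile_curve()] objects named by sample id.
#' @export
read_tensile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "strain", "stress_mpa")
  if (!all(need %in% names(df))) {
    stop("tensile CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$strain), ]
    tensile_curve(g$strain, g$stress_mpa)
  })
}

#' Write tensile curves to CSV
#'
#' @param curves A list of [tensile_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tensile_csv <- function(curves, path) {
  ids <- names(curves)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(curves))
  df <- do.call(rbind, Map(function(cv, id) {
    data.frame(sample_id = id, strain = cv$strain, stress_mpa = cv$stress)
  }, curves, ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / deserialise a material fit
#'
#' Round-trips a [material_fit()] through JSON (`.json`) or YAML
#' (`.yaml`/`.yml`), chosen by file extension.
#'
#' @param fit A [material_fit()].
#' @param path Output path.
#' @return `path` invisibly (`write_material_fit`); a [material_fit()]
#'   (`read_material_fit`).
#' @export
write_material_fit <- function(fit, path) {
  obj <- list(coeffs = unname(fit$coeffs), r2 = fit$r2,
              sigma_lim = fit$sigma_lim, density = fit$density,
              poisson = fit$poisson, strain_max = fit$strain_max)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_material_fit
#' @export
read_material_fit <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  material_fit(obj$coeffs, r2 = if (is.null(obj$r2)) NA_real_ else obj$r2,
               sigma_lim = obj$sigma_lim, density = obj$density,
               poisson = obj$poisson, strain_max = obj$strain_max)
}
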