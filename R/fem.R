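# Explicit-dynamics, total-Lagrangian membrane solver for leaflet opening.
#
# Constant-strain triangles carry in-plane Green-Lagrange strain only (no
# bending: the leaflet is thin, T << Rin).  The in-plane response is an
# isotropic plane-stress secant law built from the fitted uniaxial curve:
# E_sec(eps_eq) = sigma_fit(eps_eq)/eps_eq evaluated at the von-Mises
# equivalent Green strain (E_sec(0) = c1).  Quasi-static loading is
# approximated by explicit central-difference time stepping with selective
# mass scaling and mass-proportional damping, monitored through the
# kinetic-to-strain-energy ratio.  Unit system: mm, MPa, N, tonne, s.

#' Explicit solver configuration
#'
#' @param dt_scale Courant safety factor on the critical time step,
#'   in (0, 1], default 0.8.
#' @param damping_alpha Mass-proportional damping coefficient (1/s),
#'   default 400.  Dissipates the kinetic energy so the run approaches the
#'   quasi-static limit.
#' @param mass_scaling Density multiplier >= 1, default 400.  Enlarges the
#'   stable time step by sqrt(mass_scaling); admissible because the opening
#'   problem is treated as quasi-static and the kinetic energy fraction is
#'   monitored.
#' @param output_every Snapshot interval (s), default 0.02.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_scale = 0.8, damping_alpha = 400,
                          mass_scaling = 400, output_every = 0.02) {
  if (!is.numeric(dt_scale) || dt_scale <= 0 || dt_scale > 1) {
    stop("dt_scale must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(mass_scaling) || mass_scaling < 1) {
    stop("mass_scaling must be >= 1", call. = FALSE)
  }
  if (!is.numeric(damping_alpha) || damping_alpha < 0) {
    stop("damping_alpha must be >= 0", call. = FALSE)
  }
  if (!is.numeric(output_every) || output_every <= 0) {
    stop("output_every must be > 0", call. = FALSE)
  }
  structure(list(dt_scale = dt_scale, damping_alpha = damping_alpha,
                 mass_scaling = mass_scaling, output_every = output_every),
            class = "solver_config")
}

# Per-element reference quantities for the total-Lagrangian formulation:
# inverse reference shape matrix (in the element plane), reference area,
# characteristic length, and the lumped nodal mass.
fem_reference <- function(mesh, fit, config = solver_config()) {
  tris <- mesh$triangles
  p1 <- mesh$nodes[tris[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[tris[, 2L], , drop = FALSE] - p1
  e2 <- mesh$nodes[tris[, 3L], , drop = FALSE] - p1
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  two_area <- sqrt(rowSums(cr^2))
  if (any(two_area <= 2e-12)) {
    bad <- which(two_area <= 2e-12)[1L]
    stop("degenerate element ", bad, ": zero reference area", call. = FALSE)
  }
  A0 <- two_area / 2
  l1 <- sqrt(rowSums(e1^2))
  t1 <- e1 / l1
  nn <- cr / two_area
  t2 <- cbind(nn[, 2L] * t1[, 3L] - nn[, 3L] * t1[, 2L],
              nn[, 3L] * t1[, 1L] - nn[, 1L] * t1[, 3L],
              nn[, 1L] * t1[, 2L] - nn[, 2L] * t1[, 1L])
  cx <- rowSums(e2 * t1)
  cy <- rowSums(e2 * t2)
  det <- l1 * cy                       # = 2*A0 up to sign of local frame
  i11 <- cy / det
  i12 <- -cx / det
  i21 <- rep(0, length(det))
  i22 <- l1 / det

  elen <- sqrt(pmax(rowSums(e1^2),
                    rowSums(e2^2),
                    rowSums((e2 - e1)^2)))
  l_char <- two_area / elen            # 2*A/longest edge

  rho_eff <- fit$density * config$mass_scaling
  idx <- c(tris[, 1L], tris[, 2L], tris[, 3L])
  mcontrib <- rep(rho_eff * A0 * mesh$thickness / 3, 3L)
  mass <- numeric(nrow(mesh$nodes))
  rs <- rowsum(mcontrib, idx)
  mass[as.integer(rownames(rs))] <- rs[, 1L]
  if (any(mass <= 0)) {
    mass[mass <= 0] <- min(mass[mass > 0])  # isolated nodes: inert
  }

  list(t1 = tris[, 1L], t2 = tris[, 2L], t3 = tris[, 3L],
       i11 = i11, i12 = i12, i21 = i21, i22 = i22,
       A0 = A0, AT = A0 * mesh$thickness, l_char = l_char,
       idx = idx, mass = mass, n_nodes = nrow(mesh$nodes))
}

# One evaluation of the membrane response at nodal positions x.
# Returns internal nodal forces (-dW/dx), per-element 2nd Piola-Kirchhoff
# stress components in the element-local frame, Green strains, and the
# strain energy.
membrane_kernel <- function(ref, fit, x) {
  d1 <- x[ref$t2, , drop = FALSE] - x[ref$t1, , drop = FALSE]
  d2 <- x[ref$t3, , drop = FALSE] - x[ref$t1, , drop = FALSE]
  Fa <- d1 * ref$i11 + d2 * ref$i21
  Fb <- d1 * ref$i12 + d2 * ref$i22
  C11 <- rowSums(Fa * Fa)
  C22 <- rowSums(Fb * Fb)
  C12 <- rowSums(Fa * Fb)
  E11 <- 0.5 * (C11 - 1)
  E22 <- 0.5 * (C22 - 1)
  E12 <- 0.5 * C12
  Eeq <- sqrt(pmax(E11^2 - E11 * E22 + E22^2 + 3 * E12^2, 0))
  c1 <- fit$coeffs[[1L]]
  Es <- rep(c1, length(Eeq))
  nz <- Eeq > 1e-10
  if (any(nz)) Es[nz] <- stress_at_strain(fit, Eeq[nz]) / Eeq[nz]
  nu <- fit$poisson
  k <- Es / (1 - nu^2)
  S11 <- k * (E11 + nu * E22)
  S22 <- k * (E22 + nu * E11)
  S12 <- k * (1 - nu) * E12
  Pa <- Fa * S11 + Fb * S12
  Pb <- Fa * S12 + Fb * S22
  G1 <- ref$AT * (Pa * ref$i11 + Pb * ref$i12)
  G2 <- ref$AT * (Pa * ref$i21 + Pb * ref$i22)
  contrib <- rbind(G1 + G2, -G1, -G2)
  f <- matrix(0, ref$n_nodes, 3L)
  rs <- rowsum(contrib, ref$idx)
  f[as.integer(rownames(rs)), ] <- rs
  se <- 0.5 * sum(ref$AT * (S11 * E11 + S22 * E22 + 2 * S12 * E12))
  list(forces = f, S11 = S11, S22 = S22, S12 = S12,
       E11 = E11, E22 = E22, E12 = E12, strain_energy = se,
       d1 = d1, d2 = d2)
}

#' Internal membrane forces and element stresses
#'
#' Evaluates the total-Lagrangian constant-strain membrane response at
#' given nodal positions: deformation gradient per element, Green-Lagrange
#' in-plane strains, secant-modulus isotropic plane-stress response from
#' the fitted uniaxial law, integrated over the thickness.  The returned
#' nodal forces are the negative gradient of the strain energy and vanish
#' for rigid motions.
#'
#' @param mesh A `membrane_mesh` or `leaflet_mesh`.
#' @param fit A [material_fit()].
#' @param positions N x 3 current nodal positions (mm); defaults to the
#'   reference configuration.
#' @return A list with `forces` (N x 3, N), `stress` (M x 3: S11, S22, S12
#'   in MPa, element-local frame), `strain` (M x 3: E11, E22, E12),
#'   `vm` (M von Mises values, MPa) and `strain_energy` (mJ).
#' @export
internal_forces <- function(mesh, fit, positions = mesh$nodes) {
  ref <- fem_reference(mesh, fit)
  x <- as.matrix(positions)
  if (!all(is.finite(x)) || !all(dim(x) == dim(mesh$nodes))) {
    stop("positions must be a finite matrix conforming to mesh$nodes",
         call. = FALSE)
  }
  kk <- membrane_kernel(ref, fit, x)
  list(forces = kk$forces,
       stress = cbind(S11 = kk$S11, S22 = kk$S22, S12 = kk$S12),
       strain = cbind(E11 = kk$E11, E22 = kk$E22, E12 = kk$E12),
       vm = von_mises_plane_stress(kk$S11, kk$S22, kk$S12),
       strain_energy = kk$strain_energy)
}

#' Critical explicit time step
#'
#' Courant estimate `dt = dt_scale * l_min / c` with dilatational wave
#' speed `c = sqrt(E_max / (rho_eff * (1 - nu^2)))`, where `E_max` is the
#' largest tangent modulus over the fitted strain range, `rho_eff` the
#' mass-scaled density, and `l_min` the smallest element characteristic
#' length (twice area over longest edge).
#'
#' @param mesh A `membrane_mesh`.
#' @param fit A [material_fit()].
#' @param config A [solver_config()].
#' @return Stable time step in seconds.
#' @export
critical_time_step <- function(mesh, fit, config = solver_config()) {
  ref <- fem_reference(mesh, fit, config)
  grid <- seq(0, fit$strain_max, length.out = 201L)
  e_max <- max(abs(tangent_modulus(fit, grid)))
  rho_eff <- fit$density * config$mass_scaling
  cw <- sqrt(e_max / (rho_eff * (1 - fit$poisson^2)))
  config$dt_scale * min(ref$l_char) / cw
}

#' Plane-stress von Mises equivalent stress
#'
#' @param s11,s22,s12 In-plane stress components (MPa), vectorised.
#' @return `sqrt(s11^2 - s11*s22 + s22^2 + 3*s12^2)`.
#' @examples
#' von_mises_plane_stress(100, 50, 30) # sqrt(10200)
#' @export
von_mises_plane_stress <- function(s11, s22, s12) {
  if (!all(is.finite(c(s11, s22, s12)))) {
    stop("stress components must be finite", call. = FALSE)
  }
  sqrt(s11^2 - s11 * s22 + s22^2 + 3 * s12^2)
}

#' Simulate the leaflet opening phase
#'
#' Central-difference explicit integration from rest at `t = 0` to the end
#' of the waveform.  Each step applies the internal membrane forces, the
#' follower pressure (net transvalvular pressure on the current element
#' normals, positive net pressure pushing toward the aorta, +z), and
#' mass-proportional damping; the attachment nodes (surface F3) are pinned.
#' Snapshots of the deformed positions are recorded every
#' `config$output_every` seconds.
#'
#' @param mesh A `leaflet_mesh` (or any `membrane_mesh`).
#' @param fit A [material_fit()]; default [default_material()].
#' @param wf A [pressure_waveform()]; default 30 mmHg smoothstep over
#'   0-0.2 s.
#' @param config A [solver_config()].
#' @param t_total Total simulated time (s); defaults to `wf$t_end`.  Values
#'   beyond `wf$t_end` hold the peak pressure (settling time).
#' @return An object of class `opening_sim`: final `positions`,
#'   `element_stress` (M x 3), `element_vm`, an `energy` history data frame
#'   (`time`, `kinetic`, `strain`, `external_work`, `max_vm`), `snapshots`
#'   (list of times and positions), `ke_se_ratio` at the end, `dt`,
#'   `n_steps`, and the inputs.
#' @export
run_opening <- function(mesh, fit = default_material(),
                        wf = pressure_waveform(), config = solver_config(),
                        t_total = NULL) {
  if (is.null(t_total)) t_total <- wf$t_end
  ref <- fem_reference(mesh, fit, config)
  dt <- critical_time_step(mesh, fit, config)
  n_steps <- max(1L, as.integer(ceiling(t_total / dt)))
  dt <- t_total / n_steps
  every <- max(1L, as.integer(round(config$output_every / dt)))

  x <- mesh$nodes
  v <- matrix(0, nrow(x), 3L)
  pinned <- mesh$attachment_nodes
  inv_m <- 1 / ref$mass
  alpha <- config$damping_alpha
  work <- 0
  t <- 0

  snap_t <- numeric(0)
  snap_x <- list()
  hist <- list()
  record <- function(kk, ke) {
    hist[[length(hist) + 1L]] <<- c(
      time = t, kinetic = ke, strain = kk$strain_energy,
      external_work = work,
      max_vm = max(von_mises_plane_stress(kk$S11, kk$S22, kk$S12)))
    snap_t[length(snap_t) + 1L] <<- t
    snap_x[[length(snap_x) + 1L]] <<- x
  }

  kk <- membrane_kernel(ref, fit, x)
  record(kk, 0)

  for (s in seq_len(n_steps)) {
    p <- net_pressure(wf, t)
    # follower pressure: p * A * n per element = p/2 * (d1 x d2), third per node
    cr <- cbind(kk$d1[, 2L] * kk$d2[, 3L] - kk$d1[, 3L] * kk$d2[, 2L],
                kk$d1[, 3L] * kk$d2[, 1L] - kk$d1[, 1L] * kk$d2[, 3L],
                kk$d1[, 1L] * kk$d2[, 2L] - kk$d1[, 2L] * kk$d2[, 1L])
    fp_e <- (p / 6) * cr
    fp <- matrix(0, ref$n_nodes, 3L)
    rs <- rowsum(rbind(fp_e, fp_e, fp_e), ref$idx)
    fp[as.integer(rownames(rs)), ] <- rs

    a <- (kk$forces + fp) * inv_m
    v <- (v + dt * a) / (1 + alpha * dt)
    v[pinned, ] <- 0
    dx <- dt * v
    x <- x + dx
    t <- s * dt
    work <- work + sum(fp * dx)

    kk <- membrane_kernel(ref, fit, x)
    if (s %% 25L == 0L || s == n_steps) {
      if (!all(is.finite(x))) {
        stop("solver diverged (non-finite state) at step ", s, " (t = ",
             signif(t, 4), " s); reduce mass_scaling or the load",
             call. = FALSE)
      }
    }
    if (s %% every == 0L || s == n_steps) {
      ke <- 0.5 * sum(ref$mass * rowSums(v^2))
      record(kk, ke)
    }
  }

  energy <- as.data.frame(do.call(rbind, hist))
  ke_end <- energy$kinetic[nrow(energy)]
  se_end <- energy$strain[nrow(energy)]
  ratio <- ke_end / max(se_end, 1e-12)
  quasi_static <- ratio <= 0.10
  if (!quasi_static && se_end > 1e-9) {
    warning("kinetic/strain energy ratio ", signif(ratio, 3),
            " > 0.10 at end of run: result may not be quasi-static",
            call. = FALSE)
  }

  structure(list(
    mesh = mesh, fit = fit, waveform = wf, config = config,
    positions = x, displacement = x - mesh$nodes,
    element_stress = cbind(S11 = kk$S11, S22 = kk$S22, S12 = kk$S12),
    element_vm = von_mises_plane_stress(kk$S11, kk$S22, kk$S12),
    energy = energy, snapshots = list(time = snap_t, positions = snap_x),
    ke_se_ratio = ratio, quasi_static = quasi_static,
    dt = dt, n_steps = n_steps, time = t),
    class = "opening_sim")
}

#' @export
print.opening_sim <- function(x, ...) {
  cat("Leaflet opening simulation\n")
  cat(sprintf("  %d nodes, %d elements, %d steps of dt = %.3g s (t = %g s)\n",
              nrow(x$positions), length(x$element_vm), x$n_steps, x$dt,
              x$time))
  cat(sprintf("  max |displacement| = %.3f mm, max von Mises = %.3f MPa\n",
              max(sqrt(rowSums(x$displacement^2))), max(x$element_vm)))
  cat(sprintf("  kinetic/strain energy ratio at end: %.3g (%s)\n",
              x$ke_se_ratio,
              if (x$quasi_static) "quasi-static" else "NOT quasi-static"))
  invisible(x)
}

#' Plot simulation energy history
#'
#' Kinetic energy, strain energy and external work against time; a
#' quasi-static run ends with kinetic energy well below strain energy.
#'
#' @param x An `opening_sim`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.opening_sim <- function(x, ...) {
  e <- x$energy
  graphics::matplot(e$time, cbind(e$kinetic, e$strain, e$external_work),
                    type = "l", lty = 1, col = c("red3", "blue3", "grey30"),
                    xlab = "time (s)", ylab = "energy (mJ)", ...)
  graphics::legend("topleft", c("kinetic", "strain", "external work"),
                   lty = 1, col = c("red3", "blue3", "grey30"), bty = "n")
  invisible(x)
}
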