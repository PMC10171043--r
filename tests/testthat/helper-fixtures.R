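# Shared fixtures: tiny meshes and materials built in code.

# Single right triangle in the z = 0 plane, legs of length 1 mm.
single_tri_mesh <- function(thickness = 0.14) {
  membrane_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1L, 2L, 3L)), thickness = thickness)
}

# Linear-elastic material with modulus E (MPa).
linear_fit <- function(E, poisson = 0, strain_max = 0.5) {
  material_fit(c(E), poisson = poisson, strain_max = strain_max)
}

# Small leaflet used where the exact design does not matter.
small_leaflet <- function(nu = 5, ntheta = 9) {
  generate_leaflet_mesh(
    leaflet_params(H1 = 12, phi = 0, R = 30, Rin = 10, T = 0.3, Sec = 119),
    nu = nu, ntheta = ntheta)
}

# Table of published optimal designs (19/21/23 mm prosthesis sizes) used as
# a synthetic candidate pool for the selection logic.
optimal_design_records <- function() {
  df <- data.frame(
    design_id = 1:3,
    H1 = c(15.22, 18.81, 22.52),
    phi = c(5.17, -26.16, -7.94),
    R = c(40, 40, 40),
    Rin = c(9.38, 10.49, 11.56),
    T = c(0.14, 0.27, 0.19),
    Sec = c(119, 119, 119),
    do_percent = c(88.28, 84.48, 88.12),
    vm_mean = c(0.5, 0.3, 0.4),
    vm_max = c(3.62, 1.21, 1.87),
    vm_sd = c(0.4, 0.2, 0.3),
    status = "ok")
  df$li <- loss_index(df$do_percent, df$vm_max)
  df
}

expect_no_error <- function(expr) testthat::expect_error(expr, NA)
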