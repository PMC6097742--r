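#' Library of linear-elastic surgical patch materials
#'
#' Isotropic linear-elastic constants and sheet thicknesses for the patch
#' materials commonly used in pediatric cardiovascular reconstruction, plus
#' the native main-pulmonary-artery wall of a 9-year-old.  Biological and
#' synthetic grafts alike are modeled as nearly incompressible linear
#' elastic sheets over the operating strain range.
#'
#' @return a named list of `material_model` objects with fields `name`,
#'   `youngs_modulus` (Pa), `poissons_ratio`, `thickness` (m).
#' @export
#' @examples
#' material_library()[["PTFE"]]
material_library <- function() {
  mk <- function(name, nu, E_MPa, t_mm)
    structure(list(name = name, youngs_modulus = E_MPa * 1e6,
                   poissons_ratio = nu, thickness = t_mm * 1e-3),
              class = "material_model")
  list(
    `porcine xenopericardium` = mk("porcine xenopericardium", 0.39, 2.89, 0.4),
    `human pericardium`       = mk("human pericardium",       0.40, 3.40, 0.5),
    `PTFE`                    = mk("PTFE",                    0.31, 1.40, 0.7),
    `Dacron`                  = mk("Dacron",                  0.42, 1.19, 0.6),
    `MPA artery 9yr`          = mk("MPA artery 9yr",          0.45, 0.75, 1.0))
}

#' Look up a material by name
#'
#' @param name a key of [material_library()].
#' @return a `material_model`.
#' @export
material_lookup <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib))
    stop("unknown material '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[name]]
}

validate_material <- function(mat) {
  if (mat$youngs_modulus <= 0) stop("material invariant violated: E > 0")
  if (mat$poissons_ratio < 0 || mat$poissons_ratio >= 0.5)
    stop("material invariant violated: 0 <= nu < 0.5")
  if (mat$thickness <= 0) stop("material invariant violated: thickness > 0")
  invisible(mat)
}

#' Plane-stress forward model
#'
#' Isotropic linear elasticity under plane stress:
#' `sigma_x = E/(1 - nu^2) (eps_x + nu eps_y)` and symmetrically for y.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio (< 0.5).
#' @param strain_x,strain_y engineering strains.
#' @return a list with `stress_x`, `stress_y` (Pa).
#' @export
plane_stress_forward <- function(E, nu, strain_x, strain_y) {
  if (any(nu >= 0.5)) stop("nu must be < 0.5")
  f <- E / (1 - nu^2)
  list(stress_x = f * (strain_x + nu * strain_y),
       stress_y = f * (strain_y + nu * strain_x))
}

#' Synthesize a planar biaxial test dataset
#'
#' Emulates sinusoidal biaxial stretching of a square sample: both axes are
#' strained sinusoidally up to `peak_strain`, with a phase offset between the
#' axes so the strain path is non-proportional (proportional, strictly
#' equibiaxial paths cannot separate E from nu).  Stresses come from the
#' plane-stress forward model with optional multiplicative Gaussian noise.
#'
#' @param E,nu generating material constants.
#' @param peak_strain maximum engineering strain on each axis (default 0.20).
#' @param n_records number of sampled time points.
#' @param n_cycles number of loading cycles.
#' @param phase_offset phase shift (rad) between the two axes.
#' @param noise_level multiplicative noise standard deviation on stresses
#'   (0 = exact).
#' @param seed RNG seed, required when `noise_level > 0`.
#' @param sample_size square sample side length (m), metadata only.
#' @return a `biaxial_dataset`: data frame `records` with columns
#'   `t, eps_x, eps_y, sig_x, sig_y` plus protocol metadata.
#' @export
synth_biaxial <- function(E, nu, peak_strain = 0.20, n_records = 500,
                          n_cycles = 2, phase_offset = pi / 3,
                          noise_level = 0, seed = NULL,
                          sample_size = 0.010) {
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (noise_level > 0 && is.null(seed))
    stop("seed is required when noise_level > 0")
  t <- seq(0, n_cycles, length.out = n_records)
  eps_x <- peak_strain / 2 * (1 - cos(2 * pi * t))
  eps_y <- peak_strain / 2 * (1 - cos(2 * pi * t + phase_offset))
  s <- plane_stress_forward(E, nu, eps_x, eps_y)
  sx <- s$stress_x; sy <- s$stress_y
  if (noise_level > 0) {
    set.seed(seed)
    sx <- sx * (1 + stats::rnorm(n_records, 0, noise_level))
    sy <- sy * (1 + stats::rnorm(n_records, 0, noise_level))
  }
  structure(list(
    records = data.frame(t = t, eps_x = eps_x, eps_y = eps_y,
                         sig_x = sx, sig_y = sy),
    sample_size = sample_size,
    protocol = sprintf(
      "sinusoidal biaxial stretch to %g%%, phase offset %.2f rad, noise %g",
      100 * peak_strain, phase_offset, noise_level)),
    class = "biaxial_dataset")
}

#' Read / write a biaxial dataset as tabular text
#'
#' Tab-separated columns `t, eps_x, eps_y, sig_x, sig_y` in SI units.
#'
#' @param data a `biaxial_dataset`.
#' @param path file path.
#' @return `read_biaxial` returns a `biaxial_dataset`.
#' @export
write_biaxial <- function(data, path) {
  utils::write.table(data$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_biaxial
#' @export
read_biaxial <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("t", "eps_x", "eps_y", "sig_x", "sig_y")
  if (!all(need %in% names(rec)))
    stop("biaxial table must have columns: ", paste(need, collapse = ", "))
  structure(list(records = rec[need], sample_size = NA_real_,
                 protocol = paste("read from", path)),
            class = "biaxial_dataset")
}

#' Fit linear-elastic constants to biaxial data
#'
#' Least-squares fit of the plane-stress model to measured stress pairs over
#' a strain window (default `[0, 0.15]`, the operating strain range of the
#' main pulmonary artery).  The model is linear in the reparameterization
#' `C1 = E/(1-nu^2)`, `C2 = nu*C1`, so the minimizer of the summed squared
#' stress residuals over both channels is found by ordinary least squares
#' and mapped back to `(E, nu)`.
#'
#' @param data a `biaxial_dataset`.
#' @param strain_window numeric length-2: records are used when both strains
#'   lie inside the window.
#' @return list with `E` (Pa), `nu`, `residual_norm`, `r_squared` (per
#'   channel), `n_used`.  On a rank-deficient strain path (strictly
#'   proportional/equibiaxial data) a warning reports the only identifiable
#'   combination `E/(1-nu)`.
#' @export
fit_linear_elastic <- function(data, strain_window = c(0, 0.15)) {
  rec <- data$records
  keep <- rec$eps_x >= strain_window[1] & rec$eps_x <= strain_window[2] &
    rec$eps_y >= strain_window[1] & rec$eps_y <= strain_window[2]
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) < 10)
    stop("need >= 10 records inside the strain window (got ", nrow(rec), ")")
  # stacked design: sig_x = C1 ex + C2 ey ; sig_y = C2 ex + C1 ey
  y <- c(rec$sig_x, rec$sig_y)
  X <- rbind(cbind(rec$eps_x, rec$eps_y), cbind(rec$eps_y, rec$eps_x))
  qrX <- qr(X)
  if (qrX$rank < 2 ||
      abs(stats::cor(rec$eps_x, rec$eps_y)) > 1 - 1e-10) {
    # proportional path: only sigma = c * eps identifiable, c = E/(1-nu)
    xm <- (X[, 1] + X[, 2]) / 2
    co <- sum(xm * y) / sum(xm^2)
    warning("strain path is proportional: only E/(1-nu) is identifiable (= ",
            signif(co, 6), " Pa)")
    return(list(E = NA_real_, nu = NA_real_, identifiable = co,
                residual_norm = NA_real_, r_squared = c(NA, NA),
                n_used = nrow(rec)))
  }
  cf <- qr.coef(qrX, y)
  C1 <- cf[1]; C2 <- cf[2]
  nu <- C2 / C1
  E <- C1 * (1 - nu^2)
  fit <- X %*% cf
  res <- y - fit
  nx <- nrow(rec)
  r2 <- function(obs, hat) 1 - sum((obs - hat)^2) / sum((obs - mean(obs))^2)
  list(E = unname(E), nu = unname(nu),
       residual_norm = sqrt(sum(res^2)),
       r_squared = c(x = r2(rec$sig_x, fit[seq_len(nx)]),
                     y = r2(rec$sig_y, fit[nx + seq_len(nx)])),
       n_used = nx)
}
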