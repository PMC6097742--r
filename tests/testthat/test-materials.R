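test_that("material library holds the tabulated constants and rejects unknowns", {
  lib <- material_library()
  expect_setequal(names(lib),
                  c("porcine xenopericardium", "human pericardium", "PTFE",
                    "Dacron", "MPA artery 9yr"))
  expect_equal(lib[["PTFE"]]$youngs_modulus, 1.4e6)
  expect_equal(lib[["PTFE"]]$poissons_ratio, 0.31)
  expect_equal(lib[["PTFE"]]$thickness, 0.7e-3)
  expect_equal(lib[["MPA artery 9yr"]]$poissons_ratio, 0.45)
  expect_equal(lib[["MPA artery 9yr"]]$youngs_modulus, 0.75e6)
  expect_equal(lib[["porcine xenopericardium"]]$youngs_modulus, 2.89e6)
  expect_equal(lib[["human pericardium"]]$thickness, 0.5e-3)
  expect_equal(lib[["Dacron"]]$poissons_ratio, 0.42)
  expect_error(material_lookup("teflon"), "unknown material")
})

test_that("plane-stress forward model matches closed forms", {
  # equibiaxial: sigma = E eps / (1 - nu)
  s <- plane_stress_forward(1e6, 0.4, 0.1, 0.1)
  expect_equal(s$stress_x, 1e6 * 0.1 / (1 - 0.4), tolerance = 1e-12)
  expect_equal(s$stress_y, s$stress_x)
  # zero strain
  s0 <- plane_stress_forward(2e6, 0.3, 0, 0)
  expect_equal(c(s0$stress_x, s0$stress_y), c(0, 0))
  # nu = 0 decouples the axes
  sd <- plane_stress_forward(5e6, 0, 0.1, 0.3)
  expect_equal(sd$stress_x, 0.1 * 5e6)
  expect_equal(sd$stress_y, 0.3 * 5e6)
})

test_that("synthetic biaxial data honors the protocol and reproduces", {
  d <- synth_biaxial(2.89e6, 0.39, peak_strain = 0.20)
  expect_equal(max(d$records$eps_x), 0.20, tolerance = 1e-4)
  expect_equal(max(d$records$eps_y), 0.20, tolerance = 1e-3)
  # noise-free data equal the forward model exactly
  fw <- plane_stress_forward(2.89e6, 0.39, d$records$eps_x, d$records$eps_y)
  expect_equal(d$records$sig_x, fw$stress_x)
  # same seed -> identical dataset
  d1 <- synth_biaxial(1e6, 0.4, noise_level = 0.02, seed = 7)
  d2 <- synth_biaxial(1e6, 0.4, noise_level = 0.02, seed = 7)
  expect_identical(d1$records, d2$records)
  expect_error(synth_biaxial(1e6, 0.4, noise_level = 0.02),
               "seed is required")
})

test_that("least-squares fit recovers the generating constants", {
  d <- synth_biaxial(2.89e6, 0.39)
  fit <- fit_linear_elastic(d)
  expect_lt(abs(fit$E - 2.89e6) / 2.89e6, 1e-3)
  expect_lt(abs(fit$nu - 0.39), 1e-3 * 0.39)
  expect_lt(fit$residual_norm / max(abs(d$records$sig_x)), 1e-8)
  # 2% multiplicative noise, n = 500: modulus within 3%
  dn <- synth_biaxial(2.89e6, 0.39, n_records = 500, noise_level = 0.02,
                      seed = 11)
  fn <- fit_linear_elastic(dn)
  expect_lt(abs(fn$E - 2.89e6) / 2.89e6, 0.03)
  expect_gt(min(fn$r_squared), 0.99)
})

test_that("fit is scale-equivariant and flags proportional strain paths", {
  d <- synth_biaxial(1.4e6, 0.31)
  f1 <- fit_linear_elastic(d)
  d2 <- d
  d2$records$sig_x <- 3 * d$records$sig_x
  d2$records$sig_y <- 3 * d$records$sig_y
  f2 <- fit_linear_elastic(d2)
  expect_equal(f2$E / f1$E, 3, tolerance = 1e-9)
  expect_equal(f2$nu, f1$nu, tolerance = 1e-12)
  # strictly equibiaxial path: only E/(1-nu) identifiable
  deq <- synth_biaxial(1e6, 0.4, phase_offset = 0)
  expect_warning(feq <- fit_linear_elastic(deq), "proportional")
  expect_true(is.na(feq$E))
  expect_equal(feq$identifiable, 1e6 / (1 - 0.4), tolerance = 1e-6)
})

test_that("biaxial tabular text round-trips", {
  d <- synth_biaxial(1.19e6, 0.42, n_records = 50, noise_level = 0.01,
                     seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_biaxial(d, path)
  d2 <- read_biaxial(path)
  expect_equal(d2$records$sig_x, d$records$sig_x, tolerance = 1e-6)
  fit <- fit_linear_elastic(d2)
  expect_lt(abs(fit$E - 1.19e6) / 1.19e6, 0.1)
})
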