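# elastic_homog: voxel FE homogenization, directional modulus, anisotropy
# indices, octahedral shear strain, stimulus

test_that("a fully solid cube returns the analytic isotropic stiffness", {
  st <- homogenize_stiffness(make_phantom("solid_cube", grid = 6)$object,
                             nu = 0.3)
  lam <- 0.3 / (1.3 * 0.4); mu <- 1 / 2.6
  Cexp <- matrix(0, 6, 6)
  Cexp[1:3, 1:3] <- lam; diag(Cexp)[1:3] <- lam + 2 * mu
  diag(Cexp)[4:6] <- mu
  expect_equal(st$C, Cexp, tolerance = 1e-8)
  expect_equal(st$Ez, 1, tolerance = 1e-8)
  az <- anisotropy_az(st)
  expect_lt(az$AZ, 1e-7)
})

test_that("a vertical rod at nu = 0 gives Ez equal to its area fraction", {
  ph <- make_phantom("vertical_rod", grid = 16, f = 0.25)
  st <- suppressWarnings(homogenize_stiffness(ph$object, nu = 0))
  expect_equal(st$Ez, ph$truth$Ez_nu0, tolerance = 1e-8)
})

test_that("PCG and direct homogenization agree with a dense direct solve", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  d <- c(9, 9, 9)
  occ <- array(as.integer(runif(prod(d)) < 0.55), d)
  occ <- anisovor:::drop_floating_islands(occ)
  vol <- binary_volume(occ, pitch = 1)
  # dense oracle: assemble the full sparse system in R and solve directly
  Ke <- anisovor:::.hex_ke_cpp(0.3)
  nodes <- anisovor:::.fem_nodes_cpp(as.integer(occ), d[1], d[2], d[3])
  nn <- nrow(nodes); ndof <- 3 * nn
  NX <- d[1] + 1; NY <- d[2] + 1
  gid <- nodes[, 1] + NX * (nodes[, 2] + NY * nodes[, 3])
  idx_of <- integer(max(gid) + 1); idx_of[gid + 1] <- seq_len(nn)
  ti <- list(); tj <- list(); tx <- list(); cnt <- 0
  for (k in 0:(d[3] - 1)) for (j in 0:(d[2] - 1)) for (i in 0:(d[1] - 1)) {
    if (!occ[i + 1, j + 1, k + 1]) next
    loc <- integer(24)
    for (a in 0:7) {
      g <- (i + bitwAnd(a, 1)) +
        NX * ((j + bitwAnd(bitwShiftR(a, 1), 1)) +
              NY * (k + bitwAnd(bitwShiftR(a, 2), 1)))
      an <- idx_of[g + 1]
      loc[3 * a + 1:3] <- 3 * (an - 1) + 1:3
    }
    cnt <- cnt + 1
    ti[[cnt]] <- rep(loc, each = 24)
    tj[[cnt]] <- rep(loc, times = 24)
    tx[[cnt]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ndof, ndof))
  onb <- nodes[, 1] == 0 | nodes[, 1] == d[1] | nodes[, 2] == 0 |
    nodes[, 2] == d[2] | nodes[, 3] == 0 | nodes[, 3] == d[3]
  bdof <- rep(3 * (which(onb) - 1), each = 3) + 1:3
  fdof <- setdiff(seq_len(ndof), bdof)
  Cd <- matrix(0, 6, 6)
  for (case in 1:6) {
    ua <- anisovor:::affine_displacement(nodes, case)
    u <- as.numeric(t(ua))
    if (length(fdof))
      u[fdof] <- as.numeric(Matrix::solve(K[fdof, fdof],
                                          -K[fdof, bdof] %*% u[bdof]))
    Cd[, case] <- anisovor:::.fem_avg_stress_cpp(as.integer(occ),
                                                 d[1], d[2], d[3], 0.3, u)
  }
  Cd <- (Cd + t(Cd)) / 2
  for (solver in c("cg", "direct")) {
    st <- homogenize_stiffness(vol, nu = 0.3, solver = solver)
    expect_lt(norm(st$C - Cd, "F") / norm(Cd, "F"), 1e-6)
  }
})

test_that("directional modulus handles isotropic and transverse tensors", {
  Ciso <- make_phantom("isotropic_C", E = 1, nu = 0.25)$object
  D <- solve(Ciso)
  set.seed(2)
  for (q in 1:5) {
    n <- rnorm(3)
    expect_equal(directional_modulus(D, n), 1, tolerance = 1e-10)
    expect_equal(directional_modulus(D, n), directional_modulus(D, -n))
  }
  Ct <- make_phantom("transverse_C")$object
  Dt <- solve(Ct)
  # closed form: E_z = 1 / D33, E_x = 1 / D11
  expect_equal(directional_modulus(Dt, c(0, 0, 1)), 1 / Dt[3, 3])
  expect_equal(directional_modulus(Dt, c(1, 0, 0)),
               directional_modulus(Dt, c(0, 1, 0)))
})

test_that("anisotropy indices have their algebraic identities", {
  Ciso <- make_phantom("isotropic_C", E = 2, nu = 0.3)$object
  expect_equal(anisotropy_at(Ciso), 1, tolerance = 1e-12)
  expect_lt(anisotropy_az(solve(Ciso))$AZ, 1e-10)
  # AZ from a hand-made field
  expect_equal(1 - 0.8 / 1.0, 0.2)
  # axis-relabelling invariance of AT
  set.seed(8)
  A <- matrix(rnorm(36), 6); C <- A %*% t(A) + 6 * diag(6)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(anisotropy_at(permute_voigt(C, perm)), anisotropy_at(C),
                 tolerance = 1e-12)
  # pathological tensor with (C11+C22+C33) == (C12+C13+C23) is rejected
  Cp <- matrix(1, 6, 6)
  expect_error(anisotropy_at(Cp), "denominator")
})

test_that("normalized vertical stiffness ratio", {
  expect_equal(normalized_ez(0.012, 0.010), 1.2)
  expect_equal(normalized_ez(3, 3), 1)
  expect_error(normalized_ez(1, 0), "positive")
})

test_that("octahedral shear strain identities", {
  expect_equal(octahedral_shear(-0.01, 0, 0), (2 / 3) * 0.01 * sqrt(2))
  expect_equal(octahedral_shear(0.005, 0.005, 0.005), 0)
  expect_equal(octahedral_shear(1, -1, 0), (2 / 3) * sqrt(6))
})

test_that("octahedral strain of a uniform rod equals the uniaxial state", {
  # rod at nu = 0 compressed 1%: strain (-0.01, 0, 0) everywhere
  ph <- make_phantom("vertical_rod", grid = 12, f = 0.25)
  sf <- octahedral_strain(ph$object, "uniaxial", macro_strain = 0.01, nu = 0)
  expect_equal(unname(sf$summary[2]), (2 / 3) * 0.01 * sqrt(2),
               tolerance = 1e-6)
  # hydrostatic-free check: gamma_oct >= 0 everywhere
  expect_true(all(sf$gamma_oct >= 0))
})

test_that("strip load matches the plane-strain analytic state on a wall", {
  # solid wall spanning x and z (internal surface on its y sides)
  occ <- array(0L, c(10, 10, 10))
  occ[, 1:5, ] <- 1L
  wall <- binary_volume(occ, pitch = 1)
  nu <- 0.3; E <- 1
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  su <- octahedral_strain(wall, "uniaxial", nu = nu)
  g_uni <- octahedral_shear(-0.01, nu * 0.01, nu * 0.01)
  expect_equal(unname(su$summary[2]), g_uni, tolerance = 1e-3)
  # strip: eps_x = 0, sigma_y = 0 -> eps_y = -lam * eps_z / (lam + 2 mu)
  ss <- octahedral_strain(wall, "strip", nu = nu)
  ey <- -lam * (-0.01) / (lam + 2 * mu)
  g_strip <- octahedral_shear(0, ey, -0.01)
  expect_equal(unname(ss$summary[2]), g_strip, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(g_uni, g_strip, tolerance = 0.01)))
})

test_that("mechanical stimulus follows S = gamma/a + v/b", {
  expect_equal(mechanical_stimulus(0, 0, a = 0.0375, b = 3e-6), 0)
  expect_equal(mechanical_stimulus(0.0375, 0, a = 0.0375, b = 3e-6), 1)
  expect_equal(mechanical_stimulus(0.0375, 3e-6, a = 0.0375, b = 3e-6), 2)
  expect_error(mechanical_stimulus(1, 0, a = -1, b = 1), "positive")
})

test_that("Voigt-Reuss bounds hold for a reduced scaffold", {
  vol <- reference_volume(0.9, scale = 0.1)
  st <- homogenize_stiffness(vol, nu = 0.3)
  f <- st$solid_fraction
  expect_lte(st$Ez, 1 - porosity(vol) + 0.01)
  expect_gt(st$Ez, 0)
})
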