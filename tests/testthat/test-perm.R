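# perm_homog: pore Laplace solves, permeability tensor, scaling fit

test_that("an all-pore cube has an exactly linear pressure and K = I", {
  vol <- make_phantom("empty_cube", grid = 12)$object
  sol <- solve_pressure(vol, "z")
  expected <- array(rep(seq_len(12) - 0.5, each = 144), c(12, 12, 12))
  expect_equal(sol$p, expected, tolerance = 1e-9)
  perm <- permeability_tensor(vol)
  expect_equal(perm$K, diag(3), tolerance = 1e-6)
  expect_lt(perm$A_kappa, 1e-6)
})

test_that("a straight channel gives K_zz equal to its section fraction", {
  ph <- make_phantom("axis_channel", grid = 16, c_frac = 0.25)
  perm <- suppressWarnings(permeability_tensor(ph$object))
  expect_equal(perm$K[3, 3], ph$truth$K_zz, tolerance = 1e-3)
  expect_equal(perm$K[1, 1], 0)
  expect_equal(perm$K[2, 2], 0)
  expect_equal(perm$A_kappa, 1, tolerance = 1e-6)
  # pressure is linear in z inside the channel
  sol <- solve_pressure(ph$object, "z")
  side <- which(ph$object$occ[, 9, 9] == 0)
  p_line <- sol$p[side[1], side[1], ]
  expect_equal(diff(p_line), rep(1, 15), tolerance = 1e-8)
})

test_that("solid cube and sealed axes error or warn appropriately", {
  expect_error(solve_pressure(make_phantom("solid_cube", 8)$object, "z"),
               "percolate")
  expect_error(permeability_tensor(make_phantom("solid_cube", 8)$object),
               "no axis")
  expect_warning(permeability_tensor(make_phantom("axis_channel", 12,
                                                  c_frac = 0.25)$object),
                 "zero column")
})

test_that("anisotropy index arithmetic on a diagonal tensor", {
  K <- diag(c(2, 1, 1))
  evals <- sort(eigen(K, symmetric = TRUE)$values)
  expect_equal(1 - evals[1] / evals[3], 0.5)
})

test_that("flux is conserved and K is symmetric", {
  vol <- reference_volume(0.9, scale = 0.08)
  d <- dim(vol$occ)
  sol <- solve_pressure(vol, "z")
  # exact discrete conservation: the net flux entering the free (interior)
  # pore cells from the Dirichlet boundary cells is zero, i.e. the inflow
  # through the RVE faces balances the outflow
  p <- sol$p
  pore <- vol$occ == 0L
  fixed <- array(FALSE, d)
  fixed[1, , ] <- fixed[d[1], , ] <- TRUE
  fixed[, 1, ] <- fixed[, d[2], ] <- TRUE
  fixed[, , 1] <- fixed[, , d[3]] <- TRUE
  fixed <- fixed & pore
  free <- pore & !fixed
  net <- 0; gross <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    idx <- which(free, arr.ind = TRUE)
    nb <- sweep(idx, 2, s, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    idx <- idx[ok, , drop = FALSE]; nb <- nb[ok, , drop = FALSE]
    isfx <- fixed[nb]
    f <- p[nb[isfx, , drop = FALSE]] - p[idx[isfx, , drop = FALSE]]
    net <- net + sum(f)
    gross <- gross + sum(abs(f))
  }
  expect_lt(abs(net) / gross, 1e-6)
  perm <- permeability_tensor(vol)
  expect_lte(perm$asymmetry, 1e-3)
  expect_true(all(sort(perm$evals) >= -1e-9))
  expect_lte(max(diag(perm$K)), 1)
})

test_that("permeability decreases with solid fraction", {
  k <- vapply(c(0.9, 0.75), function(phi) {
    v <- reference_volume(phi, scale = 0.08)
    permeability_tensor(v)$K[3, 3]
  }, numeric(1))
  expect_gt(k[1], k[2])
})

test_that("fit_permeability_scaling recovers exact linear data", {
  x_tbsp <- c(10, 20, 30)
  phi <- c(0.6, 0.75, 0.9)
  x <- x_tbsp^2 * phi^1.5
  k <- 0.002 * x + 0.01
  fit <- fit_permeability_scaling(k, x_tbsp, phi)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_permeability_scaling(k[1:2], x_tbsp[1:2], phi[1:2]),
               "at least 3")
  expect_error(fit_permeability_scaling(c(1, 2, 3), c(5, 5, 5),
                                        c(0.7, 0.7, 0.7)),
               "at least 3")
})
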