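# morphometry: local thickness, MIL fabric / DA, Gaussian curvature

test_that("local thickness of a ball is its digital inscribed diameter", {
  ph <- make_phantom("ball", grid = 32, r = 8)
  lt <- local_thickness(ph$object, "solid")
  # one inscribed sphere covers (almost all of) the digital ball; its
  # radius is the largest EDT value: the distance from the central voxel
  # to the nearest background voxel centre (slightly under the continuum
  # r = 8 because diagonal background voxels are closer)
  occ <- ph$object$occ
  solid <- which(occ == 1, arr.ind = TRUE)
  bg <- which(occ == 0, arr.ind = TRUE)
  rmax <- 0
  for (q in seq_len(nrow(solid))) {
    d2 <- min((bg[, 1] - solid[q, 1])^2 + (bg[, 2] - solid[q, 2])^2 +
                (bg[, 3] - solid[q, 3])^2)
    rmax <- max(rmax, sqrt(d2))
  }
  modal <- as.numeric(names(sort(table(lt$values), decreasing = TRUE))[1])
  expect_equal(modal, 2 * rmax, tolerance = 1e-9)
  expect_equal(modal, 16, tolerance = 0.12)  # near the continuum diameter
})

test_that("local thickness of a slab equals the plate thickness", {
  # grid 30 = gap, plate, gap, plate, gap: both plates interior
  ph <- make_phantom("slab_stack", grid = 30, plate = 6, gap = 6)
  lt <- local_thickness(ph$object, "solid")
  # plates are infinite in x, y: inscribed sphere diameter = plate thickness
  expect_equal(median(lt$values), 6, tolerance = 0.2)
  # spacing: evaluate in the interior gap (edge gaps are open to the array
  # boundary and read as thicker, like pores open to the scan boundary)
  sp <- local_thickness(ph$object, "pore")
  expect_equal(median(sp$map[, , 14:17]), 6, tolerance = 0.2)
})

test_that("interior thickness of a thick rod matches its side", {
  ph <- make_phantom("vertical_rod", grid = 32, f = 0.25)
  side <- round(sqrt(0.25) * 32)
  lt <- local_thickness(ph$object, "solid")
  # the inscribed sphere of a square rod has the side as diameter
  expect_equal(max(lt$values), side, tolerance = 1)
})

test_that("local thickness is invariant under 90-degree rotations", {
  vol <- reference_volume(0.75, scale = 0.08)
  lt <- sort(local_thickness(vol, "solid")$values)
  rot <- binary_volume(aperm(vol$occ, c(3, 1, 2)), pitch = vol$pitch)
  lt_rot <- sort(local_thickness(rot, "solid")$values)
  expect_identical(lt, lt_rot)
})

test_that("thickness errors on an empty phase", {
  expect_error(local_thickness(make_phantom("empty_cube", 8)$object, "solid"),
               "empty")
})

test_that("MIL fabric: sphere is isotropic, plates are strongly anisotropic", {
  set.seed(10)
  ball <- make_phantom("ball", grid = 40, r = 16)$object
  fab <- mil_fabric(ball, n_directions = 129)
  expect_lte(fab$DA, 0.05)
  expect_true(fab$DA >= 0 && fab$DA < 1)

  plates <- make_phantom("slab_stack", grid = 40, plate = 5, gap = 5)$object
  set.seed(10)
  fabp <- mil_fabric(plates, n_directions = 129)
  expect_gte(fabp$DA, 0.5)
  # eigenvector of the largest eigenvalue (most intercepts) along z
  ang <- acos(abs(fabp$evecs[3, 3])) * 180 / pi
  expect_lte(ang, 5)
})

test_that("MIL errors on single-phase volumes", {
  expect_error(mil_fabric(make_phantom("solid_cube", 8)$object), "phases")
})

test_that("angle-deficit curvature matches the sphere and Gauss-Bonnet", {
  ph <- make_phantom("ball", grid = 36, r = 12)
  mesh <- extract_mesh(ph$object)
  curv <- gaussian_curvature(mesh)
  # total curvature = 2 pi chi = 4 pi for genus 0, exact for angle deficits
  expect_equal(sum(curv$deficit), 4 * pi, tolerance = 1e-8)
  # area-weighted mean K within 10% of 1/r^2
  mk <- sum(curv$K * curv$vertex_area) / sum(curv$vertex_area)
  expect_lt(abs(mk - 1 / 144) / (1 / 144), 0.10)
  # K <= max(k1^2, k2^2) pointwise
  expect_true(all(curv$K <= pmax(curv$k1^2, curv$k2^2) + 1e-9))
})

test_that("cylinder sides have near-zero Gaussian curvature", {
  g <- 40; r <- 8
  ax <- seq_len(g) - 0.5 - g / 2
  occ <- array(0L, c(g, g, g))
  for (k in seq_len(g))
    occ[, , k] <- as.integer(outer(ax^2, ax^2, "+") <= r^2)
  mesh <- extract_mesh(binary_volume(occ, pitch = 1))
  curv <- gaussian_curvature(mesh)
  side <- abs(mesh$vertices[, 3] - g / 2) < g / 4  # away from the caps
  mk <- median(curv$K[side])
  expect_lt(abs(mk), 0.1 / r^2)
})

test_that("scaffold surfaces are dominated by non-positive curvature", {
  # saddle-dominated strut network: the area-majority of the surface has
  # K <= 0 (measured ~0.63 at desk scale, stable from scale 0.20 to 0.25)
  vol <- reference_volume(0.75, scale = 0.2)
  curv <- gaussian_curvature(extract_mesh(vol))
  frac <- sum(curv$vertex_area[curv$K <= 0]) / sum(curv$vertex_area)
  expect_gte(frac, 0.5)
})
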