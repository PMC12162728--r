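# voxel_forge module: rasterization, smoothing, cropping, porosity, meshing

test_that("rasterize_edges equals the exhaustive distance oracle bitwise", {
  # single axis-aligned central segment
  nodes <- rbind(c(6, 16, 16), c(26, 16, 16))
  g <- anisovor:::new_edge_graph(nodes, cbind(1, 2), L = 32)
  vol <- rasterize_edges(g, 32, thickness = 6)
  expect_identical(vol$occ, raster_oracle(g, 32, 6))
  expect_equal(sum(vol$occ), sum(raster_oracle(g, 32, 6)))

  # small random graphs, bitwise agreement
  set.seed(4)
  for (rep in 1:2) {
    nodes <- matrix(runif(12, 4, 20), 4, 3)
    g <- anisovor:::new_edge_graph(nodes, rbind(c(1, 2), c(2, 3), c(3, 4)),
                                   L = 24)
    vol <- rasterize_edges(g, 24, thickness = 5)
    expect_identical(vol$occ, raster_oracle(g, 24, 5))
  }
})

test_that("rasterization always covers segment endpoints' voxels", {
  nodes <- rbind(c(5.5, 5.5, 5.5), c(10.5, 9.5, 8.5))
  g <- anisovor:::new_edge_graph(nodes, cbind(1, 2), L = 16)
  expect_warning(vol <- rasterize_edges(g, 16, thickness = 1.2),
                 "thickness")
  expect_equal(vol$occ[6, 6, 6], 1L)
  expect_equal(vol$occ[11, 10, 9], 1L)
})

test_that("collinear touching segments rasterize like one long segment", {
  a <- c(4, 8, 8); m <- c(8, 8, 8); b <- c(14, 8, 8)
  g1 <- anisovor:::new_edge_graph(rbind(a, m, b),
                                  rbind(c(1, 2), c(2, 3)), L = 16)
  g2 <- anisovor:::new_edge_graph(rbind(a, b), cbind(1, 2), L = 16)
  expect_identical(rasterize_edges(g1, 16, 4)$occ,
                   rasterize_edges(g2, 16, 4)$occ)
})

test_that("porosity is one minus mean occupancy", {
  expect_equal(porosity(make_phantom("empty_cube", grid = 4)$object), 1)
  expect_equal(porosity(make_phantom("solid_cube", grid = 4)$object), 0)
  occ <- array(0L, c(2, 2, 2)); occ[1:4] <- 1L
  expect_equal(porosity(binary_volume(occ)), 0.5)
})

test_that("smooth_to_porosity hits the target volume exactly", {
  vol <- reference_volume(0.75, scale = 0.08)
  # the generator already smooths; re-smooth to each paper target
  for (phi in c(0.60, 0.75, 0.90)) {
    sm <- smooth_to_porosity(vol, phi, n_iter = 10)
    expect_lte(abs(porosity(sm) - phi), 0.005)
  }
  # monotone: solid fraction strictly decreasing with target porosity
  s <- vapply(c(0.60, 0.75, 0.90),
              function(phi) sum(smooth_to_porosity(vol, phi,
                                                   n_iter = 5)$occ),
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(smooth_to_porosity(vol, 1.2), "porosity")
  expect_error(smooth_to_porosity(vol, 0), "porosity")
})

test_that("a ball at its own porosity is a fixed point of the smoothing", {
  ph <- make_phantom("ball", grid = 32, r = 9)
  vol <- ph$object
  sm <- smooth_to_porosity(vol, porosity(vol), n_iter = 20)
  # Hausdorff distance <= 1 voxel between input and output
  d <- dim(vol$occ)
  changed <- which(sm$occ != vol$occ, arr.ind = TRUE)
  if (nrow(changed)) {
    surf <- which(vol$occ == 1, arr.ind = TRUE)
    for (q in seq_len(nrow(changed))) {
      dd <- sqrt(rowSums((t(t(surf) - changed[q, ]))^2))
      expect_lte(min(dd), sqrt(3))
    }
  }
  succeed()
})

test_that("smoothing does not increase surface area at fixed volume", {
  vol <- reference_volume(0.75, scale = 0.08)
  area <- function(v) mesh_area_volume(extract_mesh(v))["area"]
  prev <- area(smooth_to_porosity(vol, 0.75, n_iter = 1))
  cur <- vol
  for (chunk in 1:3) {  # sampled every 10 iterations
    cur <- smooth_to_porosity(cur, 0.75, n_iter = 10)
    a <- area(cur)
    expect_lte(a, prev * 1.01)
    prev <- a
  }
})

test_that("crop_boundary removes layers and commutes with translation", {
  vol <- binary_volume(array(1L, c(40, 40, 40)))
  expect_equal(dim(crop_boundary(vol, 15)$occ), c(10, 10, 10))
  expect_identical(crop_boundary(vol, 0), vol)
  v31 <- binary_volume(array(1L, c(31, 31, 31)))
  expect_equal(dim(crop_boundary(v31, 15)$occ), c(1, 1, 1))
  expect_error(crop_boundary(binary_volume(array(1L, c(30, 30, 30))), 15),
               "too small")

  # crop(rasterize(translate)) == translate(crop(rasterize)) away from edges
  nodes <- rbind(c(10, 12, 12), c(16, 14, 12))
  g1 <- anisovor:::new_edge_graph(nodes, cbind(1, 2), L = 24)
  g2 <- anisovor:::new_edge_graph(nodes + 1, cbind(1, 2), L = 24)  # +1 voxel
  r1 <- crop_boundary(rasterize_edges(g1, 24, 4), 4)$occ
  r2 <- crop_boundary(rasterize_edges(g2, 24, 4), 4)$occ
  n <- dim(r1)[1]
  expect_identical(r1[1:(n - 1), 1:(n - 1), 1:(n - 1)],
                   r2[2:n, 2:n, 2:n])
})

test_that("calibrated thickness reproduces the target raster porosity", {
  g <- reference_graph("isotropic", 1)
  th <- calibrate_thickness(g, 50, 0.75)
  vol <- suppressWarnings(rasterize_edges(g, 50, th))
  expect_lte(abs(porosity(vol) - 0.75), 0.01)
})
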