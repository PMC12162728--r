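# surface extraction, mesh metrics, STL output

test_that("extract_mesh of a ball matches analytic area and volume", {
  ph <- make_phantom("ball", grid = 32, r = 10)
  mesh <- extract_mesh(ph$object)
  expect_true(mesh_is_watertight(mesh))
  av <- mesh_area_volume(mesh)
  expect_lt(abs(av["area"] - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(abs(av["volume"] - (4 / 3) * pi * 1000) / ((4 / 3) * pi * 1000),
            0.05)
})

test_that("a single solid voxel yields a closed mesh with positive volume", {
  occ <- array(0L, c(5, 5, 5)); occ[3, 3, 3] <- 1L
  mesh <- extract_mesh(binary_volume(occ, pitch = 1), presmooth_sigma = 0)
  expect_true(mesh_is_watertight(mesh))
  expect_gt(mesh_area_volume(mesh)["volume"], 0)
})

test_that("mesh volume matches the voxel count within 2% on scaffolds", {
  # no pre-filter: the raw occupancy isosurface is the volume-faithful one
  vol <- reference_volume(0.75, scale = 0.13)
  av <- mesh_area_volume(extract_mesh(vol, presmooth_sigma = 0))
  vox_vol <- sum(vol$occ) * vol$pitch^3
  expect_lt(abs(av["volume"] - vox_vol) / vox_vol, 0.02)
})

test_that("extraction needs both phases", {
  expect_error(extract_mesh(make_phantom("solid_cube", grid = 4)$object),
               "phases")
  expect_error(extract_mesh(make_phantom("empty_cube", grid = 4)$object),
               "phases")
})

test_that("binary STL files round-trip face counts", {
  ph <- make_phantom("ball", grid = 16, r = 5)
  mesh <- extract_mesh(ph$object)
  path <- tempfile(fileext = ".stl")
  write_stl(mesh, path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_equal(nf, nrow(mesh$faces))
  expect_equal(file.size(path), 84 + 50 * nf)
})
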