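test_that("swept tube reproduces the closed-form cylinder area", {
  g <- generate_tube_mesh(9, radius = 1.25, resolution = 0.2)
  expect_lt(abs(sum(g$mesh$face_areas) - 2 * pi * 1.25 * 9) / (2 * pi * 1.25 * 9),
            0.02)
  expect_length(g$mesh$boundary_loops, 2L)
})

test_that("bifurcation mesh is an open tube with three boundary rims", {
  ph <- get_phantom()
  mesh <- ph$geometry$mesh
  expect_length(mesh$boundary_loops, 3L)
  expect_true(all(mesh$face_areas > 0))
  expect_true(any(mesh$meta$ostium_rim_face))
  expect_true(all(c("main", "side") %in% mesh$meta$face_group))
})

test_that("mesh generation is deterministic and validates its inputs", {
  g1 <- generate_bifurcation_mesh(default_spec, 0.35)
  g2 <- generate_bifurcation_mesh(default_spec, 0.35)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$mesh$faces, g2$mesh$faces)
  # coarser than the throat radius: refuse
  expect_error(generate_bifurcation_mesh(default_spec, 0.85), "throat")
})

test_that("centerline frames are orthonormal and twist-free", {
  cl <- straight_centerline(20, ds = 0.5)
  expect_equal(unname(rowSums(cl$tangent * cl$normal)), rep(0, nrow(cl$points)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(cl$normal^2)), rep(1, nrow(cl$points)),
               tolerance = 1e-9)
  # parallel transport on a curved polyline keeps the normal continuous
  t <- seq(0, pi / 2, length.out = 50)
  arc <- centerline(cbind(10 * cos(t), 10 * sin(t), 0))
  dn <- sqrt(rowSums(diff(arc$normal)^2))
  expect_lt(max(dn), 0.1)
  expect_equal(unname(rowSums(arc$normal * arc$tangent)),
               rep(0, 50), tolerance = 1e-9)
})

test_that("meshes round-trip through PLY and OBJ and read from STL", {
  g <- get_tiny_tube()
  ply <- withr::local_tempfile(fileext = ".ply")
  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh_ply(g$mesh, ply)
  write_mesh_obj(g$mesh, obj)
  m1 <- read_mesh_ply(ply)
  m2 <- read_mesh_obj(obj)
  expect_equal(m1$vertices, unname(g$mesh$vertices), tolerance = 1e-7)
  expect_identical(m1$faces, unname(g$mesh$faces))
  expect_equal(m2$vertices, unname(g$mesh$vertices), tolerance = 1e-7)
  expect_identical(m2$faces, unname(g$mesh$faces))

  stl <- withr::local_tempfile(fileext = ".stl")
  v <- g$mesh$vertices; f <- g$mesh$faces
  lines <- c("solid tube")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               paste("vertex", tri[, 1], tri[, 2], tri[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid tube"), stl)
  m3 <- read_mesh_stl(stl)
  expect_equal(sum(m3$face_areas), sum(g$mesh$face_areas), tolerance = 1e-6)
})
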