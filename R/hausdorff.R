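#' Symmetric mean Hausdorff distance between two triangle meshes
#'
#' Computes the exact distance from every vertex of mesh A to the surface of
#' mesh B and vice versa, and returns the average of the two mean distances
#' (mm). This is the mean (not maximum) Hausdorff distance commonly used to
#' compare a reconstructed lumen surface against the ground-truth phantom.
#'
#' @param meshA,meshB [surface_mesh()] objects.
#' @return Mean symmetric surface distance in mm.
#' @examples
#' g <- generate_tube_mesh(9, radius = 1.25, resolution = 0.5)
#' mean_hausdorff(g$mesh, g$mesh) # 0
#' @export
mean_hausdorff <- function(meshA, meshB) {
  stopifnot(inherits(meshA, "surface_mesh"), inherits(meshB, "surface_mesh"))
  dAB <- .point_mesh_distances(meshA$vertices, meshB$vertices, meshB$faces)
  dBA <- .point_mesh_distances(meshB$vertices, meshA$vertices, meshA$faces)
  (mean(dAB) + mean(dBA)) / 2
}

#' Distances from points to a triangle mesh surface
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [surface_mesh()].
#' @return Numeric vector of exact point-to-surface distances (mm).
#' @export
point_mesh_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  points <- matrix(as.numeric(points), ncol = 3)
  .point_mesh_distances(points, mesh$vertices, mesh$faces)
}
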