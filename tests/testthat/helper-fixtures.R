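# Shared fixtures, all generated in code.

# coarse pelvic phantom for fast course-level tests (4 mm grid)
small_phantom <- function(seed = 1) {
  make_phantom(phantom_config(dim = c(64, 64, 32), spacing = c(4, 4, 4),
                              seed = seed))
}

# uniform dose cube on a simple grid
uniform_dose <- function(value = 50.4, dim = c(24, 24, 16),
                         spacing = c(2, 2, 2)) {
  org <- -(dim - 1) / 2 * spacing
  dose_grid(array(value, dim), spacing, org)
}

# box-shaped structure mask centred on the grid (half-widths in mm)
box_mask <- function(name, half_mm, dim, spacing, center = c(0, 0, 0)) {
  org <- -(dim - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) org[a] + (seq_len(dim[a]) - 1) * spacing[a])
  inx <- abs(ax[[1]] - center[1]) <= half_mm[1]
  iny <- abs(ax[[2]] - center[2]) <= half_mm[2]
  inz <- abs(ax[[3]] - center[3]) <= half_mm[3]
  m <- outer(outer(inx, iny, `&`), inz, `&`)
  structure_mask(name, m, spacing, org)
}

# slab world for the path-length mechanism tests: water body occupying
# |y| <= body_half_mm on a 5 mm grid, a central target box, uniform planned
# dose; extra/removed material layers are set by editing density layers
slab_world <- function(dim = c(40, 41, 16), spacing = c(5, 5, 5),
                       body_half_mm = 50) {
  # odd y-dimension puts voxel centres on multiples of 5 mm, so material
  # layers can be addressed by their physical y coordinate
  org <- -(dim - 1) / 2 * spacing
  yax <- org[2] + (seq_len(dim[2]) - 1) * spacing[2]
  dens <- array(0, dim)
  dens[, abs(yax) <= body_half_mm, ] <- 1
  planned <- dose_grid(array(50.4, dim), spacing, org)
  ctv <- box_mask("CTV", c(20, 10, 15), dim, spacing)
  list(dim = dim, spacing = spacing, origin = org, yaxis = yax,
       density = dens, planned = planned, ctv = ctv)
}

# exhaustive threshold-sweep oracle for Dq%: largest voxel dose d such that
# the volume fraction receiving >= d is at least q/100
sweep_dq <- function(doses, q) {
  cand <- sort(unique(doses))
  frac <- vapply(cand, function(d) mean(doses >= d), 0)
  # tolerance keeps rank boundaries stable when q was printed as 100*k/n
  max(cand[frac >= q / 100 - 1e-12])
}

expect_same_grid_values <- function(a, b, tol = 0) {
  expect_equal(dim(first <- if (!is.null(a$dose)) a$dose else a$voxels),
               dim(second <- if (!is.null(b$dose)) b$dose else b$voxels))
  if (tol == 0) expect_identical(first, second)
  else expect_lt(max(abs(first - second)), tol)
}
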