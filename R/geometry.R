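#' Capillary unit-cell geometry
#'
#' Geometry of the periodic skin/capillary model: a skin slab of thickness
#' \code{H} containing \code{n_layers} parallel layers of capillaries whose
#' centers sit on the corners of equilateral triangles with side \code{a}.
#' The first and last layers lie at depth \code{h} from the two skin
#' surfaces. Because the capillaries are modeled as infinitely long parallel
#' tubes, a 2-D cross-section suffices, and the infinite array reduces to a
#' unit cell of width \code{a/2} with mirror-symmetric side walls on which
#' alternate layers' capillary centers lie.
#'
#' @param H skin thickness, um.
#' @param r capillary lumen radius, um.
#' @param h depth of the first capillary layer from each surface, um.
#' @param a center-to-center capillary spacing, um.
#' @param w capillary wall thickness, um.
#' @param n_layers number of capillary layers.
#' @param d_electrodes_mm electrode gap, mm (experiment metadata only; the
#'   region of interest is assumed uniformly electroporated).
#' @return object of class \code{unit_cell_geometry}.
#' @export
unit_cell_geometry <- function(H = 300, r = 3.5, h = 72, a = 60, w = 1,
                               n_layers = 4, d_electrodes_mm = 6) {
  if (any(!is.finite(c(H, r, h, a, w, n_layers))) ||
      any(c(H, r, h, a, w) <= 0) || n_layers < 1)
    stop("geometry parameters must be positive and finite")
  if (H <= 2 * h) stop("skin thickness H must exceed 2*h")
  if (r + w >= a / 2)
    stop("capillary (r + w) must fit inside the half-spacing a/2")
  layer_gap <- a * sqrt(3) / 2
  span <- (n_layers - 1) * layer_gap + 2 * h
  if (abs(span - H) / H > 0.05)
    stop(sprintf(paste0("inconsistent packing: (n_layers-1)*a*sqrt(3)/2 + 2h",
                        " = %.1f um differs from H = %.1f um by more than 5%%"),
                 span, H))
  structure(list(H = H, r = r, h = h, a = a, w = w, n_layers = n_layers,
                 d_electrodes_mm = d_electrodes_mm, layer_gap = layer_gap),
            class = "unit_cell_geometry")
}

#' @export
print.unit_cell_geometry <- function(x, ...) {
  cat(sprintf(paste0("Unit cell: %g x %g um strip, %d capillary layers",
                     " (r = %g um, wall %g um)\n"),
              x$a / 2, x$H, x$n_layers, x$r, x$w))
  cat("  layer depths:", paste(round(capillary_centers(x)$z[
    !duplicated(capillary_centers(x)$z)], 1), collapse = ", "), "um\n")
  invisible(x)
}

#' Capillary cross-section centers inside the unit-cell strip
#'
#' Layers alternate between the two symmetric side walls (x = 0 and
#' x = a/2), so that neighboring layers' centers are exactly \code{a} apart.
#'
#' @param geometry a \code{unit_cell_geometry}.
#' @return data frame with columns \code{x}, \code{z} (um).
#' @export
capillary_centers <- function(geometry) {
  k <- seq_len(geometry$n_layers) - 1
  data.frame(x = ifelse(k %% 2 == 0, 0, geometry$a / 2),
             z = geometry$h + k * geometry$layer_gap)
}

# classify points by material: 2 lumen, 1 wall, 0 tissue
.classify_points <- function(px, pz, centers, r, w) {
  d2min <- rep(Inf, length(px))
  for (j in seq_len(nrow(centers))) {
    d2 <- (px - centers$x[j])^2 + (pz - centers$z[j])^2
    d2min <- pmin(d2min, d2)
  }
  ifelse(d2min < r^2, 2L, ifelse(d2min < (r + w)^2, 1L, 0L))
}

# material path fractions along face segments, computed exactly from the
# segment-circle intersections with the nearest capillary (segments are at
# most one cell long, far shorter than the capillary spacing, so only one
# capillary can intersect them). Returns list(fw, ft, fl): fractions of the
# center-to-center segment lying in wall, tissue and lumen material.
.face_fractions <- function(x1, z1, x2, z2, centers, r, w) {
  x1 <- as.vector(x1); z1 <- as.vector(z1)
  x2 <- as.vector(x2); z2 <- as.vector(z2)
  mx <- (x1 + x2) / 2; mz <- (z1 + z2) / 2
  d2min <- rep(Inf, length(mx))
  cxn <- czn <- numeric(length(mx))
  for (j in seq_len(nrow(centers))) {
    d2 <- (mx - centers$x[j])^2 + (mz - centers$z[j])^2
    upd <- d2 < d2min
    d2min[upd] <- d2[upd]
    cxn[upd] <- centers$x[j]; czn[upd] <- centers$z[j]
  }
  dx <- x2 - x1; dz <- z2 - z1
  px <- x1 - cxn; pz <- z1 - czn
  a <- dx^2 + dz^2                     # = h^2 > 0
  b <- 2 * (px * dx + pz * dz)
  c0 <- px^2 + pz^2
  # fraction of s in [0,1] with |P(s) - C| < rho (a sublevel interval)
  inside_frac <- function(rho) {
    disc <- b^2 - 4 * a * (c0 - rho^2)
    s1 <- ifelse(disc > 0, (-b - sqrt(pmax(disc, 0))) / (2 * a), Inf)
    s2 <- ifelse(disc > 0, (-b + sqrt(pmax(disc, 0))) / (2 * a), -Inf)
    pmax(0, pmin(s2, 1) - pmax(s1, 0))
  }
  fl <- inside_frac(r)
  fw <- inside_frac(r + w) - fl
  list(fw = fw, ft = 1 - fl - fw, fl = fl)
}

# shared grid assembly for an arbitrary set of capillary centers on a
# rectangular domain [0,Lx] x [0,Lz] with no-flux outer boundaries.
.assemble_grid <- function(Lx, Lz, centers, r, w, resolution, geometry) {
  nx <- round(Lx / resolution); nz <- round(Lz / resolution)
  if (abs(nx * resolution - Lx) > 1e-9 || abs(nz * resolution - Lz) > 1e-9)
    stop("resolution must divide the domain dimensions evenly")
  hres <- resolution
  xc <- (seq_len(nx) - 0.5) * hres
  zc <- (seq_len(nz) - 0.5) * hres
  X <- matrix(xc, nx, nz); Z <- matrix(zc, nx, nz, byrow = TRUE)
  type <- matrix(.classify_points(as.vector(X), as.vector(Z), centers, r, w),
                 nx, nz)
  # x-direction interior faces: between (i,k) and (i+1,k)
  fx <- if (nx > 1) .face_fractions(
    X[-nx, , drop = FALSE], Z[-nx, , drop = FALSE],
    X[-1L, , drop = FALSE], Z[-1L, , drop = FALSE], centers, r, w)
  else list(fw = matrix(0, 0, nz), ft = matrix(0, 0, nz),
            fl = matrix(0, 0, nz))
  fz <- if (nz > 1) .face_fractions(
    X[, -nz, drop = FALSE], Z[, -nz, drop = FALSE],
    X[, -1L, drop = FALSE], Z[, -1L, drop = FALSE], centers, r, w)
  else list(fw = matrix(0, nx, 0), ft = matrix(0, nx, 0),
            fl = matrix(0, nx, 0))
  # face codes: 0 regular, 1 Dirichlet (exactly one side in the lumen),
  # 2 inactive (both sides in the lumen)
  lum <- type == 2L
  codex <- matrix(0L, max(nx - 1L, 0L), nz)
  if (nx > 1) {
    a <- lum[-nx, , drop = FALSE]; b <- lum[-1L, , drop = FALSE]
    codex[a & b] <- 2L; codex[xor(a, b)] <- 1L
  }
  codez <- matrix(0L, nx, max(nz - 1L, 0L))
  if (nz > 1) {
    a <- lum[, -nz, drop = FALSE]; b <- lum[, -1L, drop = FALSE]
    codez[a & b] <- 2L; codez[xor(a, b)] <- 1L
  }
  structure(
    list(nx = nx, nz = nz, h = hres, type = type,
         fw_x = matrix(fx$fw, max(nx - 1L, 0L), nz),
         ft_x = matrix(fx$ft, max(nx - 1L, 0L), nz),
         code_x = codex,
         fw_z = matrix(fz$fw, nx, max(nz - 1L, 0L)),
         ft_z = matrix(fz$ft, nx, max(nz - 1L, 0L)),
         code_z = codez,
         cell_area = hres^2,
         lumen_area = sum(lum) * hres^2,
         wall_area = sum(type == 1L) * hres^2,
         tissue_area = sum(type == 0L) * hres^2,
         geometry = geometry),
    class = "transport_grid")
}

#' Discretize the unit cell on a regular grid
#'
#' Finite-volume discretization of the unit-cell strip (width a/2, height H)
#' at the given resolution. Cells are tagged lumen, wall or tissue by their
#' center's distance to the nearest capillary center; face conductances are
#' derived from the material composition of each center-to-center segment
#' (series resistances of the wall and tissue portions), which keeps the
#' wall's diffusive resistance w/D_wall nearly independent of the raster
#' resolution. Outer surfaces (z = 0 and z = H) and the two side walls
#' (mirror symmetry of the periodic array) are zero-flux boundaries.
#'
#' @param geometry a \code{unit_cell_geometry}.
#' @param resolution cell size, um; must not exceed the wall thickness.
#' @return object of class \code{transport_grid}.
#' @export
build_grid <- function(geometry, resolution = 1) {
  stopifnot(inherits(geometry, "unit_cell_geometry"))
  if (resolution > geometry$w)
    stop(sprintf(paste0("resolution %g um exceeds the wall thickness %g um;",
                        " the wall layer would be unresolved"),
                 resolution, geometry$w))
  .assemble_grid(geometry$a / 2, geometry$H, capillary_centers(geometry),
                 geometry$r, geometry$w, resolution, geometry)
}

#' @export
print.transport_grid <- function(x, ...) {
  cat(sprintf("Transport grid: %d x %d cells at %g um\n", x$nx, x$nz, x$h))
  cat(sprintf("  areas (um^2): lumen %.1f, wall %.1f, tissue %.1f\n",
              x$lumen_area, x$wall_area, x$tissue_area))
  invisible(x)
}

# small test/oracle domain: a single capillary centered in an L x L cell,
# zero-flux outer boundaries.
single_capillary_grid <- function(L = 20, r = 3.5, w = 1, resolution = 1) {
  if (resolution > w) stop("resolution exceeds wall thickness")
  .assemble_grid(L, L, data.frame(x = L / 2, z = L / 2), r, w, resolution,
                 geometry = NULL)
}
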