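#' Cylindrical tendon geometry
#'
#' @param L Tendon length (mm).
#' @param A Cross-sectional area (mm^2); the radius is `sqrt(A/pi)`.
#' @return An object of class `tendon_geometry` with `L`, `A`, `R`.
#' @examples
#' average_geometry()  # mean rat Achilles tendon: L = 8.4 mm, A = 1.63 mm^2
#' @export
tendon_geometry <- function(L, A) {
  if (!is.finite(L) || L <= 0 || !is.finite(A) || A <= 0)
    stop("geometry requires L > 0 and A > 0")
  structure(list(L = L, A = A, R = sqrt(A / pi)), class = "tendon_geometry")
}

#' @rdname tendon_geometry
#' @export
average_geometry <- function() tendon_geometry(L = 8.4, A = 1.63)

#' Structured axisymmetric mesh of a cylindrical tendon
#'
#' Builds an `nr` x `nz` grid of 4-node quadrilateral elements on the
#' meridian rectangle `[0, R] x [0, L]`, with equal-order bilinear
#' interpolation for displacements and pore pressure (2x2 Gauss points per
#' element). Node sets for the clamped base, loaded top, symmetry axis and
#' free outer surface are precomputed, as are the dof-colouring tables used
#' by the finite-difference Jacobian.
#'
#' @param geom A [tendon_geometry()].
#' @param nr,nz Number of elements radially / axially (default 4 x 16).
#' @return An object of class `tendon_mesh`.
#' @export
build_mesh <- function(geom, nr = 4, nz = 16) {
  stopifnot(inherits(geom, "tendon_geometry"))
  if (nr < 1 || nz < 1) stop("nr and nz must be >= 1")
  nr <- as.integer(nr); nz <- as.integer(nz)
  ri <- seq(0, geom$R, length.out = nr + 1)
  zi <- seq(0, geom$L, length.out = nz + 1)
  nodes <- cbind(r = rep(ri, nz + 1), z = rep(zi, each = nr + 1))
  nid <- function(i, j) i + (nr + 1) * j + 1L  # i in 0..nr, j in 0..nz
  elems <- matrix(0L, nr * nz, 4)
  k <- 1L
  for (j in 0:(nz - 1)) {
    for (i in 0:(nr - 1)) {
      elems[k, ] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))
      k <- k + 1L
    }
  }
  nn <- nrow(nodes)
  ii <- rep(0:nr, nz + 1)
  jj <- rep(0:nz, each = nr + 1)
  sets <- list(
    base = which(jj == 0L),
    top = which(jj == nz),
    axis = which(ii == 0L),
    outer = which(ii == nr)
  )
  # dof colouring: nodes three apart in each grid direction never share an
  # element neighbourhood, so their FD columns can be formed simultaneously
  col9 <- (ii %% 3L) + 3L * (jj %% 3L)
  groups <- vector("list", 27L)
  g <- 1L
  for (cc in 0:8) {
    nds <- which(col9 == cc)
    for (type in 0:2) {
      groups[[g]] <- as.integer(3L * (nds - 1L) + type)  # 0-based dofs
      g <- g + 1L
    }
  }
  # affected residual rows per dof: all dofs of nodes within one grid cell
  rows_node <- vector("list", nn)
  for (n in seq_len(nn)) {
    i <- ii[n]; j <- jj[n]
    nbr <- integer(0)
    for (dj in -1:1) for (di in -1:1) {
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 0 && i2 <= nr && j2 >= 0 && j2 <= nz)
        nbr <- c(nbr, nid(i2, j2))
    }
    rows_node[[n]] <- as.integer(sort(c(
      3L * (nbr - 1L), 3L * (nbr - 1L) + 1L, 3L * (nbr - 1L) + 2L)))
  }
  rows <- rows_node[rep(seq_len(nn), each = 3L)]
  # consistent nodal loads on the top face for a unit axial traction (MPa):
  # integral of N * 2 pi R dR over each top edge segment
  load_vec <- numeric(3L * nn)
  for (i in 0:(nr - 1)) {
    R1 <- ri[i + 1]; R2 <- ri[i + 2]
    n1 <- nid(i, nz); n2 <- nid(i + 1, nz)
    load_vec[3L * (n1 - 1L) + 2L] <- load_vec[3L * (n1 - 1L) + 2L] +
      2 * pi * (R2 - R1) * (R2 + 2 * R1) / 6
    load_vec[3L * (n2 - 1L) + 2L] <- load_vec[3L * (n2 - 1L) + 2L] +
      2 * pi * (R2 - R1) * (2 * R2 + R1) / 6
  }
  structure(list(nodes = nodes, elems = elems, nr = nr, nz = nz,
                 geom = geom, sets = sets, groups = groups, rows = rows,
                 load_vec = load_vec, nn = nn, ne = nrow(elems),
                 ngp = 4L * nrow(elems)),
            class = "tendon_mesh")
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric tendon mesh: %d x %d elements (%d nodes, %d Gauss points)\n",
    x$nr, x$nz, x$nn, x$ngp))
  cat(sprintf("  R = %.4f mm, L = %.4f mm\n", x$geom$R, x$geom$L))
  invisible(x)
}

# meridian-plane area of all elements (should equal R*L for the structured grid)
mesh_meridian_area <- function(mesh) {
  a <- 0
  for (e in seq_len(mesh$ne)) {
    xy <- mesh$nodes[mesh$elems[e, ], ]
    a <- a + 0.5 * abs(sum(xy[, 1] * xy[c(2:4, 1), 2] - xy[c(2:4, 1), 1] * xy[, 2]))
  }
  a
}

#' Boundary conditions for the tensile-test configuration
#'
#' Encodes the clamped-tendon set-up: the base (calcaneus end) is fully
#' fixed (encastre), the symmetry axis is confined radially, pore pressure
#' is zero on the free outer surface (fluid may cross it), and the top
#' (muscle end) carries either a prescribed axial displacement or a
#' prescribed axial traction. Clamped ends and the axis are impermeable
#' (natural condition).
#'
#' @param mesh A [build_mesh()] object.
#' @param control `"displacement"` (prescribed top axial displacement) or
#'   `"traction"` (prescribed axial nominal traction, MPa).
#' @param top_radial_fixed Fix the radial displacement of the top nodes to
#'   mimic the clamp (default TRUE).
#' @param drainage Where pore pressure is prescribed to zero: `"outer"`
#'   surface (default), `"top"`, or `"none"`.
#' @param confined Fix radial displacement everywhere (used by the
#'   consolidation benchmark).
#' @return An object of class `tendon_bc`.
#' @export
boundary_spec <- function(mesh, control = c("displacement", "traction"),
                          top_radial_fixed = TRUE,
                          drainage = c("outer", "top", "none"),
                          confined = FALSE) {
  control <- match.arg(control)
  drainage <- match.arg(drainage)
  ur <- function(n) 3L * (n - 1L) + 1L
  uz <- function(n) 3L * (n - 1L) + 2L
  pp <- function(n) 3L * (n - 1L) + 3L
  s <- mesh$sets
  fixed_zero <- c(ur(s$base), uz(s$base))
  fixed_zero <- c(fixed_zero, if (confined) ur(seq_len(mesh$nn)) else ur(s$axis))
  if (control == "displacement") {
    top_uz <- uz(s$top)
    if (top_radial_fixed) fixed_zero <- c(fixed_zero, ur(s$top))
  } else {
    top_uz <- integer(0)
    if (top_radial_fixed && !confined) fixed_zero <- c(fixed_zero, ur(s$top))
  }
  p_fixed <- switch(drainage,
    outer = pp(s$outer), top = pp(s$top), none = integer(0))
  fixed_zero <- sort(unique(c(fixed_zero, p_fixed)))
  fixed_zero <- setdiff(fixed_zero, top_uz)
  structure(list(control = control, fixed_zero = fixed_zero,
                 top_uz = sort(unique(top_uz)),
                 reaction_dofs = uz(s$top),
                 load_vec = mesh$load_vec),
            class = "tendon_bc")
}
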