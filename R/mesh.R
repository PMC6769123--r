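new_mesh <- function(nodes, elems, f0, s0, n0, sets, info = list()) {
  structure(list(nodes = nodes, elems = elems, f0 = f0, s0 = s0, n0 = n0,
                 sets = sets, info = info), class = "cem_mesh")
}

#' @export
print.cem_mesh <- function(x, ...) {
  cat(sprintf("cem_mesh: %d nodes, %d hex8 elements (%s)\n",
              nrow(x$nodes), nrow(x$elems),
              if (is.null(x$info$kind)) "generic" else x$info$kind))
  cat("node sets:", paste(sprintf("%s[%d]", names(x$sets),
                                  vapply(x$sets, length, 1L)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reference-configuration Jacobians of all elements
#'
#' Determinant of the isoparametric mapping at the 2x2x2 quadrature points
#' of every element; all entries must be positive for a valid mesh.
#'
#' @param mesh a \code{cem_mesh}.
#' @return matrix (elements x 8) of Jacobian determinants.
#' @export
ref_jacobians <- function(mesh) {
  .cem_ref_jacobians(mesh$nodes, mesh$elems)
}

#' Structured hexahedral plate mesh
#'
#' Builds the plate benchmark geometry: a \code{dim[1] x dim[2] x dim[3]} mm
#' slab meshed by \code{divisions} eight-node bricks, with fibers along x
#' and sheets along y.  Node sets:
#' \describe{
#'   \item{midplane_edge}{edge nodes of the mid-plane z = Lz/2 (fixed in z
#'     in the benchmark protocol).}
#'   \item{corner_origin}{node at (0,0,0) (fixed in x and y).}
#'   \item{corner_x}{node at (Lx,0,0) (fixed in y).}
#'   \item{load}{nodes of the central parallelepiped spanning one fifth of
#'     the in-plane dimensions and the full thickness, which receives the
#'     cyclic pulse load.}
#' }
#'
#' @param dim plate dimensions (mm), default the 100 x 100 x 12 mm plate.
#' @param divisions element divisions per direction, default 21 x 21 x 2.
#' @return a \code{cem_mesh}.
#' @examples
#' m <- make_plate()
#' nrow(m$nodes)  # 22 * 22 * 3 = 1452
#' @export
make_plate <- function(dim = c(100, 100, 12), divisions = c(21, 21, 2)) {
  stopifnot(length(dim) == 3, all(dim > 0), all(divisions >= 1))
  n <- as.integer(divisions)
  xs <- seq(0, dim[1], length.out = n[1] + 1)
  ys <- seq(0, dim[2], length.out = n[2] + 1)
  zs <- seq(0, dim[3], length.out = n[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (n[1] + 1) * ((j - 1) + (n[2] + 1) * (k - 1))
  elems <- matrix(0L, n[1] * n[2] * n[3], 8)
  e <- 0L
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                    nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  m <- nrow(elems)
  f0 <- matrix(rep(c(1, 0, 0), each = m), m)
  s0 <- matrix(rep(c(0, 1, 0), each = m), m)
  n0 <- matrix(rep(c(0, 0, 1), each = m), m)
  tol <- 1e-9 * max(dim)
  on_line <- function(v, a) abs(v - a) < tol
  mid <- dim / 2
  sets <- list(
    midplane_edge = which(on_line(nodes[, 3], mid[3]) &
                          (on_line(nodes[, 1], 0) | on_line(nodes[, 1], dim[1]) |
                           on_line(nodes[, 2], 0) | on_line(nodes[, 2], dim[2]))),
    corner_origin = which(on_line(nodes[, 1], 0) & on_line(nodes[, 2], 0) &
                          on_line(nodes[, 3], 0)),
    corner_x = which(on_line(nodes[, 1], dim[1]) & on_line(nodes[, 2], 0) &
                     on_line(nodes[, 3], 0)),
    load = which(abs(nodes[, 1] - mid[1]) <= dim[1] / 10 + tol &
                 abs(nodes[, 2] - mid[2]) <= dim[2] / 10 + tol))
  new_mesh(nodes, elems, f0, s0, n0, sets,
           info = list(kind = "plate", dim = dim, divisions = n))
}

#' Unit-cube mesh for isotonic contraction
#'
#' Cube with uniform fiber field along x, free boundaries, and minimal
#' rigid-body pinning (3-2-1 support): the origin node is fully fixed, the
#' (L,0,0) node is fixed in y and z, and the (0,L,0) node in z.
#'
#' @param edge edge length (mm).
#' @param n element divisions per direction.
#' @return a \code{cem_mesh} with sets \code{pin_xyz}, \code{pin_yz},
#'   \code{pin_z}.
#' @export
make_cube <- function(edge = 1, n = 1) {
  m <- make_plate(dim = rep(edge, 3), divisions = rep(n, 3))
  nodes <- m$nodes
  tol <- 1e-9 * edge
  at <- function(x, y, z) which(abs(nodes[, 1] - x) < tol &
                                abs(nodes[, 2] - y) < tol &
                                abs(nodes[, 3] - z) < tol)
  m$sets <- list(pin_xyz = at(0, 0, 0), pin_yz = at(edge, 0, 0),
                 pin_z = at(0, edge, 0))
  m$info <- list(kind = "cube", edge = edge, divisions = n)
  m
}

#' Synthetic left-ventricle geometry specification
#'
#' Truncated-ellipsoid stand-in for a rat left ventricle: endocardial and
#' epicardial ellipsoid semi-axes, truncation at the equatorial plane z = 0,
#' a target element size, and linear transmural fiber helix angles.  This is
#' a synthetic geometry at rat scale, not an image-derived ventricle.
#'
#' @param endo,epi semi-axes (a, b, c) of the endocardial and epicardial
#'   ellipsoids (mm); epi must strictly enclose endo.
#' @param target_size target element edge length (mm).
#' @param theta_endo,theta_epi fiber helix angles (degrees, relative to the
#'   circumferential direction) on the endo- and epicardium.
#' @param n_stim number of stimulus nodes on the basal endocardial rim.
#' @return list of class \code{cem_lv_spec}.
#' @export
lv_spec <- function(endo = c(2.5, 2.5, 4.5), epi = c(4.0, 4.0, 6.0),
                    target_size = 0.35, theta_endo = 80, theta_epi = -70,
                    n_stim = 7) {
  if (any(epi <= endo)) stop("degenerate wall: epicardial semi-axes must exceed endocardial")
  stopifnot(target_size > 0,
            theta_endo > -90, theta_endo <= 90, theta_epi > -90, theta_epi <= 90)
  structure(list(endo = endo, epi = epi, target_size = target_size,
                 theta_endo = theta_endo, theta_epi = theta_epi,
                 n_stim = as.integer(n_stim)), class = "cem_lv_spec")
}

lv_surface <- function(axes, v, th) {
  cbind(axes[1] * sin(v) * cos(th), axes[2] * sin(v) * sin(th),
        -axes[3] * cos(v))
}

#' Synthetic truncated-ellipsoid left-ventricle mesh
#'
#' Structured hexahedral shell between two ellipsoidal surfaces, truncated
#' at the base plane z = 0 and closed at the apex by collapsed-hexahedron
#' wedges around the axis.  Rule-based transmural fibers are assigned per
#' element (see \code{\link{assign_fibers}}).  Node sets: \code{base} (all
#' basal-ring nodes, mechanically fixed in the study protocol), \code{apex}
#' (epicardial apex node, the probe node), \code{stim} (contiguous patch of
#' \code{n_stim} nodes on the basal endocardial rim), \code{endo} and
#' \code{epi} surfaces.
#'
#' @param spec an \code{\link{lv_spec}}.
#' @return a \code{cem_mesh}.
#' @export
make_lv <- function(spec = lv_spec()) {
  stopifnot(inherits(spec, "cem_lv_spec"))
  h <- spec$target_size
  mid <- (spec$endo + spec$epi) / 2
  wall <- mean(spec$epi - spec$endo)
  arc_mer <- (pi / 2) * mean(mid[c(1, 3)])
  nv <- max(4L, as.integer(round(arc_mer / h)))
  nc <- max(8L, as.integer(round(2 * pi * mid[1] / h)))
  nt <- max(2L, as.integer(round(wall / h)))
  if (nc < spec$n_stim)
    stop("mesh too coarse for ", spec$n_stim, " distinct stimulus nodes")

  vs <- seq(0, pi / 2, length.out = nv + 1)
  ths <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  us <- seq(0, 1, length.out = nt + 1)

  n_axis <- nt + 1L
  nodes <- matrix(0, n_axis + nv * nc * n_axis, 3)
  # axis nodes (apex pole), k = 0..nt
  for (k in seq_len(n_axis))
    nodes[k, ] <- c(0, 0, -((1 - us[k]) * spec$endo[3] + us[k] * spec$epi[3]))
  rid <- function(i, j, k) # ring i = 1..nv, j = 1..nc, k = 1..nt+1
    n_axis + ((i - 1) * nc + (j - 1)) * n_axis + k
  for (i in seq_len(nv)) {
    en <- lv_surface(spec$endo, vs[i + 1], ths)
    ep <- lv_surface(spec$epi, vs[i + 1], ths)
    for (j in seq_len(nc)) for (k in seq_len(n_axis))
      nodes[rid(i, j, k), ] <- (1 - us[k]) * en[j, ] + us[k] * ep[j, ]
  }

  elems <- matrix(0L, nv * nc * nt, 8)
  epar <- matrix(0, nrow(elems), 3) # parametric element centers (v, th, u)
  e <- 0L
  for (i in seq_len(nv)) for (j in seq_len(nc)) for (k in seq_len(nt)) {
    j1 <- if (j == nc) 1L else j + 1L
    e <- e + 1L
    if (i == 1L) {
      elems[e, ] <- c(k, k, rid(1, j1, k), rid(1, j, k),
                      k + 1L, k + 1L, rid(1, j1, k + 1), rid(1, j, k + 1))
    } else {
      elems[e, ] <- c(rid(i - 1, j, k), rid(i - 1, j1, k), rid(i, j1, k),
                      rid(i, j, k), rid(i - 1, j, k + 1), rid(i - 1, j1, k + 1),
                      rid(i, j1, k + 1), rid(i, j, k + 1))
    }
    epar[e, ] <- c((vs[i] + vs[i + 1]) / 2, (ths[j] + ths[j] + 2 * pi / nc) / 2,
                   (us[k] + us[k + 1]) / 2)
  }

  sets <- list(
    base = sort(unique(as.integer(vapply(seq_len(nc), function(j)
      vapply(seq_len(n_axis), function(k) rid(nv, j, k), 1), numeric(n_axis))))),
    apex = n_axis,
    stim = vapply(seq_len(spec$n_stim), function(j) rid(nv, j, 1L), 1),
    endo = sort(unique(c(1L, as.integer(vapply(seq_len(nv), function(i)
      vapply(seq_len(nc), function(j) rid(i, j, 1L), 1), numeric(nc)))))),
    epi = sort(unique(c(n_axis, as.integer(vapply(seq_len(nv), function(i)
      vapply(seq_len(nc), function(j) rid(i, j, n_axis), 1), numeric(nc)))))))
  sets$stim <- as.integer(sets$stim)

  mesh <- new_mesh(nodes, elems,
                   f0 = matrix(0, nrow(elems), 3), s0 = matrix(0, nrow(elems), 3),
                   n0 = matrix(0, nrow(elems), 3), sets = sets,
                   info = list(kind = "lv", spec = spec, epar = epar,
                               divisions = c(nv = nv, nc = nc, nt = nt)))
  mesh <- assign_fibers(mesh, spec)
  dj <- ref_jacobians(mesh)
  if (any(dj <= 0)) stop("left-ventricle mesh has non-positive element Jacobians")
  mesh
}

#' Rule-based transmural fiber assignment
#'
#' Assigns per-element orthonormal fiber/sheet/normal frames on a
#' left-ventricle shell.  The helix angle varies linearly with the
#' normalized wall depth d (0 = endocardium):
#' \code{theta(d) = theta_endo + d (theta_epi - theta_endo)}; the fiber is
#' the circumferential direction rotated by theta about the local
#' transmural axis, the sheet direction is transmural.  At the apex cap the
#' circumferential direction is evaluated at the element center, which lies
#' off the axis, so the frame stays well defined.
#'
#' @param mesh a left-ventricle \code{cem_mesh} from \code{\link{make_lv}}.
#' @param spec the \code{\link{lv_spec}} used to build the mesh.
#' @return the mesh with populated \code{f0}, \code{s0}, \code{n0}.
#' @export
assign_fibers <- function(mesh, spec) {
  epar <- mesh$info$epar
  stopifnot(!is.null(epar))
  m <- nrow(mesh$elems)
  f0 <- s0 <- n0 <- matrix(0, m, 3)
  for (e in seq_len(m)) {
    v <- epar[e, 1]; th <- epar[e, 2]; u <- epar[e, 3]
    en <- drop(lv_surface(spec$endo, v, th))
    ep <- drop(lv_surface(spec$epi, v, th))
    # d/dtheta of the transmurally interpolated surface point
    dth <- c(-((1 - u) * spec$endo[1] + u * spec$epi[1]) * sin(v) * sin(th),
             ((1 - u) * spec$endo[2] + u * spec$epi[2]) * sin(v) * cos(th), 0)
    circ <- dth / sqrt(sum(dth^2))
    trans <- ep - en
    trans <- trans - sum(trans * circ) * circ
    trans <- trans / sqrt(sum(trans^2))
    long <- c(trans[2] * circ[3] - trans[3] * circ[2],
              trans[3] * circ[1] - trans[1] * circ[3],
              trans[1] * circ[2] - trans[2] * circ[1])
    ang <- (spec$theta_endo + u * (spec$theta_epi - spec$theta_endo)) * pi / 180
    f <- cos(ang) * circ + sin(ang) * long
    s <- trans
    nn <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
            f[1] * s[2] - f[2] * s[1])
    f0[e, ] <- f; s0[e, ] <- s; n0[e, ] <- nn
  }
  mesh$f0 <- f0; mesh$s0 <- s0; mesh$n0 <- n0
  mesh
}

#' Transmural helix angle profile
#'
#' Linear interpolation of the fiber helix angle across the wall.
#'
#' @param d normalized wall depth in [0, 1] (0 = endocardium).
#' @param spec an \code{\link{lv_spec}}.
#' @return helix angle in degrees.
#' @export
helix_angle <- function(d, spec = lv_spec()) {
  spec$theta_endo + d * (spec$theta_epi - spec$theta_endo)
}
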