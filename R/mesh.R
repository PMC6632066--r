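# Triangle-mesh geometry: a minimal STL reader/writer and the parametric
# builders for the rigs and blenders (plate + funnel, drum, cylindrical
# vessel, V-blender, double-cone).  A mesh is a list with an n x 3 vertex
# matrix (metres) and an m x 3 integer triangle index matrix (1-based).

tri_mesh <- function(vertices, triangles, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            max(triangles) <= nrow(vertices), min(triangles) >= 1)
  structure(list(vertices = vertices, triangles = triangles, name = name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d triangles\n",
              x$name, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# ---- STL I/O ---------------------------------------------------------------

#' Read an STL mesh (ASCII or binary)
#'
#' Duplicated facet vertices are merged (STL stores each facet's corners
#' independently) so downstream watertightness and volume checks work.
#'
#' @param path STL file path.
#' @param merge_tol vertex-merge tolerance in the file's length unit.
#' @return a `tri_mesh`.
#' @export
read_stl <- function(path, merge_tol = 1e-9) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head[head != as.raw(0)]),
                    ignore.case = TRUE) && {
    # ASCII files contain the word 'facet' in text form
    txt <- readLines(path, n = 5, warn = FALSE)
    any(grepl("facet", txt, ignore.case = TRUE))
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4]))
    verts <- do.call(rbind, nums)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    verts <- matrix(NA_real_, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      dat <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      verts[(3 * i - 2):(3 * i), ] <- matrix(dat[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (nrow(verts) %% 3 != 0) stop("malformed STL facet list", call. = FALSE)
  key <- apply(round(verts / merge_tol), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- apply(tris, 1, function(t) length(unique(t)) == 3L)
  tri_mesh(uverts, tris[keep, , drop = FALSE],
           name = sub("\\.stl$", "", basename(path), ignore.case = TRUE))
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  for (i in seq_len(nrow(tr))) {
    a <- v[tr[i, 1], ]; b <- v[tr[i, 2], ]; c3 <- v[tr[i, 3], ]
    n <- .cross3(b - a, c3 - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9e %.9e %.9e", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9e %.9e %.9e", a[1], a[2], a[3]),
      sprintf("      vertex %.9e %.9e %.9e", b[1], b[2], b[3]),
      sprintf("      vertex %.9e %.9e %.9e", c3[1], c3[2], c3[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
  invisible(path)
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# ---- mesh queries ----------------------------------------------------------

# Propagate a consistent winding across shared edges (BFS over the triangle
# adjacency); needed before taking the signed volume of meshes assembled
# from mirrored parts.
mesh_orient <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  emap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) for (k in 1:3) {
    a <- tr[i, k]; b <- tr[i, if (k == 3) 1 else k + 1]
    key <- edge_key(a, b)
    emap[[key]] <- c(get0(key, emap, ifnotfound = integer()), i)
  }
  seen <- logical(m)
  for (start in seq_len(m)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (k in 1:3) {
        a <- tr[i, k]; b <- tr[i, if (k == 3) 1 else k + 1]
        for (j in emap[[edge_key(a, b)]]) {
          if (j == i || seen[j]) next
          # neighbour must traverse the shared edge in the opposite order
          ej <- c(tr[j, ], tr[j, 1])
          same_dir <- any(ej[-4] == a & ej[-1] == b)
          if (same_dir) tr[j, ] <- tr[j, c(1, 3, 2)]
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  mesh$triangles <- tr
  mesh
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume after making the winding
#' consistent; the absolute value is returned.
#'
#' @param mesh a `tri_mesh` assumed closed.
#' @return volume in cubic metres.
#' @export
mesh_volume <- function(mesh) {
  mesh <- mesh_orient(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
              b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
              b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

#' Is a mesh watertight?
#'
#' Every edge must be shared by exactly two triangles.
#'
#' @param mesh a `tri_mesh`.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

mesh_merge <- function(..., name = "merged") {
  parts <- list(...)
  verts <- NULL; tris <- NULL; off <- 0L
  for (p in parts) {
    verts <- rbind(verts, p$vertices)
    tris <- rbind(tris, p$triangles + off)
    off <- off + nrow(p$vertices)
  }
  # merge coincident vertices so shared rings stitch watertight
  key <- apply(round(verts * 1e9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  tri_mesh(verts[!duplicated(key), , drop = FALSE],
           matrix(idx[tris], ncol = 3), name = name)
}

mesh_translate <- function(mesh, d) {
  mesh$vertices <- sweep(mesh$vertices, 2, d, "+")
  mesh
}

# ---- parametric builders ---------------------------------------------------

# ring of n points of radius r in the plane z = z, centred on the z axis
.ring <- function(r, z, n, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), z)
}

# stitch two rings (same n) into a triangle band
.band <- function(i0, i1, n) {
  a <- i0 + seq_len(n) - 1L; a2 <- i0 + (seq_len(n) %% n)
  b <- i1 + seq_len(n) - 1L; b2 <- i1 + (seq_len(n) %% n)
  rbind(cbind(a, a2, b), cbind(a2, b2, b))
}

# fan from a ring to an apex vertex
.fan <- function(ring0, apex, n, flip = FALSE) {
  a <- ring0 + seq_len(n) - 1L; a2 <- ring0 + (seq_len(n) %% n)
  if (flip) cbind(a2, a, apex) else cbind(a, a2, apex)
}

#' Flat circular plate
#'
#' @param radius plate radius (m).
#' @param z plate height (m).
#' @param n segments around the rim.
#' @return a `tri_mesh` (open surface).
#' @export
mesh_plate <- function(radius, z = 0, n = 48) {
  verts <- rbind(.ring(radius, z, n), c(0, 0, z))
  tri_mesh(verts, .fan(1L, n + 1L, n), name = "plate")
}

#' Open conical funnel (frustum side wall)
#'
#' @param r_top,r_orifice top and orifice radii (m).
#' @param height funnel height (m).
#' @param z_orifice height of the orifice plane (m).
#' @param n segments.
#' @export
mesh_funnel <- function(r_top, r_orifice, height, z_orifice = 0, n = 48) {
  verts <- rbind(.ring(r_orifice, z_orifice, n),
                 .ring(r_top, z_orifice + height, n))
  tri_mesh(verts, .band(1L, n + 1L, n), name = "funnel")
}

#' Cylindrical vessel with a closed bottom and open top
#'
#' @param radius,height vessel dimensions (m); bottom at `z = 0`.
#' @param n segments.
#' @export
mesh_vessel <- function(radius, height, n = 48) {
  verts <- rbind(.ring(radius, 0, n), .ring(radius, height, n), c(0, 0, 0))
  tris <- rbind(.band(1L, n + 1L, n), .fan(1L, 2L * n + 1L, n, flip = TRUE))
  m <- tri_mesh(verts, tris, name = "vessel")
  m$inside <- function(p, margin = 0) {
    sqrt(p[, 1]^2 + p[, 2]^2) < radius - margin & p[, 3] > margin &
      p[, 3] < height
  }
  m
}

#' Closed rotating drum (cylinder with end caps, axis along z)
#'
#' Built with its axis along z; the drum rig rotates it about that axis
#' after re-orienting the axis horizontally (the engine stores the rotation
#' axis separately, so the mesh itself has a horizontal axis along y after
#' the builder's final rotation).
#'
#' @param radius drum radius (m).
#' @param length axial length (m).
#' @param n segments.
#' @return a watertight `tri_mesh` with the drum axis along y, centred on
#'   the origin.
#' @export
mesh_drum <- function(radius, length, n = 48) {
  verts <- rbind(.ring(radius, -length / 2, n), .ring(radius, length / 2, n),
                 c(0, 0, -length / 2), c(0, 0, length / 2))
  tris <- rbind(.band(1L, n + 1L, n),
                .fan(1L, 2L * n + 1L, n, flip = TRUE),
                .fan(n + 1L, 2L * n + 2L, n))
  m <- tri_mesh(verts, tris, name = "drum")
  # rotate so the drum axis is horizontal (z -> y)
  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  m$vertices <- m$vertices %*% t(Rx)
  m$inside <- function(p, margin = 0) {
    sqrt(p[, 1]^2 + p[, 3]^2) < radius - margin &
      abs(p[, 2]) < length / 2 - margin
  }
  m
}

#' V-blender shell
#'
#' Two cylindrical arms of radius `r` joined along the mitre plane `x = 0`
#' (a pipe-elbow joint), opening upward with half-angle `half_angle` from
#' the vertical, closed by end caps.  Arm volume is exactly `pi r^2 L`, so
#' the shell volume is `2 pi r^2 L` by construction.
#'
#' @param volume_l nominal volume in litres; sets `r` with the default
#'   aspect `L = 4 r`.
#' @param half_angle arm half-angle from vertical in degrees (default 40).
#' @param aspect arm length as a multiple of the radius (default 4).
#' @param n segments around each arm; `n_axial` rings along each arm.
#' @param n_axial axial rings.
#' @return a watertight `tri_mesh`; attributes `r`, `L`, `half_angle`,
#'   `pivot` (rotation-axis point) and an `inside` predicate are attached.
#' @export
mesh_vblender <- function(volume_l, half_angle = 40, aspect = 4,
                          n = 36, n_axial = 8) {
  V <- volume_l / 1000
  r <- (V / (2 * pi * aspect))^(1 / 3)
  L <- aspect * r
  phi <- half_angle * pi / 180
  d <- c(sin(phi), 0, cos(phi))          # arm axis (+x side), pointing up
  e1 <- c(cos(phi), 0, -sin(phi))        # in-plane radial basis
  e2 <- c(0, 1, 0)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring_at <- function(tfun) {
    t(vapply(th, function(a) {
      tt <- tfun(a)
      tt * d + r * cos(a) * e1 + r * sin(a) * e2
    }, numeric(3)))
  }
  t_mitre <- function(a) -r * cos(a) * cos(phi) / sin(phi)
  svals <- seq(0, 1, length.out = n_axial + 1)
  rings <- lapply(svals, function(s)
    ring_at(function(a) (1 - s) * t_mitre(a) + s * L))
  verts <- do.call(rbind, rings)
  tris <- NULL
  for (i in seq_len(n_axial))
    tris <- rbind(tris, .band(1L + (i - 1L) * n, 1L + i * n, n))
  # end cap at t = L
  cap_center <- L * d
  verts <- rbind(verts, cap_center)
  tris <- rbind(tris, .fan(1L + n_axial * n, nrow(verts), n))
  arm1 <- tri_mesh(verts, tris)
  # mirrored arm (x -> -x), winding flipped to stay consistent
  verts2 <- verts; verts2[, 1] <- -verts2[, 1]
  arm2 <- tri_mesh(verts2, tris[, c(1, 3, 2)])
  m <- mesh_merge(arm1, arm2, name = "v_blender")
  zc <- 0.5 * L * cos(phi)
  m$inside <- function(p, margin = 0) {
    x <- abs(p[, 1])
    q <- cbind(x, p[, 2], p[, 3])
    tt <- q %*% d
    rad2 <- rowSums((q - tt %*% t(d))^2)
    rad2 < (r - margin)^2 & tt < L - margin
  }
  attr(m, "r") <- r; attr(m, "L") <- L
  attr(m, "half_angle") <- half_angle
  attr(m, "pivot") <- c(0, 0, zc)
  attr(m, "volume") <- 2 * pi * r^2 * L
  m
}

#' Double-cone blender shell
#'
#' Central cylinder of height `h_cyl = cyl_aspect * r` capped by two cones
#' of height `cone_aspect * r`, symmetric about `z = 0`; volume
#' `pi r^2 h_cyl + (2/3) pi r^2 h_cone`.
#'
#' @param volume_l nominal volume in litres.
#' @param cyl_aspect,cone_aspect cylinder and cone heights as multiples of
#'   the radius (defaults 0.6 and 1).
#' @param n segments.
#' @return a watertight `tri_mesh` with `inside` predicate and `pivot`
#'   attribute (rotation about a horizontal axis through the centre).
#' @export
mesh_doublecone <- function(volume_l, cyl_aspect = 0.6, cone_aspect = 1,
                            n = 48) {
  V <- volume_l / 1000
  r <- (V / (pi * (cyl_aspect + 2 * cone_aspect / 3)))^(1 / 3)
  hc <- cyl_aspect * r
  hk <- cone_aspect * r
  verts <- rbind(.ring(r, -hc / 2, n), .ring(r, hc / 2, n),
                 c(0, 0, -hc / 2 - hk), c(0, 0, hc / 2 + hk))
  tris <- rbind(.band(1L, n + 1L, n),
                .fan(1L, 2L * n + 1L, n, flip = TRUE),
                .fan(n + 1L, 2L * n + 2L, n))
  m <- tri_mesh(verts, tris, name = "double_cone")
  m$inside <- function(p, margin = 0) {
    rad <- sqrt(p[, 1]^2 + p[, 2]^2)
    z <- abs(p[, 3])
    (z < hc / 2 & rad < r - margin) |
      (z >= hc / 2 & z < hc / 2 + hk &
         rad < (r - margin) * (1 - (z - hc / 2) / hk) &
         z < hc / 2 + hk - margin)
  }
  attr(m, "r") <- r
  attr(m, "pivot") <- c(0, 0, 0)
  attr(m, "volume") <- pi * r^2 * hc + (2 / 3) * pi * r^2 * hk
  m
}

#' Two-bladed rheometer impeller
#'
#' A flat two-bladed paddle of total span `2 * radius` and chord `chord`,
#' pitched by the helix angle about the radial direction, centred on the z
#' axis at height `z`.
#'
#' @param radius blade radius (m).
#' @param chord blade chord (m).
#' @param helix_angle_deg pitch angle in degrees (FT4 convention -5).
#' @param z blade centre height (m).
#' @param n_span panels along the span.
#' @export
mesh_blade <- function(radius, chord, helix_angle_deg = -5, z = 0,
                       n_span = 8) {
  al <- helix_angle_deg * pi / 180
  xs <- seq(-radius, radius, length.out = 2 * n_span + 1)
  # pitched chord direction: rotate the y-chord about the x (radial) axis
  up <- c(0, sin(al), cos(al)) * (chord / 2)
  verts <- NULL; tris <- NULL
  for (i in seq_along(xs)) {
    p <- c(xs[i], 0, z)
    verts <- rbind(verts, p + up, p - up)
  }
  for (i in seq_len(length(xs) - 1)) {
    a <- 2L * i - 1L
    tris <- rbind(tris, c(a, a + 1L, a + 2L), c(a + 1L, a + 3L, a + 2L))
  }
  tri_mesh(verts, tris, name = "blade")
}

#' Kinematics of a rigid wall mesh
#'
#' Prescribes rotation at constant angular speed about an axis plus a
#' constant translation velocity; the engine evaluates contacts in the
#' mesh's body frame and adds the wall surface velocity `omega x r + v` to
#' the relative-velocity terms.
#'
#' @param mesh a `tri_mesh`.
#' @param axis_point point on the rotation axis (m).
#' @param axis_dir rotation axis direction (normalised internally).
#' @param rpm rotation rate in revolutions per minute.
#' @param v_trans constant translation velocity (m/s).
#' @return object of class `wall`.
#' @export
wall <- function(mesh, axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                 rpm = 0, v_trans = c(0, 0, 0)) {
  nd <- sqrt(sum(axis_dir^2))
  if (nd == 0) stop("axis_dir must be non-zero", call. = FALSE)
  structure(list(mesh = mesh, axis_point = as.numeric(axis_point),
                 axis_dir = as.numeric(axis_dir) / nd,
                 omega = rpm * 2 * pi / 60,
                 v_trans = as.numeric(v_trans)),
            class = "wall")
}
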