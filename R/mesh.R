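# Voxelization of the skull surrogate and conversion to a labelled
# tetrahedral mesh.  The surrogate is a union of signed-distance-style
# primitives (ellipsoidal shell, facial plate + palate + pterygoid pillars,
# tubular zygomatic arches with posterior root blocks) sampled on a regular
# grid whose x = 0 plane is a voxel face, so the mesh is exactly bilaterally
# symmetric.  Interior voxels are split into 5 tetrahedra with a
# checkerboard parity so that faces between neighbouring voxels conform and
# the two split variants are mirror images of each other.

.region_shell <- function(x, y, z, p) {
  ro <- (x / p$ax)^2 + (y / p$ay)^2 + (z / p$az)^2
  ri <- (x / (p$ax - p$shell_t))^2 + (y / (p$ay - p$shell_t))^2 +
    (z / (p$az - p$shell_t))^2
  ro <= 1 & ri >= 1
}

.inside_inner <- function(x, y, z, p) {
  (x / (p$ax - p$shell_t))^2 + (y / (p$ay - p$shell_t))^2 +
    (z / (p$az - p$shell_t))^2 < 1
}

.region_plate <- function(x, y, z, p) {
  abs(x) <= p$pl_hw & y >= p$pl_y0 & y <= p$pl_y0 + p$pl_t &
    z >= p$pl_zlo & z <= p$pl_zhi & !.inside_inner(x, y, z, p)
}

.region_palate <- function(x, y, z, p) {
  abs(x) <= p$pal_hw & y >= p$pal_y0 & y <= p$pl_y0 + p$pl_t &
    z >= p$pal_ztop - p$pal_t & z <= p$pal_ztop
}

.region_pillar <- function(x, y, z, p) {
  ax <- abs(x)
  ax >= p$pil_x0 & ax <= p$pil_x1 & y >= p$pil_y0 & y <= p$pil_y1 &
    z >= p$pal_ztop - p$pal_t & z <= p$pil_z1
}

.region_arch <- function(x, y, z, p) {
  (abs(x) - p$arch_x)^2 + (z - p$arch_z)^2 <= p$arch_r^2 &
    y >= p$arch_y0 & y <= p$arch_y1
}

.region_root <- function(x, y, z, p) {
  ax <- abs(x)
  ax >= p$root_x0 & ax <= p$arch_x + p$arch_r &
    y >= p$root_y0 & y <= p$root_y1 &
    z >= p$arch_z - p$arch_r & z <= p$arch_z + p$arch_r
}

.region_facial <- function(x, y, z, p) {
  .region_plate(x, y, z, p) | .region_palate(x, y, z, p) |
    .region_pillar(x, y, z, p)
}

.region_any <- function(x, y, z, p) {
  .region_shell(x, y, z, p) | .region_facial(x, y, z, p) |
    .region_arch(x, y, z, p) | .region_root(x, y, z, p)
}

# x-coordinate of the outer shell wall at (y, z); NA where outside
.wall_x <- function(y, z, p) {
  r2 <- 1 - (y / p$ay)^2 - (z / p$az)^2
  ifelse(r2 > 0, p$ax * sqrt(r2), NA_real_)
}

# flood fill over the occupied voxel array (6-connectivity); padding
# guarantees no occupied voxel touches the array boundary.
.components <- function(occ) {
  dims <- dim(occ)
  n <- prod(dims)
  offs <- c(-1L, 1L, -dims[1L], dims[1L],
            -(dims[1L] * dims[2L]), dims[1L] * dims[2L])
  occl <- as.vector(occ)
  comp <- integer(n)
  cid <- 0L
  remaining <- which(occl)
  while (length(remaining)) {
    cid <- cid + 1L
    frontier <- remaining[1L]
    comp[frontier] <- cid
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[nb >= 1L & nb <= n]
      nb <- nb[occl[nb] & comp[nb] == 0L]
      comp[nb] <- cid
      frontier <- nb
    }
    remaining <- remaining[comp[remaining] == 0L]
  }
  comp
}

# 5-tetrahedron split of a cube, two mirror-image variants selected by
# voxel parity.  Corner order: index = 1 + bx + 2 by + 4 bz.
.tet5_A <- rbind(c(1L, 2L, 3L, 5L), c(4L, 2L, 3L, 8L), c(6L, 2L, 8L, 5L),
                 c(7L, 3L, 5L, 8L), c(2L, 3L, 5L, 8L))
.tet5_B <- rbind(c(2L, 1L, 4L, 6L), c(3L, 1L, 4L, 7L), c(5L, 1L, 7L, 6L),
                 c(8L, 4L, 6L, 7L), c(1L, 4L, 6L, 7L))

.tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1L], , drop = FALSE] + nodes[tets[, 2L], , drop = FALSE] +
     nodes[tets[, 3L], , drop = FALSE] + nodes[tets[, 4L], , drop = FALSE]) / 4
}

.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 3L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  (a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
     a[, 2L] * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) +
     a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
}

.label_elements <- function(cx, cy, cz, p, active) {
  lab <- rep(NA_character_, length(cx))
  arch <- .region_arch(cx, cy, cz, p) | .region_root(cx, cy, cz, p)
  lab[arch] <- ifelse(cx[arch] > 0, "zygomatic_arch_L", "zygomatic_arch_R")
  facial <- is.na(lab) & .region_facial(cx, cy, cz, p)
  shell <- .region_shell(cx, cy, cz, p)
  lab[facial & shell] <- "facial_suture"
  lab[facial & !shell] <- "facial"
  rest <- is.na(lab)
  # suture bands need to be at least one voxel layer on each side of their
  # plane even when the nominal width is below the pitch
  hb <- pmax(p$suture_w / 2, p$pitch * (1 + 1e-9))
  base <- rest & cz < p$base_cut_z
  lab[base] <- ifelse(abs(cz[base] - p$base_joint_z) < hb,
                      "base_joint", "skull_base")
  top <- rest & !base
  font <- top & sqrt(cx^2 + (cy - p$coronal_y)^2) < p$fontanelle_r &
    cz > 0.55 * p$az
  lab[font] <- "anterior_fontanelle"
  top <- top & !font
  met <- top & abs(cx) < hb & cy > p$coronal_y
  sag <- top & abs(cx) < hb & cy <= p$coronal_y & cy >= p$lambdoid_y
  cor <- top & is.na(lab) & !met & !sag & abs(cy - p$coronal_y) < hb
  lam <- top & is.na(lab) & !met & !sag & abs(cy - p$lambdoid_y) < hb
  lab[met] <- "metopic"; lab[sag] <- "sagittal"
  lab[cor] <- "coronal"; lab[lam] <- "lambdoid"
  bone <- top & is.na(lab)
  lab[bone & cy > p$coronal_y] <- "frontal"
  lab[bone & cy < p$lambdoid_y] <- "occipital"
  lab[bone & is.na(lab)] <- "parietal"
  .relabel_closed(lab, active)
}

#' Build the labelled tetrahedral skull surrogate
#'
#' Voxelizes the parametric surrogate described by `params` on a regular
#' grid of the requested pitch and splits interior voxels into five
#' tetrahedra (parity-alternating, so the mesh conforms and is exactly
#' mirror-symmetric about the mid-sagittal plane).  Elements are labelled as
#' bone plates or suture bands according to the patency `schedule` at the
#' surrogate's age; all anatomical node sets (42 attachment landmarks, bite
#' points, TMJ nodes, nine facial probes, arch mid-span control nodes) are
#' snapped to mesh nodes.
#'
#' @param params a [skull_params()] object.
#' @param schedule active suture labels; defaults to
#'   `suture_schedule(params$age_months)`.
#' @return an object of class `skull_mesh` with fields `nodes` (N x 3 mm),
#'   `tets` (E x 4 node indices, positive orientation), `label` (E element
#'   region labels), `node_sets` (named list of node-index vectors),
#'   `landmarks` (data frame of the 42 attachment landmarks), `surface_nodes`,
#'   `mirror` (index of each node's mirror image), `arch_length` and `params`.
#' @export
#' @examples
#' mesh <- build_skull_mesh(skull_params(24, pitch = 3, size_scale = 0.65,
#'                                       shell_thickness = 7))
#' mesh
build_skull_mesh <- function(params, schedule = NULL) {
  p <- params
  if (!inherits(p, "skull_params"))
    stop("params must be a skull_params object", call. = FALSE)
  active <- if (is.null(schedule)) suture_schedule(p$age_months) else schedule
  h <- p$pitch

  # arch/wall separation must be resolvable at this pitch
  ys <- seq(p$root_y1, p$arch_y1 * 0.7, length.out = 25)
  wx <- .wall_x(ys, p$arch_z, p)
  gap <- (p$arch_x - p$arch_r) - wx
  if (any(!is.na(wx) & gap < 0.9 * h))
    stop("resolution error: voxel pitch ", h, " mm cannot keep the ",
         "zygomatic arch separated from the braincase wall", call. = FALSE)

  xmax <- max(p$pl_hw, p$arch_x + p$arch_r, p$ax) + 2 * h
  ymin <- -p$ay - 2 * h
  ymax <- max(p$ay, p$pl_y0 + p$pl_t) + 2 * h
  zmin <- min(p$pl_zlo, p$pal_ztop - p$pal_t, -p$az) - 2 * h
  zmax <- p$az + 2 * h
  nx <- as.integer(ceiling(xmax / h)) + 1L
  iy0 <- as.integer(floor(ymin / h)) - 1L; iy1 <- as.integer(ceiling(ymax / h))
  iz0 <- as.integer(floor(zmin / h)) - 1L; iz1 <- as.integer(ceiling(zmax / h))
  ix <- seq.int(-nx, nx - 1L)            # cell indices; x = 0 is a cell face
  iy <- seq.int(iy0, iy1); iz <- seq.int(iz0, iz1)
  cx <- (ix + 0.5) * h; cy <- (iy + 0.5) * h; cz <- (iz + 0.5) * h
  dims <- c(length(ix), length(iy), length(iz))

  X <- rep(cx, times = dims[2L] * dims[3L])
  Y <- rep(rep(cy, each = dims[1L]), times = dims[3L])
  Z <- rep(cz, each = dims[1L] * dims[2L])
  occ <- array(.region_any(X, Y, Z, p), dim = dims)

  if (!any(occ)) stop("empty surrogate: degenerate parameters", call. = FALSE)
  comp <- .components(occ)
  tab <- tabulate(comp[comp > 0L])
  main <- which.max(tab)
  if (sum(tab[-main]) > 0.02 * sum(tab))
    stop("resolution error: surrogate voxelization is disconnected at ",
         "pitch ", h, " mm", call. = FALSE)
  occ[] <- comp == main

  vox <- which(occ)
  vi <- arrayInd(vox, dims)
  # voxel corner lattice -> node ids
  cnx <- dims[1L] + 1L; cny <- dims[2L] + 1L; cnz <- dims[3L] + 1L
  corner_id <- array(0L, dim = c(cnx, cny, cnz))
  off <- cbind(x = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
               y = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
               z = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  nvox <- nrow(vi)
  corn <- matrix(0L, nvox, 8L)
  for (k in 1:8) {
    a <- vi[, 1L] + off[k, 1L]; b <- vi[, 2L] + off[k, 2L]
    d <- vi[, 3L] + off[k, 3L]
    corn[, k] <- a + (b - 1L) * cnx + (d - 1L) * (cnx * cny)
  }
  used <- sort(unique(as.vector(corn)))
  corner_id[used] <- seq_along(used)
  node_lin <- used
  ci <- arrayInd(node_lin, c(cnx, cny, cnz))
  node_idx <- cbind(ix[1L] + ci[, 1L] - 1L, iy[1L] + ci[, 2L] - 1L,
                    iz[1L] + ci[, 3L] - 1L)   # integer lattice coordinates
  nodes <- node_idx * h
  for (k in 1:8) corn[, k] <- corner_id[corn[, k]]

  parity <- (vi[, 1L] + vi[, 2L] + vi[, 3L]) %% 2L
  tets <- matrix(0L, nvox * 5L, 4L)
  for (v in 0:1) {
    sel <- parity == v
    pat <- if (v == 0L) .tet5_A else .tet5_B
    rows <- which(sel)
    for (t in 1:5) {
      idx <- (rows - 1L) * 5L + t
      tets[idx, ] <- corn[rows, pat[t, ]]
    }
  }
  vol <- .tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  vol <- abs(vol)
  if (any(vol <= 0)) stop("degenerate tetrahedra produced", call. = FALSE)

  cen <- .tet_centroids(nodes, tets)
  label <- .label_elements(cen[, 1L], cen[, 2L], cen[, 3L], p, active)

  need <- c(setdiff(.bone_labels, character(0)), active)
  missing <- setdiff(need, unique(label))
  if (length(missing))
    stop("resolution error: region(s) ", paste(missing, collapse = ", "),
         " not resolved at pitch ", h, " mm", call. = FALSE)

  # mirror map: node at (-ix, iy, iz)
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
  lut <- setNames(seq_len(nrow(node_idx)), key(node_idx))
  mirror <- unname(lut[key(cbind(-node_idx[, 1L], node_idx[, 2L],
                                 node_idx[, 3L]))])
  if (anyNA(mirror))
    stop("internal error: mesh is not mirror-symmetric", call. = FALSE)

  mesh <- list(nodes = nodes, node_idx = node_idx, tets = tets,
               label = label, volumes = vol, params = p,
               active_sutures = active, mirror = mirror,
               arch_length = p$arch_length)
  mesh$surface_nodes <- .surface_nodes(mesh)
  mesh$label_nodes <- .label_node_map(mesh)
  mesh$node_sets <- .build_node_sets(mesh)
  mesh$landmarks <- .build_landmarks(mesh)
  class(mesh) <- "skull_mesh"
  .check_mesh(mesh)
  mesh
}

# nodes lying on the mesh boundary (faces shared by a single tetrahedron)
.surface_nodes <- function(mesh) {
  tt <- mesh$tets
  f <- rbind(tt[, c(1L, 2L, 3L)], tt[, c(1L, 2L, 4L)],
             tt[, c(1L, 3L, 4L)], tt[, c(2L, 3L, 4L)])
  lo <- pmin(f[, 1L], f[, 2L], f[, 3L])
  hi <- pmax(f[, 1L], f[, 2L], f[, 3L])
  md <- f[, 1L] + f[, 2L] + f[, 3L] - lo - hi
  M <- as.numeric(nrow(mesh$nodes) + 1)
  keyv <- (as.numeric(lo) * M + md) * M + hi
  o <- order(keyv)
  kk <- keyv[o]
  dup <- c(kk[-1L] == kk[-length(kk)], FALSE)
  dup <- dup | c(FALSE, kk[-length(kk)] == kk[-1L])
  bnd <- o[!dup]
  sort(unique(as.vector(f[bnd, ])))
}

# label -> surface node ids (for attachment patch selection)
.label_node_map <- function(mesh) {
  surf <- mesh$surface_nodes
  is_surf <- logical(nrow(mesh$nodes)); is_surf[surf] <- TRUE
  out <- list()
  for (lb in unique(mesh$label)) {
    nd <- unique(as.vector(mesh$tets[mesh$label == lb, , drop = FALSE]))
    out[[lb]] <- nd[is_surf[nd]]
  }
  out
}

# nearest node to a target coordinate, optionally restricted to surface
# nodes adjacent to the given element labels
.snap_node <- function(mesh, target, labels = NULL) {
  cand <- if (is.null(labels)) seq_len(nrow(mesh$nodes)) else
    unique(unlist(mesh$label_nodes[intersect(labels, names(mesh$label_nodes))]))
  if (!length(cand)) cand <- seq_len(nrow(mesh$nodes))
  d2 <- (mesh$nodes[cand, 1L] - target[1L])^2 +
    (mesh$nodes[cand, 2L] - target[2L])^2 +
    (mesh$nodes[cand, 3L] - target[3L])^2
  cand[which.min(d2)]
}

.facial_labels <- c("facial", "facial_suture")
.zygo_labels <- c("zygomatic_arch_L", "zygomatic_arch_R")
.calvarial_labels <- c("frontal", "parietal", "occipital", "metopic",
                       "coronal", "sagittal", "lambdoid",
                       "anterior_fontanelle")

.build_node_sets <- function(mesh) {
  p <- mesh$params; s <- p$sites
  snapL <- function(target, labels) .snap_node(mesh, target, labels)
  mir <- function(i) mesh$mirror[i]
  inc_L <- snapL(s$incisor, .facial_labels)
  mol_L <- snapL(s$molar, .facial_labels)
  tmj_L <- vapply(s$tmj, snapL, integer(1), labels = "zygomatic_arch_L")
  mid_y <- (p$arch_y0 + p$arch_y1) / 2
  ctrl_L <- snapL(c(p$arch_x, mid_y, p$arch_z - p$arch_r), "zygomatic_arch_L")
  probes <- vapply(s$probes, snapL, integer(1),
                   labels = c(.facial_labels, .zygo_labels))
  list(bite_incisor = c(inc_L, mir(inc_L)),
       bite_molar_L = mol_L, bite_molar_R = mir(mol_L),
       tmj_L = tmj_L, tmj_R = mir(tmj_L),
       arch_control_L = ctrl_L, arch_control_R = mir(ctrl_L),
       probes = probes)
}

# 42 attachment landmarks: 12 per jaw muscle (3 origin + 3 insertion marks
# per side) and 6 for the temporal fascia (3 marks per side on the temporal
# wall).  Insertion marks of the jaw muscles are virtual (the surrogate has
# no mandible); they define force directions and are nominally snapped to
# the nearest mesh node for the node-set contract.
.build_landmarks <- function(mesh) {
  p <- mesh$params; a <- p$attach
  rows <- list()
  add <- function(muscle, side, role, station, coord, labels = NULL) {
    sgn <- if (side == "L") 1 else -1
    coord <- c(sgn * coord[1L], coord[2L], coord[3L])
    node <- .snap_node(mesh, coord, labels)
    rows[[length(rows) + 1L]] <<- data.frame(
      muscle = muscle, side = side, role = role, station = station,
      x = coord[1L], y = coord[2L], z = coord[3L], node = node,
      stringsAsFactors = FALSE)
  }
  arch_y <- function(fr) p$arch_y0 + fr * (p$arch_y1 - p$arch_y0)
  dy <- 0.04 * p$ay
  for (side in c("L", "R")) {
    for (k in 1:3) {   # temporalis origins on the temporal wall
      y <- a$tem_o[k, 2L]; z <- a$tem_o[k, 3L]
      x <- .wall_x(y, z, p)
      add("temporalis", side, "origin", k, c(x, y, z), .calvarial_labels)
    }
    for (k in 1:3)
      add("temporalis", side, "insertion", k,
          a$tem_i + c(0, (k - 2) * dy, 0))
  }
  for (side in c("L", "R")) {
    for (k in 1:3)
      add("masseter", side, "origin", k,
          c(p$arch_x, arch_y(a$mas_fr[k]), p$arch_z - p$arch_r),
          .zygo_labels)
    for (k in 1:3)
      add("masseter", side, "insertion", k, a$mas_i + c(0, (k - 2) * dy, 0))
  }
  for (side in c("L", "R")) {
    for (k in 1:3)
      add("medial_pterygoid", side, "origin", k,
          a$pt_o + c(0, (k - 2) * 0.5 * dy, 0), .facial_labels)
    for (k in 1:3)
      add("medial_pterygoid", side, "insertion", k,
          a$pt_i + c(0, (k - 2) * dy, 0))
  }
  for (side in c("L", "R")) {
    for (k in 1:3) {   # fascia marks overlying the temporalis
      y <- arch_y(a$fas_fr[k]); z <- a$fas_z
      x <- .wall_x(y, z, p)
      add("fascia", side, "mark", k, c(x, y, z), .calvarial_labels)
    }
  }
  lm <- do.call(rbind, rows)
  lm$number <- seq_len(nrow(lm))
  lm
}

.check_mesh <- function(mesh) {
  ns <- mesh$node_sets
  bite <- c(ns$bite_incisor, ns$bite_molar_L, ns$bite_molar_R)
  tmj <- c(ns$tmj_L, ns$tmj_R)
  if (!(max(mesh$nodes[bite, 3L]) < min(mesh$nodes[tmj, 3L])))
    stop("geometry error: bite nodes are not inferior to the TMJ nodes",
         call. = FALSE)
  if (!(min(mesh$nodes[bite, 2L]) > max(mesh$nodes[tmj, 2L])))
    stop("geometry error: bite nodes are not anterior to the TMJ nodes",
         call. = FALSE)
  invisible(mesh)
}

#' @export
print.skull_mesh <- function(x, ...) {
  cat("<skull_mesh> age", x$params$age_months, "months:",
      nrow(x$nodes), "nodes,", nrow(x$tets), "tetrahedra\n")
  tb <- sort(table(x$label), decreasing = TRUE)
  cat("  regions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  cat("  patent sutures:",
      if (length(x$active_sutures)) paste(x$active_sutures, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
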