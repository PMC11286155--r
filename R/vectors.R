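# Construction of muscle and temporal-fascia force vectors on the surrogate
# and their assembly into a nodal load vector.

#' Build muscle (and optionally fascia) force vectors
#'
#' For each jaw muscle and side, emits `vectors_per_side` force vectors from
#' the muscle's origin landmarks towards the paired insertion landmarks,
#' each with magnitude per-side force divided by the number of vectors on
#' that side.  Each vector's force is spread uniformly over the surface
#' nodes of the origin attachment patch (nodes within `attach_radius` of the
#' origin landmark, restricted to the anatomically admissible region).
#' Fascia vectors originate on the superior border of the zygomatic arch and
#' point towards the fascia marks overlying the temporalis; no counter-force
#' is applied at the temporal lines (the model's deliberate simplification),
#' unless `fascia_counterforce` is set.
#'
#' @param mesh a [build_skull_mesh()] result.
#' @param forces named per-side forces in N (names `temporalis`, `masseter`,
#'   `medial_pterygoid`); a muscle absent from the vector is not loaded.
#' @param constants a [muscle_constants()].
#' @param include_fascia logical; add temporal fascia vectors.
#' @param fascia_force total fascia force per side in N.
#' @param fascia_counterforce logical; also apply the equal-and-opposite
#'   fascia force at the temporal-line marks (off by default).
#' @return object of class `muscle_vectors`: a data frame with one row per
#'   vector (tag, side, station, unit direction, magnitude in N, number of
#'   patch nodes) carrying the patch node indices as a list column.
#' @export
build_vectors <- function(mesh, forces, constants = muscle_constants(),
                          include_fascia = FALSE, fascia_force = 0,
                          fascia_counterforce = FALSE) {
  lm <- mesh$landmarks
  nv <- constants$vectors_per_side
  stations <- switch(nv, 2L, c(1L, 3L), 1:3)
  patch_labels <- list(temporalis = .calvarial_labels,
                       masseter = .zygo_labels,
                       medial_pterygoid = .facial_labels)
  rows <- list()
  emit <- function(tag, side, station, origin, target, magnitude, labels) {
    dir <- target - origin
    len <- sqrt(sum(dir^2))
    if (len < 1e-9)
      stop("degenerate-direction error: origin and insertion coincide for ",
           tag, " ", side, " station ", station, call. = FALSE)
    dir <- dir / len
    nodes <- .attachment_patch(mesh, origin, labels,
                               constants$attach_radius, side)
    rows[[length(rows) + 1L]] <<- list(
      tag = tag, side = side, station = station,
      dx = dir[1L], dy = dir[2L], dz = dir[3L],
      magnitude = magnitude, nodes = nodes)
  }
  for (m in intersect(constants$muscles, names(forces))) {
    fside <- forces[[m]]
    for (side in c("L", "R")) for (k in stations) {
      o <- lm[lm$muscle == m & lm$side == side & lm$role == "origin" &
                lm$station == k, ]
      i <- lm[lm$muscle == m & lm$side == side & lm$role == "insertion" &
                lm$station == k, ]
      if (nrow(o) != 1L || nrow(i) != 1L)
        stop("lookup error: missing landmark for ", m, " ", side,
             " station ", k, call. = FALSE)
      emit(m, side, k, c(o$x, o$y, o$z), c(i$x, i$y, i$z),
           fside / length(stations), patch_labels[[m]])
    }
  }
  if (include_fascia) {
    p <- mesh$params; a <- p$attach
    nfs <- constants$fascia_vectors / 2L
    fr <- if (nfs == 3L) a$fas_fr else
      seq(max(a$fas_fr), min(a$fas_fr), length.out = nfs)
    for (side in c("L", "R")) {
      sgn <- if (side == "L") 1 else -1
      arch_lab <- paste0("zygomatic_arch_", side)
      for (k in seq_len(nfs)) {
        y <- p$arch_y0 + fr[k] * (p$arch_y1 - p$arch_y0)
        origin <- c(sgn * p$arch_x, y, p$arch_z + p$arch_r)
        target <- c(sgn * .wall_x(y, a$fas_z, p), y, a$fas_z)
        emit("fascia", side, k, origin, target, fascia_force / nfs, arch_lab)
        if (fascia_counterforce) {
          # reversed force at the temporal-line attachment (exploration only)
          nodes <- .attachment_patch(mesh, target, .calvarial_labels,
                                     constants$attach_radius, side)
          dir <- (origin - target) / sqrt(sum((origin - target)^2))
          rows[[length(rows) + 1L]] <- list(
            tag = "fascia_counter", side = side, station = k,
            dx = dir[1L], dy = dir[2L], dz = dir[3L],
            magnitude = fascia_force / nfs, nodes = nodes)
        }
      }
    }
  }
  df <- data.frame(tag = vapply(rows, `[[`, "", "tag"),
                   side = vapply(rows, `[[`, "", "side"),
                   station = vapply(rows, `[[`, 0L, "station"),
                   dx = vapply(rows, `[[`, 0, "dx"),
                   dy = vapply(rows, `[[`, 0, "dy"),
                   dz = vapply(rows, `[[`, 0, "dz"),
                   magnitude_N = vapply(rows, `[[`, 0, "magnitude"),
                   n_nodes = vapply(rows, function(r) length(r$nodes), 0L),
                   stringsAsFactors = FALSE)
  df$nodes <- lapply(rows, `[[`, "nodes")
  class(df) <- c("muscle_vectors", "data.frame")
  attr(df, "n_mesh_nodes") <- nrow(mesh$nodes)
  df
}

# surface nodes within radius of the origin, restricted to admissible
# element labels and to the origin's side of the head
.attachment_patch <- function(mesh, origin, labels, radius, side) {
  cand <- unique(unlist(mesh$label_nodes[
    intersect(labels, names(mesh$label_nodes))]))
  if (length(cand)) {
    xs <- mesh$nodes[cand, 1L]
    keep <- if (side == "L") xs > -1e-9 else xs < 1e-9
    cand <- cand[keep]
  }
  if (!length(cand)) return(.snap_node(mesh, origin))
  d2 <- (mesh$nodes[cand, 1L] - origin[1L])^2 +
    (mesh$nodes[cand, 2L] - origin[2L])^2 +
    (mesh$nodes[cand, 3L] - origin[3L])^2
  hit <- cand[d2 <= radius^2]
  if (!length(hit)) hit <- cand[which.min(d2)]
  sort(hit)
}

#' Assemble a nodal load vector from force vectors
#'
#' @param vectors a [build_vectors()] result.
#' @param scale optional scalar multiplying all magnitudes.
#' @param tags restrict to these tags (default: all).
#' @return numeric vector of length 3N (N mesh nodes), in newtons.
#' @export
load_from_vectors <- function(vectors, scale = 1, tags = NULL) {
  nN <- attr(vectors, "n_mesh_nodes")
  f <- numeric(3L * nN)
  sel <- if (is.null(tags)) seq_len(nrow(vectors)) else
    which(vectors$tag %in% tags)
  for (r in sel) {
    nodes <- vectors$nodes[[r]]
    w <- scale * vectors$magnitude_N[r] / length(nodes)
    d <- c(vectors$dx[r], vectors$dy[r], vectors$dz[r])
    for (ax in 1:3)
      f[3L * (nodes - 1L) + ax] <- f[3L * (nodes - 1L) + ax] + w * d[ax]
  }
  f
}

#' @export
print.muscle_vectors <- function(x, ...) {
  agg <- stats::aggregate(magnitude_N ~ tag + side, data = as.data.frame(x),
                          FUN = sum)
  cat("<muscle_vectors>", nrow(x), "vectors; per-side totals (N):\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
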