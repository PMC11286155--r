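# Bite pipeline: constraints per bite mode, full per-run orchestration
# (muscle forces -> vectors -> optional fascia balance -> solve -> bite
# force, TMJ reactions, probe fields), the age x mode x fascia sweep, and a
# rigid-body equilibrium oracle for cross-checking lever mechanics.

#' Constraints for a bite mode
#'
#' Mode 1: bilateral first molars; mode 2: bilateral central incisors;
#' mode 3: unilateral left first molar.  The two TMJ nodes per side are
#' constrained in all modes.  All constraints fix the three translations.
#'
#' @param mesh a [build_skull_mesh()] result.
#' @param mode 1, 2 or 3.
#' @return a [constraint_set()].
#' @export
bite_constraints <- function(mesh, mode) {
  ns <- mesh$node_sets
  bite <- switch(as.integer(mode),
                 c(ns$bite_molar_L, ns$bite_molar_R),
                 ns$bite_incisor,
                 ns$bite_molar_L)
  if (is.null(bite)) stop("mode must be 1, 2 or 3", call. = FALSE)
  constraint_set(c(bite, ns$tmj_L, ns$tmj_R),
                 role = c(rep("bite", length(bite)),
                          rep("tmj", length(ns$tmj_L) + length(ns$tmj_R))))
}

#' Run one bite simulation
#'
#' Evaluates per-side muscle forces at the mesh's age from the growth model,
#' builds the muscle vectors, optionally balances and adds the temporal
#' fascia, solves the constrained elastic problem and extracts the bite
#' force (reactions at the bite constraints), per-side TMJ reactions and the
#' nine facial probe values.
#'
#' @param fm a [fem_assemble()] result (or a `skull_mesh`, assembled on the
#'   fly).
#' @param growth a [fit_growth()] model, or a named list of per-side forces
#'   in N.
#' @param mode bite mode 1, 2 or 3.
#' @param with_fascia logical; balance and apply the temporal fascia.
#' @param constants a [muscle_constants()].
#' @param tff optional fascia force per side (N) to apply directly,
#'   bypassing the balancing solve.
#' @param scale scalar multiplying all applied loads (for linearity checks).
#' @return object of class `bite_result`: total bite force (sum of
#'   reaction-vector magnitudes over bite nodes) and its occlusal (z)
#'   component, per-side TMJ reaction magnitudes, the fascia result (if
#'   any), the probe table, and the solution/field objects.
#' @export
run_bite <- function(fm, growth, mode = 1L, with_fascia = FALSE,
                     constants = muscle_constants(), tff = NULL, scale = 1) {
  if (inherits(fm, "skull_mesh")) fm <- fem_assemble(fm)
  mesh <- fm$mesh
  forces <- if (inherits(growth, "growth_model"))
    as.list(muscle_forces_at(growth, fm$age_months)) else as.list(growth)
  fct <- fem_factor(fm, bite_constraints(mesh, mode))
  fascia <- NULL
  if (with_fascia && is.null(tff)) {
    fct1 <- if (mode == 1L) fct else NULL
    fascia <- solve_tff(fm, forces, constants, factor = fct1)
    tff <- fascia$tff_N
  }
  vec <- build_vectors(mesh, forces, constants,
                       include_fascia = with_fascia,
                       fascia_force = if (with_fascia) tff else 0)
  f <- load_from_vectors(vec, scale = scale)
  sol <- fem_solve_factored(fct, f)
  con <- fct$constraints
  rb <- sol$reactions[con$role == "bite", , drop = FALSE]
  rt <- sol$reactions[con$role == "tmj", , drop = FALSE]
  tmj_nodes <- con$node[con$role == "tmj"]
  left <- mesh$nodes[tmj_nodes, 1L] > 0
  tmj_L <- sqrt(sum(colSums(rt[left, , drop = FALSE])^2))
  tmj_R <- sqrt(sum(colSums(rt[!left, , drop = FALSE])^2))
  field <- strain_stress(fm, sol)
  res <- list(age_months = fm$age_months, mode = mode,
              with_fascia = with_fascia,
              bite_force_N = sum(sqrt(rowSums(rb^2))),
              bite_force_z_N = abs(sum(rb[, 3L])),
              tmj_L_N = tmj_L, tmj_R_N = tmj_R,
              tff_N = if (with_fascia) tff else 0,
              fascia = fascia, forces = forces,
              probes = probe_fields(fm, field),
              solution = sol, field = field, load = f)
  class(res) <- "bite_result"
  res
}

#' @export
print.bite_result <- function(x, ...) {
  cat(sprintf(paste0("<bite_result> age %s, mode %d, fascia %s: bite ",
                     "%.1f N (z %.1f N), TMJ L %.1f / R %.1f N\n"),
              format(x$age_months), x$mode,
              if (x$with_fascia) sprintf("%.1f N", x$tff_N) else "off",
              x$bite_force_N, x$bite_force_z_N, x$tmj_L_N, x$tmj_R_N))
  invisible(x)
}

#' Probe the von Mises fields at the nine facial locations
#'
#' The nodal value at each probe is the volume-weighted average of the von
#' Mises values of the elements sharing the probe node.
#'
#' @param fm a [fem_assemble()] result.
#' @param field a [strain_stress()] result.
#' @param probes named integer node indices; defaults to the mesh's nine
#'   facial probes.
#' @return data frame: `probe` (1..9), `location`, `node`,
#'   `von_mises_strain_ue`, `von_mises_stress_MPa`.
#' @export
probe_fields <- function(fm, field, probes = NULL) {
  mesh <- fm$mesh
  if (is.null(probes)) probes <- mesh$node_sets$probes
  if (anyNA(probes) || any(probes < 1L | probes > nrow(mesh$nodes)))
    stop("lookup error: missing probe node", call. = FALSE)
  out <- data.frame(probe = seq_along(probes),
                    location = if (!is.null(names(probes))) names(probes)
                    else as.character(seq_along(probes)),
                    node = as.integer(probes),
                    von_mises_strain_ue = NA_real_,
                    von_mises_stress_MPa = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(probes)) {
    el <- which(mesh$tets[, 1L] == probes[i] | mesh$tets[, 2L] == probes[i] |
                  mesh$tets[, 3L] == probes[i] | mesh$tets[, 4L] == probes[i])
    if (!length(el)) stop("lookup error: probe node ", probes[i],
                          " belongs to no element", call. = FALSE)
    w <- mesh$volumes[el] / sum(mesh$volumes[el])
    out$von_mises_strain_ue[i] <- sum(w * field$von_mises_strain[el])
    out$von_mises_stress_MPa[i] <- sum(w * field$von_mises_stress[el])
  }
  out
}

#' Run the full age x mode x fascia sweep
#'
#' Builds (or reuses) the surrogate per age, assembles once per age, runs
#' every requested (mode, fascia) combination and returns one row per run
#' plus derived columns: the mode2/mode1 bite-force ratio, the fascia
#' bite-force reduction, and the TFF ratios.  A failed cell is recorded with
#' its error message and does not abort the sweep.
#'
#' @param growth a [fit_growth()] model (or named per-side force list used
#'   at every age).
#' @param ages ages in months.
#' @param modes bite modes.
#' @param fascia logical vector of fascia flags.
#' @param constants a [muscle_constants()].
#' @param mesh_fun function(age) returning a `skull_mesh`; defaults to the
#'   calibrated surrogate at the given pitch.
#' @param pitch voxel pitch passed to the default `mesh_fun`.
#' @param keep_fields keep per-run solution/field objects (memory-hungry).
#' @return a `bite_series` data frame.
#' @export
run_series <- function(growth, ages = c(3, 6, 12, 24, 36, 48),
                       modes = 1:3, fascia = c(FALSE, TRUE),
                       constants = muscle_constants(),
                       mesh_fun = NULL, pitch = 2, keep_fields = FALSE) {
  if (is.null(mesh_fun))
    mesh_fun <- function(age) build_skull_mesh(skull_params(age, pitch = pitch))
  rows <- list(); details <- list()
  for (age in ages) {
    fm <- tryCatch(fem_assemble(mesh_fun(age)), error = function(e) e)
    for (md in modes) for (fs in fascia) {
      key <- sprintf("age%s_mode%d_%s", age, md, if (fs) "tff" else "notff")
      if (inherits(fm, "error")) {
        rows[[key]] <- data.frame(age_months = age, mode = md,
                                  with_fascia = fs, bite_force_N = NA,
                                  bite_force_z_N = NA, tmj_L_N = NA,
                                  tmj_R_N = NA, tff_N = NA,
                                  error = conditionMessage(fm))
        next
      }
      br <- tryCatch(run_bite(fm, growth, mode = md, with_fascia = fs,
                              constants = constants),
                     error = function(e) e)
      if (inherits(br, "error")) {
        rows[[key]] <- data.frame(age_months = age, mode = md,
                                  with_fascia = fs, bite_force_N = NA,
                                  bite_force_z_N = NA, tmj_L_N = NA,
                                  tmj_R_N = NA, tff_N = NA,
                                  error = conditionMessage(br))
      } else {
        rows[[key]] <- data.frame(age_months = age, mode = md,
                                  with_fascia = fs,
                                  bite_force_N = br$bite_force_N,
                                  bite_force_z_N = br$bite_force_z_N,
                                  tmj_L_N = br$tmj_L_N, tmj_R_N = br$tmj_R_N,
                                  tff_N = br$tff_N, error = NA_character_)
        if (keep_fields) details[[key]] <- br
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(age_months = numeric(0), mode = integer(0),
                      with_fascia = logical(0), bite_force_N = numeric(0),
                      bite_force_z_N = numeric(0), tmj_L_N = numeric(0),
                      tmj_R_N = numeric(0), tff_N = numeric(0),
                      error = character(0))
  } else out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out)) {
    out$mode2_mode1_ratio <- NA_real_
    out$fascia_reduction_pct <- NA_real_
    for (r in seq_len(nrow(out))) {
      m1 <- out$bite_force_N[out$age_months == out$age_months[r] &
                               out$mode == 1L &
                               out$with_fascia == out$with_fascia[r]]
      if (out$mode[r] == 2L && length(m1) == 1L && !is.na(m1))
        out$mode2_mode1_ratio[r] <- out$bite_force_N[r] / m1
      if (out$with_fascia[r]) {
        b0 <- out$bite_force_N[out$age_months == out$age_months[r] &
                                 out$mode == out$mode[r] & !out$with_fascia]
        if (length(b0) == 1L && !is.na(b0))
          out$fascia_reduction_pct[r] <- 100 * (b0 - out$bite_force_N[r]) / b0
      }
    }
  }
  attr(out, "details") <- details
  class(out) <- c("bite_series", "data.frame")
  out
}

#' Rigid-body equilibrium oracle
#'
#' Predicts the resultant bite and TMJ forces by static force/moment balance
#' of the cranium as a rigid body, with the bite constraint idealized as a
#' purely vertical (occlusal) support.  For the bilateral modes the mirror
#' symmetry reduces the statics to a uniquely solvable lever problem; for
#' mode 3 the balance is solved in the least-squares (minimum-norm) sense.
#' Used to cross-check the finite-element totals and to reason about lever
#' arms.
#'
#' @param mesh a [build_skull_mesh()] result.
#' @param vectors a [build_vectors()] result (the applied loads).
#' @param mode bite mode 1, 2 or 3.
#' @return list with `bite_force_N` (vertical bite resultant, positive =
#'   superior reaction on the cranium), `tmj_force_N` (per-side resultant
#'   magnitude), `applied_force`, `applied_moment` (about the TMJ midpoint).
#' @export
rigid_equilibrium_oracle <- function(mesh, vectors, mode = 1L) {
  ns <- mesh$node_sets
  tmj_nodes <- c(ns$tmj_L, ns$tmj_R)
  tmj_c <- colMeans(mesh$nodes[tmj_nodes, , drop = FALSE])
  bite_nodes <- switch(as.integer(mode),
                       c(ns$bite_molar_L, ns$bite_molar_R),
                       ns$bite_incisor,
                       ns$bite_molar_L)
  bite_c <- colMeans(mesh$nodes[bite_nodes, , drop = FALSE])
  # resultant applied force and moment about the TMJ midpoint
  Fap <- c(0, 0, 0); Map <- c(0, 0, 0)
  for (r in seq_len(nrow(vectors))) {
    d <- c(vectors$dx[r], vectors$dy[r], vectors$dz[r])
    nodes <- vectors$nodes[[r]]
    w <- vectors$magnitude_N[r] / length(nodes)
    for (nd in nodes) {
      fr <- w * d
      arm <- mesh$nodes[nd, ] - tmj_c
      Fap <- Fap + fr
      Map <- Map + c(arm[2L] * fr[3L] - arm[3L] * fr[2L],
                     arm[3L] * fr[1L] - arm[1L] * fr[3L],
                     arm[1L] * fr[2L] - arm[2L] * fr[1L])
    }
  }
  rb <- bite_c - tmj_c
  if (mode %in% c(1L, 2L)) {
    if (abs(rb[2L]) < 1e-9)
      stop("degeneracy error: bite point lies on the TMJ axis", call. = FALSE)
    Bz <- -Map[1L] / rb[2L]          # moment balance about the TMJ x-axis
    Tf <- -(Fap + c(0, 0, Bz))       # total TMJ force, split equally L/R
    list(bite_force_N = abs(Bz), tmj_force_N = sqrt(sum((Tf / 2)^2)),
         applied_force = Fap, applied_moment = Map)
  } else {
    tl <- colMeans(mesh$nodes[ns$tmj_L, , drop = FALSE]) - tmj_c
    tr <- colMeans(mesh$nodes[ns$tmj_R, , drop = FALSE]) - tmj_c
    skew <- function(v) rbind(c(0, -v[3L], v[2L]),
                              c(v[3L], 0, -v[1L]),
                              c(-v[2L], v[1L], 0))
    # unknowns: Bz, T_L (3), T_R (3); equations: force and moment balance
    A <- rbind(cbind(matrix(c(0, 0, 1), 3L, 1L), diag(3), diag(3)),
               cbind(matrix(c(rb[2L], -rb[1L], 0), 3L, 1L),
                     skew(tl), skew(tr)))
    b <- -c(Fap, Map)
    x <- MASS::ginv(A) %*% b
    list(bite_force_N = abs(x[1L]),
         tmj_force_N = c(L = sqrt(sum(x[2:4]^2)), R = sqrt(sum(x[5:7]^2))),
         applied_force = Fap, applied_moment = Map)
  }
}
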