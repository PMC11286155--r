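# Temporal fascia force (TFF) estimation: the minimum fascia force that
# prevents inferior deflection of the zygomatic arch under the muscle loads.
# Displacement is affine in the fascia scale, so the balancing force follows
# from the baseline solve and one unit-fascia sensitivity solve.

#' Balance criterion for the fascia solve
#'
#' @param tolerance admissible residual inferior deflection (mm) at the arch
#'   mid-span control nodes.
#' @param control optional integer node indices `c(L, R)` overriding the
#'   mesh's arch mid-span control nodes.
#' @return object of class `balance_criterion`.
#' @export
balance_criterion <- function(tolerance = 1e-6, control = NULL) {
  structure(list(tolerance = tolerance, control = control),
            class = "balance_criterion")
}

#' Solve for the balancing temporal fascia force
#'
#' Solves the model twice under the bite-mode constraints — once with the
#' muscle loads only, once with a unit (1 N per side) fascia load — and
#' scales the fascia load so that the vertical displacement of the arch
#' mid-span control node returns to zero.  Both arches must be balanced; the
#' larger required force is taken (they coincide on the symmetric
#' surrogate).  The result is verified by re-solving at the balanced scale.
#'
#' @param fm a [fem_assemble()] result.
#' @param forces named per-side muscle forces (N), as for [build_vectors()].
#' @param constants a [muscle_constants()].
#' @param mode bite mode used for the constraints during balancing
#'   (default 1, bilateral first molars).
#' @param criterion a [balance_criterion()].
#' @param factor optional pre-computed factorization (from the same
#'   constraints), reused if supplied.
#' @return object of class `fascia_result`: `tff_N` per side, scale factor
#'   `s_star`, `ratio_masseter_pct`, `ratio_temporalis_pct`, `residual_mm`.
#' @export
solve_tff <- function(fm, forces, constants = muscle_constants(),
                      mode = 1L, criterion = balance_criterion(),
                      factor = NULL) {
  mesh <- fm$mesh
  ctrl <- if (!is.null(criterion$control)) criterion$control else
    c(mesh$node_sets$arch_control_L, mesh$node_sets$arch_control_R)
  ctrl_dof <- 3L * (ctrl - 1L) + 3L   # vertical (z) component
  if (is.null(factor))
    factor <- fem_factor(fm, bite_constraints(mesh, mode))
  v0 <- build_vectors(mesh, forces, constants, include_fascia = FALSE)
  f0 <- load_from_vectors(v0)
  u0 <- fem_solve_factored(factor, f0)$u[ctrl_dof]
  v1 <- build_vectors(mesh, forces = list(), constants,
                      include_fascia = TRUE, fascia_force = 1)
  f1 <- load_from_vectors(v1)
  du <- fem_solve_factored(factor, f1)$u[ctrl_dof]
  if (any(abs(du) < 1e-14))
    stop("degeneracy error: fascia load cannot move the arch control node",
         call. = FALSE)
  if (all(u0 >= 0)) {
    warning("arch is not deflected inferiorly; TFF = 0")
    s <- 0
  } else {
    s <- max(0, -u0 / du)   # larger requirement across the two arches
  }
  resid <- min(u0 + s * du)
  if (s > 0) {
    # verification re-solve at the balanced scale
    uv <- fem_solve_factored(factor, f0 + s * f1)$u[ctrl_dof]
    resid <- min(uv)
    if (resid < -criterion$tolerance)
      stop("fascia balance verification failed: residual ", format(resid),
           " mm", call. = FALSE)
  }
  structure(list(
    tff_N = s, s_star = s, residual_mm = resid,
    ratio_masseter_pct = if (!is.null(forces$masseter))
      100 * s / forces$masseter else NA_real_,
    ratio_temporalis_pct = if (!is.null(forces$temporalis))
      100 * s / forces$temporalis else NA_real_,
    age_months = fm$age_months, mode = mode),
    class = "fascia_result")
}

#' @export
print.fascia_result <- function(x, ...) {
  cat(sprintf(paste0("<fascia_result> age %s months: TFF = %.2f N/side ",
                     "(%.1f%% of masseter, %.1f%% of temporalis), ",
                     "residual %.2e mm\n"),
              format(x$age_months), x$tff_N, x$ratio_masseter_pct,
              x$ratio_temporalis_pct, x$residual_mm))
  invisible(x)
}

#' Transfer a balanced fascia force across ages by arch length
#'
#' Scales a reference TFF by the ratio of effective zygomatic arch lengths
#' (force-per-millimetre transfer), as an alternative to re-balancing each
#' age directly.
#'
#' @param reference a [solve_tff()] result.
#' @param ref_mesh the mesh the reference was solved on.
#' @param target_mesh the mesh to transfer to.
#' @return TFF per side (N) for the target mesh.
#' @export
scale_tff_by_arch_length <- function(reference, ref_mesh, target_mesh) {
  L0 <- ref_mesh$arch_length; L1 <- target_mesh$arch_length
  if (L0 <= 0 || L1 <= 0)
    stop("zero arch length", call. = FALSE)
  reference$tff_N / L0 * L1
}
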