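# Muscle model: the two-plane CSA_max sectioning protocol, CSA -> force
# conversion via the muscle stress factor, the monotone growth regression of
# per-side muscle forces, and construction of attachment force vectors.

#' Muscle model constants
#'
#' @param stress_factor muscle stress factor in N/cm^2 converting maximum
#'   anatomical cross-sectional area to peak force (default 37).
#' @param vectors_per_side number of force vectors per muscle per side
#'   (default 3, i.e. six vectors per muscle).
#' @param fascia_vectors total number of temporal fascia vectors (6 or 8).
#' @param attach_radius radius (mm) of the surface patch over which each
#'   vector's force is spread around its origin landmark.
#' @return object of class `muscle_constants`.
#' @export
muscle_constants <- function(stress_factor = 37, vectors_per_side = 3L,
                             fascia_vectors = 6L, attach_radius = 4) {
  if (stress_factor <= 0) stop("stress_factor must be positive", call. = FALSE)
  if (vectors_per_side < 1L || vectors_per_side > 3L)
    stop("vectors_per_side must be 1, 2 or 3", call. = FALSE)
  if (!fascia_vectors %in% c(6L, 8L))
    stop("fascia_vectors must be 6 or 8", call. = FALSE)
  structure(list(stress_factor = stress_factor,
                 vectors_per_side = as.integer(vectors_per_side),
                 fascia_vectors = as.integer(fascia_vectors),
                 attach_radius = attach_radius,
                 muscles = c("temporalis", "masseter", "medial_pterygoid")),
            class = "muscle_constants")
}

#' Two-plane sectioning protocol
#'
#' The maximum anatomical cross-sectional area is measured as the mean of
#' the areas cut by a reference plane P1 and a second plane P2 exactly 2 mm
#' above it along the plane normal.
#'
#' @param normal unit plane normal (sections are perpendicular to the mean
#'   fibre direction).
#' @param p1_offset offset of P1 along the normal, mm.
#' @return object of class `sectioning_protocol` (P2 = P1 + 2 mm).
#' @export
sectioning_protocol <- function(normal = c(0, 0, 1), p1_offset = 0) {
  n2 <- sqrt(sum(normal^2))
  if (abs(n2 - 1) > 1e-8)
    stop("plane normal must be unit length", call. = FALSE)
  structure(list(normal = normal, p1 = p1_offset, p2 = p1_offset + 2),
            class = "sectioning_protocol")
}

#' Synthetic muscle mask volume
#'
#' Voxelizes a simple solid as a boolean volume for exercising the CSA
#' protocol: an elliptic cylinder (`dims = c(semi_a, semi_b, height)`), a
#' cone (`dims = c(base_radius, height)`, apex up), or a rectangular prism
#' (`dims = c(width_x, width_y, height)`, full widths).  The solid's axis is
#' z, its base at z = 0.
#'
#' @param shape `"elliptic_cylinder"`, `"cone"` or `"prism"`.
#' @param dims dimensions in mm (see above).
#' @param pitch voxel pitch in mm; scalar or per-axis length 3.
#' @param label name recorded with the mask.
#' @return object of class `muscle_mask`: logical 3-D array `vox`, per-axis
#'   `pitch`, and `origin` such that the centre of voxel (i,j,k) is
#'   `origin + (c(i,j,k) - 0.5) * pitch`.
#' @export
make_muscle_mask <- function(shape = c("elliptic_cylinder", "cone", "prism"),
                             dims, pitch = 0.5, label = shape[1L]) {
  shape <- match.arg(shape)
  pitch <- rep_len(pitch, 3L)
  if (any(pitch <= 0) || any(dims <= 0))
    stop("dims and pitch must be positive", call. = FALSE)
  need <- switch(shape, elliptic_cylinder = 3L, cone = 2L, prism = 3L)
  if (length(dims) != need)
    stop(shape, " needs ", need, " dimensions", call. = FALSE)
  ext <- switch(shape,
                elliptic_cylinder = c(dims[1L], dims[2L], dims[3L] / 2),
                cone = c(dims[1L], dims[1L], dims[2L] / 2),
                prism = c(dims[1L] / 2, dims[2L] / 2, dims[3L] / 2))
  if (any(2 * ext <= pitch))
    stop("degenerate dims: voxel pitch exceeds the solid", call. = FALSE)
  half <- ext + pitch          # one empty voxel of margin
  n <- ceiling(half / pitch)
  cx <- (seq_len(2 * n[1L]) - n[1L] - 0.5) * pitch[1L]
  cy <- (seq_len(2 * n[2L]) - n[2L] - 0.5) * pitch[2L]
  cz <- (seq_len(2 * n[3L]) - n[3L] - 0.5) * pitch[3L] + ext[3L]
  X <- rep(cx, times = length(cy) * length(cz))
  Y <- rep(rep(cy, each = length(cx)), times = length(cz))
  Z <- rep(cz, each = length(cx) * length(cy))
  inside <- switch(shape,
    elliptic_cylinder = (X / dims[1L])^2 + (Y / dims[2L])^2 <= 1 &
      Z >= 0 & Z <= dims[3L],
    cone = {
      r <- dims[1L] * pmax(0, 1 - Z / dims[2L])
      X^2 + Y^2 <= r^2 & Z >= 0 & Z <= dims[2L]
    },
    prism = abs(X) <= dims[1L] / 2 & abs(Y) <= dims[2L] / 2 &
      Z >= 0 & Z <= dims[3L])
  vox <- array(inside, dim = c(length(cx), length(cy), length(cz)))
  if (!any(vox)) stop("degenerate dims: empty mask", call. = FALSE)
  origin <- c(cx[1L] - pitch[1L] / 2, cy[1L] - pitch[2L] / 2,
              cz[1L] - pitch[3L] / 2)
  structure(list(vox = vox, pitch = pitch, origin = origin, label = label),
            class = "muscle_mask")
}

#' Maximum anatomical cross-sectional area
#'
#' Measures the CSA of a voxel mask in the two protocol planes (P1 and P2 =
#' P1 + 2 mm along the normal) and returns their mean in cm^2.  Areas are
#' obtained by a Cavalieri count: voxels whose centres fall within a
#' one-pitch slab around the plane, times voxel volume, divided by the slab
#' thickness.
#'
#' @param mask a [make_muscle_mask()] object (or compatible list).
#' @param protocol a [sectioning_protocol()].
#' @return CSA_max in cm^2.
#' @export
#' @examples
#' m <- make_muscle_mask("elliptic_cylinder", c(10, 5, 30), pitch = 0.25)
#' csa_max(m, sectioning_protocol(p1_offset = 10))  # ~ pi*1*0.5 cm^2
csa_max <- function(mask, protocol = sectioning_protocol()) {
  stopifnot(inherits(protocol, "sectioning_protocol"))
  n <- protocol$normal
  dims <- dim(mask$vox)
  idx <- which(mask$vox)
  ai <- arrayInd(idx, dims)
  centers <- sweep((ai - 0.5) %*% diag(mask$pitch), 2L, -mask$origin)
  t_ <- as.numeric(centers %*% n)
  slab <- sum(abs(n) * mask$pitch)
  vvol <- prod(mask$pitch)
  area_at <- function(off) {
    eps <- 1e-6 * slab   # half-open slab, robust to center/boundary rounding
    cnt <- sum(t_ >= off - slab / 2 - eps & t_ < off + slab / 2 - eps)
    if (cnt == 0L)
      stop("empty-section error: plane at offset ", off,
           " does not intersect the mask", call. = FALSE)
    cnt * vvol / slab
  }
  mean(c(area_at(protocol$p1), area_at(protocol$p2))) / 100  # mm^2 -> cm^2
}

#' Peak muscle force from CSA
#'
#' Multiplies the maximum anatomical cross-sectional area by the muscle
#' stress factor (37 N/cm^2 by default): a 1 cm^2 muscle produces 37 N.
#'
#' @param csa CSA_max in cm^2 (vectorized).
#' @param constants a [muscle_constants()] object.
#' @return peak force(s) in N.
#' @export
#' @examples
#' peak_force(1)    # 37 N
#' peak_force(1.5)  # 55.5 N
peak_force <- function(csa, constants = muscle_constants()) {
  if (any(csa < 0)) stop("csa must be nonnegative", call. = FALSE)
  csa * constants$stress_factor
}

#' Fit muscle-force growth curves
#'
#' Converts cohort CSAs to per-side peak forces and fits, per muscle, a
#' monotone increasing cubic I-spline least-squares curve (nonnegative
#' derivative weights, the same basis that generates the synthetic cohort).
#' 95% confidence bands come from a residual bootstrap.
#'
#' @param cohort a `csa_table` from [generate_csa_cohort()] (or a data frame
#'   with the same columns).
#' @param constants a [muscle_constants()].
#' @param n_boot bootstrap resamples for the confidence band.
#' @param seed seed for the bootstrap.
#' @return object of class `growth_model`; use [predict.growth_model()] to
#'   evaluate mean force and band at arbitrary ages.
#' @export
fit_growth <- function(cohort, constants = muscle_constants(),
                       n_boot = 500L, seed = 1L) {
  req <- c("age_months", "muscle", "csa_cm2")
  if (!all(req %in% names(cohort)))
    stop("cohort must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- cohort$csa_cm2 <= 0 | !is.finite(cohort$csa_cm2)
  if (any(bad)) {
    warning(sum(bad), " non-positive CSA row(s) rejected")
    cohort <- cohort[!bad, , drop = FALSE]
  }
  b <- growth_basis()
  fits <- list()
  for (m in unique(cohort$muscle)) {
    d <- cohort[cohort$muscle == m, , drop = FALSE]
    if (length(unique(d$age_months)) < 6L)
      stop("fit error: muscle ", m, " has fewer than 6 distinct ages",
           call. = FALSE)
    y <- peak_force(d$csa_cm2, constants)
    Tm <- .tie_matrix(b$k)
    X <- cbind(1, b$eval(d$age_months) %*% Tm)
    expand <- function(th) c(th[1L], as.numeric(Tm %*% th[-1L]))
    lambda <- .gcv_lambda(X, y)
    th <- .nnls_fit(X, y, lambda)
    cf <- expand(th)
    fit0 <- as.numeric(X %*% th)
    res <- y - fit0
    set.seed(seed + 7L)
    bootc <- matrix(0, n_boot, length(cf))
    for (r in seq_len(n_boot)) {
      yb <- fit0 + sample(res, length(res), replace = TRUE)
      bootc[r, ] <- expand(.nnls_fit(X, yb, lambda))
    }
    fits[[m]] <- list(coef = cf, boot = bootc, sigma = sqrt(mean(res^2)),
                      n = length(y))
  }
  structure(list(fits = fits, constants = constants,
                 target_ages = c(3, 6, 12, 24, 36, 48)),
            class = "growth_model")
}

# second-difference penalty matrix over the derivative (I-spline) weights;
# the intercept column is unpenalized
.smooth_penalty <- function(p) {
  k <- p - 1L
  D <- diff(diag(k), differences = 2L)
  cbind(0, D)
}

# curvature-penalty weight chosen by generalized cross-validation on the
# unconstrained ridge path.  With noise-free data the unpenalized fit is
# exact and GCV selects lambda = 0, so the noiseless recovery stays exact.
.gcv_lambda <- function(X, y, grid = c(0, 10^seq(-2, 5, by = 0.5))) {
  D <- .smooth_penalty(ncol(X))
  n <- nrow(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); DtD <- crossprod(D)
  best <- grid[1L]; best_gcv <- Inf
  for (lam in grid) {
    A <- XtX + lam * DtD
    cf <- tryCatch(solve(A, Xty), error = function(e) NULL)
    if (is.null(cf)) next
    fit <- X %*% cf
    edf <- sum(diag(solve(A, XtX)))
    rss <- sum((y - fit)^2)
    gcv <- n * rss / (n - edf)^2
    if (is.finite(gcv) && gcv < best_gcv) { best_gcv <- gcv; best <- lam }
  }
  best
}

# (penalized) nonnegative least squares; falls back to the unconstrained
# solution when it is already feasible (exact in the noiseless case)
.nnls_fit <- function(X, y, lambda = 0) {
  if (lambda > 0) {
    D <- .smooth_penalty(ncol(X))
    X <- rbind(X, sqrt(lambda) * D)
    y <- c(y, numeric(nrow(D)))
  }
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (!is.null(cf) && !anyNA(cf) && all(cf >= -1e-8 * max(abs(cf), 1)))
    return(pmax(cf, 0))
  as.numeric(pracma::lsqnonneg(X, y)$x)
}

#' Predict per-side muscle force from a growth model
#'
#' @param object a [fit_growth()] model.
#' @param age ages in months.
#' @param muscle muscle name; `NULL` returns a data frame for all muscles.
#' @param level confidence level for the bootstrap band.
#' @param ... unused.
#' @return data frame with columns `muscle`, `age_months`, `force_N`,
#'   `ci_lo`, `ci_hi`.
#' @export
predict.growth_model <- function(object, age = object$target_ages,
                                 muscle = NULL, level = 0.95, ...) {
  b <- growth_basis()
  X <- cbind(1, b$eval(age))
  ms <- if (is.null(muscle)) names(object$fits) else muscle
  out <- do.call(rbind, lapply(ms, function(m) {
    f <- object$fits[[m]]
    if (is.null(f)) stop("model has no muscle ", m, call. = FALSE)
    mean_ <- as.numeric(X %*% f$coef)
    bootp <- f$boot %*% t(X)
    a <- (1 - level) / 2
    data.frame(muscle = m, age_months = age, force_N = mean_,
               ci_lo = apply(bootp, 2L, quantile, probs = a),
               ci_hi = apply(bootp, 2L, quantile, probs = 1 - a),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model>", length(x$fits), "muscles; per-side force at",
      "target ages (N):\n")
  print(stats::reshape(predict(x)[, 1:3], direction = "wide",
                       idvar = "muscle", timevar = "age_months"),
        row.names = FALSE)
  invisible(x)
}

# per-side forces for the three jaw muscles at one age, as a named vector
muscle_forces_at <- function(gm, age) {
  pr <- predict(gm, age = age)
  setNames(pr$force_N, pr$muscle)
}
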