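# Synthetic cohort of per-individual muscle cross-sectional areas (CSAs).
# Growth curves are monotone cubic splines expressed in an I-spline basis
# (integrated B-splines with nonnegative weights); the regression in
# fit_growth() uses the same basis, so the zero-noise cohort is exactly
# recoverable.

.cranio_env <- new.env(parent = emptyenv())

# shared monotone basis on [0, 48] months: intercept + integrated cubic
# B-splines (interior knots every 8 months), tabulated on a fine grid
growth_basis <- function() {
  if (!is.null(.cranio_env$basis)) return(.cranio_env$basis)
  lo <- 0; hi <- 48
  knots <- c(rep(lo, 4L), seq(8, 40, by = 8), rep(hi, 4L))
  grid <- seq(lo, hi, by = 0.05)
  B <- splines::splineDesign(knots, grid, ord = 4L)
  I <- apply(B, 2L, pracma::cumtrapz, x = grid)
  basis <- list(grid = grid, I = I, k = ncol(I), lo = lo, hi = hi)
  basis$eval <- function(age) {
    age <- pmin(pmax(age, lo), hi)
    out <- matrix(0, length(age), basis$k)
    for (j in seq_len(basis$k))
      out[, j] <- approx(grid, I[, j], xout = age)$y
    out
  }
  .cranio_env$basis <- basis
  basis
}

# map from free derivative weights to the full weight vector: the last four
# B-spline weights are tied, which makes the growth-rate constant (the curve
# linear) over the final spline segment — a natural-boundary condition that
# stabilizes the 48-month end of the fitted curves
.tie_matrix <- function(k = 9L, tied = 4L) {
  free <- k - tied + 1L
  T <- matrix(0, k, free)
  for (j in seq_len(free - 1L)) T[j, j] <- 1
  T[seq.int(free, k), free] <- 1
  T
}

# derivative-weight templates shaping each muscle's growth trajectory (in
# the tied span: last four entries equal): temporalis grows fast in the
# first 18 months, slows, then accelerates again; masseter and medial
# pterygoid follow near-linear trajectories
.curve_templates <- list(
  temporalis       = c(1.9, 1.5, 0.9, 0.55, 0.6, 1.25, 1.25, 1.25, 1.25),
  masseter         = c(1.25, 1.1, 1.0, 0.95, 0.9, 0.95, 0.95, 0.95, 0.95),
  medial_pterygoid = c(1.1, 1.05, 1.0, 0.95, 0.95, 0.975, 0.975, 0.975, 0.975)
)

# anchor CSAs (cm^2): printed mean per-side peak force divided by the
# 37 N cm^-2 muscle stress factor, at 3 and 48 months
.default_anchors <- list(
  temporalis       = c(30.9, 87.0) / 37,
  masseter         = c(25.6, 69.6) / 37,
  medial_pterygoid = c(23.1, 58.9) / 37
)

#' Parameters of the synthetic CSA cohort
#'
#' @param n number of individuals (default 51).
#' @param age_range age span in months covered by the cohort.
#' @param anchors named list (one entry per muscle) of CSA (cm^2) at 3 and
#'   48 months.  Defaults are the published mean per-side peak forces
#'   divided by the 37 N/cm^2 stress factor.
#' @param templates named list of derivative-weight templates controlling
#'   curve shape (see `growth_basis()`); same names as `anchors`.
#' @param cv coefficient of variation of the multiplicative lognormal noise.
#' @param seed integer seed.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n = 51L, age_range = c(0, 48),
                          anchors = .default_anchors,
                          templates = .curve_templates,
                          cv = 0.10, seed = 101L) {
  if (n < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (cv < 0) stop("cv must be nonnegative", call. = FALSE)
  if (age_range[1L] < 0 || age_range[2L] > 48 ||
      age_range[1L] >= age_range[2L])
    stop("age_range must be increasing and within [0, 48]", call. = FALSE)
  for (m in names(anchors)) {
    a <- anchors[[m]]
    if (any(a <= 0) || a[2L] <= a[1L])
      stop("anchors for ", m, " must be positive and increasing with age",
           call. = FALSE)
    if (is.null(templates[[m]]))
      stop("no curve template for muscle ", m, call. = FALSE)
  }
  structure(list(n = as.integer(n), age_range = age_range, anchors = anchors,
                 templates = templates, cv = cv, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Evaluate a generating growth curve
#'
#' Returns the noise-free CSA (cm^2) growth curve for one muscle: a monotone
#' cubic spline through the muscle's anchor CSAs at 3 and 48 months, shaped
#' by the muscle's template.
#'
#' @param age ages in months.
#' @param muscle muscle name.
#' @param params a [cohort_params()] object.
#' @return numeric vector of CSAs (cm^2).
#' @export
growth_curve <- function(age, muscle, params = cohort_params()) {
  b <- growth_basis()
  w <- params$templates[[muscle]]
  if (is.null(w)) stop("unknown muscle: ", muscle, call. = FALSE)
  anch <- params$anchors[[muscle]]
  S <- b$eval(c(3, 48)) %*% w
  beta <- (anch[2L] - anch[1L]) / (S[2L] - S[1L])
  alpha <- anch[1L] - beta * S[1L]
  if (alpha < 0)
    stop("template for ", muscle, " incompatible with anchors (negative ",
         "birth CSA)", call. = FALSE)
  as.numeric(alpha + b$eval(age) %*% (beta * w))
}

#' Generate the synthetic CSA cohort
#'
#' One row per individual per muscle.  Expected values follow the monotone
#' anchor-interpolating growth curves; observed CSAs carry multiplicative
#' lognormal noise with the configured coefficient of variation (mean-one,
#' so the curve is the expectation).  Ages are spread evenly over the age
#' range.  Fully deterministic given the seed.
#'
#' @param params a [cohort_params()] object.
#' @return a `csa_table`: data frame with columns `individual_id`,
#'   `age_months`, `muscle`, `csa_cm2`.
#' @export
#' @examples
#' head(generate_csa_cohort(cohort_params(cv = 0)))
generate_csa_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  ages <- round(seq(params$age_range[1L], params$age_range[2L],
                    length.out = params$n))
  muscles <- names(params$anchors)
  out <- do.call(rbind, lapply(muscles, function(m) {
    data.frame(individual_id = sprintf("ind%02d", seq_len(params$n)),
               age_months = ages, muscle = m,
               csa_cm2 = growth_curve(ages, m, params),
               stringsAsFactors = FALSE)
  }))
  if (params$cv > 0) {
    set.seed(params$seed)
    sdlog <- sqrt(log(1 + params$cv^2))
    fac <- rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    out$csa_cm2 <- out$csa_cm2 * fac
  }
  class(out) <- c("csa_table", "data.frame")
  out
}
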