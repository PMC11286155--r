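# Small-strain linear-elastic finite elements on labelled tetrahedral
# meshes: constant-strain (4-node) tetrahedra, isotropic Hooke's law,
# sparse symmetric assembly, direct solve with constraint elimination and
# reaction recovery, element strain/stress tensors and von Mises scalars.
# Unit system: mm - N - MPa; strains dimensionless (reported as microstrain).

#' Assemble the global stiffness operator
#'
#' Builds the sparse symmetric stiffness matrix of a labelled tetrahedral
#' mesh under an age-dependent isotropic material model (bone vs. cranial
#' joint by element label).  Element matrices are those of the linear
#' (constant-strain) tetrahedron.
#'
#' @param mesh a [build_skull_mesh()] result, or any list with `nodes`,
#'   `tets` and `label` fields.
#' @param age_months age used to evaluate the material model; defaults to the
#'   mesh's own age.
#' @param model an [age_material_model()].
#' @return an object of class `fem_model`: the stiffness operator `K`
#'   (sparse, 3N x 3N), cached shape-function gradients, element volumes and
#'   per-element material constants.
#' @export
fem_assemble <- function(mesh, age_months = mesh$params$age_months,
                         model = age_material_model()) {
  nodes <- mesh$nodes; tets <- mesh$tets
  nN <- nrow(nodes); nE <- nrow(tets)
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  det <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
    e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
    e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
  bad <- which(det <= 0)
  if (length(bad))
    stop("mesh-quality error: inverted or degenerate element(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  vol <- det / 6
  # rows of inv(M)^T = gradients of shape functions 2..4 (M = [e1 e2 e3])
  inv <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  g2 <- inv(e2, e3) / det
  g3 <- inv(e3, e1) / det
  g4 <- inv(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  grad <- array(0, dim = c(nE, 4L, 3L))
  grad[, 1L, ] <- g1; grad[, 2L, ] <- g2; grad[, 3L, ] <- g3; grad[, 4L, ] <- g4

  mat <- .element_materials(mesh$label, age_months, model)
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))

  nnz <- nE * 144L
  ii <- integer(nnz); jj <- integer(nnz); xx <- numeric(nnz)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    ga <- matrix(grad[, a, ], ncol = 3L); gb <- matrix(grad[, b, ], ncol = 3L)
    dot <- ga[, 1L] * gb[, 1L] + ga[, 2L] * gb[, 2L] + ga[, 3L] * gb[, 3L]
    ra <- 3L * (tets[, a] - 1L); rb <- 3L * (tets[, b] - 1L)
    for (i in 1:3) for (j in 1:3) {
      val <- vol * (lam * ga[, i] * gb[, j] + mu * gb[, i] * ga[, j] +
                      (if (i == j) mu * dot else 0))
      idx <- pos + seq_len(nE)
      ii[idx] <- ra + i; jj[idx] <- rb + j; xx[idx] <- val
      pos <- pos + nE
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * nN, 3L * nN))
  structure(list(K = K, grad = grad, vol = vol, lam = lam, mu = mu,
                 nu = mat$nu, E = mat$E, mesh = mesh,
                 age_months = age_months),
            class = "fem_model")
}

#' Constraint set for a solve
#'
#' All three translational directions are fixed at every constrained node
#' (no rotational constraints exist for solid elements).
#'
#' @param nodes integer node indices.
#' @param role character role tags (`"bite"` or `"tmj"`), recycled.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(nodes, role = "bite") {
  nodes <- as.integer(nodes)
  if (anyDuplicated(nodes)) stop("a node appears twice in the constraint set",
                                 call. = FALSE)
  role <- rep_len(role, length(nodes))
  structure(data.frame(node = nodes, role = role), class = c("constraint_set",
                                                             "data.frame"))
}

# factorize the free-free block once; reuse across load cases
fem_factor <- function(fm, constraints) {
  nN <- nrow(fm$mesh$nodes)
  cn <- constraints$node
  if (any(cn < 1L | cn > nN)) stop("constraint node out of range", call. = FALSE)
  # fully fixing three non-collinear points removes all rigid-body modes
  P <- fm$mesh$nodes[cn, , drop = FALSE]
  if (nrow(P) < 3L ||
      qr(sweep(P, 2L, colMeans(P)))$rank < 2L)
    warning("constrained nodes are collinear; rigid modes may remain")
  cdof <- as.vector(t(outer(3L * (cn - 1L), 1:3, `+`)))
  free <- setdiff(seq_len(3L * nN), cdof)
  Kff <- fm$K[free, free]
  fac <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
    error = function(e)
      stop("singularity error: constraints do not remove all rigid-body ",
           "modes (", conditionMessage(e), ")", call. = FALSE))
  list(fm = fm, constraints = constraints, free = free, cdof = cdof,
       fac = fac)
}

fem_solve_factored <- function(fct, f) {
  fm <- fct$fm
  u <- numeric(length(f))
  uf <- as.numeric(Matrix::solve(fct$fac, f[fct$free]))
  u[fct$free] <- uf
  r <- as.numeric(fm$K %*% u) - f
  nf <- sqrt(sum(f^2))
  resid <- if (nf > 0) sqrt(sum((r[fct$free])^2)) / nf else 0
  if (is.na(resid) || resid > 1e-8)
    stop("solver error: residual ", format(resid), " exceeds tolerance",
         call. = FALSE)
  reactions <- matrix(r[fct$cdof], ncol = 3L, byrow = TRUE)
  structure(list(u = u, reactions = reactions,
                 constraints = fct$constraints, residual = resid,
                 method = "sparse Cholesky"),
            class = "fem_solution")
}

#' Solve a constrained load case
#'
#' Displacements are obtained by eliminating the constrained rows/columns
#' and factorizing the remaining symmetric positive-definite block; reaction
#' forces are recovered from the unmodified operator as `K u - f` at the
#' constrained degrees of freedom.  The relative residual on the free
#' equations is checked against 1e-8.
#'
#' @param fm a [fem_assemble()] result.
#' @param load numeric load vector of length `3 * nrow(nodes)`
#'   (x1,y1,z1,x2,...), in newtons.
#' @param constraints a [constraint_set()].
#' @return object of class `fem_solution`: `u` (mm), `reactions` (one row
#'   per constrained node, N), `residual`, plus the constraint set.
#' @export
fem_solve <- function(fm, load, constraints) {
  if (length(load) != 3L * nrow(fm$mesh$nodes))
    stop("load vector has wrong length", call. = FALSE)
  fct <- fem_factor(fm, constraints)
  fem_solve_factored(fct, load)
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("<fem_solution>", length(x$u) / 3, "nodes;",
      nrow(x$reactions), "constrained;",
      "max |u| =", format(max(abs(x$u)), digits = 4), "mm;",
      "residual", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Element strain and stress fields
#'
#' Computes the constant strain tensor of every element from the nodal
#' displacements, the stress tensor via the isotropic Hooke law, the von
#' Mises stress, and the von Mises equivalent strain
#' `1/(1 + nu') * sqrt(((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)/2)` where `nu'`
#' defaults to the element material's Poisson ratio (the usual
#' elastic-strain convention of commercial solvers).
#'
#' @param fm a [fem_assemble()] result.
#' @param solution a [fem_solve()] result (or any object with `$u`).
#' @param nu_prime effective Poisson ratio for the equivalent strain;
#'   `NULL` (default) uses each element's material value.
#' @return object of class `field_result`: matrices `strain` and `stress`
#'   (E x 6, component order xx, yy, zz, xy, yz, zx; tensor shear
#'   components), `von_mises_stress` (MPa) and `von_mises_strain`
#'   (microstrain).
#' @export
strain_stress <- function(fm, solution, nu_prime = NULL) {
  u <- if (is.list(solution)) solution$u else solution
  tets <- fm$mesh$tets
  nE <- nrow(tets)
  eps <- matrix(0, nE, 6L)
  # tensor strain e_ij = sum_a (g_a,i u_a,j + g_a,j u_a,i) / 2
  for (a in 1:4) {
    ua <- cbind(u[3L * (tets[, a] - 1L) + 1L],
                u[3L * (tets[, a] - 1L) + 2L],
                u[3L * (tets[, a] - 1L) + 3L])
    ga <- matrix(fm$grad[, a, ], ncol = 3L)
    eps[, 1L] <- eps[, 1L] + ga[, 1L] * ua[, 1L]
    eps[, 2L] <- eps[, 2L] + ga[, 2L] * ua[, 2L]
    eps[, 3L] <- eps[, 3L] + ga[, 3L] * ua[, 3L]
    eps[, 4L] <- eps[, 4L] + (ga[, 1L] * ua[, 2L] + ga[, 2L] * ua[, 1L]) / 2
    eps[, 5L] <- eps[, 5L] + (ga[, 2L] * ua[, 3L] + ga[, 3L] * ua[, 2L]) / 2
    eps[, 6L] <- eps[, 6L] + (ga[, 3L] * ua[, 1L] + ga[, 1L] * ua[, 3L]) / 2
  }
  tr <- eps[, 1L] + eps[, 2L] + eps[, 3L]
  sig <- 2 * fm$mu * eps
  sig[, 1L] <- sig[, 1L] + fm$lam * tr
  sig[, 2L] <- sig[, 2L] + fm$lam * tr
  sig[, 3L] <- sig[, 3L] + fm$lam * tr
  np <- if (is.null(nu_prime)) fm$nu else rep_len(nu_prime, nE)
  colnames(eps) <- colnames(sig) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  structure(list(strain = eps, stress = sig,
                 von_mises_stress = von_mises(sig),
                 von_mises_strain = 1e6 * von_mises(eps) / (1 + np),
                 nu_prime = np),
            class = "field_result")
}

#' von Mises equivalent of a symmetric tensor field
#'
#' @param tens matrix with columns xx, yy, zz, xy, yz, zx (tensor shear
#'   components, not engineering shear).
#' @return numeric vector of equivalent (deviatoric-intensity) values.
#' @export
von_mises <- function(tens) {
  sqrt(pmax(0, ((tens[, 1L] - tens[, 2L])^2 + (tens[, 2L] - tens[, 3L])^2 +
                  (tens[, 3L] - tens[, 1L])^2 +
                  6 * (tens[, 4L]^2 + tens[, 5L]^2 + tens[, 6L]^2)) / 2))
}

#' @export
print.field_result <- function(x, ...) {
  cat("<field_result>", nrow(x$strain), "elements; von Mises stress",
      sprintf("[%.4g, %.4g] MPa;", min(x$von_mises_stress),
              max(x$von_mises_stress)),
      "von Mises strain",
      sprintf("[%.4g, %.4g] microstrain\n", min(x$von_mises_strain),
              max(x$von_mises_strain)))
  invisible(x)
}
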