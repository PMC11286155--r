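# Shared fixtures: coarse desk-scale surrogates (memoized per age), a
# rectangular box mesher on the same parity-alternating 5-tet scheme, and
# the published per-side muscle forces at 48 months.

.fixture_env <- new.env()

# coarse surrogate: thicker shell relative to size so a 3 mm pitch resolves
# it; used by the property tests (the calibrated default surrogate is
# exercised in the acceptance tests)
coarse_params <- function(age, ...) {
  skull_params(age, pitch = 3, size_scale = 0.7, shell_thickness = 7,
               arch_clearance = 3, ...)
}

coarse_mesh <- function(age) {
  key <- paste0("mesh", age)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_skull_mesh(coarse_params(age))
  .fixture_env[[key]]
}

coarse_fm <- function(age) {
  key <- paste0("fm", age)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- fem_assemble(coarse_mesh(age))
  .fixture_env[[key]]
}

forces_48 <- list(temporalis = 87.0, masseter = 69.6,
                  medial_pterygoid = 58.9)

# calibrated default-resolution surrogate (shared across test files; the
# acceptance tests populate the 48-month entry first)
default_fm <- function(age) {
  key <- paste0("dfm", age)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- fem_assemble(build_skull_mesh(skull_params(age)))
  .fixture_env[[key]]
}

# axis-aligned box mesh (nx x ny x nz voxels of size h) using the package's
# 5-tet split; all elements labelled as bone
box_mesh <- function(nx, ny, nz, h = 1) {
  tA <- cranioload:::.tet5_A
  tB <- cranioload:::.tet5_B
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  g <- expand.grid(x = 0:nx, y = 0:ny, z = 0:nz)
  nodes <- as.matrix(g) * h
  vox <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  corn <- cbind(nid(vox$i, vox$j, vox$k), nid(vox$i + 1L, vox$j, vox$k),
                nid(vox$i, vox$j + 1L, vox$k),
                nid(vox$i + 1L, vox$j + 1L, vox$k),
                nid(vox$i, vox$j, vox$k + 1L),
                nid(vox$i + 1L, vox$j, vox$k + 1L),
                nid(vox$i, vox$j + 1L, vox$k + 1L),
                nid(vox$i + 1L, vox$j + 1L, vox$k + 1L))
  par <- (vox$i + vox$j + vox$k) %% 2L
  tets <- matrix(0L, nrow(vox) * 5L, 4L)
  for (v in 0:1) {
    pat <- if (v == 0L) tA else tB
    rows <- which(par == v)
    for (t in 1:5)
      tets[(rows - 1L) * 5L + t, ] <- corn[rows, pat[t, ]]
  }
  vol <- cranioload:::.tet_volumes(nodes, tets)
  fl <- vol < 0
  tets[fl, c(3L, 4L)] <- tets[fl, c(4L, 3L)]
  list(nodes = nodes, tets = tets, label = rep("parietal", nrow(tets)),
       volumes = abs(cranioload:::.tet_volumes(nodes, tets)))
}

# dense brute-force stiffness assembly via explicit B and C matrices
# (independent of the vectorized closed-form path in fem_assemble)
dense_stiffness <- function(mesh, E, nu) {
  nN <- nrow(mesh$nodes)
  K <- matrix(0, 3 * nN, 3 * nN)
  C <- matrix(0, 6, 6)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  for (e in seq_len(nrow(mesh$tets))) {
    id <- mesh$tets[e, ]
    X <- cbind(1, mesh$nodes[id, ])
    V <- det(X) / 6
    grads <- solve(X)[2:4, ]   # rows: d/dx, d/dy, d/dz of the 4 shape fns
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      gx <- grads[1, a]; gy <- grads[2, a]; gz <- grads[3, a]
      cB <- 3 * (a - 1)
      B[1, cB + 1] <- gx; B[2, cB + 2] <- gy; B[3, cB + 3] <- gz
      B[4, cB + 1] <- gy; B[4, cB + 2] <- gx
      B[5, cB + 2] <- gz; B[5, cB + 3] <- gy
      B[6, cB + 1] <- gz; B[6, cB + 3] <- gx
    }
    Ke <- V * t(B) %*% C %*% B
    dof <- as.vector(t(outer(3 * (id - 1), 1:3, `+`)))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  K
}
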