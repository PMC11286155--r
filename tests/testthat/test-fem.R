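# Finite-element core: material model, assembly against a brute-force
# oracle, solver contracts, field recovery, and the elastic invariants.

test_that("material model matches the published constants and growth rates", {
  m3 <- material_at_age(3)
  expect_identical(m3$E_bone, 421)
  expect_identical(m3$E_joint, 30)
  expect_identical(m3$nu_bone, 0.22)
  expect_identical(m3$nu_joint, 0.30)
  m12 <- material_at_age(12)
  expect_identical(m12$E_bone, 421 + 125 * 9)   # 1546
  expect_identical(m12$E_joint, 30 + 100 * 9)   # 930
  m48 <- material_at_age(48)
  expect_identical(m48$E_bone, 6046)
  expect_identical(m48$E_joint, 930)             # frozen after month 12
  expect_error(material_at_age(2), "age_months")
  expect_error(material_at_age(49), "age_months")
})

test_that("element stiffness is symmetric with zero row sums", {
  # one regular-ish tetrahedron
  mesh <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(0, 0, 1)),
               tets = matrix(1:4, 1), label = "parietal")
  fm <- fem_assemble(mesh, age_months = 3)
  K <- as.matrix(fm$K)
  expect_equal(K, t(K), tolerance = 1e-12)
  # rigid translations are in the null space: per-axis row sums vanish
  for (ax in 1:3) {
    u <- numeric(12); u[seq(ax, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-12)
  }
})

test_that("vectorized assembly equals dense brute-force assembly", {
  m <- box_mesh(2, 1, 1, h = 0.8)
  E <- 1234; nu <- 0.27
  fm <- fem_assemble(m, age_months = 3,
                     model = age_material_model(E_bone0 = E, bone_rate = 0,
                                                nu_bone = nu))
  Kd <- dense_stiffness(m, E, nu)
  expect_equal(as.matrix(fm$K), Kd, tolerance = 1e-12 * max(abs(Kd)))
})

test_that("inverted elements are reported by name", {
  m <- box_mesh(1, 1, 1)
  m$tets[3, c(1, 2)] <- m$tets[3, c(2, 1)]
  expect_error(fem_assemble(m, age_months = 3), "mesh-quality.*3")
})

test_that("solver honours zero loads, equilibrium and the residual bound", {
  m <- box_mesh(3, 2, 2, h = 1)
  fm <- fem_assemble(m, age_months = 12)
  fixed <- which(m$nodes[, 1] == 0)
  con <- constraint_set(fixed)
  f0 <- numeric(3 * nrow(m$nodes))
  s0 <- fem_solve(fm, f0, con)
  expect_identical(max(abs(s0$u)), 0)
  expect_identical(max(abs(s0$reactions)), 0)
  set.seed(4)
  f <- rnorm(length(f0))
  s <- fem_solve(fm, f, con)
  applied <- colSums(matrix(f, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(applied + colSums(s$reactions))),
            1e-8 * sqrt(sum(f^2)))
  expect_lt(s$residual, 1e-8)
  # no constraints: rigid modes remain (collinearity warning, then failure)
  expect_error(suppressWarnings(fem_solve(fm, f, constraint_set(integer(0)))),
               "singularity")
})

test_that("cantilever tip deflection matches slender-beam theory", {
  L <- 20; a <- 2; n <- 6
  m <- box_mesh(round(L / (a / n)), n, n, h = a / n)
  fm <- fem_assemble(m, age_months = 3,
                     model = age_material_model(nu_bone = 0))
  E <- 421; P <- 1
  tip <- which(m$nodes[, 1] == L)
  f <- numeric(3 * nrow(m$nodes))
  f[3 * (tip - 1) + 3] <- -P / length(tip)
  sol <- fem_solve(fm, f, constraint_set(which(m$nodes[, 1] == 0)))
  defl <- -mean(sol$u[3 * (tip - 1) + 3])
  I <- a^4 / 12; G <- E / 2; A <- a^2
  closed <- P * L^3 / (3 * E * I) + P * L / (5 / 6 * G * A)
  expect_lt(abs(defl - closed) / closed, 0.15)
})

test_that("patch test: linear displacement gives uniform constant strain", {
  m <- box_mesh(3, 3, 3, h = 0.7)
  fm <- fem_assemble(m, age_months = 3)
  A <- rbind(c(1e-3, 2e-4, -1e-4),
             c(2e-4, -5e-4, 3e-4),
             c(-1e-4, 3e-4, 8e-4))   # symmetric -> strain equals A
  u <- as.vector(t(m$nodes %*% A))
  fr <- strain_stress(fm, list(u = u))
  want <- c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[2, 3], A[3, 1])
  for (k in 1:6)
    expect_lt(max(abs(fr$strain[, k] - want[k])), 1e-10)
})

test_that("von Mises equivalents match closed forms", {
  s <- 3.7
  expect_equal(von_mises(cbind(s, 0, 0, 0, 0, 0)), s)
  expect_equal(von_mises(cbind(s, s, s, 0, 0, 0)), 0)     # hydrostatic
  tau <- 1.3
  expect_equal(von_mises(cbind(0, 0, 0, tau, 0, 0)), sqrt(3) * tau)
  expect_true(all(von_mises(matrix(rnorm(60), ncol = 6)) >= 0))
})

test_that("solutions are linear, superposable and mirror-symmetric", {
  fm <- coarse_fm(48)
  mesh <- fm$mesh
  con <- bite_constraints(mesh, 1)
  vec <- build_vectors(mesh, forces_48)
  f1 <- load_from_vectors(vec)
  set.seed(9)
  f2 <- numeric(length(f1))
  free_nodes <- setdiff(seq_len(nrow(mesh$nodes)), con$node)
  pick <- sample(free_nodes, 40)
  f2[3 * (pick - 1) + 3] <- rnorm(40)
  s1 <- fem_solve(fm, f1, con)
  s2 <- fem_solve(fm, f2, con)
  s12 <- fem_solve(fm, f1 + f2, con)
  expect_equal(fem_solve(fm, 2 * f1, con)$u, 2 * s1$u,
               tolerance = 1e-8)
  expect_equal(s12$u, s1$u + s2$u, tolerance = 1e-8)
  # mirrored nodes see mirrored displacements under the symmetric load
  ux <- s1$u[seq(1, length(f1), 3)]
  uy <- s1$u[seq(2, length(f1), 3)]
  uz <- s1$u[seq(3, length(f1), 3)]
  sc <- max(abs(s1$u))
  expect_lt(max(abs(ux[mesh$mirror] + ux)) / sc, 1e-6)
  expect_lt(max(abs(uy[mesh$mirror] - uy)) / sc, 1e-6)
  expect_lt(max(abs(uz[mesh$mirror] - uz)) / sc, 1e-6)
})

test_that("stiffer (older) materials deflect less for the same load", {
  mesh <- coarse_mesh(48)
  fm3 <- fem_assemble(mesh, age_months = 3)
  fm48 <- fem_assemble(mesh, age_months = 48)
  f <- load_from_vectors(build_vectors(mesh, forces_48))
  con <- bite_constraints(mesh, 1)
  u3 <- max(abs(fem_solve(fm3, f, con)$u))
  u48 <- max(abs(fem_solve(fm48, f, con)$u))
  expect_lt(u48, u3)
})
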