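# Bite pipeline: linearity, bilateral symmetry, working/balancing side
# asymmetry, fascia effect, the age sweep, probes and the rigid-body oracle.

test_that("bite reactions scale linearly with the applied muscle forces", {
  fm <- coarse_fm(48)
  b1 <- run_bite(fm, forces_48, mode = 1)
  b2 <- run_bite(fm, forces_48, mode = 1, scale = 2)
  expect_equal(b2$bite_force_N, 2 * b1$bite_force_N, tolerance = 1e-8)
  expect_equal(b2$tmj_L_N, 2 * b1$tmj_L_N, tolerance = 1e-8)
})

test_that("bilateral molar biting loads both sides identically", {
  fm <- coarse_fm(48)
  b <- run_bite(fm, forces_48, mode = 1)
  con <- b$solution$constraints
  rb <- b$solution$reactions[con$role == "bite", , drop = FALSE]
  bn <- con$node[con$role == "bite"]
  mag <- sqrt(rowSums(rb^2))
  left <- fm$mesh$nodes[bn, 1] > 0
  expect_equal(sum(mag[left]), sum(mag[!left]), tolerance = 1e-6)
  expect_equal(b$tmj_L_N, b$tmj_R_N, tolerance = 1e-6)
})

test_that("unilateral biting loads the balancing-side TMJ more", {
  fm <- coarse_fm(48)
  b3 <- run_bite(fm, forces_48, mode = 3)
  expect_gt(b3$tmj_R_N, b3$tmj_L_N)   # right = balancing, left = working
})

test_that("applying the balanced fascia lowers the bite force", {
  fm <- coarse_fm(48)
  b0 <- run_bite(fm, forces_48, mode = 1, with_fascia = FALSE)
  b1 <- run_bite(fm, forces_48, mode = 1, with_fascia = TRUE)
  expect_gt(b1$tff_N, 0)
  expect_lt(b1$bite_force_N, b0$bite_force_N)
})

test_that("every run conserves total force to 1e-8 of the load", {
  fm <- coarse_fm(48)
  for (md in 1:3) {
    b <- run_bite(fm, forces_48, mode = md)
    applied <- colSums(matrix(b$load, ncol = 3, byrow = TRUE))
    total <- applied + colSums(b$solution$reactions)
    expect_lt(max(abs(total)), 1e-8 * sqrt(sum(b$load^2)))
  }
})

test_that("bite force grows monotonically over the six target ages", {
  gm <- fit_growth(generate_csa_cohort(cohort_params(cv = 0)), n_boot = 5)
  series <- run_series(gm, ages = c(3, 6, 12, 24, 36, 48), modes = 1,
                       fascia = FALSE, mesh_fun = function(a)
                         build_skull_mesh(coarse_params(a)))
  expect_true(all(is.na(series$error)))
  expect_true(all(diff(series$bite_force_N) >= -1e-9))
  # empty mode list: empty table, no error
  empty <- run_series(gm, ages = 48, modes = integer(0), fascia = FALSE,
                      mesh_fun = function(a) coarse_mesh(a))
  expect_identical(nrow(empty), 0L)
})

test_that("strain fields show the facial-calvarial and age gradients", {
  facial <- c("facial", "facial_suture", "zygomatic_arch_L",
              "zygomatic_arch_R")
  calvarial <- cranioload:::.calvarial_labels
  peak_facial <- numeric(0)
  for (age in c(3, 6, 48)) {
    fm <- coarse_fm(age)
    gm_forces <- lapply(forces_48, `*`,
                        growth_curve(age, "temporalis") /
                          growth_curve(48, "temporalis"))
    b <- run_bite(fm, gm_forces, mode = 1)
    lab <- fm$mesh$label
    if (age >= 6)
      expect_gt(median(b$field$von_mises_strain[lab %in% facial]),
                median(b$field$von_mises_strain[lab %in% calvarial]))
    peak_facial[as.character(age)] <-
      max(b$field$von_mises_strain[lab %in% facial])
  }
  # peak facial strain decreases from 3 to 48 months
  expect_lt(peak_facial[["48"]], peak_facial[["3"]])
})

test_that("probes average the fields and respond to the fascia", {
  # uniform strain field: every probe reports the same value
  m <- box_mesh(3, 3, 3)
  fmb <- fem_assemble(m, age_months = 3)
  u <- as.vector(t(m$nodes %*% diag(c(1e-3, 0, 0))))
  fr <- strain_stress(fmb, list(u = u))
  pv <- probe_fields(fmb, fr, probes = c(5L, 17L, 33L))
  expect_lt(diff(range(pv$von_mises_strain_ue)), 1e-9)
  expect_error(probe_fields(fmb, fr, probes = c(5L, NA_integer_)),
               "lookup error")

  # fronto-zygomatic probes (1, 7, 8) are relieved by the fascia on the
  # calibrated default surrogate (the coarse variant's floor-thickened arch
  # does not reproduce the slender-strut bending this relies on)
  fm <- default_fm(48)
  b0 <- run_bite(fm, forces_48, mode = 1, with_fascia = FALSE)
  b1 <- run_bite(fm, forces_48, mode = 1, with_fascia = TRUE)
  expect_identical(nrow(b0$probes), 9L)
  for (k in c(1L, 7L, 8L))
    expect_lt(b1$probes$von_mises_strain_ue[k],
              b0$probes$von_mises_strain_ue[k])
})

test_that("unilateral biting breaks left-right probe symmetry most", {
  fm <- coarse_fm(48)
  mesh <- fm$mesh
  asym <- function(b) {
    pr <- mesh$node_sets$probes
    v <- probe_fields(fm, b$field, probes = pr)$von_mises_strain_ue
    vm <- probe_fields(fm, b$field,
                       probes = mesh$mirror[pr])$von_mises_strain_ue
    sum(abs(v - vm))
  }
  b1 <- run_bite(fm, forces_48, mode = 1)
  b3 <- run_bite(fm, forces_48, mode = 3)
  expect_gt(asym(b3), asym(b1))
})

test_that("rigid-body oracle reproduces the lever arithmetic", {
  mesh <- coarse_mesh(48)
  vec <- build_vectors(mesh, forces_48)
  o1 <- rigid_equilibrium_oracle(mesh, vec, 1)
  o2 <- rigid_equilibrium_oracle(mesh, vec, 2)
  # same applied moment, so the mode ratio is the inverse out-lever ratio
  tmj_y <- mean(mesh$nodes[c(mesh$node_sets$tmj_L, mesh$node_sets$tmj_R), 2])
  lever1 <- mean(mesh$nodes[c(mesh$node_sets$bite_molar_L,
                              mesh$node_sets$bite_molar_R), 2]) - tmj_y
  lever2 <- mean(mesh$nodes[mesh$node_sets$bite_incisor, 2]) - tmj_y
  expect_equal(o2$bite_force_N / o1$bite_force_N, lever1 / lever2,
               tolerance = 1e-10)
  # a more posterior molar (shorter out-lever) raises the oracle bite force
  m2 <- mesh
  post <- cranioload:::.snap_node(mesh, mesh$nodes[mesh$node_sets$bite_molar_L, ] -
                                    c(0, 6, 0), c("facial", "facial_suture"))
  m2$node_sets$bite_molar_L <- post
  m2$node_sets$bite_molar_R <- mesh$mirror[post]
  o1b <- rigid_equilibrium_oracle(m2, vec, 1)
  expect_gt(o1b$bite_force_N, o1$bite_force_N)
  # FEM totals satisfy the oracle's balance equations (Newton's third law)
  fm <- coarse_fm(48)
  b <- run_bite(fm, forces_48, mode = 1)
  expect_lt(max(abs(o1$applied_force +
                      colSums(b$solution$reactions))),
            1e-6 * sqrt(sum(b$load^2)))
  # mode-3 least-squares statics also balances and loads the right side more
  o3 <- rigid_equilibrium_oracle(mesh, vec, 3)
  expect_gt(o3$tmj_force_N[["R"]], o3$tmj_force_N[["L"]])
})
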