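# CSA sectioning protocol, the stress-factor conversion and the force
# vector construction.

test_that("csa_max recovers analytic section areas of solid fixtures", {
  # elliptic cylinder, semi-axes 10 x 5 mm: every slice is pi*10*5 mm^2
  m <- make_muscle_mask("elliptic_cylinder", c(10, 5, 30), pitch = 0.25)
  a <- csa_max(m, sectioning_protocol(p1_offset = 10))
  expect_equal(a, pi * 10 * 5 / 100, tolerance = 0.02)

  # prism 10 x 10 mm: slice area 100 mm^2 within one voxel ring
  mp <- make_muscle_mask("prism", c(10, 10, 20), pitch = 0.25)
  ap <- csa_max(mp, sectioning_protocol(p1_offset = 8))
  ring <- 4 * 10 * 0.25 / 100
  expect_lt(abs(ap - 1), ring)

  # cone: section area varies (near-)linearly over the 2 mm gap, so the
  # two-plane mean equals the midpoint area up to discretization
  mc <- make_muscle_mask("cone", c(10, 20), pitch = 0.2)
  off <- 8
  amean <- csa_max(mc, sectioning_protocol(p1_offset = off))
  amid <- pi * (10 * (1 - (off + 1) / 20))^2 / 100
  expect_equal(amean, amid, tolerance = 0.04)
})

test_that("csa_max is invariant under in-plane translation of the mask", {
  m <- make_muscle_mask("elliptic_cylinder", c(8, 4, 24), pitch = 0.25)
  a0 <- csa_max(m, sectioning_protocol(p1_offset = 10))
  m2 <- m
  m2$origin <- m$origin + c(3.1, -2.4, 0)   # translate along the plane
  a1 <- csa_max(m2, sectioning_protocol(p1_offset = 10))
  expect_equal(a0, a1, tolerance = 1e-12)
})

test_that("csa_max rejects degenerate protocols and empty sections", {
  m <- make_muscle_mask("prism", c(6, 6, 10), pitch = 0.5)
  expect_error(sectioning_protocol(normal = c(0, 0, 2)), "unit")
  expect_error(csa_max(m, sectioning_protocol(p1_offset = 50)),
               "empty-section")
  expect_identical(sectioning_protocol(p1_offset = 4)$p2, 6)
  expect_error(make_muscle_mask("prism", c(1, 1, 1), pitch = 2),
               "degenerate")
})

test_that("peak_force applies the 37 N/cm^2 stress factor linearly", {
  expect_identical(peak_force(1), 37)
  expect_identical(peak_force(0), 0)
  expect_identical(peak_force(1.5), 55.5)
  a <- 0.73; b <- 1.91
  expect_equal(peak_force(a + b), peak_force(a) + peak_force(b),
               tolerance = 1e-15)
  expect_error(peak_force(-0.1), "nonnegative")
})

test_that("build_vectors conserves per-side force and mirrors sides", {
  mesh <- coarse_mesh(48)
  vec <- build_vectors(mesh, forces_48)
  df <- as.data.frame(vec)
  tot <- stats::aggregate(magnitude_N ~ tag + side, df, sum)
  for (m in names(forces_48))
    for (s in c("L", "R"))
      expect_equal(tot$magnitude_N[tot$tag == m & tot$side == s],
                   forces_48[[m]], tolerance = 1e-12)
  # per-side force 87 N over 3 vectors -> 29 N each
  expect_equal(df$magnitude_N[df$tag == "temporalis"], rep(29, 6))
  # mirror: directions x-negate, magnitudes equal, patches mirror
  for (m in unique(df$tag)) for (k in unique(df$station)) {
    l <- df[df$tag == m & df$side == "L" & df$station == k, ]
    r <- df[df$tag == m & df$side == "R" & df$station == k, ]
    expect_equal(l$dx, -r$dx, tolerance = 1e-12)
    expect_equal(l$dy, r$dy, tolerance = 1e-12)
    expect_equal(l$dz, r$dz, tolerance = 1e-12)
    expect_equal(l$magnitude_N, r$magnitude_N)
    expect_setequal(mesh$mirror[vec$nodes[[which(df$tag == m &
                                                   df$side == "L" &
                                                   df$station == k)]]],
                    vec$nodes[[which(df$tag == m & df$side == "R" &
                                       df$station == k)]])
  }
  # single vector per side carries the whole per-side force
  v1 <- build_vectors(mesh, list(masseter = 50),
                      muscle_constants(vectors_per_side = 1))
  expect_equal(as.data.frame(v1)$magnitude_N, c(50, 50))
})

test_that("degenerate directions and missing landmarks are errors", {
  mesh <- coarse_mesh(48)
  m2 <- mesh
  # force origin onto its own insertion: degenerate direction
  i <- which(m2$landmarks$muscle == "temporalis" &
               m2$landmarks$role == "insertion")
  o <- which(m2$landmarks$muscle == "temporalis" &
               m2$landmarks$role == "origin")
  m2$landmarks[o, c("x", "y", "z")] <- m2$landmarks[i, c("x", "y", "z")]
  expect_error(build_vectors(m2, forces_48), "degenerate-direction")
  m3 <- mesh
  m3$landmarks <- m3$landmarks[m3$landmarks$muscle != "masseter", ]
  expect_error(build_vectors(m3, forces_48), "lookup error")
})
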