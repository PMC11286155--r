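# The parametric skull surrogate: determinism, suture patency, symmetry,
# growth monotonicity and resolution guards.

test_that("surrogate generation is deterministic and mirror-symmetric", {
  m1 <- build_skull_mesh(coarse_params(24))
  m2 <- build_skull_mesh(coarse_params(24))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$label, m2$label)

  m <- coarse_mesh(48)
  # node lattice maps onto itself under x-negation, exactly
  expect_identical(m$nodes[m$mirror, 1L], -m$nodes[, 1L])
  expect_identical(m$nodes[m$mirror, 2L], m$nodes[, 2L])
  # paired node sets are mirror images
  ns <- m$node_sets
  expect_identical(sort(m$mirror[ns$tmj_L]), sort(ns$tmj_R))
  expect_identical(m$mirror[ns$bite_molar_L], ns$bite_molar_R)
  expect_identical(sort(m$mirror[ns$bite_incisor]), sort(ns$bite_incisor))
  # all tetrahedra positively oriented, one label each
  expect_true(all(m$volumes > 0))
  expect_length(m$label, nrow(m$tets))
})

test_that("suture patency follows the ontogenetic schedule and is monotone", {
  expect_setequal(suture_schedule(3),
                  c("metopic", "coronal", "sagittal", "lambdoid",
                    "anterior_fontanelle", "facial_suture", "base_joint"))
  expect_setequal(suture_schedule(6),
                  c("metopic", "coronal", "sagittal", "lambdoid",
                    "anterior_fontanelle"))
  expect_identical(suture_schedule(12), "anterior_fontanelle")
  expect_identical(suture_schedule(24), character(0))
  expect_identical(suture_schedule(48), character(0))

  joint <- cranioload:::.joint_labels
  counts <- vapply(c(3, 6, 12, 24), function(a)
    sum(coarse_mesh(a)$label %in% joint), numeric(1))
  expect_true(all(diff(counts) <= 0))     # non-increasing with age
  expect_identical(counts[[4]], 0)        # fully ossified from 24 months
  expect_gt(counts[[1]], 0)
  # 3-month model carries facial, calvarial and base joint bands
  expect_true(all(c("facial_suture", "coronal", "base_joint") %in%
                    coarse_mesh(3)$label))
})

test_that("every linear dimension grows monotonically with age", {
  ages <- seq(3, 48, by = 5)
  dims <- t(vapply(ages, function(a) {
    p <- skull_params(a)
    c(p$ax, p$ay, p$az, p$pl_zhi - p$pl_zlo, p$arch_length, p$pal_hw)
  }, numeric(6)))
  expect_true(all(diff(dims) >= 0))
  # facial height grows faster than breadth
  rel_h <- dims[, 4] / dims[1, 4]
  rel_w <- dims[, 1] / dims[1, 1]
  expect_true(all(rel_h[-1] >= rel_w[-1] - 1e-12))
})

test_that("bite nodes sit inferior-anterior to the TMJ and arches connect", {
  m <- coarse_mesh(48)
  ns <- m$node_sets
  bite <- c(ns$bite_incisor, ns$bite_molar_L, ns$bite_molar_R)
  tmj <- c(ns$tmj_L, ns$tmj_R)
  expect_lt(max(m$nodes[bite, 3L]), min(m$nodes[tmj, 3L]))
  expect_gt(min(m$nodes[bite, 2L]), max(m$nodes[tmj, 2L]))
  # the mesh (arches included) is a single connected body: a solve under a
  # pure arch load would otherwise be singular, so connectivity was already
  # enforced at build time; assert the arch labels are present on both sides
  expect_true(all(c("zygomatic_arch_L", "zygomatic_arch_R") %in% m$label))
})

test_that("default 48-month surrogate at 2 mm pitch is desk scale", {
  m <- build_skull_mesh(skull_params(48, pitch = 2))
  expect_gte(nrow(m$tets), 20000)
  expect_lte(nrow(m$tets), 80000)
  expect_identical(sum(m$label %in% cranioload:::.joint_labels), 0L)
})

test_that("invalid parameters raise explicit domain/resolution errors", {
  expect_error(skull_params(2), "age_months")
  expect_error(skull_params(50), "age_months")
  expect_error(skull_params(24, pitch = 3, shell_thickness = 4),
               "resolution error")
  expect_error(build_skull_mesh(coarse_params(48, suture_width = 20)),
               "suture band")
})
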