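test_that("rigid transforms compose, invert and power correctly", {
  expect_equal(rt_power(rt_identity(), 5)$R, diag(3))
  # a 180-degree rotation about z squares to the identity
  half <- dof_to_transform(six_dof(rz = 180))
  sq <- rt_power(half, 2)
  expect_lt(max(abs(sq$R - diag(3))), 1e-9)
  expect_lt(max(abs(sq$t)), 1e-9)
  set.seed(1)
  for (rep in 1:5) {
    tr <- dof_to_transform(six_dof(runif(1, -5, 5), runif(1, -5, 5),
                                   runif(1, -5, 5), runif(1, -170, 170),
                                   runif(1, -80, 80), runif(1, -170, 170)))
    x <- matrix(rnorm(30), 10, 3)
    seq3 <- rt_apply(tr, rt_apply(tr, rt_apply(tr, x)))
    expect_lt(max(abs(rt_apply(rt_power(tr, 3), x) - seq3)), 1e-9)
    inv <- rt_compose(tr, rt_inverse(tr))
    expect_lt(max(abs(inv$R - diag(3))), 1e-9)
    expect_lt(max(abs(inv$t)), 1e-9)
    # isometry: pairwise distances preserved
    expect_lt(max(abs(dist(rt_apply(tr, x)) - dist(x))), 1e-9)
  }
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
})

test_that("six-DOF round trip is exact away from gimbal lock", {
  set.seed(2)
  for (rep in 1:10) {
    d <- six_dof(runif(1, -10, 10), runif(1, -10, 10), runif(1, -10, 10),
                 runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    d2 <- transform_to_dof(dof_to_transform(d))
    expect_lt(max(abs(unlist(d) - unlist(d2))), 1e-6)
  }
})

test_that("Kabsch superposition matches a quaternion oracle and recovers transforms", {
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_kabsch(x, x)$rmsd, 0, tolerance = 1e-10)
  expect_lt(superpose_kabsch(sweep(x, 2, c(3, -2, 7), "+"), x)$rmsd, 1e-10)
  set.seed(3)
  for (rep in 1:10) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_equal(superpose_kabsch(a, b)$rmsd,
                 quaternion_superpose_rmsd(a, b), tolerance = 1e-6)
    tr <- dof_to_transform(six_dof(1, -2, 3, runif(1, -170, 170),
                                   runif(1, -80, 80), runif(1, -170, 170)))
    fit <- superpose_kabsch(a, rt_apply(tr, a))
    expect_lt(max(abs(fit$transform$R - tr$R)), 1e-6)
    expect_lt(max(abs(fit$transform$t - tr$t)), 1e-6)
  }
  expect_error(superpose_kabsch(x[1:2, ], x[1:2, ]), "at least 3")
  expect_true(superpose_kabsch(cbind(1:5, 0, 0),
                               cbind(2 * (1:5), 0, 0))$degenerate)
})

test_that("ideal helix has standard alpha-helix geometry in the placement frame", {
  h <- make_ideal_helix(12)
  cas <- ca_matrix(h)
  steps <- sqrt(rowSums(diff(cas)^2))
  expect_lt(abs(mean(steps) - 3.8), 0.1)
  expect_lt(abs(mean(diff(cas[, 3])) - 1.5), 0.15)   # rise per residue
  # radius 0, orientation 0: axis collinear with z (via the one-residue
  # screw transform of the CA trace)
  st <- superpose_kabsch(cas[1:11, ], cas[2:12, ])
  ev <- eigen(st$transform$R)
  u <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  expect_lt(acos(min(1, abs(u[3] / sqrt(sum(u^2))))) * 180 / pi, 0.5)
  tor <- backbone_torsions(h)
  expect_true(all(abs(tor$phi[-1] + 57) < 0.01))
  expect_true(all(abs(tor$psi[-12] + 47) < 0.01))
  expect_error(make_ideal_helix(2), "at least 3")
})

test_that("torsion extraction and rebuilding are mutually inverse", {
  hp <- make_fixture("beta_hairpin", length = 12)
  tor <- backbone_torsions(hp)
  rb <- rebuild_from_torsions(tor)
  expect_lt(superpose_kabsch(ca_matrix(rb), ca_matrix(hp))$rmsd, 0.1)
  # omega fixed at 180 for all rebuilt residues
  rb_tor <- backbone_torsions(rb)
  expect_true(all(abs(abs(rb_tor$omega[!is.na(rb_tor$omega)]) - 180) < 1e-6))
  # rebuilding is rigid-motion covariant: torsions unchanged under motion
  tr <- dof_to_transform(six_dof(4, -1, 2, 30, 20, -50))
  tor2 <- backbone_torsions(rt_apply(tr, hp))
  expect_equal(tor2$phi, tor$phi, tolerance = 1e-6)
  expect_equal(tor2$psi, tor$psi, tolerance = 1e-6)
})

test_that("clash check flags close contacts and passes ideal structures", {
  # two CA atoms at 1 A in different, non-adjacent residues
  m <- build_chain(data.frame(phi = c(-120, -120), psi = c(130, 130),
                              omega = 180))
  m$residues$break_after[1] <- TRUE
  m2 <- m
  m2$xyz[m2$atoms$resno == 2, ] <-
    sweep(m2$xyz[m2$atoms$resno == 2, ], 2,
          atom_xyz(m2, 2, "CA") - (atom_xyz(m2, 1, "CA") + c(1, 0, 0)))
  expect_true(clash_check(m2))
  h <- make_ideal_helix(20)
  expect_false(clash_check(h))
  # exhaustive-pair oracle on the helix: no pair below threshold
  at <- h$atoms; xyz <- h$xyz
  worst <- Inf
  for (i in seq_len(nrow(at))) for (j in seq_len(nrow(at))) {
    if (j <= i || abs(at$resno[i] - at$resno[j]) <= 1) next
    worst <- min(worst, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  expect_gt(worst, 0.6 * 2 * 1.7)
  # threshold factor configurable
  expect_true(clash_check(h, factor = 2.0))
})
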