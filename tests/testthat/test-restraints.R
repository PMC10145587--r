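# independent brute-force oracle for internal coordinates: plain acos
# angles and a projection-based dihedral, no shared code with the package
oracle_coords <- function(xyz) {
  a <- xyz[1, ]; b <- xyz[2, ]; cc <- xyz[3, ]
  A <- xyz[4, ]; B <- xyz[5, ]; C <- xyz[6, ]
  ang <- function(p, q, s) {
    u <- p - q; v <- s - q
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  dih <- function(p1, p2, p3, p4) {
    ax <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    u <- (p1 - p2) - sum((p1 - p2) * ax) * ax
    v <- (p4 - p3) - sum((p4 - p3) * ax) * ax
    s <- sign(sum(ax * c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])))
    d <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    if (s == 0) d else s * d
  }
  list(r = sqrt(sum((a - A)^2)), theta = ang(b, a, A), Theta = ang(a, A, B),
       phi = dih(cc, b, a, A), Phi = dih(b, a, A, B), Psi = dih(a, A, B, C))
}

test_that("internal coordinates match simple and planar cases", {
  fx <- boresch_fixture()
  # distance a-A from the fixture coordinates
  ic <- internal_coords(fx$ensemble, fx$spec)
  expect_equal(ic$r, sqrt(1.5^2 + 2^2 + 1^2), tolerance = 1e-9)

  # planar cis arrangement: dihedral 0; trans: pi
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(quadbind:::dihedral4(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(quadbind:::dihedral4(trans[1, ], trans[2, ], trans[3, ],
                                        trans[4, ])), pi)

  # collinear triplet errors with the offending coordinate named
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
               c(3, 0, 0), c(4, 1, 0), c(5, 0, 0))
  expect_error(internal_coords(bad), "collinear|coincident")
})

test_that("internal coordinates agree with the brute-force oracle on random frames", {
  set.seed(19)
  for (i in 1:25) {
    xyz <- matrix(rnorm(18, sd = 3), 6, 3)
    ic <- try(internal_coords(xyz), silent = TRUE)
    if (inherits(ic, "try-error")) next  # degenerate draw
    oc <- oracle_coords(xyz)
    for (f in c("r", "theta", "Theta", "phi", "Phi", "Psi")) {
      expect_equal(ic[[f]], oc[[f]], tolerance = 1e-9)
    }
  }
})

test_that("internal coordinates are invariant under rigid motion", {
  set.seed(23)
  xyz <- matrix(rnorm(18, sd = 3), 6, 3)
  ic0 <- internal_coords(xyz)
  for (i in 1:10) {
    moved <- apply_rigid(xyz, random_rotation(), rnorm(3, sd = 10))
    ic1 <- internal_coords(moved)
    for (f in c("r", "theta", "Theta", "phi", "Phi", "Psi")) {
      expect_equal(ic1[[f]], ic0[[f]], tolerance = 1e-9)
    }
  }
})

test_that("restraint energy obeys coupling, reference and wrap rules", {
  fx <- boresch_fixture()
  ic <- internal_coords(fx$ensemble, fx$spec)
  spec <- fx$spec
  spec$r0 <- ic$r; spec$theta0 <- ic$theta; spec$Theta0 <- ic$Theta
  spec$phi0 <- ic$phi; spec$Phi0 <- ic$Phi; spec$Psi0 <- ic$Psi
  # lambda = 0: zero for any frame; at the references: zero at lambda = 1
  expect_equal(restraint_energy(ic, spec, lam = 0), 0)
  expect_equal(restraint_energy(ic, spec, lam = 1), 0)

  # single dihedral displaced by pi/2 with k = 1000 kJ/mol/rad^2:
  # 0.5 * 1000 * (pi/2)^2 kJ/mol = 1233.70 kJ/mol = 294.86 kcal/mol
  spec2 <- spec
  spec2$Psi0 <- quadbind:::wrap_pi(ic$Psi - pi / 2)
  e <- restraint_energy(ic, spec2, lam = 1)
  expect_equal(e, 0.5 * 1000 * (pi / 2)^2 / 4.184, tolerance = 1e-6)
  # and scales linearly in lambda
  expect_equal(restraint_energy(ic, spec2, lam = 0.25), e / 4, tolerance = 1e-9)

  # continuity across the wrap point: reference at ~pi, coordinate just
  # past -pi gives a small difference, not ~2*pi
  spec3 <- spec
  spec3$Psi0 <- pi - 0.01
  ic3 <- ic
  ic3$Psi <- -pi + 0.01
  e3 <- restraint_energy(ic3, spec3, lam = 1)
  expect_equal(e3, 0.5 * k_ang_to_kcal(1000) * 0.02^2, tolerance = 1e-9)
})

test_that("references from an ensemble use arithmetic and circular means", {
  fx <- boresch_fixture()
  # identical frames: references equal that frame's coordinates
  ens2 <- fx$ensemble
  ens2$coords <- array(rep(ens2$coords, 3), dim = c(6, 3, 3))
  filled <- reference_from_ensemble(ens2, fx$spec)
  ic <- internal_coords(fx$ensemble, fx$spec)
  expect_equal(filled$r0, ic$r, tolerance = 1e-12)
  expect_equal(filled$Psi0, ic$Psi, tolerance = 1e-12)

  # circular mean of {+179, -179} degrees is 180, not 0
  cm <- quadbind:::circular_mean(c(179, -179) * pi / 180)
  expect_equal(abs(cm$mean), pi, tolerance = 1e-9)

  # gaussian-jittered geometry recovers construction values within 3 SE
  df <- rbind(
    atom_row("CA", "C", 0, 3, 1, chain = "R", resid = 3, jitter = 0.05),
    atom_row("CB", "C", 1, 2, 0, chain = "R", resid = 2, jitter = 0.05),
    atom_row("NA", "N", 0, 0, 0, chain = "R", resid = 1, jitter = 0.05),
    atom_row("N1", "N", 1.5, -2, 1, chain = "L", resid = 1, record = "HETATM",
             jitter = 0.05),
    atom_row("C2", "C", 3, -3, 0, chain = "L", resid = 1, record = "HETATM",
             jitter = 0.05),
    atom_row("C3", "C", 4, -2, 2, chain = "L", resid = 1, record = "HETATM",
             jitter = 0.05))
  jit <- plant_contact_frames(df, n_frames = 400, seed = 5)
  filled2 <- reference_from_ensemble(jit, fx$spec)
  expect_lt(abs(filled2$r0 - ic$r), 3 * 0.05 * sqrt(2) / sqrt(400) * 3)
  expect_lt(abs(quadbind:::wrap_pi(filled2$Phi0 - ic$Phi)), 0.05)

  # bimodal dihedral (+90 / -90 degrees across frames): resultant length
  # 0, circular mean degenerate
  xyz1 <- rbind(c(0, 1, 0),      # a
                c(0, 2, 1),      # b
                c(1, 3, 1),      # c
                c(0, 0, 0),      # A
                c(1, 0, 0),      # B
                c(1, 0, 1))      # C (Psi = +90 deg)
  xyz2 <- xyz1
  xyz2[6, ] <- c(1, 0, -1)       # C mirrored (Psi = -90 deg)
  # reorder rows to the fixture's atom-table order (c, b, a, A, B, C)
  bim <- fx$ensemble
  bim$coords <- array(NA_real_, dim = c(6, 3, 2))
  bim$coords[, , 1] <- xyz1[c(3, 2, 1, 4, 5, 6), ]
  bim$coords[, , 2] <- xyz2[c(3, 2, 1, 4, 5, 6), ]
  expect_error(reference_from_ensemble(bim, fx$spec),
               "degenerate|dispersed")
})

test_that("bulk restraint term matches its closed-form scalings", {
  spec <- restraint_spec(theta0 = pi / 2, Theta0 = pi / 2)
  kt <- kBT(300)
  base <- bulk_restraint_term(spec, 300, 1, r_star = 20)
  # multiplying all six force constants by 100 adds kT ln(100^3)
  spec_big <- restraint_spec(k_r = 1e5, k_theta = 1e5, k_phi = 1e5,
                             k_Theta = 1e5, k_Phi = 1e5, k_Psi = 1e5,
                             theta0 = pi / 2, Theta0 = pi / 2)
  expect_equal(bulk_restraint_term(spec_big, 300, 1, r_star = 20) - base,
               kt * log(1e6), tolerance = 1e-9)
  # r* 20 -> 22.5 A changes the term by 2 kT ln(22.5/20) in magnitude
  shift <- bulk_restraint_term(spec, 300, 1, r_star = 22.5) - base
  expect_equal(abs(shift), 2 * kt * log(22.5 / 20), tolerance = 1e-9)
  expect_lt(shift, 0)  # larger r* = larger accessible shell = cheaper restraint

  # monotone increasing in each force constant
  for (kname in c("k_r", "k_theta", "k_phi", "k_Theta", "k_Phi", "k_Psi")) {
    sp <- spec
    sp[[kname]] <- 2000
    expect_gt(bulk_restraint_term(sp, 300, 1, r_star = 20), base)
  }
  # degenerate reference angles rejected
  expect_error(bulk_restraint_term(restraint_spec(), 300, 1, r_star = 20),
               "sin")
})
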