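# Shared fixtures: reduced-unit temperature and small planted geometries.

# temperature at which kBT = 1 kcal/mol, so potentials declared "in kBT
# units" can be written directly in kcal/mol
T_RED <- 1 / quadbind::KB_KCAL

atom_row <- function(name, element, x, y, z, chain = "A", resid = 1L,
                     resname = "RES", record = "ATOM", jitter = 0) {
  data.frame(name = name, element = element, chain = chain, resid = resid,
             resname = resname, record = record, x = x, y = y, z = z,
             jitter = jitter, stringsAsFactors = FALSE)
}

# donor N (receptor, ATOM) with one H, acceptor O (ligand, HETATM):
# d(N...O) = d_da, angle N-H-A = angle_deg, N-H bond length 1.0 A
hbond_spec <- function(d_da = 3.0, angle_deg = 170) {
  alpha <- (180 - angle_deg) * pi / 180  # angle of O-H off the N->H axis
  # |O - N|^2 = 1 + 2 L cos(alpha) + L^2 = d_da^2
  L <- -cos(alpha) + sqrt(cos(alpha)^2 + d_da^2 - 1)
  o <- c(1 + L * cos(alpha), L * sin(alpha), 0)
  rbind(
    atom_row("N1", "N", 0, 0, 0, chain = "A", resid = 1, resname = "GUA"),
    atom_row("H1", "H", 1, 0, 0, chain = "A", resid = 1, resname = "GUA"),
    atom_row("O1", "O", o[1], o[2], o[3], chain = "L", resid = 1,
             resname = "LIG", record = "HETATM"))
}

# six restraint atoms c,b,a (receptor) and A,B,C (ligand) in a zig-zag
# with no degenerate angles; returns a one-frame ensemble plus the spec
boresch_fixture <- function() {
  spec_df <- rbind(
    atom_row("CA", "C", 0, 3, 1, chain = "R", resid = 3),   # c
    atom_row("CB", "C", 1, 2, 0, chain = "R", resid = 2),   # b
    atom_row("NA", "N", 0, 0, 0, chain = "R", resid = 1),   # a
    atom_row("N1", "N", 1.5, -2, 1, chain = "L", resid = 1, record = "HETATM"),  # A
    atom_row("C2", "C", 3, -3, 0, chain = "L", resid = 1, record = "HETATM"),    # B
    atom_row("C3", "C", 4, -2, 2, chain = "L", resid = 1, record = "HETATM"))    # C
  ens <- quadbind::plant_contact_frames(spec_df, n_frames = 1)
  rs <- quadbind::restraint_spec(
    receptor_atoms = list(a = list(chain = "R", resid = 1, name = "NA"),
                          b = list(chain = "R", resid = 2, name = "CB"),
                          c = list(chain = "R", resid = 3, name = "CA")),
    ligand_atoms = list(A = list(chain = "L", resid = 1, name = "N1"),
                        B = list(chain = "L", resid = 1, name = "C2"),
                        C = list(chain = "L", resid = 1, name = "C3")))
  list(ensemble = ens, spec = rs)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2, trans, `+`)
}
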