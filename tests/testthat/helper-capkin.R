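# Shared fixtures: wild-type rate constants, standard step protocol,
# toy structures.  Everything is built in code at test time.

wt_base <- function() rate_constants(0.061, 0.016, 0.42, 0.17)

# reactivation law anchored at the oxidative step potential, so that
# k_react(-0.21 V) equals the wild-type pH 7 reference value
wt_law <- function() kreact_exponential(k0 = 0.17, E_ref = -0.21, slope = 15)

wt_truth <- function() list(base = wt_base(), law = wt_law())

std_protocol <- function() make_step_protocol()

std_amps <- function() amplitude_map(c(-0.31, -0.21), c(0.7, 1))

# smaller protocol for fast unit-level fitting tests (still two
# distinct potentials, so all parameters stay identifiable)
small_protocol <- function()
  make_step_protocol(n_cycles = 2, durations = 40)

fast_fit_options <- function(...)
  utils::modifyList(list(multistart = 3, seed = 99, mask_after_step = 0),
                    list(...))

# cache one noiseless fit of the standard protocol: several tests
# inspect it and it is the most expensive fixture
.fit_cache <- new.env(parent = emptyenv())
noiseless_aai_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    prot <- std_protocol()
    tr <- generate_chronoamperogram(prot, wt_truth(), activity_weights(),
                                    std_amps(), noise = noise_spec(0, 1))
    .fit_cache$trace <- tr
    .fit_cache$fit <- fit_model(tr, prot, "aai", fast_fit_options())
  }
  list(trace = .fit_cache$trace, fit = .fit_cache$fit)
}

# fixed-width PDB writer for toy fixtures
toy_pdb_line <- function(record, serial, name, resname, chain, resno,
                         x, y, z, occ = 1, b = 10, element) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, "", resname, chain, resno, x, y, z,
          occ, b, formatC(element, width = 2, flag = " "))
}

# atoms: data.frame(record, serial, name, resname, chain, resno,
#                   x, y, z, occ, b, element)
write_toy_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    with(atoms[i, ], toy_pdb_line(record, serial, name, resname, chain,
                                  resno, x, y, z, occ, b, element)),
    character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(atoms, path) {
  head <- c("data_toy", "loop_",
            "_atom_site.group_PDB", "_atom_site.id",
            "_atom_site.type_symbol", "_atom_site.label_atom_id",
            "_atom_site.label_alt_id", "_atom_site.label_comp_id",
            "_atom_site.label_asym_id", "_atom_site.label_entity_id",
            "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y",
            "_atom_site.Cartn_z", "_atom_site.occupancy",
            "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
            "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
            "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
            "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(atoms)), function(i)
    with(atoms[i, ], sprintf(
      "%s %d %s %s . %s %s %d %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      record, serial, element, name, resname, chain, i, resno,
      x, y, z, occ, b, resno, resname, chain, name)),
    character(1))
  writeLines(c(head, rows), path)
  path
}

# a toy H-cluster-like arrangement: cap cysteine SG, a diiron group
# with one Fe close to and one far from a [4Fe-4S] cubane
toy_hcluster_atoms <- function() {
  data.frame(
    record = c("ATOM", rep("HETATM", 6)),
    serial = 1:7,
    name = c("SG", "FE1", "FE2", "FE1", "FE2", "FE3", "FE4"),
    resname = c("CYS", "F2H", "F2H", "SF4", "SF4", "SF4", "SF4"),
    chain = "A",
    resno = c(367L, 501L, 501L, 502L, 502L, 502L, 502L),
    x = c(0, 0, 0, 1, -1, 0, 0),
    y = c(0, 0, 0, 0, 0, 1, -1),
    z = c(8, 3, 6, 0, 0, 0, 0),
    occ = 1, b = 10,
    element = c("S", "FE", "FE", "FE", "FE", "FE", "FE"),
    stringsAsFactors = FALSE
  )
}

# in-memory structure object (same shape load_structure returns)
as_toy_structure <- function(atoms) {
  structure(
    data.frame(serial = atoms$serial, name = atoms$name,
               resname = atoms$resname, chain = atoms$chain,
               resno = atoms$resno, element = atoms$element,
               x = atoms$x, y = atoms$y, z = atoms$z,
               occupancy = atoms$occ, b = atoms$b,
               stringsAsFactors = FALSE),
    class = c("capkin_structure", "data.frame"))
}

rotation_about_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)

apply_rigid <- function(struct, R, t) {
  xyz <- as.matrix(struct[, c("x", "y", "z")]) %*% R
  struct$x <- xyz[, 1] + t[1]
  struct$y <- xyz[, 2] + t[2]
  struct$z <- xyz[, 3] + t[3]
  struct
}

# vectorised classical RK4 for the AAI master equation: integrates many
# (rates, dt) instances simultaneously; the independent oracle for
# propagate()
rk4_batch <- function(k1, km1, ki, kr, s0, dt, n_steps) {
  a1 <- s0[1, ]; a2 <- s0[2, ]; h <- s0[3, ]
  hstep <- dt / n_steps
  f <- function(a1, a2, h) list(
    d1 = -k1 * a1 + km1 * a2,
    d2 = k1 * a1 - (km1 + ki) * a2 + kr * h,
    d3 = ki * a2 - kr * h)
  for (i in seq_len(n_steps)) {
    k1v <- f(a1, a2, h)
    k2v <- f(a1 + hstep / 2 * k1v$d1, a2 + hstep / 2 * k1v$d2,
             h + hstep / 2 * k1v$d3)
    k3v <- f(a1 + hstep / 2 * k2v$d1, a2 + hstep / 2 * k2v$d2,
             h + hstep / 2 * k2v$d3)
    k4v <- f(a1 + hstep * k3v$d1, a2 + hstep * k3v$d2,
             h + hstep * k3v$d3)
    a1 <- a1 + hstep / 6 * (k1v$d1 + 2 * k2v$d1 + 2 * k3v$d1 + k4v$d1)
    a2 <- a2 + hstep / 6 * (k1v$d2 + 2 * k2v$d2 + 2 * k3v$d2 + k4v$d2)
    h <- h + hstep / 6 * (k1v$d3 + 2 * k2v$d3 + 2 * k3v$d3 + k4v$d3)
  }
  rbind(a1, a2, h)
}
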