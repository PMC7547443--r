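# Hand-built V2000 blocks and synthetic molecules shared across tests.

methane_sdf <- function() {
  paste(c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "$$$$"), collapse = "\n")
}

# ethanol with explicit hydrogens
ethanol_sdf <- function() {
  paste(c(
    "ethanol", "  test", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0500    1.3500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000   -0.5000    0.8000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000   -0.5000   -0.8000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9000   -0.5000    0.8000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9000   -0.5000   -0.8000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0100    1.3000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  4  1  0", "  1  5  1  0", "  1  6  1  0",
    "  2  7  1  0", "  2  8  1  0", "  3  9  1  0", "  2  3  1  0",
    "M  END", "$$$$"), collapse = "\n")
}

# same ethanol, hydrogen-suppressed
ethanol_implicit_sdf <- function() {
  paste(c(
    "ethanol_implicit", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0500    1.3500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$"), collapse = "\n")
}

# bicyclo[2.2.2]octane-like cage: two bridgeheads joined by three
# two-carbon bridges (hand geometry, chemically plausible distances)
bicyclooctane <- function(id = "bco") {
  coords <- rbind(
    c(0, 0, 1.2), c(1.2, 0.6, 0.6), c(1.2, 0.6, -0.6),
    c(-1.1, 0.7, 0.6), c(-1.1, 0.7, -0.6),
    c(0, -1.3, 0.6), c(0, -1.3, -0.6), c(0, 0, -1.2))
  mol3d(id,
        tibble::tibble(index = 1:8, element = "C",
                       x = coords[, 1], y = coords[, 2], z = coords[, 3]),
        tibble::tibble(a1 = c(1, 2, 3, 1, 4, 5, 1, 6, 7),
                       a2 = c(2, 3, 8, 4, 5, 8, 6, 7, 8),
                       order = 1L))
}

# methyl formate: H-C(=O)-O-CH3, hydrogen-suppressed
methyl_formate <- function(id = "formate") {
  mol3d(id,
        tibble::tibble(index = 1:4, element = c("C", "O", "O", "C"),
                       x = c(0, 0.6, 0.6, 2.0), y = c(0, 1.1, -1.1, -1.3),
                       z = 0),
        tibble::tibble(a1 = c(1, 1, 3), a2 = c(2, 3, 4),
                       order = c(2L, 1L, 1L)))
}

# methanol, hydrogen-suppressed
methanol <- function(id = "methanol") {
  mol3d(id,
        tibble::tibble(index = 1:2, element = c("C", "O"),
                       x = c(0, 1.43), y = 0, z = 0),
        tibble::tibble(a1 = 1L, a2 = 2L, order = 1L))
}

rigid_motion <- function(mol, angle = 0.7, shift = c(3, -2, 5)) {
  ca <- cos(angle); sa <- sin(angle)
  rot <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(rot)
  out <- mol
  out$atoms$x <- xyz[, 1] + shift[1]
  out$atoms$y <- xyz[, 2] + shift[2]
  out$atoms$z <- xyz[, 3] + shift[3]
  out
}

standard_fixtures <- function() {
  list(
    hexane = make_molecule(fixture_spec("chain", 6, id = "hexane")),
    cyclohexane = make_molecule(fixture_spec("ring", 6, id = "cyclohexane")),
    neopentane = make_molecule(fixture_spec("branch", 5, id = "neopentane")),
    two_rings = make_molecule(fixture_spec("two_dc_linker", 2,
                                           id = "two_rings"))
  )
}
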