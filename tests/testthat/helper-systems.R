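# Shared builders and independent oracles for the test suite.

# A topology with n free beads and no bonds (ideal-gas reference system).
free_bead_topology <- function(n = 1, bead_class = "H") {
  structure(list(
    beads = data.frame(index = seq_len(n), bead_class = bead_class,
                       molecule_id = seq_len(n), molecule_kind = "lipid",
                       layer = NA_integer_, stringsAsFactors = FALSE),
    fene_bonds = data.frame(i = integer(0), j = integer(0)),
    harmonic_bonds = data.frame(i = integer(0), j = integer(0),
                                r0 = numeric(0)),
    elastic_bonds = data.frame(i = integer(0), j = integer(0),
                               r0 = numeric(0)),
    reference_coords = matrix(0, n, 3)),
    class = "cooke_topology")
}

# Two beads joined by a single elastic bond (harmonic dimer).
elastic_dimer_topology <- function(r0) {
  structure(list(
    beads = data.frame(index = 1:2, bead_class = "H",
                       molecule_id = 1:2, molecule_kind = "peptide",
                       layer = NA_integer_, stringsAsFactors = FALSE),
    fene_bonds = data.frame(i = integer(0), j = integer(0)),
    harmonic_bonds = data.frame(i = integer(0), j = integer(0),
                                r0 = numeric(0)),
    elastic_bonds = data.frame(i = 1L, j = 2L, r0 = r0),
    reference_coords = rbind(c(0, 0, 0), c(r0, 0, 0))),
    class = "cooke_topology")
}

# Note: with two "peptide"-kind H beads the pair interaction between the
# bonded beads is excluded (elastic partners carry no nonbonded term), so
# the dimer is a pure radial harmonic oscillator.

# Mean potential energy of a 3-d harmonic dimer by direct quadrature over
# the radial Boltzmann weight: <V> = Int V(r) r^2 exp(-bV) / Int r^2 exp(-bV).
harmonic_dimer_mean_V <- function(k, r0, kT) {
  V <- function(r) 0.5 * k * (r - r0)^2
  w <- function(r) r^2 * exp(-V(r) / kT)
  z <- stats::integrate(w, 0, r0 + 20 * sqrt(kT / k))$value
  stats::integrate(function(r) V(r) * w(r), 0, r0 + 20 * sqrt(kT / k))$value / z
}

# Brute-force minimum-image distance matrix.
min_image_dist <- function(pos, box) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dd <- sweep(pos, 2, pos[i, ])
    dd <- dd - box * round(dd / box)
    d[i, ] <- sqrt(rowSums(dd^2))
  }
  d
}

# Independent single-linkage components over an adjacency threshold, via a
# plain union-find written against the distance matrix.
brute_components <- function(pos, box, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- min_image_dist(pos, box)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= cutoff) {
      a <- find(i); b <- find(j)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# Canonical form of a clustering label vector (for label-invariant
# comparison).
canon_labels <- function(lab) as.integer(factor(lab, levels = unique(lab)))

# Least-squares superposed RMSD (Kabsch) between two coordinate sets.
superposed_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(a, b))
  dsgn <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsgn)) %*% t(s$u)
  sqrt(mean(rowSums((b - a %*% t(R))^2)))
}

# Points uniformly on a sphere surface (deterministic spiral).
sphere_points <- function(n, R) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  R * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}
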