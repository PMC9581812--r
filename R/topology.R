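#' Build the 3-bead lipid topology
#'
#' One hydrophilic head bead (H) and two hydrophobic tail beads (T), chained
#' by two FENE bonds (head--tail1, tail1--tail2) and straightened by one
#' harmonic bond between the head and second tail bead with rest length
#' \eqn{4\sigma}. The reference geometry places the beads on a line at
#' \eqn{\sigma} spacing (FENE bonds have no rest length; the build
#' coordinates only fix a packing convention).
#'
#' @param params `cooke_ff` parameter record (supplies `sigma`, `r_bend0`).
#' @return A `cooke_topology` with 3 beads, 2 FENE bonds, 1 harmonic bond.
#' @examples
#' lip <- build_lipid()
#' lip$beads$bead_class  # "H" "T" "T"
#' @export
build_lipid <- function(params = ff_params()) {
  s <- params$sigma
  beads <- data.frame(
    index = 1:3,
    bead_class = c("H", "T", "T"),
    molecule_id = 1L,
    molecule_kind = "lipid",
    layer = NA_integer_,
    stringsAsFactors = FALSE
  )
  ref <- rbind(c(0, 0, 0), c(0, 0, -s), c(0, 0, -2 * s))
  new_topology(
    beads = beads,
    fene_bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L)),
    harmonic_bonds = data.frame(i = 1L, j = 3L, r0 = params$r_bend0),
    elastic_bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0)),
    reference_coords = ref
  )
}

#' Build the 42-bead hexagonal-stack peptide topology
#'
#' Six layers, each a filled hexagon of 7 beads (1 center + 6 vertices on a
#' ring of radius \eqn{0.95\sigma}), stacked at \eqn{0.95\sigma} spacing so
#' neighboring beads sit near their repulsion minimum. Rigidity comes from a
#' fully connected elastic network: all 21 intra-layer pairs in each layer
#' and all 49 pairs between beads of adjacent layers (371 bonds total), with
#' rest lengths taken from the build geometry. A bead in an end layer
#' therefore has 13 bonds (6 intra-layer + 7 to the next layer); a
#' middle-layer bead has 20.
#'
#' Eight beads are hydrophobic (class T): by default two adjacent vertex
#' beads per layer on the four middle layers, aligned on one face, forming a
#' contiguous 2 x 4 lateral stripe that mimics the hydrophobic surface of a
#' membrane-bound amphipathic helix. The end layers are fully hydrophilic
#' caps. The stripe placement is configurable.
#'
#' @param params `cooke_ff` parameter record (supplies `sigma`).
#' @param stripe_layers Layers (1-6) carrying hydrophobic beads.
#' @param stripe_vertices Vertex positions (1-6, counted around the ring)
#'   marked hydrophobic within each stripe layer.
#' @return A `cooke_topology` with 42 beads and 371 elastic bonds.
#' @examples
#' pep <- build_peptide()
#' nrow(pep$beads)                        # 42
#' sum(pep$beads$bead_class == "H")       # 34
#' @export
build_peptide <- function(params = ff_params(),
                          stripe_layers = 2:5,
                          stripe_vertices = c(1L, 2L)) {
  s <- params$sigma
  ring_r <- 0.95 * s
  dz <- 0.95 * s
  stopifnot(all(stripe_layers %in% 1:6), all(stripe_vertices %in% 1:6))

  coords <- matrix(0, nrow = 42, ncol = 3)
  layer <- integer(42)
  vertex <- integer(42)  # 0 = center, 1..6 = ring position
  k <- 0L
  for (L in 1:6) {
    z <- (L - 1) * dz
    k <- k + 1L
    coords[k, ] <- c(0, 0, z); layer[k] <- L; vertex[k] <- 0L
    for (v in 1:6) {
      ang <- (v - 1) * pi / 3
      k <- k + 1L
      coords[k, ] <- c(ring_r * cos(ang), ring_r * sin(ang), z)
      layer[k] <- L; vertex[k] <- v
    }
  }

  cls <- rep("H", 42)
  cls[layer %in% stripe_layers & vertex %in% stripe_vertices] <- "T"

  ei <- integer(0); ej <- integer(0)
  for (L in 1:6) {
    idx <- which(layer == L)
    cmb <- utils::combn(idx, 2)
    ei <- c(ei, cmb[1, ]); ej <- c(ej, cmb[2, ])
  }
  for (L in 1:5) {
    a <- which(layer == L); b <- which(layer == L + 1)
    g <- expand.grid(i = a, j = b)
    ei <- c(ei, g$i); ej <- c(ej, g$j)
  }
  r0 <- sqrt(rowSums((coords[ei, , drop = FALSE] - coords[ej, , drop = FALSE])^2))

  beads <- data.frame(
    index = 1:42,
    bead_class = cls,
    molecule_id = 1L,
    molecule_kind = "peptide",
    layer = layer,
    stringsAsFactors = FALSE
  )
  new_topology(
    beads = beads,
    fene_bonds = data.frame(i = integer(0), j = integer(0)),
    harmonic_bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0)),
    elastic_bonds = data.frame(i = as.integer(ei), j = as.integer(ej), r0 = r0),
    reference_coords = coords
  )
}

#' Assemble a multi-molecule topology
#'
#' Concatenates `n_lipids` lipid and `n_peptides` peptide fragments with
#' globally consistent bead indices and molecule ids (lipids first, then
#' peptides). The molecule-id map is recoverable from the `beads` table.
#'
#' @param n_lipids,n_peptides Molecule counts (>= 0).
#' @param params `cooke_ff` parameter record.
#' @param ... Passed to [build_peptide()] (stripe configuration).
#' @return A `cooke_topology` with `3 n_lipids + 42 n_peptides` beads.
#' @examples
#' topo <- assemble_system(10, 2)
#' nrow(topo$beads)  # 10*3 + 2*42 = 114
#' @export
assemble_system <- function(n_lipids, n_peptides = 0, params = ff_params(),
                            ...) {
  if (n_lipids < 0 || n_peptides < 0)
    stop("assemble_system: molecule counts must be >= 0")
  lip <- build_lipid(params)
  pep <- if (n_peptides > 0) build_peptide(params, ...) else NULL

  beads <- list(); fene <- list(); harm <- list(); elas <- list(); ref <- list()
  offset <- 0L
  mol <- 0L
  add_fragment <- function(frag) {
    b <- frag$beads
    b$index <- b$index + offset
    b$molecule_id <- mol
    beads[[length(beads) + 1L]] <<- b
    if (nrow(frag$fene_bonds)) {
      f <- frag$fene_bonds; f$i <- f$i + offset; f$j <- f$j + offset
      fene[[length(fene) + 1L]] <<- f
    }
    if (nrow(frag$harmonic_bonds)) {
      h <- frag$harmonic_bonds; h$i <- h$i + offset; h$j <- h$j + offset
      harm[[length(harm) + 1L]] <<- h
    }
    if (nrow(frag$elastic_bonds)) {
      e <- frag$elastic_bonds; e$i <- e$i + offset; e$j <- e$j + offset
      elas[[length(elas) + 1L]] <<- e
    }
    ref[[length(ref) + 1L]] <<- frag$reference_coords
    offset <<- offset + nrow(b)
  }
  for (m in seq_len(n_lipids)) { mol <- mol + 1L; add_fragment(lip) }
  for (m in seq_len(n_peptides)) { mol <- mol + 1L; add_fragment(pep) }

  empty_ij <- data.frame(i = integer(0), j = integer(0))
  empty_ijr <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  new_topology(
    beads = if (length(beads)) do.call(rbind, beads) else
      data.frame(index = integer(0), bead_class = character(0),
                 molecule_id = integer(0), molecule_kind = character(0),
                 layer = integer(0), stringsAsFactors = FALSE),
    fene_bonds = if (length(fene)) do.call(rbind, fene) else empty_ij,
    harmonic_bonds = if (length(harm)) do.call(rbind, harm) else empty_ijr,
    elastic_bonds = if (length(elas)) do.call(rbind, elas) else empty_ijr,
    reference_coords = if (length(ref)) do.call(rbind, ref) else
      matrix(0, 0, 3)
  )
}

new_topology <- function(beads, fene_bonds, harmonic_bonds, elastic_bonds,
                         reference_coords) {
  rownames(beads) <- NULL
  topo <- list(beads = beads, fene_bonds = fene_bonds,
               harmonic_bonds = harmonic_bonds,
               elastic_bonds = elastic_bonds,
               reference_coords = reference_coords)
  class(topo) <- "cooke_topology"
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  n <- nrow(topo$beads)
  all_bonds <- rbind(topo$fene_bonds[, c("i", "j")],
                     topo$harmonic_bonds[, c("i", "j")],
                     topo$elastic_bonds[, c("i", "j")])
  if (nrow(all_bonds)) {
    if (any(all_bonds$i == all_bonds$j)) stop("topology: self-bond")
    if (any(all_bonds < 1L) || any(all_bonds > n))
      stop("topology: bond index out of range")
    key <- paste(pmin(all_bonds$i, all_bonds$j),
                 pmax(all_bonds$i, all_bonds$j))
    if (anyDuplicated(key)) stop("topology: duplicate bond")
  }
  if (nrow(topo$reference_coords) != n)
    stop("topology: reference_coords row count != bead count")
  invisible(topo)
}

#' @export
print.cooke_topology <- function(x, ...) {
  kinds <- table(x$beads$molecule_kind[!duplicated(x$beads$molecule_id)])
  cat(sprintf("Cooke topology: %d beads, %d molecules (%s)\n",
              nrow(x$beads), length(unique(x$beads$molecule_id)),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", ")))
  cat(sprintf("  bonds: %d FENE, %d harmonic, %d elastic\n",
              nrow(x$fene_bonds), nrow(x$harmonic_bonds),
              nrow(x$elastic_bonds)))
  invisible(x)
}

# Flatten a topology into the integer/double arrays the C++ core consumes.
topology_arrays <- function(topology) {
  b <- topology$beads
  list(
    cls = as.integer(b$bead_class == "T"),
    kind = as.integer(b$molecule_kind == "peptide"),
    fene = as.matrix(topology$fene_bonds[, c("i", "j"), drop = FALSE]) |>
      matrix_int(),
    harm = as.matrix(topology$harmonic_bonds[, c("i", "j"), drop = FALSE]) |>
      matrix_int(),
    harm_r0 = as.numeric(topology$harmonic_bonds$r0),
    elas = as.matrix(topology$elastic_bonds[, c("i", "j"), drop = FALSE]) |>
      matrix_int(),
    elas_r0 = as.numeric(topology$elastic_bonds$r0)
  )
}

matrix_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Per-bead elastic-network bond degree
#'
#' @param topology `cooke_topology`.
#' @return Integer vector: number of elastic bonds touching each bead.
#' @export
elastic_degree <- function(topology) {
  n <- nrow(topology$beads)
  tabulate(c(topology$elastic_bonds$i, topology$elastic_bonds$j), nbins = n)
}
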