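#' Deterministic idealized configurations for analysis testing
#'
#' Builds pre-assembled coordinate sets with known structure so every
#' analysis operation can be exercised without running long self-assembly
#' dynamics:
#' \describe{
#'   \item{`micelle`}{Spherical micelle, heads out, tails in; hydrophobic
#'     shells dense enough that the contact graph at the default 0.9 nm
#'     cutoff is connected. Geometrically sensible up to ~150 lipids (the
#'     all-bead Rg stays below the 2.5 nm disc threshold).}
#'   \item{`disc`}{Flat circular bilayer patch; any peptides stand on the
#'     rim, axes normal to the disc plane with the hydrophobic stripe
#'     facing the lipid tails (the "picket fence" arrangement). Needs
#'     roughly >= 160 lipids for the all-bead Rg to exceed the 2.5 nm
#'     threshold.}
#'   \item{`bilayer`}{Planar square bilayer patch in the box center.}
#'   \item{`dispersed`}{Monomers placed with all inter-molecular bead
#'     distances beyond the interaction cutoff: no aggregates by
#'     construction.}
#'   \item{`mixture`}{One planted micelle plus one planted disc, separated
#'     well beyond the clustering cutoff; the planted per-aggregate
#'     composition and labels are returned.}
#' }
#'
#' @param kind One of `"micelle"`, `"disc"`, `"bilayer"`, `"dispersed"`,
#'   `"mixture"`.
#' @param n_lipids Total lipid count (for `mixture`, split between micelle
#'   and disc via `n_micelle_lipids`).
#' @param n_peptides Peptide count (rim peptides for `disc`/`mixture`).
#' @param seed Integer seed (orientation jitter in `dispersed`).
#' @param box_edge_nm Box edge; `NULL` derives one from the geometry
#'   (or from `concentration_mM` for `dispersed`).
#' @param concentration_mM Lipid concentration used when deriving the
#'   `dispersed` box (default 0.01 mM, far below the CMC).
#' @param area_per_lipid_nm2 Leaflet area per lipid for disc/bilayer
#'   packing.
#' @param n_micelle_lipids For `mixture`: lipids in the planted micelle.
#' @param params `cooke_ff`.
#' @return List with `state`, `topology`, and for `mixture` a `planted`
#'   data frame (aggregate label and composition).
#' @examples
#' fx <- generate_fixture("micelle", n_lipids = 30)
#' cl <- cluster_frame(fx$state, fx$topology)
#' max(cl)  # 1: a single aggregate of 30 molecules
#' @export
generate_fixture <- function(kind = c("micelle", "disc", "bilayer",
                                      "dispersed", "mixture"),
                             n_lipids, n_peptides = 0, seed = 1,
                             box_edge_nm = NULL, concentration_mM = 0.01,
                             area_per_lipid_nm2 = 0.45,
                             n_micelle_lipids = 30,
                             params = ff_params()) {
  kind <- match.arg(kind)
  set.seed(seed)
  s <- params$sigma
  switch(kind,
    micelle = {
      topo <- assemble_system(n_lipids, 0, params)
      pos <- micelle_coords(n_lipids, s)
      box <- box_or(box_edge_nm, 6 * max(abs(pos)) + 6)
      list(state = new_system_state(sweep(pos, 2, rep(box / 2, 3), "+"), box),
           topology = topo)
    },
    disc = {
      topo <- assemble_system(n_lipids, n_peptides, params)
      pos <- disc_coords(n_lipids, n_peptides, s, area_per_lipid_nm2, params)
      box <- box_or(box_edge_nm, 4 * max(abs(pos)) + 6)
      list(state = new_system_state(sweep(pos, 2, rep(box / 2, 3), "+"), box),
           topology = topo)
    },
    bilayer = {
      topo <- assemble_system(n_lipids, 0, params)
      pos <- bilayer_coords(n_lipids, s, area_per_lipid_nm2)
      box <- box_or(box_edge_nm, max(4 * max(abs(pos)) + 4, 8))
      list(state = new_system_state(sweep(pos, 2, rep(box / 2, 3), "+"), box),
           topology = topo)
    },
    dispersed = {
      topo <- assemble_system(n_lipids, n_peptides, params)
      box <- box_or(box_edge_nm,
                    box_edge_from_concentration(max(n_lipids, 1),
                                                concentration_mM))
      spec <- system_spec(n_lipids, n_peptides,
                         lipid_concentration_mM =
                           concentration_from_count(max(n_lipids, 1), box))
      packed <- random_pack(spec, topology = topo, seed = seed,
                            floor_nm = 2.0, params = params)
      list(state = packed$state, topology = topo)
    },
    mixture = {
      n_mic <- n_micelle_lipids
      n_disc <- n_lipids - n_mic
      stopifnot(n_disc > 0)
      topo <- assemble_system(n_lipids, n_peptides, params)
      mic <- micelle_coords(n_mic, s)
      dsc <- disc_coords(n_disc, n_peptides, s, area_per_lipid_nm2, params)
      gap <- max(abs(mic)) + max(abs(dsc)) + 5
      box <- box_or(box_edge_nm, 2 * gap + 10)
      ctr <- rep(box / 2, 3)
      mic <- sweep(mic, 2, ctr + c(-gap / 2, 0, 0), "+")
      # disc lipids occupy molecule ids n_mic+1 .. n_lipids, then peptides
      dsc <- sweep(dsc, 2, ctr + c(gap / 2, 0, 0), "+")
      pos <- rbind(mic, dsc)
      planted <- data.frame(
        label = c("micelle", "disc"),
        n_lipids = c(n_mic, n_disc),
        n_peptides = c(0L, as.integer(n_peptides)),
        stringsAsFactors = FALSE)
      list(state = new_system_state(pos, box), topology = topo,
           planted = planted)
    })
}

box_or <- function(box, fallback) if (is.null(box)) fallback else box

# Evenly distributed unit vectors (Fibonacci sphere).
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Spherical micelle centered at the origin: heads on the outer shell, tails
# pointing inward along the radius.
micelle_coords <- function(n, s) {
  stopifnot(n >= 1)
  u <- fib_sphere(n)
  r_head <- s + sqrt(0.49 * n / (4 * pi))  # tail-1 shell spacing ~0.7 nm
  pos <- matrix(0, 3 * n, 3)
  for (k in seq_len(n)) {
    rows <- (3 * (k - 1) + 1):(3 * k)
    pos[rows[1], ] <- u[k, ] * r_head
    pos[rows[2], ] <- u[k, ] * max(r_head - s, 0.15)
    pos[rows[3], ] <- u[k, ] * max(r_head - 2 * s, 0.05)
  }
  pos
}

# Sunflower (phyllotaxis) points filling a disc of given per-point area.
sunflower <- function(n, area_per_point) {
  k <- seq_len(n)
  r <- sqrt(k * area_per_point / pi)
  th <- k * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th))
}

# Flat circular bilayer patch in the z = 0 plane, optional rim peptides.
disc_coords <- function(n_lipids, n_peptides, s, a0, params) {
  n_up <- ceiling(n_lipids / 2)
  n_dn <- n_lipids - n_up
  sb <- 0.9 * s                      # intra-lipid spacing along the normal
  z_t2 <- 0.25                       # half of the tail-tail gap
  leaf <- function(n, sgn) {
    xy <- sunflower(n, a0)
    pos <- matrix(0, 3 * n, 3)
    for (k in seq_len(n)) {
      rows <- (3 * (k - 1) + 1):(3 * k)
      pos[rows[1], ] <- c(xy[k, ], sgn * (z_t2 + 2 * sb))  # head
      pos[rows[2], ] <- c(xy[k, ], sgn * (z_t2 + sb))      # tail 1
      pos[rows[3], ] <- c(xy[k, ], sgn * z_t2)             # tail 2
    }
    pos
  }
  pos <- rbind(leaf(n_up, +1), leaf(n_dn, -1))
  if (n_peptides > 0) {
    r_edge <- sqrt(max(n_up, n_dn) * a0 / pi)
    pep_ref <- build_peptide(params)$reference_coords
    pep_ref <- sweep(pep_ref, 2, colMeans(pep_ref))
    # hydrophobic stripe direction in the reference frame (vertices at 0
    # and 60 degrees -> mean azimuth 30 degrees)
    stripe_ang <- pi / 6
    for (k in seq_len(n_peptides)) {
      az <- 2 * pi * (k - 1) / n_peptides
      rot_z <- (az + pi) - stripe_ang   # stripe faces the disc center
      R <- matrix(c(cos(rot_z), -sin(rot_z), 0,
                    sin(rot_z),  cos(rot_z), 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
      axis_r <- r_edge + 0.3
      ctr <- c(axis_r * cos(az), axis_r * sin(az), 0)
      pos <- rbind(pos, sweep(pep_ref %*% t(R), 2, ctr, "+"))
    }
  }
  pos
}

# Planar square bilayer patch centered at the origin.
bilayer_coords <- function(n_lipids, s, a0) {
  n_up <- ceiling(n_lipids / 2)
  n_dn <- n_lipids - n_up
  sp <- sqrt(a0)
  sb <- 0.9 * s
  z_t2 <- 0.25
  leaf <- function(n, sgn) {
    nx <- ceiling(sqrt(n))
    g <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))[seq_len(n), ]
    xy <- cbind((g$ix - (nx + 1) / 2) * sp, (g$iy - (nx + 1) / 2) * sp)
    pos <- matrix(0, 3 * n, 3)
    for (k in seq_len(n)) {
      rows <- (3 * (k - 1) + 1):(3 * k)
      pos[rows[1], ] <- c(xy[k, ], sgn * (z_t2 + 2 * sb))
      pos[rows[2], ] <- c(xy[k, ], sgn * (z_t2 + sb))
      pos[rows[3], ] <- c(xy[k, ], sgn * z_t2)
    }
    pos
  }
  rbind(leaf(n_up, +1), leaf(n_dn, -1))
}
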