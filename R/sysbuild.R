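#' System composition and concentration specification
#'
#' Defines a simulated composition: lipid count, peptide count (equivalently
#' the bulk P/L ratio), target lipid concentration, and the replica set.
#' Concentration is defined on lipids only; peptides are additional
#' molecules in the same box.
#'
#' @param n_lipids Lipid count (>= 0).
#' @param n_peptides Peptide count (>= 0).
#' @param lipid_concentration_mM Total lipid concentration (mmol/L).
#' @param replicas Number of replicas.
#' @param base_seed Base seed; replica k uses `base_seed + k - 1`.
#' @return A `system_spec` object with the derived `box_edge_nm` and
#'   `p_over_l`.
#' @export
system_spec <- function(n_lipids, n_peptides = 0,
                        lipid_concentration_mM = 10,
                        replicas = 1, base_seed = 1) {
  stopifnot(n_lipids >= 0, n_peptides >= 0, lipid_concentration_mM > 0,
            replicas >= 1)
  spec <- list(n_lipids = as.integer(n_lipids),
               n_peptides = as.integer(n_peptides),
               lipid_concentration_mM = lipid_concentration_mM,
               p_over_l = if (n_lipids > 0) n_peptides / n_lipids else NA_real_,
               replicas = as.integer(replicas),
               base_seed = as.integer(base_seed),
               box_edge_nm = box_edge_from_concentration(
                 max(n_lipids, 1L), lipid_concentration_mM))
  class(spec) <- "system_spec"
  spec
}

#' Cubic box edge from lipid count and concentration
#'
#' Solves \eqn{n / (N_A V) = c} for a cubic box:
#' \eqn{L = (n / (N_A c))^{1/3}}.
#'
#' @param n_lipids Lipid count (>= 1).
#' @param concentration_mM Lipid concentration (mmol/L).
#' @return Box edge (nm).
#' @examples
#' box_edge_from_concentration(1000, 10)  # ~54.95 nm
#' @export
box_edge_from_concentration <- function(n_lipids, concentration_mM) {
  if (n_lipids < 1 || concentration_mM <= 0)
    stop("box_edge_from_concentration: need n_lipids >= 1 and concentration > 0")
  # c [mol/L] * N_A / 1e24 = molecules per nm^3
  per_nm3 <- concentration_mM * 1e-3 * .avogadro * 1e-24
  (n_lipids / per_nm3)^(1 / 3)
}

#' Molar concentration from a count and a box volume
#'
#' @param n Molecule count.
#' @param box_edge_nm Cubic box edge (nm).
#' @return Concentration (mmol/L).
#' @export
concentration_from_count <- function(n, box_edge_nm) {
  n / (.avogadro * (box_edge_nm^3 * 1e-24)) * 1e3
}

#' Random initial configuration at target composition
#'
#' Places each molecule (rigid reference geometry, uniformly random position
#' and orientation) into the cubic box by rejection sampling: a placement is
#' accepted only if every bead stays at least `floor_nm` from all beads of
#' previously placed molecules under minimum image. This reproduces the role
#' of a packing tool in an assembly workflow and keeps the artifact
#' self-contained. Deterministic for a given seed.
#'
#' @param spec `system_spec`.
#' @param topology Matching `cooke_topology`, or `NULL` to build it from the
#'   spec.
#' @param seed Integer seed.
#' @param floor_nm Minimum inter-molecular bead distance (nm).
#' @param max_tries Placement attempts per molecule before giving up.
#' @param params `cooke_ff`.
#' @return List with `state` (`cooke_state`) and `topology`.
#' @export
random_pack <- function(spec, topology = NULL, seed = spec$base_seed,
                        floor_nm = 0.8 * 0.6, max_tries = 2000,
                        params = ff_params()) {
  if (is.null(topology))
    topology <- assemble_system(spec$n_lipids, spec$n_peptides, params)
  box <- spec$box_edge_nm
  set.seed(seed)

  mol_ids <- unique(topology$beads$molecule_id)
  n_beads <- nrow(topology$beads)
  pos <- matrix(NA_real_, n_beads, 3)
  placed <- matrix(numeric(0), 0, 3)
  cutoff2 <- floor_nm^2

  for (m in mol_ids) {
    rows <- which(topology$beads$molecule_id == m)
    ref <- topology$reference_coords[rows, , drop = FALSE]
    ref <- sweep(ref, 2, colMeans(ref))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      R <- random_rotation()
      center <- stats::runif(3, 0, box)
      cand <- sweep(ref %*% t(R), 2, center, "+")
      if (nrow(placed) == 0 || min_image_min_dist2(cand, placed, box) >= cutoff2) {
        pos[rows, ] <- cand
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("random_pack: failed to place molecule %d after %d",
                          " tries; the box is too crowded - lower the",
                          " concentration or the placement floor"),
                   m, max_tries))
  }
  list(state = new_system_state(pos, box), topology = topology)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Squared minimum-image distance between the closest pair of rows of a and b.
min_image_min_dist2 <- function(a, b, box) {
  best <- Inf
  for (k in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[k, ])
    d <- d - box * round(d / box)
    best <- min(best, min(rowSums(d^2)))
  }
  best
}

#' Build, relax, and thermalize a system in one call
#'
#' Convenience pipeline: random pack, energy minimization, ramped-timestep
#' equilibration. Returns a production-ready state.
#'
#' @param spec `system_spec`.
#' @param seed Integer seed.
#' @param params `cooke_ff`.
#' @param config `engine_config`.
#' @param stage_steps Equilibration steps per time-step stage.
#' @param min_steps Minimization step budget.
#' @return List with `state` and `topology`.
#' @export
prepare_system <- function(spec, seed = spec$base_seed,
                           params = ff_params(), config = engine_config(),
                           stage_steps = 1e4, min_steps = 2000) {
  built <- random_pack(spec, seed = seed, params = params)
  st <- minimize(built$state, built$topology, params, max_steps = min_steps)
  st <- equilibrate(st, built$topology, params, seed = seed,
                    stage_steps = stage_steps, config = config)
  list(state = st, topology = built$topology)
}
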