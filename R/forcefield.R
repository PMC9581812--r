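#' Cooke-model force-field parameters
#'
#' Builds the single parameter record used by every energy, force, and
#' dynamics routine. Defaults reproduce the standard parametrization of the
#' implicit-solvent Cooke lipid model with a characteristic length
#' \eqn{\sigma = 0.6} nm and energy \eqn{\epsilon = 1} kcal/mol:
#' bead diameters \eqn{b_{HH} = b_{HT} = 0.95\sigma}, \eqn{b_{TT} = \sigma};
#' attraction width \eqn{w_c = \sigma} (applied only to
#' hydrophobic--hydrophobic pairs involving at least one lipid bead);
#' FENE bonds with \eqn{k_{bond} = 30\epsilon/\sigma^2} and
#' \eqn{r_\infty = 1.5\sigma}; a harmonic head--second-tail bond with
#' \eqn{k_{bend} = 10\epsilon/\sigma^2} and rest length \eqn{4\sigma}; and
#' elastic-network bonds with \eqn{k = 30\epsilon/\sigma^2}.
#'
#' All quantities are in nm, kcal/mol, and K. The WCA cutoff for any pair is
#' \eqn{r_c = 2^{1/6} b}.
#'
#' @param sigma Characteristic length (nm).
#' @param epsilon Characteristic energy (kcal/mol).
#' @param b_HH,b_HT,b_TT Pair diameters by bead class (nm).
#' @param w_c Attraction width for eligible hydrophobic pairs (nm).
#' @param k_bond FENE stiffness (kcal/mol/nm^2).
#' @param r_inf FENE divergence length (nm).
#' @param k_bend Harmonic head--tail2 stiffness (kcal/mol/nm^2).
#' @param r_bend0 Harmonic head--tail2 rest length (nm).
#' @param k_elastic Elastic-network stiffness (kcal/mol/nm^2).
#' @param temperature Thermostat temperature (K).
#' @param r_min_frac Overlap floor on pair distances, as a fraction of the
#'   pair diameter `b`; guards numerical overflow in heavily overlapped
#'   starting configurations.
#' @return An object of class `cooke_ff`: a named list of parameters plus the
#'   Boltzmann constant `kB` (kcal/mol/K).
#' @examples
#' ff <- ff_params()
#' ff$sigma              # 0.6 nm
#' ff$kB * ff$temperature / ff$epsilon  # kT/eps ~ 0.616 at 310 K
#' @export
ff_params <- function(sigma = 0.6, epsilon = 1.0,
                      b_HH = 0.95 * sigma, b_HT = 0.95 * sigma,
                      b_TT = 1.0 * sigma, w_c = sigma,
                      k_bond = 30 * epsilon / sigma^2,
                      r_inf = 1.5 * sigma,
                      k_bend = 10 * epsilon / sigma^2,
                      r_bend0 = 4 * sigma,
                      k_elastic = 30 * epsilon / sigma^2,
                      temperature = 310,
                      r_min_frac = 0.3) {
  stopifnot(sigma > 0, epsilon > 0,
            b_HH >= 0, b_HT >= 0, b_TT >= 0, w_c >= 0,
            k_bond >= 0, r_inf > 0, k_bend >= 0, r_bend0 >= 0,
            k_elastic >= 0, temperature > 0,
            r_min_frac > 0, r_min_frac < 1)
  p <- list(sigma = sigma, epsilon = epsilon,
            b_HH = b_HH, b_HT = b_HT, b_TT = b_TT, w_c = w_c,
            k_bond = k_bond, r_inf = r_inf,
            k_bend = k_bend, r_bend0 = r_bend0,
            k_elastic = k_elastic,
            temperature = temperature,
            kB = .kB_kcal,
            r_min_frac = r_min_frac)
  class(p) <- "cooke_ff"
  p
}

.kB_kcal <- 0.0019872041      # Boltzmann constant, kcal/mol/K
.time_unit_fs <- 488.8821     # sqrt(amu nm^2 / (kcal/mol)) in fs
.avogadro <- 6.02214076e23

#' @export
print.cooke_ff <- function(x, ...) {
  cat("Cooke force field (nm, kcal/mol, K)\n")
  cat(sprintf("  sigma = %.3g nm, epsilon = %.3g kcal/mol, T = %g K (kT/eps = %.4f)\n",
              x$sigma, x$epsilon, x$temperature,
              x$kB * x$temperature / x$epsilon))
  cat(sprintf("  b_HH = b_HT = %.3g, b_TT = %.3g, w_c = %.3g nm\n",
              x$b_HH, x$b_TT, x$w_c))
  cat(sprintf("  k_bond = %.3g, r_inf = %.3g | k_bend = %.3g, r0 = %.3g | k_elastic = %.3g\n",
              x$k_bond, x$r_inf, x$k_bend, x$r_bend0, x$k_elastic))
  invisible(x)
}

#' Weeks-Chandler-Andersen repulsion
#'
#' Purely repulsive truncated-shifted Lennard-Jones:
#' \eqn{V(r) = 4\epsilon[(b/r)^{12} - (b/r)^6 + 1/4]} for
#' \eqn{r \le r_c = 2^{1/6} b}, zero beyond. Continuous and once
#' differentiable at the cutoff.
#'
#' @param r Pair distance(s), nm. Must be positive.
#' @param b Pair diameter, nm.
#' @param params `cooke_ff` parameter record (supplies `epsilon`).
#' @return Energy (kcal/mol), vectorized over `r`.
#' @export
v_rep <- function(r, b, params = ff_params()) {
  if (any(r <= 0)) stop("v_rep: r must be positive")
  if (b <= 0) stop("v_rep: b must be positive")
  rc <- 2^(1/6) * b
  sr6 <- (b / r)^6
  ifelse(r <= rc, 4 * params$epsilon * (sr6^2 - sr6 + 0.25), 0)
}

#' Broadened cosine-squared attraction
#'
#' The Cooke-model attraction: \eqn{-\epsilon} for \eqn{r < r_c},
#' \eqn{-\epsilon\cos^2[\pi (r - r_c)/(2 w_c)]} on
#' \eqn{r_c \le r \le r_c + w_c}, and zero beyond, with
#' \eqn{r_c = 2^{1/6} b}. Continuous at both junctions. The width `w_c`
#' tunes the range of the hydrophobic attraction; `w_c = 0` disables the
#' term entirely.
#'
#' @param r Pair distance(s), nm. Must be positive.
#' @param w_c Attraction width, nm (>= 0).
#' @param b Pair diameter, nm (sets the onset \eqn{r_c}).
#' @param params `cooke_ff` parameter record.
#' @return Energy (kcal/mol), vectorized over `r`.
#' @export
v_att <- function(r, w_c, b, params = ff_params()) {
  if (any(r <= 0)) stop("v_att: r must be positive")
  if (w_c < 0) stop("v_att: w_c must be >= 0")
  if (w_c == 0) return(rep(0, length(r)))
  rc <- 2^(1/6) * b
  eps <- params$epsilon
  out <- numeric(length(r))
  out[r < rc] <- -eps
  mid <- r >= rc & r <= rc + w_c
  out[mid] <- -eps * cos(pi * (r[mid] - rc) / (2 * w_c))^2
  out
}

#' FENE bond potential
#'
#' Finitely extensible nonlinear elastic bond
#' \eqn{V(r) = -\tfrac12 k_{bond} r_\infty^2 \log[1 - (r/r_\infty)^2]},
#' diverging at the maximum extension \eqn{r_\infty}. A distance at or
#' beyond \eqn{r_\infty} is a fatal bond overextension.
#'
#' @param r Bond distance(s), nm; `0 <= r < r_inf`.
#' @param params `cooke_ff` parameter record.
#' @return Energy (kcal/mol), vectorized over `r`.
#' @export
v_fene <- function(r, params = ff_params()) {
  if (any(r < 0)) stop("v_fene: r must be >= 0")
  if (any(r >= params$r_inf))
    stop(sprintf("v_fene: bond overextended (r >= r_inf = %.4g nm)", params$r_inf))
  -0.5 * params$k_bond * params$r_inf^2 * log(1 - (r / params$r_inf)^2)
}

#' Harmonic head--tail straightening bond
#'
#' \eqn{V(r) = \tfrac12 k_{bend} (r - 4\sigma)^2} between the head bead and
#' the second tail bead; its long rest length keeps the 3-bead lipid linear.
#'
#' @param r Bond distance(s), nm (>= 0).
#' @param params `cooke_ff` parameter record.
#' @return Energy (kcal/mol), vectorized over `r`.
#' @export
v_bend <- function(r, params = ff_params()) {
  if (any(r < 0)) stop("v_bend: r must be >= 0")
  0.5 * params$k_bend * (r - params$r_bend0)^2
}

#' Elastic-network bond
#'
#' \eqn{V(r) = \tfrac12 k (r - r_0)^2} with the rest length \eqn{r_0} taken
#' from the peptide's build-time reference geometry. The dense network of
#' these bonds keeps the 42-bead peptide nearly rigid.
#'
#' @param r Bond distance(s), nm (>= 0).
#' @param r0 Rest length(s), nm.
#' @param params `cooke_ff` parameter record.
#' @return Energy (kcal/mol), vectorized.
#' @export
v_elastic <- function(r, r0, params = ff_params()) {
  if (any(r < 0)) stop("v_elastic: r must be >= 0")
  0.5 * params$k_elastic * (r - r0)^2
}

#' Pair diameter and attraction width for a bead pair
#'
#' `b` is assigned by bead class only (`b_TT` for T--T, `b_HH` for H--H,
#' `b_HT` otherwise). The attraction width is `w_c` for
#' hydrophobic--hydrophobic pairs in which at least one bead belongs to a
#' lipid, and 0 for all other pairs -- in particular the peptide--peptide
#' attraction is zero.
#'
#' @param class_i,class_j Bead classes, `"H"` or `"T"`.
#' @param kind_i,kind_j Molecule kinds, `"lipid"` or `"peptide"`.
#' @param params `cooke_ff` parameter record.
#' @return List with elements `b`, `w_c`, and `r_c` (nm).
#' @export
pair_coefficients <- function(class_i, class_j, kind_i, kind_j,
                              params = ff_params()) {
  stopifnot(class_i %in% c("H", "T"), class_j %in% c("H", "T"),
            kind_i %in% c("lipid", "peptide"),
            kind_j %in% c("lipid", "peptide"))
  b <- if (class_i == "T" && class_j == "T") params$b_TT
       else if (class_i == "H" && class_j == "H") params$b_HH
       else params$b_HT
  wc <- if (class_i == "T" && class_j == "T" &&
            !(kind_i == "peptide" && kind_j == "peptide")) params$w_c else 0
  list(b = b, w_c = wc, r_c = 2^(1/6) * b)
}

#' Nonbonded energy and force for one bead pair
#'
#' Sum of the WCA repulsion and the cosine-squared attraction with the
#' pair's `b` and `w_c`, plus the analytic force on bead i
#' (\eqn{-dV/dr} along the displacement); the force on j is its negative.
#'
#' @param r_vec Minimum-image displacement `x_i - x_j` (length-3, nm).
#' @param class_i,class_j Bead classes, `"H"` or `"T"`.
#' @param kind_i,kind_j Molecule kinds, `"lipid"` or `"peptide"`.
#' @param params `cooke_ff` parameter record.
#' @return List with `energy` (kcal/mol) and `force_i` (kcal/mol/nm,
#'   length 3).
#' @export
pair_energy_force <- function(r_vec, class_i, class_j, kind_i, kind_j,
                              params = ff_params()) {
  co <- pair_coefficients(class_i, class_j, kind_i, kind_j, params)
  r <- sqrt(sum(r_vec^2))
  if (r < params$r_min_frac * co$b)
    stop("pair_energy_force: beads overlap below the numerical floor")
  e <- v_rep(r, co$b, params) + v_att(r, co$w_c, co$b, params)
  # analytic -dV/dr
  fmag <- 0
  if (r <= co$r_c) {
    sr6 <- (co$b / r)^6
    fmag <- fmag + 4 * params$epsilon * (12 * sr6^2 - 6 * sr6) / r
  }
  if (co$w_c > 0 && r >= co$r_c && r <= co$r_c + co$w_c) {
    arg <- pi * (r - co$r_c) / (2 * co$w_c)
    fmag <- fmag - params$epsilon * pi / co$w_c * cos(arg) * sin(arg)
  }
  list(energy = e, force_i = fmag * r_vec / r)
}

#' Total potential energy and per-bead forces
#'
#' Sums every nonbonded pair term (over a cell-list neighbor search under
#' minimum image) and every bonded term (FENE, harmonic head--tail,
#' elastic network). With no external field the forces sum to zero.
#'
#' @param state `cooke_state` system state.
#' @param topology `cooke_topology`.
#' @param params `cooke_ff` parameter record.
#' @param method `"cell"` (cell-list search) or `"brute"` (all-pairs
#'   reference path, used as the cross-check oracle in tests).
#' @return List with `energy` (total, kcal/mol), `forces` (N x 3 matrix,
#'   kcal/mol/nm), and the per-term breakdown `pair`, `fene`, `bend`,
#'   `elastic`.
#' @export
total_energy_forces <- function(state, topology, params = ff_params(),
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  ta <- topology_arrays(topology)
  cpp_energy_forces(state$positions, state$box_edge,
                    ta$cls, ta$kind, ta$fene, ta$harm, ta$harm_r0,
                    ta$elas, ta$elas_r0, unclass(params),
                    brute = (method == "brute"), soft = FALSE)
}
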