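#' Single-linkage clustering of molecules by hydrophobic-bead contacts
#'
#' Connected components of the contact graph over hydrophobic (T) beads at
#' the given cutoff (default 0.9 nm), with minimum-image distances.
#' Clustering only the hydrophobic beads reduces artificial merge events
#' when aggregates merely drift within a cutoff of each other. A molecule
#' joins a cluster if any of its hydrophobic beads does; molecules with no
#' hydrophobic bead within the cutoff of any other are singletons.
#'
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param cutoff_nm Contact cutoff (nm).
#' @param method `"cell"` or `"brute"` (all-pairs oracle path).
#' @return Integer vector of cluster labels, one per molecule (labels are
#'   arbitrary but deterministic); names are molecule ids.
#' @export
cluster_frame <- function(state, topology, cutoff_nm = 0.9,
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff_nm > 0)
  hyd <- which(topology$beads$bead_class == "T")
  mol_ids <- sort(unique(topology$beads$molecule_id))
  labels <- seq_along(mol_ids)
  names(labels) <- mol_ids
  if (length(hyd) == 0) return(labels)

  bead_lab <- cpp_cluster(state$positions[hyd, , drop = FALSE],
                          state$box_edge, cutoff_nm,
                          brute = (method == "brute"))
  hyd_mol <- topology$beads$molecule_id[hyd]
  # merge molecules sharing a bead component (a molecule's own beads all
  # join through it as well)
  merge_map <- seq_len(max(bead_lab) + length(mol_ids))
  find <- function(i) { while (merge_map[i] != i) i <- merge_map[i]; i }
  moff <- max(bead_lab)
  for (k in seq_along(hyd)) {
    a <- find(bead_lab[k])
    b <- find(moff + match(hyd_mol[k], mol_ids))
    if (a != b) merge_map[a] <- b
  }
  roots <- vapply(seq_along(mol_ids), function(m) find(moff + m), integer(1))
  labels <- as.integer(factor(roots, levels = unique(roots)))
  names(labels) <- mol_ids
  labels
}

#' Unwrap a cluster across periodic boundaries
#'
#' Breadth-first traversal of the cluster's molecule contact graph, placing
#' each molecule by minimum image relative to an already-placed neighbor;
#' within each molecule beads are placed by minimum image from the
#' molecule's first bead. Geometry metrics (radius of gyration, principal
#' components) are meaningless on wrapped coordinates, so every aggregate is
#' unwrapped before measurement.
#'
#' @param mol_ids Molecule ids forming one cluster.
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param cutoff_nm Contact cutoff used to define adjacency (nm).
#' @return Matrix of unwrapped coordinates for all beads of the cluster
#'   (row order: beads of `mol_ids` in the topology's order).
#' @export
unwrap_cluster <- function(mol_ids, state, topology, cutoff_nm = 0.9) {
  box <- state$box_edge
  rows_of <- lapply(mol_ids, function(m) which(topology$beads$molecule_id == m))
  # internally unwrap each molecule and compute a hydrophobic anchor point
  local_coords <- vector("list", length(mol_ids))
  anchors <- matrix(0, length(mol_ids), 3)
  for (k in seq_along(mol_ids)) {
    xyz <- state$positions[rows_of[[k]], , drop = FALSE]
    d <- sweep(xyz, 2, xyz[1, ])
    d <- d - box * round(d / box)
    xyz <- sweep(d, 2, xyz[1, ], "+")
    local_coords[[k]] <- xyz
    anchors[k, ] <- colMeans(xyz)
  }
  if (length(mol_ids) > 1) {
    # adjacency between molecules: any hydrophobic bead pair within cutoff
    hyd_of <- lapply(seq_along(mol_ids), function(k) {
      cls <- topology$beads$bead_class[rows_of[[k]]]
      local_coords[[k]][cls == "T", , drop = FALSE]
    })
    n <- length(mol_ids)
    placed <- rep(FALSE, n)
    shift <- matrix(0, n, 3)
    placed[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      pa <- hyd_of[[a]]
      if (nrow(pa) == 0) pa <- local_coords[[a]]
      pa <- sweep(pa, 2, shift[a, ], "+")
      for (b in which(!placed)) {
        pb <- hyd_of[[b]]
        if (nrow(pb) == 0) pb <- local_coords[[b]]
        # minimum-image displacement from b's anchor beads to a's
        best <- NULL; bestd <- Inf
        for (i in seq_len(nrow(pb))) {
          d <- sweep(pa, 2, pb[i, ])
          dmi <- d - box * round(d / box)
          r2 <- rowSums(dmi^2)
          j <- which.min(r2)
          if (r2[j] < bestd) {
            bestd <- r2[j]
            best <- (d[j, ] - dmi[j, ]) # lattice shift * box
          }
        }
        if (bestd <= cutoff_nm^2) {
          shift[b, ] <- best  # pa already carries shift[a]
          placed[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
    # any unplaced molecule (shouldn't occur for a genuine cluster): place
    # by minimum image of anchors relative to molecule 1
    for (b in which(!placed)) {
      d <- anchors[b, ] - (anchors[1, ] + shift[1, ])
      shift[b, ] <- -box * round(d / box)
    }
    for (k in seq_along(mol_ids))
      local_coords[[k]] <- sweep(local_coords[[k]], 2, shift[k, ], "+")
  }
  do.call(rbind, local_coords)
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\langle |r - \bar r|^2 \rangle}} over all rows
#' (unit bead masses).
#'
#' @param coords Unwrapped N x 3 coordinate matrix (nm).
#' @return Radius of gyration (nm).
#' @export
radius_of_gyration <- function(coords) {
  d <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(d^2)))
}

#' Aggregate size from the top two principal components
#'
#' Eigen-decomposes the bead-position covariance and reports the mean of the
#' coordinate ranges (max minus min) along the first two principal axes. For
#' beads on a sphere of radius R this tends to the diameter 2R; for a flat
#' disc of diameter D both leading axes span the disc plane and the measure
#' tends to D. The radius of gyration separates micelles from discs but
#' underestimates physical extent; this measure is the size proxy.
#'
#' @param coords Unwrapped N x 3 coordinate matrix (nm) of the aggregate's
#'   member beads.
#' @return Size (nm). Degenerate (collinear) aggregates fall back to the
#'   available components with a warning.
#' @export
aggregate_size <- function(coords) {
  d <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)
  nz <- ev$values > 1e-12 * max(ev$values, 1e-300)
  k <- min(2, sum(nz))
  if (k < 2) {
    warning("aggregate_size: degenerate aggregate; using ", k,
            " principal component(s)")
    if (k == 0) return(0)
  }
  proj <- d %*% ev$vectors[, seq_len(k), drop = FALSE]
  mean(apply(proj, 2, function(p) diff(range(p))))
}

#' Aggregate table for one frame
#'
#' Applies the full per-frame methodology: cluster molecules on hydrophobic
#' beads ([cluster_frame()]), discard clusters of fewer than `min_size`
#' molecules, unwrap each surviving cluster, and measure composition,
#' all-bead radius of gyration, and principal-component size. An aggregate
#' is labeled `"disc"` when its Rg is at or above `rg_cutoff_nm` (2.5 nm for
#' this model) and `"micelle"` otherwise. Lipids outside all reported
#' aggregates -- including those in sub-threshold clusters -- count as free.
#'
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param cutoff_nm Clustering cutoff (nm).
#' @param min_size Minimum molecules per reported aggregate.
#' @param rg_cutoff_nm Disc/micelle Rg threshold (nm).
#' @return A `frame_analysis`: list with `aggregates` (data frame: id,
#'   n_molecules, n_lipids, n_peptides, rg_nm, size_nm, label),
#'   `members` (list of molecule-id vectors), `coords` (list of unwrapped
#'   member-bead coordinates), `n_free_lipids`, `free_lipid_mM`, and
#'   `time_fs`.
#' @export
analyze_frame <- function(state, topology, cutoff_nm = 0.9, min_size = 5,
                          rg_cutoff_nm = 2.5) {
  labels <- cluster_frame(state, topology, cutoff_nm)
  make_aggregates(labels, state, topology, min_size = min_size,
                  rg_cutoff_nm = rg_cutoff_nm, cutoff_nm = cutoff_nm)
}

build_frame_analysis <- function(labels, state, topology, cutoff_nm,
                                 min_size, rg_cutoff_nm) {
  mol_ids <- as.integer(names(labels))
  mol_kind <- topology$beads$molecule_kind[match(mol_ids,
                                                 topology$beads$molecule_id)]
  total_lipids <- sum(mol_kind == "lipid")

  keep <- names(which(table(labels) >= min_size))
  agg_rows <- list(); members <- list(); coords <- list()
  aid <- 0L
  for (cl in keep) {
    aid <- aid + 1L
    mm <- mol_ids[labels == as.integer(cl)]
    kk <- mol_kind[labels == as.integer(cl)]
    xyz <- unwrap_cluster(mm, state, topology, cutoff_nm)
    rg <- radius_of_gyration(xyz)
    agg_rows[[aid]] <- data.frame(
      id = aid,
      n_molecules = length(mm),
      n_lipids = sum(kk == "lipid"),
      n_peptides = sum(kk == "peptide"),
      rg_nm = rg,
      size_nm = aggregate_size(xyz),
      label = if (rg >= rg_cutoff_nm) "disc" else "micelle",
      stringsAsFactors = FALSE
    )
    members[[aid]] <- mm
    coords[[aid]] <- xyz
  }
  aggregates <- if (aid > 0) do.call(rbind, agg_rows) else
    data.frame(id = integer(0), n_molecules = integer(0),
               n_lipids = integer(0), n_peptides = integer(0),
               rg_nm = numeric(0), size_nm = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  n_free <- total_lipids - sum(aggregates$n_lipids)
  out <- list(aggregates = aggregates, members = members, coords = coords,
              n_free_lipids = n_free,
              free_lipid_mM = concentration_from_count(n_free,
                                                       state$box_edge),
              total_lipids = total_lipids,
              time_fs = state$time_fs)
  class(out) <- "frame_analysis"
  out
}

#' @export
print.frame_analysis <- function(x, ...) {
  cat(sprintf("Frame analysis (t = %.3g ns): %d aggregate(s), %d free lipid(s) (%.3g mM)\n",
              x$time_fs / 1e6, nrow(x$aggregates), x$n_free_lipids,
              x$free_lipid_mM))
  if (nrow(x$aggregates)) print(x$aggregates)
  invisible(x)
}

#' Aggregates from precomputed clusters
#'
#' Lower-level entry point of [analyze_frame()] for callers that already
#' hold cluster labels from [cluster_frame()] (possibly computed with a
#' different cutoff or on a frame subset).
#'
#' @param clusters Named integer vector from [cluster_frame()].
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param min_size Minimum molecules per reported aggregate.
#' @param rg_cutoff_nm Disc/micelle Rg threshold (nm).
#' @param cutoff_nm Contact cutoff for unwrapping (nm).
#' @return A `frame_analysis` (see [analyze_frame()]).
#' @export
make_aggregates <- function(clusters, state, topology, min_size = 5,
                            rg_cutoff_nm = 2.5, cutoff_nm = 0.9) {
  build_frame_analysis(clusters, state, topology, cutoff_nm = cutoff_nm,
                       min_size = min_size, rg_cutoff_nm = rg_cutoff_nm)
}

#' Free-lipid concentration series and plateau
#'
#' Time series of the free-lipid concentration over analyzed frames and its
#' plateau (mean and SD) over the equilibrated window, by default the final
#' third of the trajectory. When no aggregates form, the free concentration
#' equals the total concentration; when every lipid joins one aggregate it
#' is zero.
#'
#' @param frame_analyses List of `frame_analysis` objects.
#' @param window Fraction range of frames for the plateau, e.g.
#'   `c(2/3, 1)`.
#' @return List with `series` (data frame: time_fs, n_free, free_mM),
#'   `plateau_mM`, `plateau_sd_mM`.
#' @export
free_lipid_series <- function(frame_analyses, window = c(2/3, 1)) {
  if (length(frame_analyses) < 1) stop("free_lipid_series: no frames")
  series <- data.frame(
    time_fs = vapply(frame_analyses, function(f) f$time_fs, numeric(1)),
    n_free = vapply(frame_analyses, function(f) f$n_free_lipids, numeric(1)),
    free_mM = vapply(frame_analyses, function(f) f$free_lipid_mM, numeric(1))
  )
  n <- nrow(series)
  lo <- max(1L, floor(window[1] * n) + 1L)
  hi <- max(lo, min(n, ceiling(window[2] * n)))
  idx <- lo:hi
  if (!length(idx)) stop("free_lipid_series: empty plateau window")
  list(series = series,
       plateau_mM = mean(series$free_mM[idx]),
       plateau_sd_mM = stats::sd(series$free_mM[idx]),
       window_frames = idx)
}

#' CMC estimate from a system-size scan at fixed concentration
#'
#' Across systems of increasing lipid count at the same total concentration,
#' the free-lipid plateau rises from an artificially low value in the
#' smallest systems and levels off; the plateau of the largest system(s) is
#' the CMC estimate. Systems whose lipid count is below
#' `small_system_factor` times the mean aggregate size are flagged
#' artificially low.
#'
#' @param scan Data frame with columns `n_lipids`, `free_mM`, optionally
#'   `free_sd_mM` and `mean_lipids_per_aggregate`.
#' @param n_largest How many of the largest systems to average.
#' @param small_system_factor Finite-size flagging factor.
#' @return List with `cmc_mM`, `cmc_sd_mM`, and the annotated `curve`
#'   (adds `flag_artificially_low`).
#' @export
cmc_from_size_scan <- function(scan, n_largest = 1,
                               small_system_factor = 3) {
  stopifnot(all(c("n_lipids", "free_mM") %in% names(scan)))
  scan <- scan[order(scan$n_lipids), , drop = FALSE]
  if (is.unsorted(scan$free_mM, strictly = FALSE) &&
      any(diff(scan$free_mM) < -.Machine$double.eps^0.5))
    message("cmc_from_size_scan: free-lipid curve is non-monotone ",
            "(noise or finite-size effects)")
  if ("mean_lipids_per_aggregate" %in% names(scan)) {
    ref <- scan$mean_lipids_per_aggregate[which.max(scan$n_lipids)]
    scan$flag_artificially_low <- scan$n_lipids < small_system_factor * ref
  } else {
    scan$flag_artificially_low <- scan$n_lipids < max(scan$n_lipids)
  }
  top <- utils::tail(seq_len(nrow(scan)), n_largest)
  sd_top <- if ("free_sd_mM" %in% names(scan))
    sqrt(mean(scan$free_sd_mM[top]^2)) else stats::sd(scan$free_mM[top])
  list(cmc_mM = mean(scan$free_mM[top]), cmc_sd_mM = sd_top, curve = scan)
}

#' CMC estimate from a concentration scan at fixed system size
#'
#' Below the CMC no stable aggregates form and the free concentration equals
#' the total; above it the free concentration plateaus. The CMC is the mean
#' free-lipid concentration over the plateau region: the concentrations at
#' or above `min_conc_mM` where stable aggregates form (for this model
#' micelles consistently form at 2 mM and above).
#'
#' @param scan Data frame with columns `total_mM`, `free_mM`, and logical
#'   `aggregates_formed`.
#' @param min_conc_mM Lower edge of the usable plateau (mmol/L).
#' @return List with `cmc_mM`, `cmc_sd_mM`, `plateau_concentrations`.
#' @export
cmc_from_concentration_scan <- function(scan, min_conc_mM = 2) {
  stopifnot(all(c("total_mM", "free_mM", "aggregates_formed") %in% names(scan)))
  use <- scan$aggregates_formed & scan$total_mM >= min_conc_mM
  if (!any(use))
    stop("cmc_from_concentration_scan: no plateau detected; aggregates form at: ",
         paste(scan$total_mM[scan$aggregates_formed], collapse = ", "), " mM")
  list(cmc_mM = mean(scan$free_mM[use]),
       cmc_sd_mM = stats::sd(scan$free_mM[use]),
       plateau_concentrations = scan$total_mM[use])
}

#' Replica ergodic measure
#'
#' Mean square deviation of an observable (here the aggregate count) between
#' replicas as a function of time:
#' \eqn{d(t) = \mathrm{mean}_{i<j} [n_i(t) - n_j(t)]^2}. Decay toward a
#' small plateau signals that the replicas have converged to the same
#' macrostate. The replica-variance form \eqn{2\,\mathrm{var}_i n_i(t)}
#' (its unbiased-estimator twin) is also returned.
#'
#' @param counts Numeric matrix, time points x replicas, on a common time
#'   grid; or a list of equal-length per-replica vectors.
#' @param times Optional time stamps (one per row).
#' @return Data frame with `time`, `msd_pairwise`, `msd_variance`.
#' @export
ergodic_measure <- function(counts, times = NULL) {
  if (is.list(counts) && !is.matrix(counts)) {
    len <- vapply(counts, length, integer(1))
    if (length(unique(len)) != 1) {
      warning("ergodic_measure: replica series lengths differ; ",
              "truncating to the shortest common grid")
      counts <- lapply(counts, function(v) v[seq_len(min(len))])
    }
    counts <- do.call(cbind, counts)
  }
  if (ncol(counts) < 2) stop("ergodic_measure: need >= 2 replicas")
  nrep <- ncol(counts)
  pairs <- utils::combn(nrep, 2)
  msd <- apply(counts, 1, function(row) {
    mean((row[pairs[1, ]] - row[pairs[2, ]])^2)
  })
  if (is.null(times)) times <- seq_len(nrow(counts))
  data.frame(time = times, msd_pairwise = msd,
             msd_variance = 2 * apply(counts, 1, stats::var))
}

#' Lipids-per-aggregate distribution, Gaussian fit, and QQ comparison
#'
#' Histogram of lipids per aggregate pooled over the final frames of all
#' replicas, maximum-likelihood Gaussian fit (sample mean and SD; no
#' truncation correction, so a fit to small aggregates can put mass on
#' negative counts), QQ pairs of order statistics against Gaussian
#' quantiles, and the maximum upper-tail deviation (sample minus theoretical
#' over the top decile) -- large positive values indicate the long tail
#' contributed by discs, while micelle-only populations are near-Gaussian.
#'
#' @param lipids_per_aggregate Numeric vector (>= 10 values).
#' @param breaks Passed to [graphics::hist()] (computed, not plotted).
#' @return List with `histogram`, `mean`, `sd`, `qq` (data frame:
#'   `theoretical`, `sample`), `upper_tail_deviation`.
#' @export
size_distribution_qq <- function(lipids_per_aggregate, breaks = "Sturges") {
  x <- lipids_per_aggregate
  if (length(x) < 10)
    stop("size_distribution_qq: need at least 10 aggregates, got ", length(x))
  mu <- mean(x); sdev <- stats::sd(x)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  xs <- sort(x)
  theo <- stats::qnorm(stats::ppoints(length(x)), mean = mu, sd = sdev)
  topdec <- xs >= stats::quantile(xs, 0.9)
  list(histogram = h, mean = mu, sd = sdev,
       qq = data.frame(theoretical = theo, sample = xs),
       upper_tail_deviation = max(xs[topdec] - theo[topdec]))
}

#' Finite-size phase diagram
#'
#' Assigns each (lipid count, P/L) grid point a phase from its aggregate
#' labels over the equilibrated window: `"micelle"` when every aggregate is
#' micellar, `"disc"` when all are discs, `"mixture"` otherwise. The
#' finite-size boundary follows the three-times heuristic: a point is
#' flagged when its lipid count is below `factor` times the preferred
#' aggregate size, taken as the mean lipids per aggregate of the largest
#' system at the same P/L.
#'
#' @param grid Data frame with columns `n_lipids`, `p_over_l`, `n_micelle`,
#'   `n_disc`, `mean_lipids_per_aggregate`, and optionally `converged`.
#' @param factor Finite-size heuristic multiplier (default 3).
#' @return Data frame of `PhasePoint`s: the grid plus `phase`,
#'   `preferred_size`, `finite_size_flag`.
#' @export
build_phase_diagram <- function(grid, factor = 3) {
  need <- c("n_lipids", "p_over_l", "n_micelle", "n_disc",
            "mean_lipids_per_aggregate")
  stopifnot(all(need %in% names(grid)))
  if ("converged" %in% names(grid) && any(!grid$converged))
    warning("build_phase_diagram: ", sum(!grid$converged),
            " unconverged point(s) included")
  grid$phase <- ifelse(grid$n_disc == 0 & grid$n_micelle > 0, "micelle",
                ifelse(grid$n_micelle == 0 & grid$n_disc > 0, "disc",
                ifelse(grid$n_micelle > 0 & grid$n_disc > 0, "mixture",
                       NA_character_)))
  pref <- vapply(seq_len(nrow(grid)), function(k) {
    same <- grid$p_over_l == grid$p_over_l[k]
    grid$mean_lipids_per_aggregate[same][which.max(grid$n_lipids[same])]
  }, numeric(1))
  grid$preferred_size <- pref
  grid$finite_size_flag <- grid$n_lipids < factor * pref
  grid
}

#' Summarize a trajectory window into analysis aggregates
#'
#' Runs [analyze_frame()] on every frame in the window and pools per-frame
#' aggregate counts and compositions; convenience for the CMC and phase
#' pipelines.
#'
#' @param trajectory `cooke_trajectory`.
#' @param topology `cooke_topology`.
#' @param window Fraction range of frames to analyze.
#' @param ... Passed to [analyze_frame()].
#' @return List with `frames` (list of `frame_analysis`), `n_aggregates`
#'   (per frame), `aggregates` (pooled data frame with a `frame` column),
#'   `free` (from [free_lipid_series()] over the window frames).
#' @export
analyze_trajectory <- function(trajectory, topology, window = c(2/3, 1),
                               ...) {
  n <- length(trajectory$frames)
  if (n < 1) stop("analyze_trajectory: empty trajectory")
  lo <- max(1L, floor(window[1] * n) + 1L)
  idx <- lo:n
  fas <- lapply(trajectory$frames[idx], analyze_frame, topology = topology,
                ...)
  pooled <- do.call(rbind, lapply(seq_along(fas), function(k) {
    a <- fas[[k]]$aggregates
    if (nrow(a)) a$frame <- idx[k]
    a
  }))
  list(frames = fas,
       n_aggregates = vapply(fas, function(f) nrow(f$aggregates), numeric(1)),
       aggregates = pooled,
       free = free_lipid_series(fas, window = c(0, 1)))
}
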