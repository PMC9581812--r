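ff <- ff_params()

test_that("clustering: singletons, transitivity, and molecule mapping", {
  # two lipids with nearest hydrophobic beads far apart -> two singletons
  lip <- build_lipid()
  topo <- assemble_system(2, 0)
  pos <- rbind(sweep(lip$reference_coords, 2, c(3, 3, 3), "+"),
               sweep(lip$reference_coords, 2, c(9, 9, 9), "+"))
  st <- new_system_state(pos, 15)
  expect_equal(max(cluster_frame(st, topo)), 2)

  # chain A-B-C: A-B and B-C within cutoff, A-C beyond -> one cluster
  topo3 <- assemble_system(3, 0)
  pos3 <- rbind(sweep(lip$reference_coords, 2, c(3, 3, 3), "+"),
                sweep(lip$reference_coords, 2, c(3.8, 3, 3), "+"),
                sweep(lip$reference_coords, 2, c(4.6, 3, 3), "+"))
  st3 <- new_system_state(pos3, 15)
  lab <- cluster_frame(st3, topo3)
  expect_equal(max(lab), 1)
})

test_that("clustering equals the brute-force union-find oracle on random beads", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 200
    box <- 12
    pos <- matrix(runif(3 * n, 0, box), ncol = 3)
    # all-T single-bead molecules so bead components = molecule clusters
    topo <- free_bead_topology(n, bead_class = "T")
    st <- new_system_state(pos, box)
    mine <- canon_labels(cluster_frame(st, topo, cutoff_nm = 0.9))
    oracle <- canon_labels(brute_components(pos, box, 0.9))
    expect_equal(unname(mine), unname(oracle))
    fast <- canon_labels(cluster_frame(st, topo, cutoff_nm = 0.9,
                                       method = "brute"))
    expect_equal(unname(fast), unname(oracle))
  }
})

test_that("clustering is invariant to rigid translation and periodic shifts", {
  fx <- generate_fixture("mixture", n_lipids = 220, n_peptides = 4, seed = 3)
  base <- canon_labels(cluster_frame(fx$state, fx$topology))
  box <- fx$state$box_edge
  for (shift in list(c(1.3, -2.2, 0.7), c(box / 2, box / 2, box / 2))) {
    st2 <- new_system_state(sweep(fx$state$positions, 2, shift, "+"), box)
    expect_equal(canon_labels(cluster_frame(st2, fx$topology)), base)
  }
})

test_that("aggregate filtering: clusters below 5 molecules are discarded and counted free", {
  lip <- build_lipid()
  topo <- assemble_system(4, 0)
  # 4 lipids in contact: a cluster, but below the reporting threshold
  pos <- do.call(rbind, lapply(0:3, function(k)
    sweep(lip$reference_coords, 2, c(3 + 0.7 * k, 3, 3), "+")))
  st <- new_system_state(pos, 12)
  fa <- analyze_frame(st, topo)
  expect_equal(nrow(fa$aggregates), 0)
  expect_equal(fa$n_free_lipids, 4)
})

test_that("micelle and disc fixtures are labeled by the 2.5 nm Rg cutoff", {
  mic <- generate_fixture("micelle", n_lipids = 30)
  fa <- analyze_frame(mic$state, mic$topology)
  expect_equal(nrow(fa$aggregates), 1)
  expect_equal(fa$aggregates$n_lipids, 30)
  expect_equal(fa$aggregates$label, "micelle")
  expect_lt(fa$aggregates$rg_nm, 2.5)
  expect_equal(fa$n_free_lipids, 0)

  dsc <- generate_fixture("disc", n_lipids = 200)
  fd <- analyze_frame(dsc$state, dsc$topology)
  expect_equal(nrow(fd$aggregates), 1)
  expect_equal(fd$aggregates$label, "disc")
  expect_gte(fd$aggregates$rg_nm, 2.5)
})

test_that("molecule conservation: free + aggregated = total lipids", {
  fx <- generate_fixture("mixture", n_lipids = 240, n_peptides = 6, seed = 5)
  fa <- analyze_frame(fx$state, fx$topology)
  expect_equal(fa$n_free_lipids + sum(fa$aggregates$n_lipids), 240)
})

test_that("planted mixture composition and labels are recovered exactly", {
  fx <- generate_fixture("mixture", n_lipids = 230, n_peptides = 6, seed = 2,
                         n_micelle_lipids = 30)
  fa <- analyze_frame(fx$state, fx$topology)
  expect_equal(nrow(fa$aggregates), 2)
  got <- fa$aggregates[order(fa$aggregates$n_lipids), ]
  expect_equal(got$label, c("micelle", "disc"))
  expect_equal(got$n_lipids, c(30, 200))
  expect_equal(got$n_peptides, c(0, 6))
})

test_that("size metric recovers 2R on a sphere and D on a disc, and is rotation-invariant", {
  R <- 2.5
  sph <- sphere_points(2000, R)
  expect_equal(aggregate_size(sph), 2 * R, tolerance = 0.05)
  # uniform flat disc of diameter D
  set.seed(19)
  D <- 7
  rr <- (D / 2) * sqrt(runif(4000))
  th <- runif(4000, 0, 2 * pi)
  dsc <- cbind(rr * cos(th), rr * sin(th), 0)
  expect_equal(aggregate_size(dsc), D, tolerance = 0.05 * D)
  # rotation invariance to 1e-9
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  expect_equal(aggregate_size(sph %*% t(Rz)), aggregate_size(sph),
               tolerance = 1e-9)
  # radius of gyration of a thin spherical shell is R
  expect_equal(radius_of_gyration(sph), R, tolerance = 1e-3)
  # degenerate collinear input warns
  expect_warning(aggregate_size(cbind(1:10, 0, 0)), "degenerate")
})

test_that("aggregate geometry is correct across the periodic boundary", {
  fx <- generate_fixture("micelle", n_lipids = 40)
  fa0 <- analyze_frame(fx$state, fx$topology)
  # shift so the micelle straddles a box corner
  box <- fx$state$box_edge
  st2 <- new_system_state(sweep(fx$state$positions, 2,
                                rep(box / 2, 3), "+"), box)
  fa2 <- analyze_frame(st2, fx$topology)
  expect_equal(fa2$aggregates$rg_nm, fa0$aggregates$rg_nm, tolerance = 1e-9)
  expect_equal(fa2$aggregates$size_nm, fa0$aggregates$size_nm,
               tolerance = 1e-9)
})

test_that("free-lipid series: closures and plateau on constructed frames", {
  # dispersed fixture far below the CMC: zero aggregates, free = total
  dis <- generate_fixture("dispersed", n_lipids = 20, seed = 7,
                          concentration_mM = 0.01)
  fa <- analyze_frame(dis$state, dis$topology)
  expect_equal(nrow(fa$aggregates), 0)
  expect_equal(fa$free_lipid_mM,
               concentration_from_count(20, dis$state$box_edge))
  # all lipids in one aggregate: zero free
  mic <- generate_fixture("micelle", n_lipids = 30)
  fm <- analyze_frame(mic$state, mic$topology)
  expect_equal(fm$n_free_lipids, 0)
  # synthetic frames with known free counts: plateau = arithmetic mean
  mk <- function(nfree, t) {
    structure(list(aggregates = data.frame(), n_free_lipids = nfree,
                   free_lipid_mM = nfree, total_lipids = 100, time_fs = t),
              class = "frame_analysis")
  }
  fas <- Map(mk, c(9, 8, 7, 5, 5, 6), 1:6 * 1e6)
  fl <- free_lipid_series(fas, window = c(0.5, 1))
  expect_equal(fl$plateau_mM, mean(c(5, 5, 6)))
})

test_that("CMC from a size scan uses the largest system and flags small ones", {
  scan <- data.frame(n_lipids = c(50, 100, 250, 500, 1000),
                     free_mM = c(0.21, 0.35, 0.44, 0.47, 0.48),
                     mean_lipids_per_aggregate = c(47, 90, 110, 115, 120))
  res <- cmc_from_size_scan(scan)
  expect_equal(res$cmc_mM, 0.48)
  expect_true(res$curve$flag_artificially_low[res$curve$n_lipids == 50])
  expect_false(res$curve$flag_artificially_low[res$curve$n_lipids == 1000])
  # identical synthetic plateaus: CMC equals the plateau
  flat <- data.frame(n_lipids = c(100, 500, 1000), free_mM = 0.5)
  expect_equal(cmc_from_size_scan(flat)$cmc_mM, 0.5)
})

test_that("CMC from a concentration scan averages the plateau region", {
  scan <- data.frame(total_mM = c(0.01, 0.1, 1, 2, 10, 100),
                     free_mM = c(0.01, 0.1, 1, 0.52, 0.50, 0.48),
                     aggregates_formed = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                           TRUE))
  res <- cmc_from_concentration_scan(scan)
  expect_equal(res$cmc_mM, mean(c(0.52, 0.50, 0.48)))
  expect_equal(res$plateau_concentrations, c(2, 10, 100))
  none <- data.frame(total_mM = c(0.01, 0.1), free_mM = c(0.01, 0.1),
                     aggregates_formed = FALSE)
  expect_error(cmc_from_concentration_scan(none), "plateau")
})

test_that("ergodic measure: identical, offset, and Poisson replicas", {
  tgrid <- 1:50
  a <- rep(3, 50)
  em <- ergodic_measure(cbind(a, a), tgrid)
  expect_true(all(em$msd_pairwise == 0))
  em2 <- ergodic_measure(cbind(a, a + 1))
  expect_true(all(em2$msd_pairwise == 1))
  # independent Poisson counts at equal rates: E[(n1-n2)^2] = 2*lambda
  set.seed(77)
  lam <- 4
  counts <- matrix(rpois(500 * 6, lam), ncol = 6)
  em3 <- ergodic_measure(counts)
  expect_equal(mean(em3$msd_pairwise), 2 * lam, tolerance = 0.1)
  expect_error(ergodic_measure(cbind(a)), ">= 2")
})

test_that("QQ analysis: Gaussian sample near identity, planted outliers inflate the tail", {
  set.seed(31)
  x <- rnorm(200, mean = 40, sd = 6)
  qq <- size_distribution_qq(x)
  expect_equal(qq$mean, mean(x))
  expect_lt(max(abs(qq$qq$sample - qq$qq$theoretical)) / sd(x), 0.6)
  # 5% large-disc outliers produce a positive upper-tail deviation
  xo <- c(rnorm(190, 40, 6), rnorm(10, 160, 10))
  qo <- size_distribution_qq(xo)
  expect_gt(qo$upper_tail_deviation, qq$upper_tail_deviation + 10)
  expect_error(size_distribution_qq(rnorm(5)), "at least 10")
})

test_that("phase diagram recovers planted phases and the 3x finite-size line", {
  grid <- data.frame(
    n_lipids = c(50, 200, 1000, 50, 200, 1000),
    p_over_l = rep(c(0.5, 0.05), each = 3),
    n_micelle = c(1, 4, 20, 1, 1, 3),
    n_disc = c(0, 0, 0, 0, 1, 2),
    mean_lipids_per_aggregate = c(45, 48, 50, 45, 100, 120))
  pd <- build_phase_diagram(grid)
  expect_equal(pd$phase, c("micelle", "micelle", "micelle",
                           "micelle", "mixture", "mixture"))
  # preferred size comes from the largest system at each P/L
  expect_equal(pd$preferred_size, c(50, 50, 50, 120, 120, 120))
  expect_equal(pd$finite_size_flag, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # all-disc point
  grid2 <- data.frame(n_lipids = 400, p_over_l = 0.02, n_micelle = 0,
                      n_disc = 2, mean_lipids_per_aggregate = 190)
  expect_equal(build_phase_diagram(grid2)$phase, "disc")
})

test_that("unwrap_cluster reproduces continuous geometry for a split aggregate", {
  mic <- generate_fixture("micelle", n_lipids = 25)
  box <- mic$state$box_edge
  pos <- sweep(mic$state$positions, 2, rep(box / 2, 3), "+")  # straddle corner
  st <- new_system_state(pos, box)
  lab <- cluster_frame(st, mic$topology)
  stopifnot(max(lab) == 1)
  xyz <- unwrap_cluster(as.integer(names(lab)), st, mic$topology)
  # pairwise extent must be far below the box edge after unwrapping
  expect_lt(max(dist(xyz)), box / 2)
})
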