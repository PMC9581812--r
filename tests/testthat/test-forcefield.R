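ff <- ff_params()
s <- ff$sigma
eps <- ff$epsilon

test_that("default parameters reproduce the model's published values", {
  expect_equal(ff$sigma, 0.6)
  expect_equal(ff$epsilon, 1)
  expect_equal(ff$b_HH, 0.95 * s)
  expect_equal(ff$b_HT, 0.95 * s)
  expect_equal(ff$b_TT, s)
  expect_equal(ff$w_c, s)
  expect_equal(ff$k_bond, 30 * eps / s^2)
  expect_equal(ff$r_inf, 1.5 * s)
  expect_equal(ff$k_bend, 10 * eps / s^2)
  expect_equal(ff$r_bend0, 4 * s)
  expect_equal(ff$k_elastic, 30 * eps / s^2)
  expect_equal(ff$temperature, 310)
  expect_equal(ff$kB * 310 / eps, 0.616, tolerance = 1e-3)
})

test_that("WCA repulsion: exact values and cutoff behavior", {
  for (b in c(ff$b_HH, ff$b_TT)) {
    rc <- 2^(1/6) * b
    expect_equal(v_rep(rc, b, ff), 0, tolerance = 1e-12)
    expect_equal(v_rep(b, b, ff), eps)
    expect_equal(v_rep(3 * b, b, ff), 0)
    # monotone decreasing repulsion inside the cutoff
    r <- seq(0.6 * b, rc, length.out = 50)
    expect_true(all(diff(v_rep(r, b, ff)) < 0))
  }
  expect_error(v_rep(-1, s, ff), "positive")
  expect_error(v_rep(0.5, -1, ff), "positive")
})

test_that("cosine-squared attraction: branches, junctions, zero width", {
  b <- ff$b_TT
  rc <- 2^(1/6) * b
  wc <- ff$w_c
  expect_equal(v_att(0.9 * rc, wc, b, ff), -eps)
  expect_equal(v_att(rc + wc, wc, b, ff), 0, tolerance = 1e-12)
  expect_equal(v_att(rc + wc / 2, wc, b, ff), -eps / 2, tolerance = 1e-12)
  expect_equal(v_att(rc + 2 * wc, wc, b, ff), 0)
  expect_equal(v_att(c(0.5, 1, 2), 0, b, ff), c(0, 0, 0))
  expect_error(v_att(-0.1, wc, b, ff), "positive")
})

test_that("FENE bond: closed forms and overextension error", {
  expect_equal(v_fene(0, ff), 0)
  expect_equal(v_fene(ff$r_inf / 2, ff),
               -0.5 * ff$k_bond * ff$r_inf^2 * log(3 / 4))
  # divergence approaching maximum extension
  expect_gt(v_fene(0.999 * ff$r_inf, ff), v_fene(0.99 * ff$r_inf, ff))
  expect_gt(v_fene(0.9999 * ff$r_inf, ff), 100 * eps)
  expect_error(v_fene(ff$r_inf, ff), "overextended")
  expect_error(v_fene(2 * ff$r_inf, ff), "overextended")
})

test_that("harmonic straightening and elastic bonds: minima and symmetry", {
  expect_equal(v_bend(4 * s, ff), 0)
  d <- 0.123
  expect_equal(v_bend(4 * s + d, ff), v_bend(4 * s - d, ff))
  expect_equal(v_bend(5 * s, ff), 5 * eps)  # (1/2)(10 eps/s^2)(s)^2
  expect_equal(v_elastic(0.7, 0.7, ff), 0)
  expect_equal(v_elastic(0.7 + s, 0.7, ff), 15 * eps)
  # numerical gradient vanishes at the rest length
  h <- 1e-7
  expect_lt(abs(v_elastic(0.7 + h, 0.7, ff) - v_elastic(0.7 - h, 0.7, ff)) /
              (2 * h), 1e-5)
})

test_that("pair coefficient rules: b by class, w_c only for lipid hydrophobics", {
  expect_equal(pair_coefficients("T", "T", "lipid", "lipid", ff)$w_c, s)
  expect_equal(pair_coefficients("T", "T", "lipid", "peptide", ff)$w_c, s)
  expect_equal(pair_coefficients("T", "T", "peptide", "peptide", ff)$w_c, 0)
  expect_equal(pair_coefficients("H", "T", "lipid", "lipid", ff)$w_c, 0)
  expect_equal(pair_coefficients("H", "H", "lipid", "lipid", ff)$w_c, 0)
  expect_equal(pair_coefficients("T", "T", "lipid", "lipid", ff)$b, s)
  expect_equal(pair_coefficients("H", "T", "peptide", "lipid", ff)$b, 0.95 * s)
  expect_equal(pair_coefficients("H", "H", "peptide", "peptide", ff)$b, 0.95 * s)
})

test_that("pair energy within attraction range reflects the w_c rule", {
  rvec <- c(0.62, 0, 0)  # inside r_c for b = 0.6
  pp <- pair_energy_force(rvec, "T", "T", "peptide", "peptide", ff)
  ll <- pair_energy_force(rvec, "T", "T", "lipid", "lipid", ff)
  lp <- pair_energy_force(rvec, "T", "T", "lipid", "peptide", ff)
  # attraction contributes -eps to lipid pairs, nothing to peptide-peptide
  expect_equal(ll$energy - pp$energy, -eps, tolerance = 1e-12)
  expect_equal(lp$energy, ll$energy, tolerance = 1e-12)
})

test_that("potentials are continuous at r_c and r_c + w_c on a fine grid", {
  for (b in c(ff$b_HH, ff$b_TT)) {
    rc <- 2^(1/6) * b
    for (r0 in c(rc, rc + ff$w_c)) {
      below <- r0 - 10^seq(-9, -5)
      above <- r0 + 10^seq(-9, -5)
      vtot <- function(r) v_rep(r, b, ff) + v_att(r, ff$w_c, b, ff)
      expect_lt(abs(vtot(max(below)) - vtot(min(above))), 1e-4)
      expect_lt(abs(vtot(r0 - 1e-9) - vtot(r0 + 1e-9)), 1e-8)
    }
  }
})

test_that("analytic pair force matches central finite differences at 100 random geometries", {
  set.seed(101)
  classes <- c("H", "T")
  kinds <- c("lipid", "peptide")
  h <- 1e-7
  for (rep in 1:100) {
    ci <- sample(classes, 1); cj <- sample(classes, 1)
    ki <- sample(kinds, 1); kj <- sample(kinds, 1)
    co <- pair_coefficients(ci, cj, ki, kj, ff)
    r <- runif(1, 0.55 * co$b, co$r_c + co$w_c + 0.2)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rvec <- r * u
    pe <- function(rv) pair_energy_force(rv, ci, cj, ki, kj, ff)$energy
    fan <- pair_energy_force(rvec, ci, cj, ki, kj, ff)$force_i
    for (d in 1:3) {
      ep <- rvec; ep[d] <- ep[d] + h
      em <- rvec; em[d] <- em[d] - h
      fnum <- -(pe(ep) - pe(em)) / (2 * h)
      expect_lt(abs(fnum - fan[d]) / max(1, abs(fan[d])), 1e-6)
    }
  }
})

test_that("total energy is additive over isolated molecules and forces sum to zero", {
  topo1 <- assemble_system(1, 0)
  st1 <- new_system_state(sweep(topo1$reference_coords, 2, c(5, 5, 5), "+"), 20)
  e1 <- total_energy_forces(st1, topo1, ff)

  topo2 <- assemble_system(2, 0)
  pos <- rbind(sweep(topo1$reference_coords, 2, c(5, 5, 5), "+"),
               sweep(topo1$reference_coords, 2, c(14, 14, 14), "+"))
  st2 <- new_system_state(pos, 20)
  e2 <- total_energy_forces(st2, topo2, ff)
  expect_equal(e2$energy, 2 * e1$energy, tolerance = 1e-12)
  expect_lt(max(abs(colSums(e2$forces))), 1e-8)
})

test_that("cell-list energies and forces equal the all-pairs oracle", {
  set.seed(7)
  for (case in 1:3) {
    nl <- c(10, 25, 20)[case]
    np <- c(0, 0, 1)[case]
    topo <- assemble_system(nl, np)
    spec <- system_spec(nl, np, lipid_concentration_mM = c(50, 150, 300)[case])
    packed <- random_pack(spec, topology = topo, seed = case)
    ec <- total_energy_forces(packed$state, topo, ff, method = "cell")
    eb <- total_energy_forces(packed$state, topo, ff, method = "brute")
    expect_equal(ec$energy, eb$energy, tolerance = 1e-12)
    expect_lt(max(abs(ec$forces - eb$forces)), 1e-9)
    expect_lt(max(abs(colSums(ec$forces))), 1e-8)
  }
})

test_that("total energy is invariant under rigid translation and rotation", {
  set.seed(11)
  topo <- assemble_system(8, 1)
  spec <- system_spec(8, 1, lipid_concentration_mM = 100)
  packed <- random_pack(spec, topology = topo, seed = 4)
  # make each molecule whole across the wrap, then center in a big box so
  # no pair crosses the boundary
  pos <- packed$state$positions
  box0 <- packed$state$box_edge
  for (m in unique(topo$beads$molecule_id)) {
    rows <- which(topo$beads$molecule_id == m)
    d <- sweep(pos[rows, , drop = FALSE], 2, pos[rows[1], ])
    d <- d - box0 * round(d / box0)
    pos[rows, ] <- sweep(d, 2, pos[rows[1], ], "+")
  }
  pos <- sweep(pos, 2, colMeans(pos))
  big <- 60
  st0 <- new_system_state(sweep(pos, 2, rep(big / 2, 3), "+"), big)
  e0 <- total_energy_forces(st0, topo, ff)$energy
  st1 <- new_system_state(sweep(pos, 2, c(big / 2 + 1.7, big / 2 - 2.1,
                                          big / 2 + 0.4), "+"), big)
  expect_equal(total_energy_forces(st1, topo, ff)$energy, e0,
               tolerance = 1e-10)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  st2 <- new_system_state(sweep(pos %*% t(R), 2, rep(big / 2, 3), "+"), big)
  expect_equal(total_energy_forces(st2, topo, ff)$energy, e0,
               tolerance = 1e-10)
})
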