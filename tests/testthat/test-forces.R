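test_that("site-pair adhesion is linear, attractive and reciprocal", {
  # at the cutoff the bond force vanishes
  expect_equal(site_pair_adhesion_force(c(0, 0, 0), c(1, 0, 0),
                                        sigma = 0.004, r_cut = 1),
               c(0, 0, 0))
  # halfway inside the cutoff: magnitude sigma * (r_cut - s) / r_cut^2
  f <- site_pair_adhesion_force(c(0, 0, 0), c(0.5, 0, 0), 0.004, 1)
  expect_equal(f, c(0.002, 0, 0))
  # action-reaction between the two engaged sites
  g <- site_pair_adhesion_force(c(0.5, 0, 0), c(0, 0, 0), 0.004, 1)
  expect_equal(g, -f)
  # coincident sites: direction undefined, zero returned
  expect_equal(site_pair_adhesion_force(c(1, 1, 1), c(1, 1, 1), 0.004, 1),
               c(0, 0, 0))
})

test_that("overlap adhesion engages only the minimum trapped count", {
  nij <- c(0, 1, 0)
  expect_equal(overlap_adhesion_force(0, 5, 0.004, 1, nij), c(0, 0, 0))
  expect_equal(overlap_adhesion_force(3, 5, 0.004, 1, nij),
               0.012 * nij)
  # swapping the roles negates the direction with the same magnitude
  expect_equal(overlap_adhesion_force(5, 3, 0.004, 1, -nij),
               -overlap_adhesion_force(3, 5, 0.004, 1, nij))
})

test_that("negotiation engages free sites one-to-one within the cutoff", {
  # one site on each cell, facing each other across a gap of 0.5
  a <- cell_state(c(0, 0, 0), 1, cc_sites = rbind(c(1, 0, 0)))
  b <- cell_state(c(2.5, 0, 0), 1, cc_sites = rbind(c(-1, 0, 0)))
  pr <- negotiate_pairings(a, b, r_cut = 1, order = 1L)
  expect_equal(nrow(pr$matches), 1L)
  expect_equal(pr$m_i + pr$m_j, 0L)
  # beyond the cutoff nothing engages
  b_far <- cell_state(c(4, 0, 0), 1, cc_sites = rbind(c(-1, 0, 0)))
  pr2 <- negotiate_pairings(a, b_far, r_cut = 1, order = 1L)
  expect_equal(nrow(pr2$matches), 0L)
})

test_that("negotiation equals the brute-force greedy for every permutation", {
  set.seed(31)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (rep in 1:20) {
    a <- cell_state(c(0, 0, 0), 1, cc_sites = sample_sphere_sites(3))
    b <- cell_state(c(runif(1, 2.0, 2.6), 0, 0), 1,
                    cc_sites = sample_sphere_sites(3))
    Pi <- site_positions(a, "cc"); Pj <- site_positions(b, "cc")
    for (ord in perms3) {
      got <- negotiate_pairings(a, b, r_cut = 1, order = ord)$matches
      want <- oracle_greedy_match(Pi, Pj, 1:3, 1:3, ord, r_cut = 1)
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("negotiation matches the oracle on random instances up to 6 sites", {
  set.seed(32)
  for (rep in 1:200) {
    ni <- sample(1:6, 1); nj <- sample(1:6, 1)
    d <- runif(1, 1.2, 3.2)
    a <- cell_state(c(0, 0, 0), 1, cc_sites = sample_sphere_sites(ni))
    b <- cell_state(c(d, 0, 0), 1, cc_sites = sample_sphere_sites(nj))
    ord <- sample(ni)
    got <- negotiate_pairings(a, b, r_cut = 1, order = ord)
    Pi <- site_positions(a, "cc"); Pj <- site_positions(b, "cc")
    free_i <- which(!in_overlap_region(Pi, b$center, 1))
    free_j <- which(!in_overlap_region(Pj, a$center, 1))
    want <- oracle_greedy_match(Pi, Pj, free_i, free_j, ord, 1)
    expect_equal(unname(got$matches), unname(want))
    # one-to-one exclusivity
    expect_false(any(duplicated(got$matches[, 1])))
    expect_false(any(duplicated(got$matches[, 2])))
  }
})

test_that("total adhesion decomposes over neighbors and obeys action-reaction", {
  a <- cell_state(c(0, 0, 0), 1, cc_sites = rbind(c(1, 0, 0)))
  expect_equal(total_adhesion(a, list(), list(), 0.004, 1), c(0, 0, 0))
  set.seed(33)
  for (rep in 1:10) {
    d <- runif(1, 1.1, 2.8)
    ci <- cell_state(c(0, 0, 0), 1, cc_sites = sample_sphere_sites(8))
    cj <- cell_state(c(d, 0, 0), 1, cc_sites = sample_sphere_sites(8))
    pr_ij <- negotiate_pairings(ci, cj, 1, order = 1:8)
    pr_ji <- list(matches = pr_ij$matches[, 2:1, drop = FALSE],
                  m_i = pr_ij$m_j, m_j = pr_ij$m_i)
    fi <- total_adhesion(ci, list(cj), list(pr_ij), 0.004, 1)
    fj <- total_adhesion(cj, list(ci), list(pr_ji), 0.004, 1)
    expect_lt(sqrt(sum((fi + fj)^2)), 1e-12)
  }
})

test_that("traction sums K * f_lr over exposed outward normals", {
  u <- unit(c(1, 2, -1))
  solo <- cell_state(c(0, 0, 0), 1, cm_sites = rbind(u))
  expect_equal(traction_force(solo, list(), K = 1, f_lr = 0.01), 0.01 * u)
  # two antipodal exposed sites cancel exactly
  duo <- cell_state(c(0, 0, 0), 1, cm_sites = rbind(u, -u))
  expect_equal(traction_force(duo, list(), 1, 0.01), c(0, 0, 0))
  # a site trapped inside a neighbor is inactive
  facing <- cell_state(c(0, 0, 0), 1, cm_sites = rbind(c(1, 0, 0)))
  nb <- cell_state(c(1.5, 0, 0), 1)
  expect_equal(traction_force(facing, list(nb), 1, 0.01), c(0, 0, 0))
})

test_that("repulsion is zero at contact, linear inside, capped at the core", {
  expect_equal(repulsion_force(c(0, 0, 0), c(2, 0, 0), eps = 0.025, R = 1,
                               alpha = 0.5), c(0, 0, 0))
  f <- repulsion_force(c(0, 0, 0), c(1.5, 0, 0), 0.025, 1, 0.5)
  expect_equal(f, c(-0.025 * 0.5 / 4, 0, 0))  # magnitude eps(2R-d)/(2R)^2
  w <- repulsion_force(c(0, 0, 0), c(0.9, 0, 0), 0.025, 1, 0.5,
                       wall_force_cap = 1000)
  expect_equal(sqrt(sum(w^2)), 1000)
  expect_true(w[1] < 0)  # pushes away from the neighbor
  expect_error(repulsion_force(c(0, 0, 0), c(0, 0, 0), 0.025, 1, 0.5),
               "coincident")
})

test_that("the overdamped velocity is the force over the Stokes drag", {
  bd <- list(adhesion = c(0, 0, 0), traction = c(0, 0, 0),
             repulsion = c(0, 0, 0))
  expect_equal(net_velocity(bd, 0.0016, 1), c(0, 0, 0))
  bd$traction <- c(6 * pi * 0.0016, 0, 0)
  expect_equal(net_velocity(bd, 0.0016, 1), c(1, 0, 0))
  expect_equal(net_velocity(bd, 0.0032, 1), c(0.5, 0, 0))
})

test_that("paired cells exchange exactly opposite adhesion+repulsion forces", {
  p <- cell_params()
  set.seed(34)
  for (rep in 1:50) {
    d <- runif(1, 1.05, 3.4)
    st <- make_pair_system(d, sample_sphere_sites(20), sample_sphere_sites(20),
                           sample_sphere_sites(20), sample_sphere_sites(20))
    sr <- list(perms = list(sample(20), sample(20)),
               assign = list(numeric(20), numeric(20)))
    f <- compute_system_forces(st$centers, 1, st$cc, st$cm, p, p$sigma0, sr)
    resid <- colSums(f$adhesion) + colSums(f$repulsion)
    expect_lt(sqrt(sum(resid^2)), 1e-12)
  }
})

test_that("cells beyond the interaction reach exert no force at all", {
  p <- cell_params(f_lr = 0)
  set.seed(35)
  st <- make_pair_system(2 * p$R + p$r_cut,  # exactly at reach: no force
                         sample_sphere_sites(30), sample_sphere_sites(30))
  f <- compute_system_forces(st$centers, 1, st$cc, st$cm, p, p$sigma0, NULL)
  expect_equal(f$adhesion, matrix(0, 2, 3))
  expect_equal(f$repulsion, matrix(0, 2, 3))
})
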