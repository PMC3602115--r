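test_that("the adhesion depletion schedule decays from sigma0 to zero", {
  expect_equal(sigma_schedule(0, 0.004, 8, 2), 0.004)
  expect_equal(sigma_schedule(0, 0.004, 8, "none"), 0.004)
  for (p in c(0.5, 1, 2, 4)) {
    expect_equal(sigma_schedule(8, 0.004, 8, p), 0)
    s <- vapply(seq(0, 8, by = 0.25), sigma_schedule, numeric(1),
                sigma0 = 0.004, t_total = 8, p = p)
    expect_true(all(diff(s) <= 1e-15))
    expect_true(all(s >= 0))
  }
  expect_error(sigma_schedule(1, 0.004, 8, -1), "positive")
})

test_that("an isolated cell with static sites advances on a straight line", {
  p <- cell_params(n_cc = 10, n_cm = 10, t_total = 0.5)
  set.seed(41)
  cm <- sample_sphere_sites(10)
  st <- cell_system(matrix(0, 1, 3), 1,
                    cc = list(sample_sphere_sites(10)), cm = list(cm))
  traj <- run_simulation(st, p, seed = 42)
  v <- p$K * p$f_lr * colSums(cm) / (6 * pi * p$eta * p$R)
  last <- traj[traj$t == max(traj$t), ]
  expect_equal(unlist(last[c("x", "y", "z")], use.names = FALSE),
               v * 0.5, tolerance = 1e-12)
})

test_that("a zero-force system is a fixed point of the integrator", {
  p <- cell_params(f_lr = 0, n_cc = 6, n_cm = 6, t_total = 0.2)
  set.seed(43)
  st <- make_pair_system(3.5, sample_sphere_sites(6), sample_sphere_sites(6))
  traj <- run_simulation(st, p, seed = 44)
  expect_equal(max(abs(traj$x - rep(c(0, 3.5), length.out = nrow(traj)))), 0)
  expect_equal(max(abs(traj$y)), 0)
  expect_equal(max(abs(traj$z)), 0)
})

test_that("the integrator shows fourth-order convergence on a smooth segment", {
  # one facing C-C site per cell, no traction: a smooth two-cell pull
  base <- cell_params(n_cc = 1, n_cm = 0, f_lr = 0, negotiation = "fixed")
  state0 <- function() cell_system(rbind(c(0, 0, 0), c(2.5, 0, 0)), 1,
                                   cc = list(rbind(c(1, 0, 0)),
                                             rbind(c(-1, 0, 0))),
                                   cm = list(sample_sphere_sites(0),
                                             sample_sphere_sites(0)))
  end_x <- function(dt, t_end = 0.2) {
    p <- base; p$dt <- dt; p$t_total <- t_end
    traj <- run_simulation(state0(), p, seed = NULL)
    last <- traj[traj$t == max(traj$t) & traj$cell == 1, ]
    last$x
  }
  ref <- end_x(1e-4)
  e1 <- abs(end_x(0.02) - ref)
  e2 <- abs(end_x(0.01) - ref)
  order <- log2(e1 / e2)
  expect_gt(order, 3.5)
})

test_that("site reallocation follows the case semantics exactly", {
  set.seed(45)
  st <- make_pair_system(2, sample_sphere_sites(5), sample_sphere_sites(5),
                         sample_sphere_sites(5), sample_sphere_sites(5))
  p1 <- cell_params(n_cc = 5, n_cm = 5)          # case I
  expect_identical(update_sites(st, p1)[c("cc", "cm")], st[c("cc", "cm")])
  p2 <- apply_case(p1, "II")
  st2 <- update_sites(st, p2)
  expect_identical(st2$cc, st$cc)
  expect_false(identical(st2$cm, st$cm))
  p4 <- apply_case(p1, "IV")
  st4 <- update_sites(st, p4)
  expect_false(identical(st4$cc, st$cc))
  expect_false(identical(st4$cm, st$cm))
})

test_that("case II keeps C-C sites while C-M sites change across a run", {
  p <- apply_case(fast_params(t_total = 0.1), "II")
  set.seed(46)
  st <- init_pair(p)
  cc0 <- st$cc
  traj <- run_simulation(st, p, seed = 47)
  fin <- attr(traj, "final_state")
  expect_identical(fin$cc, cc0)
  expect_false(identical(fin$cm, st$cm))
})

test_that("trajectories are reproducible and respond to the seed", {
  p <- apply_case(fast_params(t_total = 0.1), "IV")
  set.seed(48)
  st <- init_pair(p)
  t1 <- run_simulation(st, p, seed = 7)
  t2 <- run_simulation(st, p, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_simulation(st, p, seed = 8)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("a run samples the initial frame plus one frame per step", {
  p <- fast_params(t_total = 0.1)  # 10 steps
  set.seed(49)
  st <- init_pair(p)
  traj <- run_simulation(st, p, seed = 50)
  expect_identical(length(unique(traj$t)), 11L)
  expect_equal(min(traj$t), 0)
  expect_equal(max(traj$t), 0.1)
})

test_that("a zero-traction pair conserves its center of mass exactly", {
  p <- cell_params(f_lr = 0, t_total = 1)  # 100 steps at full site count
  set.seed(51)
  st <- init_pair(p)
  com0 <- colMeans(st$centers)
  traj <- run_simulation(st, p, seed = 52)
  fin <- attr(traj, "final_state")
  expect_lt(sqrt(sum((colMeans(fin$centers) - com0)^2)), 1e-10)
})

test_that("a touching pair without traction relaxes to a bound equilibrium", {
  p <- cell_params(f_lr = 0, t_total = 2)
  set.seed(53)
  st <- init_pair(p)
  traj <- run_simulation(st, p, seed = NULL)
  eq <- relax_to_equilibrium(attr(traj, "final_state"), p, tol = 1e-9)
  expect_true(eq$converged)
  expect_lt(eq$speed, 1e-8)
  d_star <- sqrt(sum((eq$state$centers[1, ] - eq$state$centers[2, ])^2))
  expect_lte(d_star, 2 * p$R)
  expect_gt(d_star, 2 * p$R * (1 - p$alpha))
})
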