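test_that("initialization lays out the primordium column with the leading Wnt domain", {
  st <- init_abm(abm_params())
  expect_equal(nrow(st$agents), 150)
  expect_equal(sum(st$agents$breed == "WNTER"), 90)
  expect_equal(sum(st$agents$breed == "FGFER"), 60)
  # WNTERs occupy the leading (largest-x) portion
  expect_gt(min(st$agents$x[st$agents$breed == "WNTER"]),
            max(st$agents$x[st$agents$breed == "FGFER"]))

  degenerate <- init_abm(abm_params(column_width = 2, column_length = 3,
                                    wnt_fraction = 1.0))
  expect_equal(nrow(degenerate$agents), 6)
  expect_true(all(degenerate$agents$breed == "WNTER"))

  expect_error(abm_params(column_width = 0))
})

test_that("agents advance by their breed speed and depositers stay put", {
  p <- abm_params(column_width = 1, column_length = 1, wnt_fraction = 1,
                  repulsion_constant = 0)
  set.seed(1)
  st <- init_abm(p)
  x0 <- st$agents$x
  st <- step_abm(st, p)
  expect_equal(st$agents$x, x0 + 0.018)
  expect_equal(st$step_index, 1L)

  st$agents$breed <- "DEPOSITER"
  x1 <- st$agents$x
  st <- step_abm(st, p)
  expect_equal(st$agents$x, x1)
})

test_that("links beyond the break threshold are removed by the next step", {
  p <- abm_params(column_width = 1, column_length = 2, wnt_fraction = 1,
                  speed_wnt = 0, repulsion_constant = 0, turnover_rate = 0)
  set.seed(1)
  st <- init_abm(p)
  expect_equal(nrow(st$links), 1)
  # teleport one agent far away, then step: link must rupture, none remade
  st$agents$x[2] <- 100
  st <- step_abm(st, p)
  expect_equal(nrow(st$links), 0)
})

test_that("spring relaxation follows the stated force law", {
  p <- abm_params(column_width = 1, column_length = 2, wnt_fraction = 1,
                  spring_constant = 0.18, spring_length = 1,
                  repulsion_constant = 0, turnover_rate = 0)
  set.seed(1)
  st <- init_abm(p)

  # at rest length: no displacement
  st0 <- apply_spring_forces(st, p)
  expect_equal(st0$agents$x, st$agents$x, tolerance = 1e-12)

  # at rest length + 1: each endpoint attracted by s * 1 = 0.18
  st$agents$x <- c(0, 2)
  st1 <- apply_spring_forces(st, p)
  expect_equal(st1$agents$x, c(0.18, 2 - 0.18), tolerance = 1e-12)

  # symmetric ring at rest spacing, zero speed: positions fixed
  pr <- abm_params(column_width = 1, column_length = 4, wnt_fraction = 1,
                   speed_wnt = 0, link_radius = 1.1, spring_length = 1,
                   repulsion_constant = 0, turnover_rate = 0)
  set.seed(1)
  ring <- init_abm(pr)
  ring2 <- step_abm(ring, pr)
  expect_equal(ring2$agents$x, ring$agents$x, tolerance = 1e-9)
})

test_that("a linked pair with repulsion settles at the force-balance distance", {
  s <- 0.18; L <- 1; r <- 0.05
  # independent 1D root: s*(l - L) = r / l^2
  lstar <- uniroot(function(l) s * (l - L) - r / l^2, c(1.0001, 5))$root
  p <- abm_params(column_width = 1, column_length = 2, wnt_fraction = 1,
                  speed_wnt = 0, spring_constant = s, spring_length = L,
                  repulsion_constant = r, turnover_rate = 0,
                  link_radius = 10, break_threshold = 20)
  set.seed(1)
  st <- init_abm(p)
  st$agents$x <- c(0, 2)
  for (i in 1:400) st <- apply_spring_forces(st, p)
  expect_equal(abs(diff(st$agents$x)), lstar, tolerance = 1e-3)
})

test_that("proliferation obeys breed rates and zero-rate invariance", {
  p0 <- abm_params(column_width = 2, column_length = 5, wnt_fraction = 0.6)
  set.seed(2)
  st <- init_abm(p0)
  expect_equal(nrow(proliferate(st, p0)$agents), nrow(st$agents))

  p1 <- abm_params(column_width = 2, column_length = 5, wnt_fraction = 0,
                   proliferation_rate = c(FGFER = 1.0))
  set.seed(2)
  st1 <- init_abm(p1)
  expect_true(all(st1$agents$breed == "FGFER"))
  st2 <- proliferate(st1, p1)
  expect_equal(nrow(st2$agents), 2 * nrow(st1$agents))
  expect_true(all(st2$agents$breed == "FGFER"))

  # depositers never divide, whatever the configured rates
  st1$agents$breed <- "DEPOSITER"
  expect_equal(nrow(proliferate(st1, p1)$agents), nrow(st1$agents))
})

test_that("deposition respects the permitted-length rule with a strict boundary", {
  p <- abm_params(shrinkage = TRUE, wnt_shrink_rate = 0)
  set.seed(1)
  st <- init_abm(p)
  st$wnt_domain_length <- 30
  expect_equal(permitted_length(st, p), 48)

  # agent exactly at the boundary is not re-specified; strictly beyond is
  p2 <- abm_params(shrinkage = TRUE, wnt_shrink_rate = 0, length_factor = 1.6)
  st$wnt_domain_length <- 10   # permitted = 16, leading edge = 29
  st2 <- shrink_and_deposit(st, p2)
  ag <- st2$agents
  # every FGFER strictly beyond (x < 29 - 16 = 13) was re-specified; the
  # strict rule spares anything at or inside the boundary
  expect_false(any(ag$breed == "FGFER" & ag$x < 13 - 1e-9))
  expect_true(all(ag$breed[ag$x <= 11 + 1e-9] == "DEPOSITER"))
  boundary <- abs(ag$x - 13) < 1e-9
  expect_false(any(ag$breed[boundary] == "DEPOSITER"))

  # zero shrink rate, everything inside: no breed changes
  set.seed(1)
  st3 <- init_abm(p)
  st4 <- shrink_and_deposit(st3, p)
  expect_equal(st4$agents$breed, st3$agents$breed)
})

test_that("density classification matches the brute-force pairwise oracle", {
  p <- abm_params(density_radius = 1.3, density_threshold = 4)
  set.seed(33)
  st <- init_abm(abm_params(column_width = 5, column_length = 10))
  st$agents <- st$agents[sample(nrow(st$agents), 50), ]
  st$agents$x <- st$agents$x + runif(50, -2, 2)
  st$agents$y <- st$agents$y + runif(50, -2, 2)
  st <- density_classify(st, p)
  expected <- bf_neighbor_counts(cbind(st$agents$x, st$agents$y), 1.3)
  expect_identical(st$agents$neighbor_count, expected)
  expect_identical(st$agents$flagged_dense, expected > 4)

  # strict inequality at the threshold; isolated agent unflagged
  one <- st; one$agents <- one$agents[1, ]
  one <- density_classify(one, p)
  expect_identical(one$agents$neighbor_count, 0L)
  expect_false(one$agents$flagged_dense)
})

test_that("agent and breed counts change only through the designated rules", {
  p <- abm_preset("abm_fast_leader")
  set.seed(5)
  st <- init_abm(p)
  for (i in 1:50) st <- step_abm(st, p)
  expect_equal(nrow(st$agents), 150)   # no proliferation configured
  expect_equal(sum(st$agents$breed == "WNTER"), 90)
  expect_equal(sum(st$agents$breed == "FGFER"), 60)

  # after any step, no surviving link exceeds its break threshold by more
  # than the within-step relaxation can stretch it
  ag <- st$agents; lk <- st$links
  ia <- match(lk$a, ag$id); ib <- match(lk$b, ag$id)
  len <- sqrt((ag$x[ia] - ag$x[ib])^2 + (ag$y[ia] - ag$y[ib])^2)
  expect_lt(max(len), max(lk$break_threshold) + 2 * p$displacement_cap)
})

test_that("runs are reproducible at a fixed seed", {
  p <- abm_preset("abm_fast_leader")
  s1 <- run_abm(p, n_steps = 30, seed = 9, sample_every = 10)
  s2 <- run_abm(p, n_steps = 30, seed = 9, sample_every = 10)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$state$agents, s2$state$agents)
})

test_that("shrinking-wnt runs deposit trailing cells and keep the length rule", {
  p <- abm_preset("abm_shrinking_wnt")
  sim <- run_abm(p, n_steps = 600, seed = 3, sample_every = 100)
  st <- sim$state
  expect_lt(st$wnt_domain_length, (p$column_length - 1) / p$length_factor)
  # no FGFER survives strictly beyond the permitted length
  ag <- st$agents
  movers <- ag$breed != "DEPOSITER"
  lead <- max(ag$x[movers])
  lim <- lead - permitted_length(st, p)
  expect_false(any(ag$breed == "FGFER" & ag$x < lim - 1e-9))
})
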