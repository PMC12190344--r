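# Engine-level checks: energy terms, incremental-vs-full agreement, the
# acceptance rule, neighbour shells, link bookkeeping, and conservation.

single_cell_state <- function(v = 9, lambda_v = 2, V = 9, lambda_s = 0,
                              A = 0, contact = 0) {
  lat <- matrix(0L, 10, 10)
  side <- floor(sqrt(v))
  lat[3:(2 + side), 3:(2 + side)] <- 1L
  extra <- v - side^2
  if (extra > 0) lat[2 + side + 1, 3:(2 + extra)] <- 1L
  types <- cpm_types("a", lambda_volume = lambda_v, target_volume = V,
                     lambda_surface = lambda_s, target_surface = A)
  ct <- contact_table("a", default = contact)
  cpm_state(lat, cell_type = 1L, types = types, contacts = ct,
            engine = cpm_engine_params(20, 0, 3))
}

test_that("hamiltonian reduces to its closed-form single-cell terms", {
  # v = V, a = A irrelevant (beta 0), no contact energy, no links -> 0
  st <- single_cell_state(v = 9, V = 9, contact = 0)
  expect_equal(cpm_hamiltonian(st), 0)

  # volume term alone: lambda (v - V)^2 = 2 * 2^2 = 8
  st2 <- single_cell_state(v = 9, V = 7, lambda_v = 2, contact = 0)
  expect_equal(cpm_hamiltonian(st2), 8)
})

test_that("hamiltonian equals the exhaustive brute-force oracle", {
  set.seed(101)
  for (i in 1:8) {
    st <- random_compact_scene()
    expect_equal(cpm_hamiltonian(st), bf_hamiltonian(st), tolerance = 1e-9)
  }
})

test_that("incremental delta equals the full-recompute difference on random scenes", {
  set.seed(202)
  checked <- 0
  while (checked < 100) {
    st <- random_compact_scene()
    att <- random_attempt(st)
    if (is.null(att)) next
    d <- cpm_delta_J(st, att$source, att$target)
    before <- cpm_hamiltonian(st)
    st2 <- st
    st2$lattice[att$target[2], att$target[1]] <-
      st$lattice[att$source[2], att$source[1]]
    after <- cpm_hamiltonian(st2)
    expect_equal(d[["core"]], after - before, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_equal(checked, 100)
})

test_that("a same-owner copy attempt is a no-op with zero delta", {
  st <- single_cell_state(v = 9, V = 9)
  ij <- which(st$lattice == 1L, arr.ind = TRUE)
  # two adjacent pixels of the same cell
  d <- cpm_delta_J(st, c(ij[1, 2], ij[1, 1]), c(ij[2, 2], ij[2, 1]))
  expect_equal(unname(d), c(0, 0))
})

test_that("acceptance probability implements the thresholded Boltzmann rule", {
  eng <- cpm_engine_params(temperature = 20, energy_threshold = 0)
  expect_equal(accept_probability(0, eng), 1)
  expect_equal(accept_probability(-5, eng), 1)
  expect_equal(accept_probability(20, eng), exp(-1))
  # continuity at h, monotone decrease, temperature dependence
  expect_equal(accept_probability(1e-12, eng), 1, tolerance = 1e-9)
  ds <- seq(0.5, 50, by = 0.5)
  ps <- accept_probability(ds, eng)
  expect_true(all(diff(ps) < 0))
  hot <- cpm_engine_params(temperature = 40)
  expect_true(all(accept_probability(ds, hot) > ps))

  engh <- cpm_engine_params(temperature = 20, energy_threshold = 3)
  expect_equal(accept_probability(3, engh), 1)
  expect_equal(accept_probability(23, engh), exp(-1))
})

test_that("neighbour shells have the standard sizes and offsets", {
  expect_equal(nrow(neighbor_offsets(1)), 4)
  expect_equal(nrow(neighbor_offsets(2)), 8)
  expect_equal(nrow(neighbor_offsets(3)), 12)
  # order-3 shell = all integer offsets with squared distance <= 4, origin excluded
  full <- expand.grid(dx = -2:2, dy = -2:2)
  full <- full[full$dx^2 + full$dy^2 > 0 & full$dx^2 + full$dy^2 <= 4, ]
  got <- neighbor_offsets(3)
  expect_setequal(paste(got[, 1], got[, 2]), paste(full$dx, full$dy))
  expect_error(neighbor_offsets(4))
})

test_that("frozen types never change and pixels are conserved every step", {
  st <- random_compact_scene(with_links = FALSE)
  st$types$frozen <- c(TRUE, TRUE)
  set.seed(1)
  st2 <- cpm_step(st, 5)
  expect_identical(st2$lattice, st$lattice)

  st$types$frozen <- c(FALSE, FALSE)
  set.seed(2)
  total <- nrow(st$lattice) * ncol(st$lattice)
  for (i in 1:5) {
    st <- cpm_step(st, 1)
    expect_equal(sum(st$volume) + sum(st$lattice == 0), total)
  }
})

test_that("caches recomputed from the raw lattice match the running caches", {
  st <- random_compact_scene()
  set.seed(3)
  st <- cpm_step(st, 10)
  fresh <- pllpsim:::refresh_caches(st)
  expect_equal(st$volume, fresh$volume)
  expect_equal(st$surface, fresh$surface)
  expect_equal(st$com_y, fresh$com_y, tolerance = 1e-9)
  dx <- (st$com_x - fresh$com_x) %% ncol(st$lattice)
  expect_true(all(pmin(dx, ncol(st$lattice) - dx) < 1e-6))
})

test_that("near zero temperature only energy-decreasing flips are accepted", {
  st <- random_compact_scene(with_links = FALSE)
  st$engine <- cpm_engine_params(temperature = 1e-9, energy_threshold = 0)
  E0 <- cpm_hamiltonian(st)
  set.seed(4)
  for (i in 1:5) {
    st <- cpm_step(st, 1)
    E1 <- cpm_hamiltonian(st)
    expect_lte(E1, E0 + 1e-6)
    E0 <- E1
  }
})

test_that("a free cell with a volume constraint equilibrates near its target", {
  lat <- matrix(0L, 20, 20)
  lat[8:12, 8:12] <- 1L
  types <- cpm_types("a", lambda_volume = 2, target_volume = 25)
  ct <- contact_table("a", default = 8)
  st <- cpm_state(lat, cell_type = 1L, types = types, contacts = ct,
                  engine = cpm_engine_params(temperature = 15,
                                             energy_threshold = 0,
                                             neighbor_order = 1))
  set.seed(5)
  vols <- numeric(100)
  st <- cpm_step(st, 100)            # burn-in
  for (i in 1:100) {
    st <- cpm_step(st, 5)
    vols[i] <- st$volume[1]
  }
  expect_lt(abs(mean(vols) - 25) / 25, 0.1)
})

test_that("the hamiltonian is invariant under periodic-x translation", {
  set.seed(606)
  st <- random_compact_scene(order = 3)
  E0 <- cpm_hamiltonian(st)
  for (k in c(3, 11)) {
    st2 <- st
    st2$lattice <- st$lattice[, c((ncol(st$lattice) - k + 1):ncol(st$lattice),
                                  1:(ncol(st$lattice) - k))]
    st2 <- pllpsim:::refresh_caches(st2)
    expect_equal(cpm_hamiltonian(st2), E0, tolerance = 1e-9)
  }
})

test_that("link bookkeeping breaks strictly beyond max length and reforms on contact", {
  # two cells sharing a boundary, one link class eligible to reform
  lat <- matrix(0L, 10, 20)
  lat[4:6, 3:6] <- 1L
  lat[4:6, 7:10] <- 2L
  lat[4:6, 14:16] <- 3L
  types <- cpm_types("a", target_volume = 12)
  ct <- contact_table("a", default = 5)
  rc <- data.frame(class_id = 1L, type_a = 1L, type_b = 1L,
                   strength = 2, target_length = 4, max_length = 6)
  st <- cpm_state(lat, cell_type = c(1L, 1L, 1L), types = types,
                  contacts = ct, reform_classes = rc,
                  engine = cpm_engine_params(20, 0, 1))
  st <- update_fpp_links(st)
  # cells 1-2 share boundary -> linked; cell 3 is distant -> unlinked
  key <- paste(pmin(st$links$cell_a, st$links$cell_b),
               pmax(st$links$cell_a, st$links$cell_b))
  expect_true("1 2" %in% key)
  expect_false(any(grepl("3", key)))

  # a link exactly at max length is retained (strictly "beyond")
  st$links <- data.frame(cell_a = 1L, cell_b = 2L, strength = 2,
                         target_length = 4,
                         max_length = abs(st$com_x[1] - st$com_x[2]),
                         internal = FALSE, class_id = 99L)
  st2 <- update_fpp_links(st)
  expect_true(99L %in% st2$links$class_id)

  # stretched past max: external breaks, internal survives
  st$links$max_length <- abs(st$com_x[1] - st$com_x[2]) - 0.5
  st3 <- update_fpp_links(st)
  expect_false(99L %in% st3$links$class_id)
  st$links$internal <- TRUE
  st4 <- update_fpp_links(st)
  expect_true(99L %in% st4$links$class_id)
})

test_that("the migration-force bias is linear and sign-correct", {
  expect_equal(external_force_bias(5, 0, 2), 5)
  expect_equal(external_force_bias(5, -10, 0.3), 2)
  expect_equal(external_force_bias(5, -10, -0.3) - 5,
               -(external_force_bias(5, -10, 0.3) - 5))

  # a +x-shifting copy on a forced cell lowers the total delta
  lat <- matrix(0L, 8, 16)
  lat[3:5, 3:5] <- 1L
  types <- cpm_types("a", lambda_volume = 0, target_volume = 9,
                     migration_force_x = -50)
  ct <- contact_table("a", default = 0)
  st <- cpm_state(lat, cell_type = 1L, types = types, contacts = ct,
                  engine = cpm_engine_params(20, 0, 1))
  # copy cell onto the medium pixel just right of it: com moves +x
  d <- cpm_delta_J(st, source = c(5, 4), target = c(6, 4))
  expect_lt(d[["force"]], 0)
  # and symmetric -x growth raises it by the same magnitude
  d2 <- cpm_delta_J(st, source = c(3, 4), target = c(2, 4))
  expect_equal(d2[["force"]], -d[["force"]], tolerance = 1e-9)
})
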