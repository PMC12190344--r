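make_abm_state <- function(x, y, flagged = rep(TRUE, length(x)),
                           breed = rep("FGFER", length(x))) {
  st <- list(
    agents = data.frame(id = seq_along(x), breed = breed, x = x, y = y,
                        neighbor_count = 0L, flagged_dense = flagged,
                        stringsAsFactors = FALSE),
    links = data.frame(), step_index = 0L, wnt_domain_length = 10)
  class(st) <- "abm_state"
  st
}

test_that("abm cluster counting handles empty, disjoint and threshold cases", {
  p <- abm_params(density_radius = 1.0, min_cluster_size = 3)

  none <- make_abm_state(1:5, rep(0, 5), flagged = rep(FALSE, 5))
  expect_equal(abm_cluster_count(none, p)$n_rosettes, 0)

  # two flagged triples far apart -> 2 clusters, ordered by centroid x
  st <- make_abm_state(c(0, 0.5, 1, 20, 20.5, 21), rep(0, 6))
  rep <- abm_cluster_count(st, p)
  expect_equal(rep$n_rosettes, 2)
  expect_lt(rep$clusters[[1]]$centroid[["x"]], rep$clusters[[2]]$centroid[["x"]])

  # a flagged pair is below min_cluster_size
  st2 <- make_abm_state(c(0, 0.5), c(0, 0))
  expect_equal(abm_cluster_count(st2, p)$n_rosettes, 0)
})

test_that("abm clusters equal brute-force union-find on random layouts", {
  p <- abm_params(density_radius = 1.2, min_cluster_size = 1)
  set.seed(41)
  for (rep_i in 1:5) {
    n <- 40
    x <- runif(n, 0, 12); y <- runif(n, 0, 4)
    st <- make_abm_state(x, y)
    got <- abm_cluster_count(st, p)
    comp <- bf_components(cbind(x, y), 1.2)
    expect_equal(got$n_rosettes, length(unique(comp)))
    got_sizes <- sort(vapply(got$clusters, `[[`, 0L, "size"))
    expect_equal(got_sizes, sort(unname(as.vector(table(comp)))))
  }
})

test_that("cluster counts are invariant under uniform translation", {
  p <- abm_params(density_radius = 1.2, min_cluster_size = 2)
  set.seed(7)
  x <- runif(30, 0, 10); y <- runif(30, 0, 3)
  a <- abm_cluster_count(make_abm_state(x, y), p)$n_rosettes
  b <- abm_cluster_count(make_abm_state(x + 113.7, y - 42.1), p)$n_rosettes
  expect_equal(a, b)
})

# hand-built CPM state with apical compartments at chosen x positions
make_api_state <- function(groups, gap = 4) {
  # groups: list of integer vectors, sizes of consecutive apical runs
  n_api <- sum(unlist(groups))
  w <- 3
  nx <- 40 + (n_api + length(groups)) * (w + gap)
  ny <- 20
  lat <- matrix(0L, ny, nx)
  x <- 3
  id <- 0
  for (g in seq_along(groups)) {
    for (i in seq_len(groups[[g]])) {
      id <- id + 1
      lat[5:8, x:(x + w - 1)] <- id
      x <- x + w          # members of a group are adjacent
    }
    x <- x + gap          # groups separated by medium
  }
  types <- cpm_types(c("fgfapi", "wnt"), target_volume = 12)
  ct <- contact_table(c("fgfapi", "wnt"), default = 5)
  cpm_state(lat, cell_type = rep(1L, id), types = types, contacts = ct,
            engine = cpm_engine_params(20, 0, 1))
}

test_that("cpm rosette detection counts adjacency components over the size rule", {
  st0 <- make_api_state(list(1, 1, 1), gap = 6)   # isolated apicals
  expect_equal(detect_rosettes_cpm(st0)$n_rosettes, 0)

  st1 <- make_api_state(list(3, 3), gap = 8)      # two disjoint triples
  r1 <- detect_rosettes_cpm(st1)
  expect_equal(r1$n_rosettes, 2)
  expect_equal(vapply(r1$clusters, `[[`, 0L, "size"), c(3L, 3L))

  st2 <- make_api_state(list(5))                  # one chain of five
  expect_equal(detect_rosettes_cpm(st2)$n_rosettes, 1)

  # an active apical-apical link merges two otherwise-separate groups
  st3 <- make_api_state(list(3, 3), gap = 8)
  st3$links <- data.frame(cell_a = 3L, cell_b = 4L, strength = 1,
                          target_length = 3, max_length = 100,
                          internal = FALSE, class_id = 1L)
  expect_equal(detect_rosettes_cpm(st3)$n_rosettes, 1)
})

test_that("bridging members never increase the rosette count", {
  st <- make_api_state(list(3, 3), gap = 8)
  base <- detect_rosettes_cpm(st)$n_rosettes
  st$links <- data.frame(cell_a = 3L, cell_b = 4L, strength = 1,
                         target_length = 3, max_length = 100,
                         internal = FALSE, class_id = 1L)
  expect_lte(detect_rosettes_cpm(st)$n_rosettes, base)
})

test_that("primordium extent handles depositers and the periodic x-boundary", {
  st <- make_abm_state(c(10, 30, 58), rep(0, 3))
  ext <- primordium_extent(st)
  expect_equal(ext[["length"]], 48)
  expect_equal(ext[["leading_edge_x"]], 58)

  # depositers excluded
  st$agents$breed[1] <- "DEPOSITER"
  expect_equal(primordium_extent(st)[["length"]], 28)

  one <- make_abm_state(5, 0)
  expect_equal(primordium_extent(one)[["length"]], 0)

  # CPM scene wrapped across x = 0: unwrapped span, not the raw extremes
  lat <- matrix(0L, 10, 50)
  lat[4:6, c(46:50, 1:5)] <- rep(1:2, each = 3 * 5)
  lat[4:6, 46:50] <- 1L; lat[4:6, 1:5] <- 2L
  types <- cpm_types(c("wnt"), target_volume = 15)
  ct <- contact_table("wnt", default = 5)
  stc <- cpm_state(lat, cell_type = c(1L, 1L), types = types, contacts = ct,
                   engine = cpm_engine_params(20, 0, 1))
  extc <- primordium_extent(stc)
  expect_equal(extc[["length"]], 9)
  expect_lt(extc[["length"]], 50)
})

test_that("edge velocities recover linear motion and reject bad windows", {
  mk_rep <- function(t, le, tr) {
    structure(list(time = t, clusters = list(), n_rosettes = 0L,
                   leading_edge_x = le, trailing_edge_x = tr,
                   primordium_length = le - tr), class = "rosette_report")
  }
  # stationary edges
  reps <- lapply(0:5, function(t) mk_rep(t, 10, 2))
  v <- edge_velocity_series(reps)
  expect_true(all(v$v_leading[!is.na(v$v_leading)] == 0))

  # linear advance at 0.018 per step
  reps <- lapply(seq(0, 500, by = 100),
                 function(t) mk_rep(t, 10 + 0.018 * t, 2 + 0.01 * t))
  v <- edge_velocity_series(reps, window = 1)
  expect_equal(v$v_leading[3], 0.018, tolerance = 1e-12)
  expect_equal(v$v_trailing[3], 0.01, tolerance = 1e-12)

  # noisy linear series: centered-difference velocity near the LS slope
  set.seed(11)
  t <- seq(0, 2000, by = 100)
  le <- 10 + 0.018 * t + rnorm(length(t), 0, 0.05)
  reps <- lapply(seq_along(t), function(i) mk_rep(t[i], le[i], 0))
  v <- edge_velocity_series(reps, window = 3)
  fit <- lm(le ~ t)
  mid <- v$v_leading[!is.na(v$v_leading)]
  expect_lt(abs(mean(mid) - coef(fit)[2]), 3 * summary(fit)$coefficients[2, 2])

  expect_error(edge_velocity_series(reps[1]), "at least two")
  expect_error(edge_velocity_series(reps, window = 30), "window")
})

test_that("reports are pure functions of state", {
  p <- abm_params()
  set.seed(13)
  st <- init_abm(p)
  for (i in 1:20) st <- step_abm(st, p)
  r1 <- abm_cluster_count(st, p)
  r2 <- abm_cluster_count(st, p)
  expect_identical(r1, r2)
})
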