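# Agent-based model of the migrating primordium: a column of point agents
# ("turtles") coupled by breakable spring links, with breed-specific migration
# speeds, link turnover, optional Wnt-domain shrinkage and trailing-cell
# deposition, and density-based cluster flagging.

ABM_BREEDS <- c("WNTER", "FGFER", "DEPOSITER")

#' Parameters of the agent-based primordium model
#'
#' Constructs the full parameter set of the spring-linked agent model. The
#' primordium is initialized as a `column_width` x `column_length` column of
#' agents on a unit grid, the migration axis along x. Agents in the leading
#' `wnt_fraction` of the column are WNTERs (Wnt-active leading domain), the
#' rest FGFERs (FGF-active trailing domain). Published constants: spring
#' constant 0.18, WNTER speed 0.018, FGFER speed 0.016, leading Wnt fraction
#' 0.6, permitted primordium length 1.6 times the Wnt-domain length. All other
#' numeric defaults (link radii, break thresholds, turnover, repulsion,
#' density radius/threshold, shrink rate) are calibrated defaults, not
#' published values.
#'
#' @param column_width agents per row across the column (default 5).
#' @param column_length agents along the migration axis (default 30).
#' @param wnt_fraction leading fraction of the column occupied by WNTERs.
#' @param speed_wnt,speed_fgf forward displacement per step (grid units) of
#'   WNTERs and FGFERs; DEPOSITERs never move.
#' @param link_radius named vector, per-breed radius within which an agent
#'   forms links; a pair links if closer than the larger of the two radii.
#' @param spring_constant spring stiffness `s`: attractive displacement per
#'   unit link extension.
#' @param spring_length rest length all links relax toward.
#' @param repulsion_constant strength of the inverse-square short-range
#'   repulsion between nearby agents.
#' @param break_threshold named vector, per-breed maximum link length before
#'   rupture; a link uses the smaller threshold of its two endpoints, and
#'   DEPOSITERs get a low threshold so motion of the rest of the column
#'   detaches them.
#' @param turnover_rate per-step probability that an existing link is removed.
#' @param density_radius,density_threshold neighbourhood radius and strict
#'   neighbour-count threshold of the density ("cyan") flag.
#' @param proliferation_rate named vector, per-step division probability per
#'   breed; DEPOSITERs never divide.
#' @param wnt_shrink_rate Wnt-domain length lost per step when shrinkage is
#'   enabled.
#' @param length_factor permitted primordium length as a multiple of the
#'   current Wnt-domain length (default 1.6).
#' @param shrinkage logical; enable Wnt-domain shrinkage and deposition.
#' @param displacement_cap per-sweep cap on the spring-relaxation displacement
#'   of any one agent (numerical stability).
#' @param daughter_offset radius of the uniform random offset at which a
#'   daughter agent is placed.
#' @param min_cluster_size smallest connected group of density-flagged agents
#'   counted as a cluster by [abm_cluster_count()].
#' @return an object of class `abm_params` (a validated list).
#' @seealso [init_abm()], [step_abm()], [run_abm()], [abm_preset()]
#' @export
abm_params <- function(column_width = 5,
                       column_length = 30,
                       wnt_fraction = 0.6,
                       speed_wnt = 0.018,
                       speed_fgf = 0.016,
                       link_radius = c(WNTER = 2.4, FGFER = 2.0, DEPOSITER = 2.0),
                       spring_constant = 0.18,
                       spring_length = 0.55,
                       repulsion_constant = 0.22,
                       break_threshold = c(WNTER = 2.8, FGFER = 2.8, DEPOSITER = 1.0),
                       turnover_rate = 0.005,
                       density_radius = 1.0,
                       density_threshold = 6,
                       proliferation_rate = c(WNTER = 0, FGFER = 0, DEPOSITER = 0),
                       wnt_shrink_rate = 0.002,
                       length_factor = 1.6,
                       shrinkage = FALSE,
                       displacement_cap = 0.5,
                       daughter_offset = 0.2,
                       min_cluster_size = 3) {
  link_radius <- fill_breed_vector(link_radius, 2.0)
  break_threshold <- fill_breed_vector(break_threshold, 2.8)
  proliferation_rate <- fill_breed_vector(proliferation_rate, 0)
  proliferation_rate["DEPOSITER"] <- 0

  p <- list(
    column_width = column_width, column_length = column_length,
    wnt_fraction = wnt_fraction,
    speed_wnt = speed_wnt, speed_fgf = speed_fgf,
    link_radius = link_radius,
    spring_constant = spring_constant, spring_length = spring_length,
    repulsion_constant = repulsion_constant,
    break_threshold = break_threshold, turnover_rate = turnover_rate,
    density_radius = density_radius, density_threshold = density_threshold,
    proliferation_rate = proliferation_rate,
    wnt_shrink_rate = wnt_shrink_rate, length_factor = length_factor,
    shrinkage = shrinkage,
    displacement_cap = displacement_cap, daughter_offset = daughter_offset,
    min_cluster_size = min_cluster_size
  )
  validate_abm_params(p)
  class(p) <- "abm_params"
  p
}

fill_breed_vector <- function(x, default) {
  out <- stats::setNames(rep(default, 3), ABM_BREEDS)
  if (is.null(names(x)) && length(x) == 1) {
    out[] <- x
  } else {
    bad <- setdiff(names(x), ABM_BREEDS)
    if (length(bad)) stop("unknown breed name(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

validate_abm_params <- function(p) {
  stopifnot(
    p$column_width >= 1, p$column_length >= 1,
    p$wnt_fraction >= 0, p$wnt_fraction <= 1,
    p$speed_wnt >= 0, p$speed_fgf >= 0,
    all(p$link_radius > 0),
    p$spring_constant >= 0, p$spring_length > 0,
    all(p$break_threshold >= p$spring_length),
    p$repulsion_constant >= 0,
    p$turnover_rate >= 0, p$turnover_rate <= 1,
    p$density_radius > 0, p$density_threshold >= 0,
    all(p$proliferation_rate >= 0), all(p$proliferation_rate <= 1),
    p$wnt_shrink_rate >= 0, p$length_factor > 1,
    p$displacement_cap > 0, p$min_cluster_size >= 1
  )
  invisible(p)
}

#' Scenario presets for the agent-based model
#'
#' Named parameter presets matching the published in-silico experiments:
#' `"abm_no_migration"` (all speeds zero; clusters form along the whole
#' column and slowly coalesce), `"abm_fast_leader"` (WNTER speed 0.018 >
#' FGFER speed 0.016; tension stretches the column into about three clusters
#' at intermediate times), `"abm_slow_leader"` (speeds swapped; the column
#' compresses and coalescence accelerates, two dense clusters by step 2000),
#' and `"abm_shrinking_wnt"` (fast-leader migration plus a shrinking Wnt
#' domain with trailing FGFERs re-specified as DEPOSITERs and left behind).
#'
#' @param name preset name.
#' @param ... overrides forwarded to [abm_params()].
#' @return an `abm_params` object.
#' @export
abm_preset <- function(name = c("abm_no_migration", "abm_fast_leader",
                                "abm_slow_leader", "abm_shrinking_wnt"),
                       ...) {
  name <- match.arg(name)
  args <- switch(name,
    abm_no_migration = list(speed_wnt = 0, speed_fgf = 0),
    abm_fast_leader  = list(speed_wnt = 0.018, speed_fgf = 0.016),
    abm_slow_leader  = list(speed_wnt = 0.016, speed_fgf = 0.018),
    abm_shrinking_wnt = list(speed_wnt = 0.018, speed_fgf = 0.016,
                             shrinkage = TRUE)
  )
  do.call(abm_params, utils::modifyList(args, list(...)))
}

#' Initialize the agent column
#'
#' Lays out `column_width * column_length` agents on a unit grid, the long
#' axis along x (the migration axis). Agents whose column index falls in the
#' leading `wnt_fraction` of the column length are WNTERs; the trailing
#' remainder are FGFERs. Links are created between all pairs within link
#' radius. The initial Wnt-domain length is set to the column extent divided
#' by `length_factor`, so the permitted primordium length starts exactly at
#' the initial column extent.
#'
#' @param params an [abm_params()] object.
#' @return an object of class `abm_state`: a list with an `agents` data frame
#'   (`id`, `breed`, `x`, `y`, `neighbor_count`, `flagged_dense`), a `links`
#'   data frame (`a`, `b`, `spring_constant`, `spring_length`,
#'   `break_threshold`), `step_index`, and `wnt_domain_length`.
#' @examples
#' st <- init_abm(abm_params())
#' nrow(st$agents)          # 150
#' table(st$agents$breed)   # 90 WNTER, 60 FGFER
#' @export
init_abm <- function(params) {
  validate_abm_params(params)
  w <- params$column_width
  l <- params$column_length
  g <- expand.grid(y = seq_len(w) - 1, x = seq_len(l) - 1)
  # leading (largest-x) wnt_fraction of the l grid columns are WNTERs
  cutoff <- (1 - params$wnt_fraction) * l
  breed <- ifelse(g$x >= cutoff - 1e-9, "WNTER", "FGFER")
  agents <- data.frame(
    id = seq_len(nrow(g)),
    breed = breed,
    x = g$x, y = g$y,
    neighbor_count = 0L,
    flagged_dense = FALSE,
    stringsAsFactors = FALSE
  )
  state <- list(
    agents = agents,
    links = empty_links(),
    step_index = 0L,
    wnt_domain_length = (l - 1) / params$length_factor,
    next_id = nrow(agents) + 1L
  )
  class(state) <- "abm_state"
  state <- remake_links(state, params)
  state <- density_classify(state, params)
  state
}

empty_links <- function() {
  data.frame(a = integer(), b = integer(), spring_constant = numeric(),
             spring_length = numeric(), break_threshold = numeric())
}

# squared-distance matrix helper; n is small (<= a few hundred)
abm_dist <- function(agents) {
  as.matrix(stats::dist(cbind(agents$x, agents$y)))
}

#' One update step of the agent-based model
#'
#' Applies, in order: (1) forward motion — every WNTER advances by
#' `speed_wnt` and every FGFER by `speed_fgf` along +x, DEPOSITERs do not
#' move; (2) link removal — each link is dropped with probability
#' `turnover_rate`, and every link stretched beyond its break threshold is
#' broken; (3) link remaking among unlinked pairs within link radius; (4) one
#' spring-relaxation sweep ([apply_spring_forces()]); (5) proliferation
#' ([proliferate()]); (6) Wnt-domain shrinkage and deposition
#' ([shrink_and_deposit()]), when enabled; (7) density classification
#' ([density_classify()]).
#'
#' @param state an `abm_state`.
#' @param params an [abm_params()] object.
#' @return the updated `abm_state` with `step_index` incremented.
#' @export
step_abm <- function(state, params) {
  ag <- state$agents
  ag$x <- ag$x + c(WNTER = params$speed_wnt, FGFER = params$speed_fgf,
                   DEPOSITER = 0)[ag$breed]
  state$agents <- ag

  # one distance matrix serves link breaking, remaking and repulsion:
  # positions do not change between those sub-steps
  d <- abm_dist(ag)
  state <- turnover_links(state, params)
  state <- break_links(state, params, d)
  state <- remake_links(state, params, d)
  state <- apply_spring_forces(state, params, d)
  state <- proliferate(state, params)
  if (isTRUE(params$shrinkage)) state <- shrink_and_deposit(state, params)
  state <- density_classify(state, params)
  state$step_index <- state$step_index + 1L
  state
}

turnover_links <- function(state, params) {
  if (nrow(state$links) && params$turnover_rate > 0) {
    keep <- stats::runif(nrow(state$links)) >= params$turnover_rate
    state$links <- state$links[keep, , drop = FALSE]
  }
  state
}

break_links <- function(state, params, d = NULL) {
  lk <- state$links
  if (!nrow(lk)) return(state)
  ag <- state$agents
  ia <- match(lk$a, ag$id); ib <- match(lk$b, ag$id)
  len <- if (is.null(d))
    sqrt((ag$x[ia] - ag$x[ib])^2 + (ag$y[ia] - ag$y[ib])^2)
  else d[cbind(ia, ib)]
  state$links <- lk[len <= lk$break_threshold, , drop = FALSE]
  state
}

# create links between unlinked pairs within radius; a pair is eligible when
# its distance is at most the larger of the two endpoint breeds' radii
remake_links <- function(state, params, d = NULL) {
  ag <- state$agents
  n <- nrow(ag)
  if (n < 2) return(state)
  if (is.null(d)) d <- abm_dist(ag)
  rad <- params$link_radius[ag$breed]
  rmax <- outer(rad, rad, pmax)
  idx <- which(d <= rmax & upper.tri(d), arr.ind = TRUE)
  if (!nrow(idx)) return(state)
  a <- ag$id[idx[, 1]]; b <- ag$id[idx[, 2]]
  key_base <- max(ag$id) + 1
  if (nrow(state$links)) {
    have <- state$links$a * key_base + state$links$b
    keep <- is.na(match(a * key_base + b, have))
    a <- a[keep]; b <- b[keep]
  }
  if (!length(a)) return(state)
  ba <- ag$breed[match(a, ag$id)]
  bb <- ag$breed[match(b, ag$id)]
  new <- list(
    a = a, b = b,
    spring_constant = rep.int(params$spring_constant, length(a)),
    spring_length = rep.int(params$spring_length, length(a)),
    break_threshold = unname(pmin(params$break_threshold[ba],
                                  params$break_threshold[bb]))
  )
  class(new) <- "data.frame"
  attr(new, "row.names") <- .set_row_names(length(a))
  old <- state$links
  attr(old, "row.names") <- .set_row_names(nrow(old))
  state$links <- rbind(old, new)
  state
}

#' One spring-relaxation sweep
#'
#' Each linked pair at distance `l` receives an attractive displacement of
#' magnitude `spring_constant * (l - spring_length)` along the link (restoring
#' when compressed), applied to both endpoints; every agent pair within link
#' radius additionally receives an inverse-square repulsive displacement
#' `repulsion_constant / l^2`. The net displacement of any agent is capped at
#' `displacement_cap` per sweep; coincident agents are repelled at a floor
#' distance of 1e-3 grid units in a deterministic direction.
#'
#' @inheritParams step_abm
#' @return the updated `abm_state`.
#' @export
apply_spring_forces <- function(state, params, d = NULL) {
  ag <- state$agents
  n <- nrow(ag)
  if (n < 2) return(state)
  eps <- 1e-3
  dx <- numeric(n); dy <- numeric(n)

  lk <- state$links
  if (nrow(lk)) {
    ia <- match(lk$a, ag$id); ib <- match(lk$b, ag$id)
    ex <- ag$x[ib] - ag$x[ia]; ey <- ag$y[ib] - ag$y[ia]
    len <- pmax(sqrt(ex^2 + ey^2), eps)
    mag <- lk$spring_constant * (len - lk$spring_length)
    fx <- mag * ex / len; fy <- mag * ey / len
    dx <- dx + acc_by_index(c(fx, -fx), c(ia, ib), n)
    dy <- dy + acc_by_index(c(fy, -fy), c(ia, ib), n)
  }

  if (params$repulsion_constant > 0) {
    if (is.null(d)) d <- abm_dist(ag)
    rad <- params$link_radius[ag$breed]
    rmax <- outer(rad, rad, pmax)
    idx <- which(d <= rmax & upper.tri(d), arr.ind = TRUE)
    if (nrow(idx)) {
      i <- idx[, 1]; j <- idx[, 2]
      ex <- ag$x[j] - ag$x[i]; ey <- ag$y[j] - ag$y[i]
      len <- sqrt(ex^2 + ey^2)
      # coincident agents: deterministic separation direction, floor distance
      zero <- len < eps
      if (any(zero)) {
        ex[zero] <- 1; ey[zero] <- 0; len[zero] <- eps
      }
      rmag <- params$repulsion_constant / pmax(len, eps)^2
      fx <- rmag * ex / len; fy <- rmag * ey / len
      dx <- dx + acc_by_index(c(-fx, fx), c(i, j), n)
      dy <- dy + acc_by_index(c(-fy, fy), c(i, j), n)
    }
  }

  norm <- sqrt(dx^2 + dy^2)
  over <- norm > params$displacement_cap
  if (any(over)) {
    sc <- params$displacement_cap / norm[over]
    dx[over] <- dx[over] * sc
    dy[over] <- dy[over] * sc
  }
  ag$x <- ag$x + dx
  ag$y <- ag$y + dy
  state$agents <- ag
  state
}

acc_by_index <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Proliferation
#'
#' Each WNTER and FGFER divides with its breed's per-step probability; a
#' daughter is placed at a uniform random offset within `daughter_offset`
#' grid units, inherits the mother's breed, and starts unlinked (it acquires
#' links at the next link-remake pass). DEPOSITERs never divide.
#'
#' @inheritParams step_abm
#' @return the updated `abm_state`.
#' @export
proliferate <- function(state, params) {
  ag <- state$agents
  rate <- params$proliferation_rate[ag$breed]
  if (all(rate == 0)) return(state)
  divide <- stats::runif(nrow(ag)) < rate & ag$breed != "DEPOSITER"
  if (!any(divide)) return(state)
  mothers <- ag[divide, , drop = FALSE]
  k <- nrow(mothers)
  theta <- stats::runif(k, 0, 2 * pi)
  r <- params$daughter_offset * sqrt(stats::runif(k))
  daughters <- data.frame(
    id = seq.int(state$next_id, length.out = k),
    breed = mothers$breed,
    x = mothers$x + r * cos(theta),
    y = mothers$y + r * sin(theta),
    neighbor_count = 0L,
    flagged_dense = FALSE,
    stringsAsFactors = FALSE
  )
  state$agents <- rbind(ag, daughters)
  state$next_id <- state$next_id + k
  state
}

#' Wnt-domain shrinkage and trailing-cell deposition
#'
#' Reduces the Wnt-domain length by `wnt_shrink_rate` (floored at zero). The
#' permitted primordium length is `length_factor` times the current
#' Wnt-domain length, measured back from the current leading edge (the
#' largest x among non-DEPOSITER agents). FGFERs strictly beyond the
#' permitted length in the trailing direction are re-specified as DEPOSITERs:
#' they stop moving, never proliferate, and their links adopt the low
#' DEPOSITER break threshold, so continued motion of the column detaches
#' ("deposits") them.
#'
#' @inheritParams step_abm
#' @return the updated `abm_state`.
#' @export
shrink_and_deposit <- function(state, params) {
  state$wnt_domain_length <-
    max(0, state$wnt_domain_length - params$wnt_shrink_rate)
  ag <- state$agents
  movers <- ag$breed != "DEPOSITER"
  if (!any(movers)) return(state)
  leading <- max(ag$x[movers])
  permitted <- params$length_factor * state$wnt_domain_length
  respec <- ag$breed == "FGFER" & ag$x < leading - permitted
  if (any(respec)) {
    ag$breed[respec] <- "DEPOSITER"
    state$agents <- ag
    # links touching a fresh DEPOSITER adopt its low break threshold
    lk <- state$links
    if (nrow(lk)) {
      dep_ids <- ag$id[respec]
      touch <- lk$a %in% dep_ids | lk$b %in% dep_ids
      lk$break_threshold[touch] <-
        pmin(lk$break_threshold[touch], params$break_threshold["DEPOSITER"])
      state$links <- lk
    }
  }
  state
}

#' Density classification
#'
#' Sets each agent's `neighbor_count` to the number of other agents within
#' `density_radius`, and flags the agent dense (the "cyan" state) when that
#' count strictly exceeds `density_threshold`.
#'
#' @inheritParams step_abm
#' @return the updated `abm_state`.
#' @export
density_classify <- function(state, params) {
  ag <- state$agents
  n <- nrow(ag)
  if (n == 1) {
    ag$neighbor_count <- 0L
    ag$flagged_dense <- FALSE
  } else {
    d <- abm_dist(ag)
    ag$neighbor_count <- as.integer(colSums(d <= params$density_radius) - 1L)
    ag$flagged_dense <- ag$neighbor_count > params$density_threshold
  }
  state$agents <- ag
  state
}

#' Permitted primordium length
#'
#' @param state an `abm_state`.
#' @param params an [abm_params()] object.
#' @return `length_factor * wnt_domain_length`.
#' @export
permitted_length <- function(state, params) {
  params$length_factor * state$wnt_domain_length
}

#' Run the agent-based model
#'
#' Steps the model `n_steps` times from a fresh [init_abm()] state, recording
#' a time-series row every `sample_every` steps (and at the final step).
#'
#' @param params an [abm_params()] object (see [abm_preset()]).
#' @param n_steps number of update steps.
#' @param seed integer seed; all stochastic draws (turnover, proliferation,
#'   daughter offsets) consume one seeded generator in a fixed order.
#' @param sample_every sampling interval for the time series.
#' @return an object of class `abm_sim`: list with `series` (data frame with
#'   columns `step`, `n_agents`, `n_wnter`, `n_fgfer`, `n_depositer`,
#'   `n_links`, `primordium_length`, `n_clusters`), `state` (final
#'   `abm_state`), `params`, and `seed`.
#' @examples
#' sim <- run_abm(abm_preset("abm_fast_leader"), n_steps = 50, seed = 1)
#' tail(sim$series, 2)
#' @export
run_abm <- function(params, n_steps, seed = 1L, sample_every = 100L) {
  set.seed(seed)
  state <- init_abm(params)
  rows <- vector("list", n_steps %/% sample_every + 2L)
  k <- 1L
  rows[[k]] <- abm_series_row(state, params)
  for (i in seq_len(n_steps)) {
    state <- step_abm(state, params)
    if (i %% sample_every == 0L || i == n_steps) {
      k <- k + 1L
      rows[[k]] <- abm_series_row(state, params)
    }
  }
  series <- do.call(rbind, rows[seq_len(k)])
  series <- series[!duplicated(series$step), , drop = FALSE]
  rownames(series) <- NULL
  out <- list(series = series, state = state, params = params, seed = seed)
  class(out) <- "abm_sim"
  out
}

abm_series_row <- function(state, params) {
  ag <- state$agents
  ext <- primordium_extent(state)
  rep <- abm_cluster_count(state, params)
  data.frame(
    step = state$step_index,
    n_agents = nrow(ag),
    n_wnter = sum(ag$breed == "WNTER"),
    n_fgfer = sum(ag$breed == "FGFER"),
    n_depositer = sum(ag$breed == "DEPOSITER"),
    n_links = nrow(state$links),
    primordium_length = ext[["length"]],
    n_clusters = rep$n_rosettes
  )
}

#' @export
print.abm_state <- function(x, ...) {
  ag <- x$agents
  cat("<abm_state> step", x$step_index, "|", nrow(ag), "agents (",
      sum(ag$breed == "WNTER"), "WNTER,", sum(ag$breed == "FGFER"), "FGFER,",
      sum(ag$breed == "DEPOSITER"), "DEPOSITER ) |",
      nrow(x$links), "links\n")
  invisible(x)
}

#' @export
print.abm_sim <- function(x, ...) {
  cat("<abm_sim>", max(x$series$step), "steps, seed", x$seed, "\n")
  cat("terminal:", x$series$n_agents[nrow(x$series)], "agents,",
      x$series$n_clusters[nrow(x$series)], "clusters\n")
  invisible(x)
}

#' @export
summary.abm_sim <- function(object, ...) {
  s <- object$series
  structure(list(
    n_steps = max(s$step),
    terminal = s[nrow(s), ],
    modal_clusters = modal_value(s$n_clusters[s$step > 0])
  ), class = "summary.abm_sim")
}

#' @export
print.summary.abm_sim <- function(x, ...) {
  cat("abm run:", x$n_steps, "steps; modal cluster count",
      x$modal_clusters, "\n")
  print(x$terminal, row.names = FALSE)
  invisible(x)
}

#' Plot an agent-based model state
#'
#' Two visualization modes mirroring the model's two display styles: breed
#' colors (WNTER green, FGFER yellow, DEPOSITER red) or density shading (red
#' shades by neighbour count, cyan when flagged dense).
#'
#' @param x an `abm_state`.
#' @param mode `"breed"` or `"density"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.abm_state <- function(x, mode = c("breed", "density"), ...) {
  mode <- match.arg(mode)
  ag <- x$agents
  if (mode == "breed") {
    col <- c(WNTER = "forestgreen", FGFER = "gold2", DEPOSITER = "red3")[ag$breed]
  } else {
    shade <- pmin(ag$neighbor_count / max(1, max(ag$neighbor_count)), 1)
    col <- grDevices::rgb(0.3 + 0.7 * shade, 0.05, 0.05)
    col[ag$flagged_dense] <- "cyan3"
  }
  graphics::plot(ag$x, ag$y, col = col, pch = 19, asp = 1,
                 xlab = "x (migration axis)", ylab = "y", ...)
  invisible(x)
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}
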