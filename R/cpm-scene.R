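# Side-view primordium scene for the Cellular Potts engine: skin above, a
# thin ECM layer and a 5-cell-thick muscle band below, and a primordium of
# leading Wnt cells, trailing three-compartment FGF cells (apical/lateral/
# basal), and superficial sheath cells, plus the published scenarios.
#
# All numeric type, contact and link parameters here are calibrated defaults
# (chosen to satisfy the adhesion hierarchy and reproduce the qualitative
# scenario behavior); they are not published values.

SCENE_TYPES <- c("muscle", "ecm", "skin", "wnt", "fgfapi", "fgfbas",
                 "fgflat", "sheath")

#' Scene specification for the primordium CPM
#'
#' Geometry and parameter set of the side-view scene. The default is a
#' 400 x 150 lattice; `lattice_width = 800, lattice_height = 300` gives the
#' full-size scene with the same layout scaled up. The muscle band is always
#' 5 cell rows thick; the ECM is a thin single row of cells between muscle
#' and primordium; the skin is a single row of wide cells spanning the
#' lattice directly above the primordium; sheath cells form a superficial
#' band between the skin and the Wnt/FGF core. Each FGF cell is a vertical
#' apical-over-lateral-over-basal stack of three compartments sharing a
#' composite id.
#'
#' @param lattice_width,lattice_height lattice dimensions in pixels.
#' @param n_wnt,n_fgf,n_sheath number of Wnt cells, composite FGF cells, and
#'   sheath cells.
#' @param temperature,energy_threshold,neighbor_order engine parameters
#'   (see [cpm_engine_params()]).
#' @param wnt_force,sheath_force,fgfbas_force migration-force coefficients
#'   (`lambdaVecX`-style; negative drives +x migration) of the three
#'   force-bearing types.
#' @param api_shrink apical target volume as a fraction of the built apical
#'   compartment area (apical constriction strength).
#' @param api_link_strength,api_link_target,api_link_max apical-apical
#'   focal-point-plasticity link class (short and strong; breakable,
#'   re-forms on contact).
#' @param lat_link_strength,lat_link_max lateral-lateral link strength and
#'   rupture length (the tissue-scale mechanical coupling along the column).
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(lattice_width = 400, lattice_height = 150,
                       n_wnt = 10, n_fgf = 20, n_sheath = 6,
                       temperature = 33, energy_threshold = 0,
                       neighbor_order = 3,
                       wnt_force = -200, sheath_force = -100,
                       fgfbas_force = -150,
                       api_shrink = 0.45,
                       api_link_strength = 8, api_link_target = 3,
                       api_link_max = 8,
                       lat_link_strength = 0.2, lat_link_max = 15) {
  stopifnot(lattice_width >= 100, lattice_height >= 60,
            n_wnt >= 1, n_fgf >= 1, n_sheath >= 1)
  spec <- list(
    lattice_width = as.integer(lattice_width),
    lattice_height = as.integer(lattice_height),
    n_wnt = as.integer(n_wnt), n_fgf = as.integer(n_fgf),
    n_sheath = as.integer(n_sheath),
    temperature = temperature, energy_threshold = energy_threshold,
    neighbor_order = neighbor_order,
    wnt_force = wnt_force, sheath_force = sheath_force,
    fgfbas_force = fgfbas_force,
    api_shrink = api_shrink,
    api_link_strength = api_link_strength,
    api_link_target = api_link_target, api_link_max = api_link_max,
    lat_link_strength = lat_link_strength, lat_link_max = lat_link_max
  )
  class(spec) <- "scene_spec"
  spec
}

# default external contact-energy table (lower energy = stronger adhesion)
scene_contacts <- function() {
  prim <- c("wnt", "fgfapi", "fgfbas", "fgflat", "sheath")
  pairs <- list()
  add <- function(a, b, e) pairs[[length(pairs) + 1]] <<- list(a, b, e)
  for (t in SCENE_TYPES) add(t, t, 4)
  for (i in seq_along(prim)) {
    for (j in seq_along(prim)) if (i < j) add(prim[i], prim[j], 6)
  }
  for (t in prim) { add(t, "skin", 14); add(t, "ecm", 14) }
  add("sheath", "skin", 8)    # attached to skin, detachable
  add("fgfbas", "ecm", 7)     # attached to ECM, detachable
  add("fgfapi", "sheath", 5)  # apical surfaces face the sheath layer
  add("fgfapi", "fgfbas", 7)  # apicobasal polarity: api avoids bas ends
  add("fgfapi", "fgflat", 7)  # apicals segregate from neighbouring laterals
  add("fgfapi", "wnt", 7)
  for (t in prim) add(t, "Medium", 25)
  add("skin", "Medium", 10)
  add("ecm", "Medium", 22)
  add("ecm", "muscle", 5)
  for (t in c(prim, "skin")) add("muscle", t, 22)
  add("muscle", "Medium", 22)
  add("skin", "ecm", 16)
  df <- data.frame(
    type_a = vapply(pairs, `[[`, "", 1),
    type_b = vapply(pairs, `[[`, "", 2),
    energy = vapply(pairs, function(p) p[[3]], 0)
  )
  contact_table(SCENE_TYPES, default = 16, pairs = df)
}

# internal (same-composite) compartment contact energies
scene_contacts_internal <- function() {
  df <- data.frame(
    type_a = c("fgfapi", "fgflat", "fgfapi"),
    type_b = c("fgflat", "fgfbas", "fgfbas"),
    energy = c(2, 2, 18)   # api and bas must stay apart
  )
  contact_table(SCENE_TYPES, default = 16, pairs = df)
}

#' Build the side-view primordium scene
#'
#' Tiles the lattice with the layered scene described in [scene_spec()]:
#' frozen muscle (5 cell rows) at the bottom, a thin ECM row, the primordium
#' (trailing composite FGF cells, leading Wnt cells, superficial sheath
#' band), a skin row spanning the full width above it, and Medium elsewhere.
#' Instantiates all link classes: skin-skin, ECM-ECM, Wnt-Wnt,
#' lateral-lateral and apical-apical links between neighbouring cells, the
#' single Wnt-to-first-lateral bridge link, and the three internal
#' compartment links of every FGF cell.
#'
#' @param spec a [scene_spec()].
#' @return a [cpm_state()] ready for [cpm_step()] / [run_cpm()].
#' @export
build_primordium_scene <- function(spec = scene_spec()) {
  W <- spec$lattice_width; H <- spec$lattice_height
  lat <- matrix(0L, nrow = H, ncol = W)

  # vertical layout (1 = bottom row)
  mh <- max(3L, round(H / 30))          # muscle cell height; band = 5 rows
  muscle_top <- 5L * mh
  eh <- max(3L, round(H * 0.02))        # ECM thickness
  ecm_top <- muscle_top + eh
  ph <- round(H * 0.24)                 # primordium height
  core_h <- round(ph * 5 / 6)
  sheath_h <- ph - core_h
  prim_top <- ecm_top + ph
  kh <- max(6L, round(H * 0.08))        # skin thickness
  skin_top <- prim_top + kh
  stopifnot(skin_top < H)

  # horizontal primordium layout: trailing FGF block then leading Wnt block
  fgf_w <- max(4L, round(W / 80))
  wnt_w <- max(6L, round(W / 50))
  x0 <- round(W * 0.10)
  prim_w <- spec$n_fgf * fgf_w + spec$n_wnt * wnt_w
  if (x0 + prim_w > W) stop("primordium composition does not fit the lattice")

  cells <- list()   # accumulators: type name, composite id
  new_cell <- function(type, comp = 0L) {
    cells[[length(cells) + 1]] <<- list(type = type, comp = comp)
    length(cells)
  }
  fill <- function(id, x1, x2, y1, y2) {
    lat[y1:y2, (x1:x2)] <<- id
  }

  # muscle: 5 rows of mw-wide frozen cells
  mw <- 20L
  for (r in 1:5) {
    for (cx in seq_len(ceiling(W / mw))) {
      id <- new_cell("muscle")
      fill(id, (cx - 1L) * mw + 1L, min(cx * mw, W),
           (r - 1L) * mh + 1L, r * mh)
    }
  }
  # ECM row
  ecm_ids <- integer(0)
  for (cx in seq_len(ceiling(W / mw))) {
    id <- new_cell("ecm")
    ecm_ids <- c(ecm_ids, id)
    fill(id, (cx - 1L) * mw + 1L, min(cx * mw, W), muscle_top + 1L, ecm_top)
  }
  # skin row (full width, above the primordium band)
  skin_ids <- integer(0)
  for (cx in seq_len(ceiling(W / mw))) {
    id <- new_cell("skin")
    skin_ids <- c(skin_ids, id)
    fill(id, (cx - 1L) * mw + 1L, min(cx * mw, W), prim_top + 1L, skin_top)
  }

  core_y1 <- ecm_top + 1L
  core_y2 <- ecm_top + core_h
  # FGF composite cells (trailing block): apical over lateral over basal
  api_h <- round(core_h * 0.22)
  bas_h <- round(core_h * 0.22)
  api_ids <- lat_ids <- bas_ids <- integer(spec$n_fgf)
  for (i in seq_len(spec$n_fgf)) {
    xa <- x0 + (i - 1L) * fgf_w + 1L
    xb <- x0 + i * fgf_w
    comp <- i
    bas_ids[i] <- new_cell("fgfbas", comp)
    fill(bas_ids[i], xa, xb, core_y1, core_y1 + bas_h - 1L)
    lat_ids[i] <- new_cell("fgflat", comp)
    fill(lat_ids[i], xa, xb, core_y1 + bas_h, core_y2 - api_h)
    api_ids[i] <- new_cell("fgfapi", comp)
    fill(api_ids[i], xa, xb, core_y2 - api_h + 1L, core_y2)
  }
  # Wnt cells (leading block)
  wnt_x0 <- x0 + spec$n_fgf * fgf_w
  wnt_ids <- integer(spec$n_wnt)
  for (i in seq_len(spec$n_wnt)) {
    wnt_ids[i] <- new_cell("wnt")
    fill(wnt_ids[i], wnt_x0 + (i - 1L) * wnt_w + 1L, wnt_x0 + i * wnt_w,
         core_y1, core_y2)
  }
  # sheath band above the core, spanning the primordium
  sheath_w <- ceiling(prim_w / spec$n_sheath)
  sheath_ids <- integer(spec$n_sheath)
  for (i in seq_len(spec$n_sheath)) {
    sheath_ids[i] <- new_cell("sheath")
    fill(sheath_ids[i], x0 + (i - 1L) * sheath_w + 1L,
         min(x0 + i * sheath_w, x0 + prim_w), core_y2 + 1L, prim_top)
  }

  type_name <- vapply(cells, `[[`, "", "type")
  composite <- vapply(cells, `[[`, 0L, "comp")
  cell_type <- match(type_name, SCENE_TYPES)

  # per-type parameters; targets from the as-built geometry
  areas <- tabulate(lat[lat > 0], nbins = length(cells))
  mean_area <- function(t) mean(areas[type_name == t])
  perim_of <- function(w, h) 2 * (w + h)
  types <- cpm_types(
    SCENE_TYPES,
    lambda_volume = c(0, 4, 2, 2, 3, 2, 2, 2),
    target_volume = c(mean_area("muscle"), mean_area("ecm"),
                      mean_area("skin"), mean_area("wnt"),
                      spec$api_shrink * mean_area("fgfapi"),
                      mean_area("fgfbas"), mean_area("fgflat"),
                      mean_area("sheath")),
    lambda_surface = c(0, 0, 0.2, 0.2, 0.4, 0.3, 0.3, 0.2),
    target_surface = c(0, 0, perim_of(mw, kh), perim_of(wnt_w, core_h),
                       perim_of(fgf_w, api_h) * 0.8,
                       perim_of(fgf_w, bas_h),
                       perim_of(fgf_w, core_h - api_h - bas_h),
                       perim_of(sheath_w, sheath_h)),
    migration_force_x = c(0, 0, 0, spec$wnt_force, 0, spec$fgfbas_force,
                          0, spec$sheath_force),
    frozen = c(TRUE, rep(FALSE, 7))
  )

  t_id <- function(nm) match(nm, SCENE_TYPES)
  lat_h <- core_h - api_h - bas_h
  reform_classes <- data.frame(
    class_id = 1:3,
    type_a = c(t_id("fgfapi"), t_id("fgflat"), t_id("wnt")),
    type_b = c(t_id("fgfapi"), t_id("fgflat"), t_id("wnt")),
    strength = c(spec$api_link_strength, spec$lat_link_strength, 1.5),
    target_length = c(spec$api_link_target, fgf_w, wnt_w),
    max_length = c(spec$api_link_max, spec$lat_link_max, 2.5 * wnt_w)
  )

  mk_links <- function(a, b, strength, target, max_len, internal, class_id) {
    if (!length(a)) return(empty_cpm_links())
    data.frame(cell_a = a, cell_b = b, strength = strength,
               target_length = target, max_length = max_len,
               internal = internal, class_id = class_id)
  }
  chain <- function(ids) list(a = ids[-length(ids)], b = ids[-1])
  sk <- chain(skin_ids); ap <- chain(api_ids); lt <- chain(lat_ids)
  wn <- chain(wnt_ids); ec <- chain(ecm_ids)
  links <- rbind(
    mk_links(sk$a, sk$b, 4, mw, 3 * mw, FALSE, 0L),
    mk_links(ec$a, ec$b, 4, mw, 3 * mw, FALSE, 0L),
    mk_links(ap$a, ap$b, spec$api_link_strength, spec$api_link_target,
             spec$api_link_max, FALSE, 1L),
    mk_links(lt$a, lt$b, spec$lat_link_strength, fgf_w, spec$lat_link_max,
             FALSE, 2L),
    mk_links(wn$a, wn$b, 1.5, wnt_w, 2.5 * wnt_w, FALSE, 3L),
    # bridge: last Wnt cell (trailing end of the Wnt block) to the leading
    # lateral compartment
    mk_links(wnt_ids[1], lat_ids[spec$n_fgf], 3,
             (wnt_w + fgf_w) / 2 + 2, 6 * wnt_w, FALSE, 0L),
    # internal compartment links of each FGF cell
    mk_links(api_ids, lat_ids, 3, (api_h + lat_h) / 2, 4 * core_h, TRUE, 0L),
    mk_links(lat_ids, bas_ids, 3, (lat_h + bas_h) / 2, 4 * core_h, TRUE, 0L),
    mk_links(api_ids, bas_ids, 2, core_h - (api_h + bas_h) / 2, 4 * core_h,
             TRUE, 0L)
  )

  st <- cpm_state(
    lattice = lat, cell_type = cell_type, types = types,
    contacts = scene_contacts(),
    contacts_internal = scene_contacts_internal(),
    composite = composite, links = links, reform_classes = reform_classes,
    engine = cpm_engine_params(spec$temperature, spec$energy_threshold,
                               spec$neighbor_order)
  )
  st$spec <- spec
  st$applied_events <- integer(0)
  st
}

#' Check the adhesion hierarchy of a contact table
#'
#' Verifies, in contact-energy terms (lower energy = stronger adhesion),
#' the assumptions the scene is built on: (i) each primordium type adheres
#' most to its own type; (ii) primordium-internal pairs adhere more strongly
#' than any primordium-skin or primordium-ECM pair; (iii) sheath-skin and
#' fgfbas-ECM adhesion is strong enough to attach (stronger than the
#' substrate-Medium pair) but weaker than primordium-internal adhesion, so
#' the primordium can slide.
#'
#' @param contacts external contact matrix (with dimnames; see
#'   [contact_table()]); defaults to the shipped scene table.
#' @return data frame with columns `check`, `pass`, `detail`; attribute
#'   `all_pass`.
#' @export
validate_adhesion_hierarchy <- function(contacts = scene_contacts()) {
  prim <- c("wnt", "fgfapi", "fgfbas", "fgflat", "sheath")
  labs <- rownames(contacts)
  stopifnot(all(c(prim, "skin", "ecm", "Medium") %in% labs))
  others <- setdiff(labs, "Medium")
  res <- list()
  add <- function(check, pass, detail)
    res[[length(res) + 1]] <<- data.frame(check = check, pass = pass,
                                          detail = detail)
  for (t in prim) {
    cross <- contacts[t, setdiff(others, t)]
    add(paste0("self_adhesion_strongest:", t),
        all(contacts[t, t] <= cross),
        sprintf("E(%s,%s)=%g vs min cross %g", t, t, contacts[t, t],
                min(cross)))
  }
  internal <- contacts[prim, prim]
  substrate <- c(contacts[prim, "skin"], contacts[prim, "ecm"])
  add("primordium_cohesion_over_substrate",
      max(internal) <= min(substrate),
      sprintf("max internal %g vs min substrate %g", max(internal),
              min(substrate)))
  add("sheath_skin_attachment",
      contacts["sheath", "skin"] < contacts["skin", "Medium"] &&
        contacts["sheath", "skin"] > min(internal),
      sprintf("E(sheath,skin)=%g", contacts["sheath", "skin"]))
  add("fgfbas_ecm_attachment",
      contacts["fgfbas", "ecm"] < contacts["ecm", "Medium"] &&
        contacts["fgfbas", "ecm"] > min(internal),
      sprintf("E(fgfbas,ecm)=%g", contacts["fgfbas", "ecm"]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Scenario presets for the primordium CPM
#'
#' Scheduled parameter overrides reproducing the published in-silico
#' experiments: `"wildtype"` (no events; directed migration with stable
#' rosettes), `"stall_leading"` (Wnt migration force set to zero at
#' `stall_time`, mimicking loss of chemokine-guided leading-cell migration;
#' rosettes fuse), `"stall_then_recover"` (as above, with the original force
#' restored at `recover_time`; a fused rosette can split again), and
#' `"boost_lat_contractility"` (at `boost_time`, lateral-lateral link
#' strength multiplied by `boost_factor` and lateral-lateral contact energy
#' reduced by `contact_drop`; rosettes fuse without impairing migration).
#'
#' @param name scenario name.
#' @param stall_time,recover_time,boost_time event times in MCS.
#' @param boost_factor multiplier on lateral-lateral link strength.
#' @param contact_drop fraction by which the lateral-lateral contact energy
#'   is reduced.
#' @param stall_all also zero sheath and basal forces during a stall
#'   (sensitivity flag; default stalls the Wnt force only).
#' @return a list of class `cpm_scenario` with a time-ordered `events` list.
#' @export
cpm_scenario <- function(name = c("wildtype", "stall_leading",
                                  "stall_then_recover",
                                  "boost_lat_contractility"),
                         stall_time = 600, recover_time = 1800,
                         boost_time = 300, boost_factor = 8,
                         contact_drop = 0.8, stall_all = FALSE) {
  name <- match.arg(name)
  events <- list()
  ev <- function(time, fn) events[[length(events) + 1]] <<-
    list(time = time, fn = fn)
  stall_fn <- function(state) {
    tset <- if (stall_all) c("wnt", "sheath", "fgfbas") else "wnt"
    ix <- match(tset, state$types$type_name)
    state$prestall_force <- state$types$migration_force_x
    state$types$migration_force_x[ix] <- 0
    state
  }
  recover_fn <- function(state) {
    if (!is.null(state$prestall_force))
      state$types$migration_force_x <- state$prestall_force
    state
  }
  boost_fn <- function(state) {
    lat_t <- match("fgflat", state$types$type_name)
    cls <- state$reform_classes
    sel <- cls$type_a == lat_t & cls$type_b == lat_t
    cls$strength[sel] <- cls$strength[sel] * boost_factor
    state$reform_classes <- cls
    lsel <- state$links$class_id %in% cls$class_id[sel]
    state$links$strength[lsel] <- state$links$strength[lsel] * boost_factor
    state$contacts[lat_t + 1L, lat_t + 1L] <-
      state$contacts[lat_t + 1L, lat_t + 1L] * (1 - contact_drop)
    state
  }
  switch(name,
    wildtype = NULL,
    stall_leading = ev(stall_time, stall_fn),
    stall_then_recover = { ev(stall_time, stall_fn)
                           ev(recover_time, recover_fn) },
    boost_lat_contractility = ev(boost_time, boost_fn)
  )
  times <- vapply(events, `[[`, 0, "time")
  structure(list(name = name, events = events[order(times)]),
            class = "cpm_scenario")
}

#' Apply scheduled scenario events up to a time
#'
#' Applies, once each, every scenario event whose scheduled time is at or
#' before `t`. Already-applied events (tracked in the state) are skipped, so
#' the call is idempotent.
#'
#' @param state a [cpm_state()] built by [build_primordium_scene()].
#' @param scenario a [cpm_scenario()].
#' @param t current MCS time.
#' @return the (possibly modified) state.
#' @export
apply_scenario <- function(state, scenario, t) {
  stopifnot(inherits(scenario, "cpm_scenario"))
  if (is.null(state$applied_events)) state$applied_events <- integer(0)
  for (i in seq_along(scenario$events)) {
    e <- scenario$events[[i]]
    if (e$time <= t && !(i %in% state$applied_events)) {
      state <- e$fn(state)
      state$applied_events <- c(state$applied_events, i)
    }
  }
  state
}

#' Run a primordium CPM scenario
#'
#' Builds the scene (unless a prebuilt state is supplied), then advances the
#' Monte Carlo dynamics in `sample_every`-MCS chunks, applying scenario
#' events as their times are reached and recording a rosette report
#' ([detect_rosettes_cpm()]) at every sample.
#'
#' @param spec a [scene_spec()], or a prebuilt [cpm_state()].
#' @param scenario a [cpm_scenario()] or scenario name.
#' @param n_mcs total Monte Carlo steps.
#' @param seed integer seed for the run.
#' @param sample_every sampling/event-resolution interval in MCS.
#' @param min_apical_members rosette size threshold.
#' @param burn_in MCS excluded from settling statistics (initial relaxation
#'   from the rectangular tiling).
#' @return an object of class `cpm_sim`: list with `series` (data frame),
#'   `reports` (list of `rosette_report`s), `state` (final), `scenario`,
#'   `seed`, `burn_in`.
#' @export
run_cpm <- function(spec = scene_spec(), scenario = "wildtype",
                    n_mcs = 2000, seed = 1L, sample_every = 50L,
                    min_apical_members = 3L, burn_in = 200L) {
  if (is.character(scenario)) scenario <- cpm_scenario(scenario)
  set.seed(seed)
  state <- if (inherits(spec, "cpm_state")) spec
           else build_primordium_scene(spec)
  reports <- list(detect_rosettes_cpm(state, min_apical_members))
  t <- 0L
  while (t < n_mcs) {
    state <- apply_scenario(state, scenario, t)
    chunk <- min(sample_every, n_mcs - t)
    state <- cpm_step(state, chunk)
    t <- t + chunk
    reports[[length(reports) + 1]] <- detect_rosettes_cpm(state,
                                                          min_apical_members)
  }
  out <- list(series = report_series(reports), reports = reports,
              state = state, scenario = scenario, seed = seed,
              burn_in = burn_in)
  class(out) <- "cpm_sim"
  out
}

#' Terminal (settled) rosette count of a run
#'
#' A configuration counts as stable when the rosette count is unchanged over
#' at least `window` consecutive MCS (after burn-in). The terminal count is
#' the value of the most recent stable stretch of the series — so a
#' transient flicker in the last few samples does not override a
#' long-established configuration. If no stretch qualifies, the final count
#' is returned with `settled = FALSE`.
#'
#' @param sim a `cpm_sim` (or `abm_sim`, using its cluster series).
#' @param window settling window in the run's time units (default 200).
#' @return integer count with attributes `settled` (logical: a qualifying
#'   stable stretch exists) and `settling_time` (start of that stretch, NA
#'   if none).
#' @export
terminal_count <- function(sim, window = 200) {
  s <- sim$series
  counts <- if (!is.null(s$n_rosettes)) s$n_rosettes else s$n_clusters
  times <- if (!is.null(s$time)) s$time else s$step
  keep <- times >= (if (!is.null(sim$burn_in)) sim$burn_in else 0)
  if (any(keep)) { counts <- counts[keep]; times <- times[keep] }
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- times[ends] - times[starts]
  qual <- which(spans >= window)
  if (length(qual)) {
    i <- max(qual)
    structure(as.integer(r$values[i]), settled = TRUE,
              settling_time = times[starts[i]])
  } else {
    structure(as.integer(counts[length(counts)]), settled = FALSE,
              settling_time = NA_real_)
  }
}

#' @export
print.cpm_sim <- function(x, ...) {
  s <- x$series
  tc <- terminal_count(x)
  cat("<cpm_sim>", x$scenario$name, "|", max(s$time), "MCS, seed", x$seed,
      "|", "terminal rosettes:", tc,
      if (attr(tc, "settled")) "(settled)" else "(not settled)", "\n")
  invisible(x)
}

#' @export
summary.cpm_sim <- function(object, ...) {
  s <- object$series
  post <- s[s$time >= object$burn_in, ]
  structure(list(
    scenario = object$scenario$name,
    n_mcs = max(s$time),
    modal_rosettes = modal_value(post$n_rosettes),
    terminal = terminal_count(object),
    series_tail = utils::tail(s, 3)
  ), class = "summary.cpm_sim")
}

#' @export
print.summary.cpm_sim <- function(x, ...) {
  cat("cpm run (", x$scenario, "): ", x$n_mcs, " MCS; modal rosettes ",
      x$modal_rosettes, "; terminal ", x$terminal,
      if (attr(x$terminal, "settled")) " (settled)", "\n", sep = "")
  print(x$series_tail, row.names = FALSE)
  invisible(x)
}

# palette matching the published side-view figure
SCENE_PALETTE <- c(Medium = "grey95", muscle = "white", ecm = "tan4",
                   skin = "palegreen2", wnt = "blue3", fgfapi = "red2",
                   fgfbas = "lightpink2", fgflat = "green4",
                   sheath = "gold1")

#' Plot a CPM lattice
#'
#' Renders the lattice with the scene palette (blue Wnt, red apical, green
#' lateral, pink basal, yellow sheath, light-green skin, brown ECM, white
#' muscle).
#'
#' @param x a [cpm_state()].
#' @param ... passed to [graphics::image()].
#' @export
plot.cpm_state <- function(x, ...) {
  type_of_pixel <- matrix("Medium", nrow(x$lattice), ncol(x$lattice))
  own <- x$lattice > 0
  type_of_pixel[own] <- x$types$type_name[x$cell_type[x$lattice[own]]]
  lv <- names(SCENE_PALETTE)
  z <- matrix(match(type_of_pixel, lv), nrow(x$lattice), ncol(x$lattice))
  graphics::image(t(z), col = SCENE_PALETTE, zlim = c(1, length(lv)),
                  useRaster = TRUE, axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}
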