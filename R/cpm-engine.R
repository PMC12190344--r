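# R-facing surface of the Cellular Potts engine. The Monte Carlo kernel and
# incremental energy bookkeeping live in src/cpm.cpp; this file defines the
# state container, the energy/probability primitives, and the step wrapper.

#' Per-type parameters of the Cellular Potts model
#'
#' One row per cell type. Volume and surface enter the energy as
#' `lambda_volume * (v - target_volume)^2` and
#' `lambda_surface * (a - target_surface)^2`, where `v` is the cell's pixel
#' count and `a` its boundary-pair count (order-1 neighbour pixel pairs with
#' unlike owners). `migration_force_x` is the external-potential coefficient:
#' a negative value drives motion along +x. Frozen types never change pixels.
#'
#' @param type_name character vector of type labels (Medium is implicit and
#'   has no row).
#' @param lambda_volume,target_volume,lambda_surface,target_surface,migration_force_x,frozen
#'   numeric/logical vectors recycled to `length(type_name)`.
#' @return a data frame of class `cpm_types`.
#' @export
cpm_types <- function(type_name, lambda_volume = 1, target_volume = 25,
                      lambda_surface = 0, target_surface = 0,
                      migration_force_x = 0, frozen = FALSE) {
  out <- data.frame(
    type_name = as.character(type_name),
    lambda_volume = lambda_volume, target_volume = target_volume,
    lambda_surface = lambda_surface, target_surface = target_surface,
    migration_force_x = migration_force_x, frozen = frozen,
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$type_name),
            all(out$lambda_volume >= 0), all(out$target_volume >= 0),
            all(out$lambda_surface >= 0), all(out$target_surface >= 0))
  class(out) <- c("cpm_types", "data.frame")
  out
}

#' Symmetric contact-energy table
#'
#' Builds the (types + Medium) x (types + Medium) matrix of contact energies
#' per unit shared boundary. Lower energy means stronger adhesion. Entries
#' not set default to `default`; the Medium row/column uses label `"Medium"`.
#'
#' @param type_names character vector of cell-type labels (without Medium).
#' @param default energy used for unspecified pairs.
#' @param pairs a data frame or list of `(type_a, type_b, energy)` triples;
#'   symmetry is enforced.
#' @return a symmetric numeric matrix with dimnames including `"Medium"`.
#' @export
contact_table <- function(type_names, default = 16, pairs = NULL) {
  labs <- c("Medium", type_names)
  m <- matrix(default, length(labs), length(labs), dimnames = list(labs, labs))
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- as.character(pairs$type_a[i]); b <- as.character(pairs$type_b[i])
      if (!a %in% labs || !b %in% labs)
        stop("contact pair references unknown type: ", a, "-", b)
      m[a, b] <- m[b, a] <- pairs$energy[i]
    }
  }
  m
}

#' Engine parameters
#'
#' @param temperature fluctuation temperature `T` (default 20).
#' @param energy_threshold acceptance threshold `h` (default 0).
#' @param neighbor_order contact/surface interaction shell, 1-3 (default 3).
#' @return a list of class `cpm_engine_params`.
#' @export
cpm_engine_params <- function(temperature = 20, energy_threshold = 0,
                              neighbor_order = 3) {
  stopifnot(temperature > 0, neighbor_order %in% 1:3)
  structure(list(temperature = temperature,
                 energy_threshold = energy_threshold,
                 neighbor_order = as.integer(neighbor_order)),
            class = "cpm_engine_params")
}

empty_cpm_links <- function() {
  data.frame(cell_a = integer(), cell_b = integer(), strength = numeric(),
             target_length = numeric(), max_length = numeric(),
             internal = logical(), class_id = integer())
}

empty_link_classes <- function() {
  data.frame(class_id = integer(), type_a = integer(), type_b = integer(),
             strength = numeric(), target_length = numeric(),
             max_length = numeric())
}

#' Construct a Cellular Potts state
#'
#' @param lattice integer matrix (rows = y, columns = x) of pixel owners;
#'   0 is Medium, cells are numbered `1:max(lattice)` contiguously. The
#'   lattice is periodic in x and closed in y.
#' @param cell_type integer vector, type index (row of `types`) per cell id.
#' @param types a [cpm_types()] table.
#' @param contacts external contact-energy matrix from [contact_table()].
#' @param contacts_internal contact energies between compartments of the same
#'   composite cell; defaults to `contacts`.
#' @param composite integer vector, composite-cell id per cell (0 = not a
#'   compartment).
#' @param links focal-point-plasticity links: data frame with columns
#'   `cell_a`, `cell_b`, `strength`, `target_length`, `max_length`,
#'   `internal`, `class_id`. Internal links never break; external links break
#'   strictly beyond `max_length`.
#' @param reform_classes link classes re-formed on contact: data frame with
#'   `class_id`, `type_a`, `type_b` (type indices), `strength`,
#'   `target_length`, `max_length`.
#' @param engine a [cpm_engine_params()] object.
#' @return an object of class `cpm_state` with cached per-cell `volume`,
#'   `surface`, `com_x`, `com_y` and an `mcs` counter.
#' @export
cpm_state <- function(lattice, cell_type, types, contacts,
                      contacts_internal = contacts,
                      composite = integer(length(cell_type)),
                      links = empty_cpm_links(),
                      reform_classes = empty_link_classes(),
                      engine = cpm_engine_params()) {
  lattice <- as.matrix(lattice)
  storage.mode(lattice) <- "integer"
  ncell <- length(cell_type)
  stopifnot(max(lattice) <= ncell, min(lattice) >= 0,
            all(cell_type >= 1), all(cell_type <= nrow(types)),
            length(composite) == ncell)
  if (!identical(dim(contacts), dim(contacts_internal)))
    stop("internal and external contact tables must have identical shape")
  nlab <- nrow(types) + 1L
  if (nrow(contacts) != nlab)
    stop("contact table must cover Medium plus every type")
  st <- list(
    lattice = lattice,
    cell_type = as.integer(cell_type),
    composite = as.integer(composite),
    types = types,
    contacts = unname(contacts),
    contacts_internal = unname(contacts_internal),
    links = links,
    reform_classes = reform_classes,
    engine = engine,
    mcs = 0L
  )
  class(st) <- "cpm_state"
  refresh_caches(st)
}

refresh_caches <- function(state) {
  cc <- cpp_caches(state$lattice, state$cell_type, state$composite,
                   as.list(state$types), state$contacts,
                   state$contacts_internal, as.list(state$links),
                   state$engine$neighbor_order)
  state$volume <- cc$volume
  state$surface <- cc$surface
  state$com_x <- cc$com_x
  state$com_y <- cc$com_y
  state
}

#' Total system energy
#'
#' Evaluates the full energy of a configuration: volume and surface penalty
#' terms, contact energies summed over all unlike-owner neighbour pixel pairs
#' up to the configured neighbour order, and the spring-link term
#' `sum strength * (l - target_length)^2` with link length `l` the
#' centre-of-mass distance under the minimal-image convention in x.
#' Migration forces are not part of the Hamiltonian; they bias acceptance via
#' [external_force_bias()].
#'
#' @param state a [cpm_state()].
#' @return the scalar energy.
#' @export
cpm_hamiltonian <- function(state) {
  cpp_hamiltonian(state$lattice, state$cell_type, state$composite,
                  as.list(state$types), state$contacts,
                  state$contacts_internal, as.list(state$links),
                  state$engine$neighbor_order)
}

#' Incremental energy change of one pixel copy
#'
#' Energy change of copying the owner of `source` onto the pixel at `target`,
#' computed locally from the caches; it equals the full-recompute difference
#' exactly. Returned with the migration-force bias reported separately.
#'
#' @param state a [cpm_state()].
#' @param source,target integer `c(x, y)` pixel coordinates (1-based).
#' @return named numeric vector `c(core, force)`; `core` is the Hamiltonian
#'   difference, `force` the external-potential bias. A same-owner copy
#'   attempt returns zeros.
#' @export
cpm_delta_J <- function(state, source, target) {
  stopifnot(length(source) == 2, length(target) == 2)
  cpp_delta_J(state$lattice, state$cell_type, state$composite,
              as.list(state$types), state$contacts, state$contacts_internal,
              as.list(state$links), state$engine$neighbor_order,
              source[1] - 1L, source[2] - 1L, target[1] - 1L, target[2] - 1L)
}

#' Pixel-copy acceptance probability
#'
#' Returns 1 when `delta <= h` and `exp(-(delta - h) / T)` otherwise, with
#' `h` the energy threshold and `T` the fluctuation temperature.
#'
#' @param delta energy change (vectorized).
#' @param engine a [cpm_engine_params()] object.
#' @return acceptance probabilities in (0, 1].
#' @export
accept_probability <- function(delta, engine = cpm_engine_params()) {
  stopifnot(engine$temperature > 0)
  ifelse(delta <= engine$energy_threshold, 1,
         exp(-(delta - engine$energy_threshold) / engine$temperature))
}

#' Square-lattice neighbour shells
#'
#' Offsets of the interaction shells: order 1 the 4 axial offsets, order 2
#' adds the 4 diagonals (8 total), order 3 adds the 4 distance-2 axial
#' offsets (12 total).
#'
#' @param order integer in 1:3.
#' @return integer matrix with columns `dx`, `dy`.
#' @export
neighbor_offsets <- function(order) {
  if (!order %in% 1:3) stop("neighbor order must be 1, 2 or 3")
  sh <- rbind(
    cbind(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1)),
    cbind(dx = c(1, 1, -1, -1), dy = c(1, -1, 1, -1)),
    cbind(dx = c(2, -2, 0, 0), dy = c(0, 0, 2, -2))
  )
  sh[seq_len(4 * order), , drop = FALSE]
}

#' Run Monte Carlo steps
#'
#' Performs `n_mcs` Monte Carlo steps. One step is `width * height` pixel-copy
#' attempts: a random lattice pixel is picked as the copy target, a random
#' order-1 neighbour as the source; attempts between equal owners, involving
#' a frozen type, crossing the closed y-boundary, or annihilating a cell's
#' last pixel are skipped; otherwise the copy is accepted with
#' [accept_probability()] applied to the incremental energy change plus the
#' migration-force bias. Link bookkeeping ([update_fpp_links()]) runs at the
#' end of every step. Randomness comes from the R generator, so runs are
#' reproducible under [set.seed()].
#'
#' @param state a [cpm_state()].
#' @param n_mcs number of Monte Carlo steps.
#' @return the updated `cpm_state` (attempt/acceptance counters in
#'   `attr(, "acceptance")`).
#' @export
cpm_step <- function(state, n_mcs = 1L) {
  if (n_mcs < 1) return(state)
  out <- cpp_run_mcs(state$lattice, state$cell_type, state$composite,
                     as.list(state$types), state$contacts,
                     state$contacts_internal, as.list(state$links),
                     as.list(state$reform_classes),
                     state$engine$temperature, state$engine$energy_threshold,
                     state$engine$neighbor_order, as.integer(n_mcs))
  state$lattice <- out$lattice
  state$links <- out$links
  state$mcs <- state$mcs + as.integer(n_mcs)
  state <- refresh_caches(state)
  attr(state, "acceptance") <- c(attempts = out$attempts,
                                 accepted = out$accepted)
  state
}

#' Refresh focal-point-plasticity links
#'
#' Breaks external links stretched strictly beyond their maximum length
#' (internal compartment links never break) and re-forms links of each
#' reformable class between unlinked eligible cell pairs that currently share
#' an order-1 lattice boundary.
#'
#' @param state a [cpm_state()].
#' @return the updated `cpm_state`.
#' @export
update_fpp_links <- function(state) {
  out <- cpp_update_links(state$lattice, state$cell_type, state$composite,
                          as.list(state$types), state$contacts,
                          state$contacts_internal, as.list(state$links),
                          as.list(state$reform_classes),
                          state$engine$neighbor_order)
  state$links <- out$links
  state
}

#' External-potential bias of a pixel copy
#'
#' Adjusts an energy delta for the centre-of-mass x-displacement a copy
#' imparts to a cell: `delta + migration_force_x * displacement_x`. Negative
#' coefficients therefore favour +x motion.
#'
#' @param delta unadjusted energy change.
#' @param migration_force_x the cell type's force coefficient.
#' @param displacement_x signed centre-of-mass x-shift (pixels).
#' @return the adjusted delta.
#' @export
external_force_bias <- function(delta, migration_force_x, displacement_x) {
  delta + migration_force_x * displacement_x
}

#' @export
print.cpm_state <- function(x, ...) {
  cat("<cpm_state>", ncol(x$lattice), "x", nrow(x$lattice), "lattice |",
      length(x$cell_type), "cells |", nrow(x$links), "links | MCS", x$mcs, "\n")
  tb <- table(x$types$type_name[x$cell_type])
  cat(" ", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Cell table of a CPM state
#'
#' @param state a [cpm_state()].
#' @return data frame with `cell_id`, `type`, `composite_id`, `volume`,
#'   `surface`, `com_x`, `com_y`.
#' @export
cpm_cells <- function(state) {
  data.frame(
    cell_id = seq_along(state$cell_type),
    type = state$types$type_name[state$cell_type],
    composite_id = state$composite,
    volume = state$volume,
    surface = state$surface,
    com_x = state$com_x,
    com_y = state$com_y,
    stringsAsFactors = FALSE
  )
}
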