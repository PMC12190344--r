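# Cluster/rosette detection and kinematic readouts for both simulators.

#' Cluster count in the agent-based model
#'
#' Connected components of density-flagged agents, two flagged agents being
#' adjacent when they lie within `density_radius` of each other. Components
#' smaller than `min_cluster_size` are excluded. [density_classify()] must
#' have run on the state (it runs at the end of every [step_abm()]).
#'
#' @param state an `abm_state`.
#' @param params an [abm_params()] object.
#' @return an object of class `rosette_report`: list with `time`, `clusters`
#'   (list of `members`, `size`, `centroid`, ordered by centroid x),
#'   `n_rosettes`, `leading_edge_x`, `trailing_edge_x`, `primordium_length`.
#' @export
abm_cluster_count <- function(state, params) {
  ag <- state$agents
  fl <- which(ag$flagged_dense)
  clusters <- list()
  if (length(fl) >= 1) {
    pos <- cbind(ag$x[fl], ag$y[fl])
    if (length(fl) == 1) {
      memb <- list(1L)
    } else {
      d <- as.matrix(stats::dist(pos))
      adj <- which(d <= params$density_radius & upper.tri(d), arr.ind = TRUE)
      g <- igraph::make_empty_graph(n = length(fl), directed = FALSE)
      if (nrow(adj))
        g <- igraph::add_edges(g, as.vector(t(adj)))
      comp <- igraph::components(g)$membership
      memb <- split(seq_along(fl), comp)
    }
    memb <- memb[lengths(memb) >= params$min_cluster_size]
    clusters <- lapply(memb, function(ix) {
      list(members = ag$id[fl[ix]], size = length(ix),
           centroid = c(x = mean(pos[ix, 1]), y = mean(pos[ix, 2])))
    })
    ord <- order(vapply(clusters, function(cl) cl$centroid[["x"]], 0))
    clusters <- unname(clusters[ord])
  }
  ext <- primordium_extent(state)
  structure(list(
    time = state$step_index,
    clusters = clusters,
    n_rosettes = length(clusters),
    leading_edge_x = ext[["leading_edge_x"]],
    trailing_edge_x = ext[["trailing_edge_x"]],
    primordium_length = ext[["length"]]
  ), class = "rosette_report")
}

#' Rosette detection in the Cellular Potts model
#'
#' Connected components of apical (`fgfapi`) compartments under the relation
#' "shares an order-1 lattice boundary OR is joined by an active
#' apical-apical link"; components with at least `min_apical_members` count
#' as rosettes.
#'
#' @param state a [cpm_state()] containing a type named `fgfapi`.
#' @param min_apical_members minimum component size counted as a rosette.
#' @return a `rosette_report` (see [abm_cluster_count()]); `time` is the MCS
#'   index, cluster members are apical cell ids.
#' @export
detect_rosettes_cpm <- function(state, min_apical_members = 3L) {
  api_type <- match("fgfapi", state$types$type_name)
  if (is.na(api_type)) stop("state has no 'fgfapi' type")
  api <- which(state$cell_type == api_type)
  clusters <- list()
  if (length(api)) {
    adj <- cpp_adjacent_cells(state$lattice)
    keep <- adj[, 1] %in% api & adj[, 2] %in% api
    edges <- adj[keep, , drop = FALSE]
    lk <- state$links
    if (nrow(lk)) {
      keepl <- lk$cell_a %in% api & lk$cell_b %in% api & !lk$internal
      edges <- rbind(edges, cbind(lk$cell_a[keepl], lk$cell_b[keepl]))
    }
    g <- igraph::make_empty_graph(n = length(api), directed = FALSE)
    if (nrow(edges)) {
      ia <- match(edges[, 1], api)
      ib <- match(edges[, 2], api)
      g <- igraph::add_edges(g, as.vector(rbind(ia, ib)))
    }
    comp <- igraph::components(g)$membership
    memb <- split(seq_along(api), comp)
    memb <- memb[lengths(memb) >= min_apical_members]
    clusters <- lapply(memb, function(jx) {
      ids <- api[jx]
      list(members = ids, size = length(ids),
           centroid = c(x = circ_mean_x(state$com_x[ids], ncol(state$lattice)),
                        y = mean(state$com_y[ids])))
    })
    ord <- order(vapply(clusters, function(cl) cl$centroid[["x"]], 0))
    clusters <- unname(clusters[ord])
  }
  ext <- primordium_extent(state)
  structure(list(
    time = state$mcs,
    clusters = clusters,
    n_rosettes = length(clusters),
    leading_edge_x = ext[["leading_edge_x"]],
    trailing_edge_x = ext[["trailing_edge_x"]],
    primordium_length = ext[["length"]]
  ), class = "rosette_report")
}

# circular-aware mean of x positions on a lattice of width nx
circ_mean_x <- function(x, nx) {
  if (!length(x)) return(NA_real_)
  ref <- x[1]
  d <- x - ref
  d <- d - nx * round(d / nx)
  m <- ref + mean(d)
  m - nx * floor(m / nx)
}

#' Composite-cell contiguity health check
#'
#' Fraction of composite (multi-compartment) cells whose compartments are
#' still mutually contiguous on the lattice (connected through shared
#' order-1 boundaries). Compartments can drift apart during strong tissue
#' rearrangement — for example apical ends converging into a rosette focus —
#' so a fraction below 1 is reported as a model-health warning rather than
#' an error.
#'
#' @param state a [cpm_state()].
#' @param warn emit a warning when some composite is fragmented.
#' @return the contiguous fraction, with attribute `fragmented` listing the
#'   affected composite ids.
#' @export
composite_health <- function(state, warn = TRUE) {
  comps <- setdiff(unique(state$composite), 0L)
  if (!length(comps)) return(structure(1, fragmented = integer(0)))
  adj <- cpp_adjacent_cells(state$lattice)
  key <- c(paste(adj[, 1], adj[, 2]), paste(adj[, 2], adj[, 1]))
  ok <- vapply(comps, function(comp) {
    m <- which(state$composite == comp)
    g <- igraph::make_empty_graph(length(m), directed = FALSE)
    pr <- utils::combn(length(m), 2)
    for (j in seq_len(ncol(pr))) {
      if (paste(m[pr[1, j]], m[pr[2, j]]) %in% key)
        g <- igraph::add_edges(g, pr[, j])
    }
    igraph::components(g)$no == 1
  }, TRUE)
  frag <- comps[!ok]
  if (warn && length(frag))
    warning(length(frag), " of ", length(comps),
            " composite cells have non-contiguous compartments",
            call. = FALSE)
  structure(mean(ok), fragmented = frag)
}

#' Primordium extent
#'
#' Leading and trailing edge and length of the primordium. For the ABM these
#' are the extremal agent x-positions, DEPOSITERs excluded; for the CPM the
#' extremal x of pixels owned by primordium types (Wnt, sheath, and the three
#' FGF compartments), unwrapped across the periodic x-boundary by placing the
#' cut in the widest unoccupied gap of x-columns.
#'
#' @param state an `abm_state` or [cpm_state()].
#' @return named numeric vector `c(leading_edge_x, trailing_edge_x, length)`.
#' @export
primordium_extent <- function(state) {
  UseMethod("primordium_extent")
}

#' @export
primordium_extent.abm_state <- function(state) {
  x <- state$agents$x[state$agents$breed != "DEPOSITER"]
  if (!length(x)) x <- state$agents$x
  if (!length(x)) stop("empty primordium")
  c(leading_edge_x = max(x), trailing_edge_x = min(x),
    length = max(x) - min(x))
}

PRIMORDIUM_TYPES <- c("wnt", "fgfapi", "fgflat", "fgfbas", "sheath")

#' @export
primordium_extent.cpm_state <- function(state) {
  tix <- which(state$types$type_name %in% PRIMORDIUM_TYPES)
  if (!length(tix)) stop("state has no primordium cell types")
  cells <- which(state$cell_type %in% tix)
  if (!length(cells)) stop("empty primordium")
  nx <- ncol(state$lattice)
  occ_cols <- unique(((which(matrix(state$lattice %in% cells,
                                    nrow(state$lattice))) - 1L) %/%
                        nrow(state$lattice)))
  occ <- rep(FALSE, nx)
  occ[occ_cols + 1L] <- TRUE
  if (all(occ)) {
    return(c(leading_edge_x = nx, trailing_edge_x = 1, length = nx - 1))
  }
  # widest circular run of unoccupied columns -> cut point
  runs <- rle(c(occ, occ))
  best_len <- 0L; best_end <- 0L
  pos <- 0L
  for (i in seq_along(runs$lengths)) {
    pos <- pos + runs$lengths[i]
    if (!runs$values[i] && runs$lengths[i] > best_len && pos <= 2L * nx) {
      best_len <- min(runs$lengths[i], nx)
      best_end <- pos
    }
  }
  cut <- ((best_end - 1L) %% nx) + 1L   # last column of the widest gap
  shifted <- ((which(occ) - cut - 1L) %% nx) + 1L
  lead <- max(shifted); trail <- min(shifted)
  c(leading_edge_x = ((cut + lead - 1L) %% nx) + 1L,
    trailing_edge_x = ((cut + trail - 1L) %% nx) + 1L,
    length = lead - trail)
}

#' Edge velocities from a report series
#'
#' Centered finite-difference velocities of the leading and trailing edges
#' over a time-ordered series of rosette reports.
#'
#' @param reports list of `rosette_report`s, time-ordered.
#' @param window half-width (in report indices) of the centered difference
#'   (default 1: nearest neighbours).
#' @return data frame with `time`, `v_leading`, `v_trailing` (NA where the
#'   window does not fit).
#' @export
edge_velocity_series <- function(reports, window = 1L) {
  n <- length(reports)
  if (n < 2) stop("need at least two reports")
  if (2L * window >= n) stop("window larger than series")
  t <- vapply(reports, `[[`, 0, "time")
  le <- vapply(reports, `[[`, 0, "leading_edge_x")
  tr <- vapply(reports, `[[`, 0, "trailing_edge_x")
  i <- seq_len(n)
  lo <- pmax(i - window, 1L); hi <- pmin(i + window, n)
  valid <- (i - window >= 1L) & (i + window <= n)
  dt <- t[hi] - t[lo]
  out <- data.frame(
    time = t,
    v_leading = ifelse(valid, (le[hi] - le[lo]) / dt, NA_real_),
    v_trailing = ifelse(valid, (tr[hi] - tr[lo]) / dt, NA_real_)
  )
  out
}

#' @export
print.rosette_report <- function(x, ...) {
  cat("<rosette_report> t =", x$time, "|", x$n_rosettes, "rosette(s)",
      if (x$n_rosettes) paste0("(sizes ",
        paste(vapply(x$clusters, `[[`, 0L, "size"), collapse = ", "), ")"),
      "| length", round(x$primordium_length, 2), "\n")
  invisible(x)
}

#' Flatten a report series to a data frame
#'
#' @param reports list of `rosette_report`s.
#' @return data frame with `time`, `n_rosettes`, `sizes` (semicolon-joined),
#'   `leading_edge_x`, `trailing_edge_x`, `primordium_length`.
#' @export
report_series <- function(reports) {
  data.frame(
    time = vapply(reports, `[[`, 0, "time"),
    n_rosettes = vapply(reports, `[[`, 0L, "n_rosettes"),
    sizes = vapply(reports, function(r)
      paste(vapply(r$clusters, `[[`, 0L, "size"), collapse = ";"), ""),
    leading_edge_x = vapply(reports, `[[`, 0, "leading_edge_x"),
    trailing_edge_x = vapply(reports, `[[`, 0, "trailing_edge_x"),
    primordium_length = vapply(reports, `[[`, 0, "primordium_length"),
    stringsAsFactors = FALSE
  )
}
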