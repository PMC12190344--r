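# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain R, exhaustive enumeration) so they
# share no code path with the package internals they check.

# full Hamiltonian by exhaustive enumeration over all pixels and pairs
bf_hamiltonian <- function(state) {
  lat <- state$lattice
  ny <- nrow(lat); nx <- ncol(lat)
  types <- state$types
  ncell <- length(state$cell_type)

  vol <- tabulate(lat[lat > 0], nbins = ncell)
  E <- 0
  surf <- numeric(ncell)
  order <- state$engine$neighbor_order
  offs <- neighbor_offsets(order)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      c1 <- lat[y, x]
      # surface: order-1 unlike pairs per cell
      for (k in 1:4) {
        dx <- c(1, -1, 0, 0)[k]; dy <- c(0, 0, 1, -1)[k]
        qy <- y + dy
        if (qy < 1 || qy > ny) next
        qx <- ((x - 1 + dx) %% nx) + 1
        if (c1 > 0 && lat[qy, qx] != c1) surf[c1] <- surf[c1] + 1
      }
      # contact: each unordered pair once
      for (k in seq_len(nrow(offs))) {
        dx <- offs[k, 1]; dy <- offs[k, 2]
        if (!(dy > 0 || (dy == 0 && dx > 0))) next
        qy <- y + dy
        if (qy < 1 || qy > ny) next
        qx <- ((x - 1 + dx) %% nx) + 1
        c2 <- lat[qy, qx]
        if (c1 == c2) next
        t1 <- if (c1 == 0) 1L else state$cell_type[c1] + 1L
        t2 <- if (c2 == 0) 1L else state$cell_type[c2] + 1L
        same_comp <- c1 > 0 && c2 > 0 && state$composite[c1] != 0 &&
          state$composite[c1] == state$composite[c2]
        E <- E + if (same_comp) state$contacts_internal[t1, t2]
                 else state$contacts[t1, t2]
      }
    }
  }
  for (c in seq_len(ncell)) {
    t <- state$cell_type[c]
    E <- E + types$lambda_volume[t] * (vol[c] - types$target_volume[t])^2
    E <- E + types$lambda_surface[t] * (surf[c] - types$target_surface[t])^2
  }
  # links: centre-of-mass distance, minimal image in x
  coms <- bf_coms(lat, ncell)
  lk <- state$links
  if (nrow(lk)) {
    for (i in seq_len(nrow(lk))) {
      a <- lk$cell_a[i]; b <- lk$cell_b[i]
      dx <- coms[a, 1] - coms[b, 1]
      dx <- dx - nx * round(dx / nx)
      l <- sqrt(dx^2 + (coms[a, 2] - coms[b, 2])^2)
      E <- E + lk$strength[i] * (l - lk$target_length[i])^2
    }
  }
  E
}

# centres of mass with x unwrapped relative to each cell's circular mean
bf_coms <- function(lat, ncell) {
  nx <- ncol(lat)
  out <- matrix(NA_real_, ncell, 2)
  for (c in seq_len(ncell)) {
    idx <- which(lat == c, arr.ind = TRUE)
    if (!nrow(idx)) next
    xs <- idx[, 2] - 1
    ang <- 2 * pi * xs / nx
    ref <- atan2(mean(sin(ang)), mean(cos(ang))) * nx / (2 * pi)
    xs <- ref + ((xs - ref + nx / 2) %% nx) - nx / 2
    out[c, ] <- c(mean(xs), mean(idx[, 1] - 1))
  }
  out
}

# random small scene with compact (rectangular, possibly x-wrapping) cells
random_compact_scene <- function(ny = 14, nx = 20, ncell = 6,
                                 with_links = TRUE, order = NULL) {
  repeat {
    lat <- matrix(0L, ny, nx)
    for (c in seq_len(ncell)) {
      w <- sample(2:5, 1); h <- sample(2:5, 1)
      x0 <- sample(nx, 1); y0 <- sample(ny - h, 1)
      xs <- ((x0:(x0 + w - 1) - 1) %% nx) + 1
      lat[y0:(y0 + h - 1), xs] <- c
    }
    if (all(seq_len(ncell) %in% lat)) break
  }
  types <- cpm_types(c("a", "b"),
                     lambda_volume = c(1.5, 2), target_volume = c(10, 20),
                     lambda_surface = c(0.4, 0.2), target_surface = c(12, 20))
  ct <- contact_table(c("a", "b"), default = 0, pairs = data.frame(
    type_a = c("a", "a", "b", "a", "b"),
    type_b = c("a", "b", "b", "Medium", "Medium"),
    energy = c(3, 7, 2, 11, 13)))
  cti <- contact_table(c("a", "b"), default = 1)
  links <- if (with_links) data.frame(
    cell_a = c(1L, 2L, 4L), cell_b = c(2L, 3L, 6L),
    strength = c(2, 1, 3), target_length = c(3, 5, 2),
    max_length = c(100, 100, 100), internal = c(TRUE, FALSE, FALSE),
    class_id = 0L) else NULL
  args <- list(lattice = lat, cell_type = rep(1:2, length.out = ncell),
               types = types, contacts = ct, contacts_internal = cti,
               composite = c(1L, 1L, rep(0L, ncell - 2)),
               engine = cpm_engine_params(
                 20, 0, if (is.null(order)) sample(1:3, 1) else order))
  if (!is.null(links)) args$links <- links
  do.call(cpm_state, args)
}

# draw a valid random copy attempt (source, target, owners differ, no
# annihilation); returns NULL if the draw is unusable
random_attempt <- function(state) {
  ny <- nrow(state$lattice); nx <- ncol(state$lattice)
  tx <- sample(nx, 1); ty <- sample(ny, 1)
  off <- neighbor_offsets(1)[sample(4, 1), ]
  sy <- ty + off[2]
  if (sy < 1 || sy > ny) return(NULL)
  sx <- ((tx - 1 + off[1]) %% nx) + 1
  old <- state$lattice[ty, tx]; new <- state$lattice[sy, sx]
  if (old == new) return(NULL)
  if (old > 0 && state$volume[old] <= 1) return(NULL)
  list(source = c(sx, sy), target = c(tx, ty))
}

# union-find connected components over an explicit pairwise-distance graph
bf_components <- function(pos, radius) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# brute-force neighbour counts within a radius
bf_neighbor_counts <- function(pos, radius) {
  n <- nrow(pos)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius)
        counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# modal value of an integer vector (ties resolved to the smallest)
modal <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}
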