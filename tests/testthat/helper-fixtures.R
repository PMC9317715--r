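# Fixtures built in code: straight labeled tubes, random connected masks,
# and an independent shortest-path oracle on an explicit voxel edge list.

# straight 1-voxel-thick tube along x with head/body/tail labels assigned
# by position fraction
make_tube <- function(len = 12, fractions = c(0.40, 0.33, 0.26),
                      thick = 1L) {
  fractions <- fractions / sum(fractions)
  d <- c(len, thick, thick)
  mask <- array(TRUE, d)
  s <- (seq_len(len) - 1) / (len - 1)
  lab1 <- ifelse(s < fractions[1], 1L,
                 ifelse(s < fractions[1] + fractions[2], 2L, 3L))
  labels <- array(rep(lab1, thick * thick), dim = d)
  list(mask = mask, labels = labels, frac = fractions)
}

# random 26-connected mask inside a dmax^3 grid: a 6-connected random walk
# dilated by occasional small balls (connected by construction)
rand_connected_mask <- function(dmax = 12, steps = 40) {
  d <- rep(dmax, 3)
  mask <- array(FALSE, d)
  pos <- sample(3:(dmax - 2), 3, replace = TRUE)
  mask[pos[1], pos[2], pos[3]] <- TRUE
  moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(steps)) {
    pos2 <- pos + moves[sample.int(6, 1), ]
    if (any(pos2 < 1) || any(pos2 > dmax)) next
    pos <- pos2
    mask[pos[1], pos[2], pos[3]] <- TRUE
    if (runif(1) < 0.15) {
      lo <- pmax(pos - 1, 1); hi <- pmin(pos + 1, dmax)
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    }
  }
  mask
}

# independent single-source shortest-path oracle: explicit edge list over
# mask voxels + igraph Dijkstra (never touches the package's C++ path)
oracle_distance <- function(mask, source, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  vox <- which(mask)
  vid <- integer(prod(d))
  vid[vox] <- seq_along(vox)
  co <- arrayInd(vox, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- sweep(co, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    inmask <- mask[nl]
    from <- vid[vox[ok]][inmask]
    to <- vid[nl][inmask]
    w <- sqrt(sum((o * spacing)^2))
    ef <- c(ef, from); et <- c(et, to); ew <- c(ew, rep(w, length(from)))
  }
  g <- igraph::make_graph(rbind(ef, et), n = length(vox), directed = FALSE)
  src_lin <- if (length(source) == 3L) {
    source[1] + d[1] * (source[2] - 1L) + d[1] * d[2] * (source[3] - 1L)
  } else source
  dv <- igraph::distances(g, v = vid[src_lin], weights = ew)[1, ]
  out <- array(Inf, d)
  out[vox] <- dv
  out
}

# small labeled phantom set used by several test files
desk_phantoms <- function(n = 8, seed = 20260924) {
  ds <- generate_phantom_dataset(n, phantom_spec(shape = c(32, 32, 32),
                                                 preset = "J"),
                                 seed = seed)
  ds$cases
}
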