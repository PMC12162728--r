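# Shared lazy fixtures: reduced-scale reference scaffolds are expensive, so
# they are generated once per session and memoised here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- maker()
  .fixture_env[[key]]
}

# candidate pool of the reference configuration for a given rng seed
reference_candidates <- function(seed = 1) {
  fixture(paste0("cand", seed), function() {
    cfg <- design_config(rng_seed = seed)
    seeds <- sample_seeds(cfg)
    build_voronoi_edges(seeds, cfg$domain_edge_length)
  })
}

# pruned selected skeleton (isotropic or oriented) for the reference
# config, using the pipeline's listing-level selection
reference_graph <- function(beta = "isotropic", seed = 1) {
  key <- paste0("graph", format(beta), seed)
  fixture(key, function() {
    cand <- reference_candidates(seed)
    set.seed(seed * 1000 + if (identical(beta, "isotropic")) 99 else beta)
    idx <- if (identical(beta, "isotropic"))
      anisovor:::select_isotropic_incidence(cand, 5000)
    else anisovor:::select_anisotropic_incidence(cand, beta, 5000, 0.7)
    prune_disconnected(anisovor:::subset_edges(cand, idx))
  })
}

# reduced-scale scaffold volume
reference_volume <- function(phi, beta = "isotropic", seed = 1,
                             scale = 0.1) {
  key <- paste0("vol", phi, format(beta), seed, scale)
  fixture(key, function() {
    cfg <- design_config(rng_seed = seed)
    generate_scaffold(cfg, phi, scale = scale,
                      graph = reference_graph(beta, seed))
  })
}

# brute-force voxel rasterization oracle: exhaustive point-to-segment scan
raster_oracle <- function(graph, grid_n, thickness) {
  pitch <- graph$L / grid_n
  occ <- array(0L, rep(grid_n, 3))
  r2 <- (thickness / 2)^2
  for (k in seq_len(grid_n)) for (j in seq_len(grid_n)) for (i in seq_len(grid_n)) {
    p <- (c(i, j, k) - 0.5) * pitch
    hit <- FALSE
    for (e in seq_len(nrow(graph$edges))) {
      a <- graph$nodes[graph$edges[e, 1], ]
      b <- graph$nodes[graph$edges[e, 2], ]
      d <- b - a
      l2 <- sum(d^2)
      t <- if (l2 > 0) max(0, min(1, sum((p - a) * d) / l2)) else 0
      q <- a + t * d
      if (sum((q - p)^2) <= r2) { hit <- TRUE; break }
    }
    if (hit) occ[i, j, k] <- 1L
  }
  occ
}

# independent Voronoi oracle for tiny seed sets: vertices as points
# equidistant from 4 seeds (circumcentres of Delaunay tetrahedra), edges as
# vertex pairs sharing 3 nearest seeds
voronoi_oracle_edges <- function(seeds, L, tol = 1e-7) {
  n <- nrow(seeds)
  verts <- list()
  vsets <- list()
  combs <- utils::combn(n, 4)
  for (q in seq_len(ncol(combs))) {
    id <- combs[, q]
    p <- seeds[id, ]
    # solve |x - p1|^2 = |x - pk|^2, k = 2..4
    A <- 2 * (p[2:4, ] - matrix(p[1, ], 3, 3, byrow = TRUE))
    b <- rowSums(p[2:4, ]^2) - sum(p[1, ]^2)
    if (abs(det(A)) < 1e-10) next
    x <- solve(A, b)
    d <- sqrt(colSums((t(seeds) - x)^2))
    if (min(d) < d[id[1]] - tol * L) next  # some other seed strictly closer
    key <- paste(round(x / (tol * L)), collapse = "_")
    if (is.null(vsets[[key]])) {
      verts[[key]] <- x
      vsets[[key]] <- sort(which(d <= min(d) + tol * L))
    }
  }
  keys <- names(verts)
  edges <- list()
  if (length(keys) >= 2) {
    for (a in seq_along(keys)) for (b in seq_along(keys)) {
      if (a >= b) next
      shared <- intersect(vsets[[keys[a]]], vsets[[keys[b]]])
      if (length(shared) >= 3)
        edges[[length(edges) + 1]] <- c(a, b)
    }
  }
  list(vertices = do.call(rbind, verts[keys]),
       edges = if (length(edges)) do.call(rbind, edges) else
         matrix(integer(0), 0, 2))
}

# permute the axes of a Voigt stiffness matrix (x,y,z relabelling)
permute_voigt <- function(C, perm) {
  vi <- matrix(c(1, 6, 5, 6, 2, 4, 5, 4, 3), 3, 3)
  Cp <- matrix(0, 6, 6)
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (p in 1:6) for (q in 1:6) {
    ij <- pairs[[p]]; kl <- pairs[[q]]
    Cp[p, q] <- C[vi[perm[ij[1]], perm[ij[2]]], vi[perm[kl[1]], perm[kl[2]]]]
  }
  Cp
}
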