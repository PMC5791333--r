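# Independent dense linear-algebra oracle for the steady-state
# reaction-diffusion balance  0 = D lap(C) + S - k C  on small grids:
# assembles the 5-point Laplacian with zero-flux boundaries row by row and
# solves with base R's dense solver. Deliberately shares no code with the
# package's Gauss-Seidel kernel.
dense_rd_solve <- function(grid, D, S, k) {
  nx <- grid$nx; ny <- grid$ny; n <- nx * ny
  stopifnot(n <= 1000)
  h2 <- grid$h^2
  A <- matrix(0, n, n)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      i <- (y - 1) * nx + x
      nb <- c(if (x > 1) i - 1, if (x < nx) i + 1,
              if (y > 1) i - nx, if (y < ny) i + nx)
      A[i, i] <- -D * length(nb) / h2 - k[i]
      for (j in nb) A[i, j] <- D / h2
    }
  }
  as.vector(solve(A, -S))
}

# small helper: site index on a grid (duplicated on purpose so oracle-side
# bookkeeping does not depend on package internals)
sidx <- function(grid, x, y) (y - 1L) * grid$nx + x

# hand-built network whose horizontal segments cover every lattice row, so
# every site is a perfused source; used across module tests
full_perfusion_net <- function(grid, radius = 5) {
  segs <- do.call(rbind, lapply(seq_len(grid$ny), function(y) {
    x <- seq_len(grid$nx - 1L)
    data.frame(i1 = sidx(grid, x, y), i2 = sidx(grid, x + 1L, y),
               radius = radius, type = "pre", sprout = 0L,
               perfusable = TRUE, perfused = TRUE, pressurized = FALSE,
               stringsAsFactors = FALSE)
  }))
  structure(list(grid = grid, segs = segs,
                 tips = data.frame(sprout = integer(), site = integer(),
                                   age = integer(), active = logical()),
                 sprout_sites = list(), next_sprout = 1L),
            class = "tamsim_network")
}
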