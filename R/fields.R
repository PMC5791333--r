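#' @useDynLib tamsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Nondimensional length unit in micrometres. Rates carrying the "(*)" table
# convention are nondimensionalized by the oxygen diffusivity over this
# length scale; 200 um is the oxygen diffusion scale of the lesion models
# this simulator descends from, and makes the 100x100 default grid at
# 20 um/site span the 2 x 2 mm panel.
UNIT_UM <- 200

#' Create a 2D simulation lattice
#'
#' Sites are cell centres on a regular square lattice. `spacing` is the
#' physical site size in micrometres; internally fields are solved on the
#' nondimensional lattice with spacing `spacing / 200` (the 200-um
#' nondimensionalization length of the transport equations).
#'
#' @param nx,ny Site counts (each at least 3).
#' @param spacing Site spacing in micrometres (default 20).
#' @return A `tamsim_grid` object.
#' @export
make_grid <- function(nx, ny, spacing = 20) {
  stopifnot(nx >= 3, ny >= 3, spacing > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 spacing = spacing, h = spacing / UNIT_UM),
            class = "tamsim_grid")
}

#' @export
print.tamsim_grid <- function(x, ...) {
  cat(sprintf("<tamsim_grid %d x %d sites, %.1f um spacing (%.2f x %.2f mm)>\n",
              x$nx, x$ny, x$spacing,
              x$nx * x$spacing / 1000, x$ny * x$spacing / 1000))
  invisible(x)
}

n_sites <- function(grid) grid$nx * grid$ny

# linear site index from 1-based lattice coordinates
site_index <- function(grid, x, y) (y - 1L) * grid$nx + x

site_xy <- function(grid, i) {
  i0 <- i - 1L
  cbind(x = i0 %% grid$nx + 1L, y = i0 %/% grid$nx + 1L)
}

#' Create a scalar field on a grid
#'
#' Holds one real value per lattice site; used for oxygen, cytokines,
#' angiogenic factor, pressure and the tumor volume fraction. If `bounds`
#' is given, values are clamped into it now and after every update made
#' through [set_field_values()].
#'
#' @param grid A [make_grid()] lattice.
#' @param values Numeric vector of length `nx*ny` (recycled scalar allowed).
#' @param name Identifier used in error messages and file exports.
#' @param bounds Optional `c(lo, hi)` clamp.
#' @return A `tamsim_field` object.
#' @export
scalar_field <- function(grid, values = 0, name = "field", bounds = NULL) {
  v <- rep_len(as.numeric(values), n_sites(grid))
  stopifnot(all(is.finite(v)))
  if (!is.null(bounds)) v <- pmin(pmax(v, bounds[1]), bounds[2])
  structure(list(grid = grid, values = v, name = name, bounds = bounds),
            class = "tamsim_field")
}

#' Replace the values of a scalar field, applying its clamp
#' @param field A [scalar_field()].
#' @param values New values (length `nx*ny`).
#' @return The updated field.
#' @export
set_field_values <- function(field, values) {
  v <- as.numeric(values)
  stopifnot(length(v) == n_sites(field$grid))
  if (!is.null(field$bounds))
    v <- pmin(pmax(v, field$bounds[1]), field$bounds[2])
  field$values <- v
  field
}

field_matrix <- function(field) {
  matrix(field$values, nrow = field$grid$nx, ncol = field$grid$ny)
}

#' Reaction terms for a steady-state cytokine mass balance
#'
#' Describes the field-independent part of the balance
#' `0 = D lap(C) + prod (1 - C) 1_source - circ C 1_vessel - decay C`:
#' saturating production on a source mask, wash-out into the circulation on
#' the vessel mask, and first-order decay everywhere.
#'
#' @param diffusivity Nondimensional diffusivity (fraction of the oxygen
#'   diffusivity; oxygen itself is 1).
#' @param production Production rate on the source mask.
#' @param sink_linear First-order decay rate (everywhere).
#' @param vessel_sink Wash-out rate on the vessel mask.
#' @return A `tamsim_reaction` object.
#' @export
reaction_spec <- function(diffusivity, production = 0, sink_linear = 0,
                          vessel_sink = 0) {
  stopifnot(diffusivity > 0, production >= 0, sink_linear >= 0,
            vessel_sink >= 0)
  structure(list(diffusivity = diffusivity, production = production,
                 sink_linear = sink_linear, vessel_sink = vessel_sink),
            class = "tamsim_reaction")
}

#' Solve a steady-state reaction-diffusion balance
#'
#' Solves the discretized mass balance of [reaction_spec()] on the lattice by
#' red-black Gauss-Seidel iteration with zero-flux boundaries, to a maximum
#' residual of `tol`. Values are clamped to `[0, 1]` (concentrations are
#' nondimensional fractions of their vascular/source reference).
#'
#' @param spec A [reaction_spec()].
#' @param source_mask,vessel_mask Logical vectors over sites (or site index
#'   vectors) selecting the production and wash-out sites.
#' @param grid The lattice.
#' @param tol Residual infinity-norm tolerance (default 1e-8).
#' @param max_iter Sweep budget before a divergence error (default 10000).
#' @param init Optional warm-start values.
#' @param name Field name, used in the divergence error.
#' @param omega Successive over-relaxation factor (1 = plain Gauss-Seidel).
#'   `NULL` (default) picks the near-optimal factor from the Jacobi
#'   spectral-radius estimate of the discretized operator: close to 2 for
#'   diffusion-dominated balances, smaller when first-order decay damps the
#'   iteration already.
#' @return A `tamsim_field` with the steady concentration.
#' @export
solve_steady <- function(spec, source_mask, vessel_mask, grid,
                         tol = 1e-8, max_iter = 10000, init = NULL,
                         name = "cytokine", omega = NULL) {
  stopifnot(tol > 0)
  if (is.null(omega))
    omega <- sor_omega(spec$diffusivity, spec$sink_linear, grid)
  n <- n_sites(grid)
  src <- as_mask(source_mask, n)
  ves <- as_mask(vessel_mask, n)
  S <- spec$production * src
  k <- spec$production * src + spec$vessel_sink * ves + spec$sink_linear
  if (is.null(init)) init <- numeric(n)
  sol <- rd_gs_solve_cpp(grid$nx, grid$ny, grid$h, spec$diffusivity,
                         S, k, init, tol, max_iter, omega)
  log_solver(name, sol$iterations)
  if (!sol$converged)
    stop(sprintf("steady-state solve for '%s' did not converge: residual %.3g > %.3g after %d sweeps",
                 name, sol$residual, tol, sol$iterations))
  scalar_field(grid, sol$values, name = name, bounds = c(0, 1))
}

as_mask <- function(m, n) {
  if (is.logical(m)) {
    stopifnot(length(m) == n)
    as.numeric(m)
  } else {
    v <- numeric(n)
    if (length(m)) {
      stopifnot(all(m >= 1), all(m <= n))
      v[as.integer(m)] <- 1
    }
    v
  }
}

#' One-sided / centred finite-difference gradient of a field at a site
#'
#' Returns the one-sided finite-difference estimate (per nondimensional
#' length unit) of the derivative along the lattice axis, using the
#' neighbour on the requested side (`"+x"` forward, `"-x"` backward,
#' likewise in y); at the domain boundary the missing neighbour is treated
#' as zero-flux (derivative 0 in that direction).
#'
#' @param field A [scalar_field()].
#' @param site Linear site index.
#' @param direction One of `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @return The finite-difference slope (0 across the boundary).
#' @export
field_gradient <- function(field, site, direction) {
  g <- field$grid
  xy <- site_xy(g, site)
  x <- xy[1, "x"]; y <- xy[1, "y"]
  nb <- switch(direction,
    "+x" = if (x < g$nx) site + 1L else NA_integer_,
    "-x" = if (x > 1L) site - 1L else NA_integer_,
    "+y" = if (y < g$ny) site + g$nx else NA_integer_,
    "-y" = if (y > 1L) site - g$nx else NA_integer_,
    stop("direction must be one of '+x', '-x', '+y', '-y'"))
  if (is.na(nb)) return(0)
  sgn <- if (direction %in% c("+x", "+y")) 1 else -1
  sgn * (field$values[nb] - field$values[site]) / g$h
}

# Per-site 4-neighbour difference table: matrix n x 4 with value(neighbour) -
# value(site); boundary-missing neighbours get NA. Column order +x,-x,+y,-y.
neighbor_deltas <- function(grid, values) {
  nx <- grid$nx; ny <- grid$ny
  m <- matrix(values, nx, ny)
  dxp <- rbind(m[-1, , drop = FALSE], NA) - m
  dxm <- rbind(NA, m[-nx, , drop = FALSE]) - m
  dyp <- cbind(m[, -1, drop = FALSE], NA) - m
  dym <- cbind(NA, m[, -ny, drop = FALSE]) - m
  cbind(`+x` = as.vector(dxp), `-x` = as.vector(dxm),
        `+y` = as.vector(dyp), `-y` = as.vector(dym))
}

# neighbour site indices in column order +x,-x,+y,-y (NA off-domain)
neighbor_index <- function(grid, sites) {
  nx <- grid$nx; ny <- grid$ny
  xy <- site_xy(grid, sites)
  cbind(`+x` = ifelse(xy[, "x"] < nx, sites + 1L, NA_integer_),
        `-x` = ifelse(xy[, "x"] > 1L, sites - 1L, NA_integer_),
        `+y` = ifelse(xy[, "y"] < ny, sites + nx, NA_integer_),
        `-y` = ifelse(xy[, "y"] > 1L, sites - nx, NA_integer_))
}

#' Explicit diffusion step (zero-flux)
#'
#' Advances `dC/dt = D lap(C)` by one forward-Euler step. Used for
#' conservation diagnostics; the production runs use the steady-state solver.
#'
#' @param field A [scalar_field()].
#' @param D Diffusivity.
#' @param dt Time step (must satisfy `D*dt/h^2 <= 0.25` for stability).
#' @return The updated field (no clamping, so mass is conserved exactly).
#' @export
diffuse_explicit <- function(field, D, dt) {
  g <- field$grid
  d <- neighbor_deltas(g, field$values)
  lap <- rowSums(d, na.rm = TRUE) / g$h^2
  field$values <- field$values + dt * D * lap
  field
}

#' Export a field as a CSV matrix
#'
#' Writes the field row-major with the origin at the lower-left site, one
#' value per lattice site.
#'
#' @param field A [scalar_field()].
#' @param path Output file path.
#' @export
write_field_csv <- function(field, path) {
  m <- t(field_matrix(field))     # rows = y, columns = x
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export a field as a grayscale PNG snapshot
#'
#' @param field A [scalar_field()].
#' @param path Output file path.
#' @param lo,hi Value range mapped to black..white (defaults to the field
#'   bounds, else the data range).
#' @export
write_field_png <- function(field, path, lo = NULL, hi = NULL) {
  rng <- field$bounds %||% range(field$values)
  lo <- lo %||% rng[1]; hi <- hi %||% rng[2]
  if (hi <= lo) hi <- lo + 1
  m <- t(field_matrix(field))
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  png::writePNG((pmin(pmax(m, lo), hi) - lo) / (hi - lo), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# near-optimal red-black SOR factor for 0 = D lap(C) - k C + ...:
# omega_opt = 2 / (1 + sqrt(1 - mu^2)) with mu the Jacobi spectral radius
# (4D/h^2) / (4D/h^2 + k) * cos(pi / n)
sor_omega <- function(D, k_min, grid) {
  c4 <- 4 * D / grid$h^2
  mu <- c4 / (c4 + k_min) * cospi(1 / max(grid$nx, grid$ny))
  min(2 / (1 + sqrt(max(1 - mu^2, 0))), 1.95)
}

# optional solver diagnostics: set options(tamsim.solver_log = new.env())
# to accumulate total sweep counts per field name
log_solver <- function(name, iters) {
  e <- getOption("tamsim.solver_log")
  if (is.null(e)) return(invisible())
  e[[name]] <- (e[[name]] %||% 0) + iters
  invisible()
}
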