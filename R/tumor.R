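#' Create the tumor state
#'
#' The tumor is represented by a volume-fraction field `phi` in `[0, 1]`
#' (1 = fully tumor-occupied site); the tumor-host interface is the `phi =
#' phi_tumor` contour, advanced by conservative upwind advection under the
#' Darcy velocity. Each site carries its current effective viable-oxygen
#' level `Q_OL` (lowered transiently by the M2 growth factor) and its
#' M2-induced extra proliferation rate `lambda_M2`.
#'
#' Region labels are integer-coded: 0 host, 1 proliferating, 2 hypoxic,
#' 3 necrotic.
#'
#' @param grid A [make_grid()] lattice.
#' @param cfg A [default_config()] list.
#' @param center Lesion centre, lattice coordinates `c(x, y)` (defaults to
#'   the domain centre).
#' @param radius_um Initial lesion radius in micrometres.
#' @return A `tamsim_tumor` state list.
#' @export
make_tumor_state <- function(grid, cfg = default_config(),
                             center = NULL,
                             radius_um = cfg$lesion_radius_um) {
  n <- n_sites(grid)
  if (is.null(center)) center <- c((grid$nx + 1) / 2, (grid$ny + 1) / 2)
  xy <- site_xy(grid, seq_len(n))
  d_um <- sqrt((xy[, "x"] - center[1])^2 + (xy[, "y"] - center[2])^2) *
    grid$spacing
  phi <- as.numeric(d_um <= radius_um)
  labels <- ifelse(phi >= cfg$phi_tumor, 1L, 0L)
  structure(list(
    grid = grid,
    phi = phi,
    labels = labels,
    q_ol = rep(cfg$necrosis_threshold, n),
    lambda_m2 = numeric(n),
    pressure = scalar_field(grid, 0, name = "pressure"),
    extinct = FALSE
  ), class = "tamsim_tumor")
}

REGION_HOST <- 0L
REGION_P <- 1L
REGION_H <- 2L
REGION_N <- 3L

#' Classify tumor sites into proliferating / hypoxic / necrotic regions
#'
#' A tumor site is proliferating when oxygen is at or above the hypoxia
#' threshold, hypoxic when between the site's current effective viable
#' oxygen level `Q_OL` and the hypoxia threshold, and necrotic below
#' `Q_OL`. Host sites are unchanged. The effective `Q_OL` is the
#' M2-modulated viability bound, so M2-conditioned tissue at oxygen levels
#' that would otherwise be lethal is classified hypoxic (viable).
#' Necrosis is absorbing: a necrotic site stays necrotic (its debris is
#' degraded, never revived) even if oxygen later recovers.
#'
#' @param oxygen Oxygen [scalar_field()] (values in `[0, 1]`).
#' @param state A `tamsim_tumor` state.
#' @param cfg Configuration list.
#' @return The state with updated `labels`.
#' @export
classify_regions <- function(oxygen, state, cfg = default_config()) {
  sigma <- oxygen$values
  tumor <- state$phi >= cfg$phi_tumor
  lab <- integer(length(sigma))          # host
  lab[tumor] <- ifelse(sigma[tumor] >= cfg$hypoxia_threshold, REGION_P,
                ifelse(sigma[tumor] >= state$q_ol[tumor], REGION_H, REGION_N))
  lab[tumor & state$labels == REGION_N] <- REGION_N
  state$labels <- lab
  state
}

#' Net proliferation rate field
#'
#' Assembles the per-site net proliferation rate (per day): 0 in host
#' tissue; `(lambda_M + lambda_M2) sigma - (lambda_A + lambda_M1)` in the
#' proliferating region; `lambda_M2 sigma - (lambda_A + lambda_M1)` in the
#' hypoxic region; `-G_N` in the necrotic region. `lambda_M1` is the
#' nitric-oxide kill rate `lambda_NO` on sites in the immediate
#' (4-neighbour) vicinity of an M1 agent and zero elsewhere, reflecting the
#' short in-vivo diffusion distance of NO.
#'
#' @param labels Integer region labels (0 host, 1 P, 2 H, 3 N).
#' @param oxygen Oxygen field values (vector) or [scalar_field()].
#' @param lambda_m2 Per-site M2-induced proliferation rate.
#' @param m1_adjacency Logical per-site mask of M1-adjacent sites (see
#'   [emit_sources()]).
#' @param cfg Configuration list.
#' @return Numeric per-site rate field (per day).
#' @export
net_proliferation <- function(labels, oxygen, lambda_m2, m1_adjacency,
                              cfg = default_config()) {
  sigma <- if (inherits(oxygen, "tamsim_field")) oxygen$values else oxygen
  n <- length(labels)
  lambda_m2 <- rep_len(lambda_m2, n)
  m1 <- cfg$lambda_NO * as.numeric(rep_len(m1_adjacency, n))
  lp <- numeric(n)
  p <- labels == REGION_P
  h <- labels == REGION_H
  lp[p] <- (cfg$lambda_M + lambda_m2[p]) * sigma[p] - (cfg$lambda_A + m1[p])
  lp[h] <- lambda_m2[h] * sigma[h] - (cfg$lambda_A + m1[h])
  lp[labels == REGION_N] <- -cfg$G_N
  lp
}

#' Update the M2-induced proliferation rate
#'
#' Where the M2 growth factor `F` is present, `lambda_M2` rises at rate
#' `lambda_F * F`, saturating so the total `lambda_M + lambda_M2` cannot
#' exceed 1/day; where `F` is (numerically) absent it relaxes back to zero
#' at rate `lambda_rec`. Both branches are linear ODEs in `lambda_M2` and
#' are advanced with their exact exponential solution, which is
#' unconditionally stable for the large nondimensional strength of
#' `lambda_F`.
#'
#' @param lambda_m2 Per-site current rate (vector).
#' @param F_field M2 growth factor [scalar_field()] or values in `[0, 1]`.
#' @param dt Time step (day).
#' @param cfg Configuration list.
#' @return Updated per-site `lambda_M2` (always in `[0, 1 - lambda_M]`).
#' @export
update_m2_effect <- function(lambda_m2, F_field, dt, cfg = default_config()) {
  f <- if (inherits(F_field, "tamsim_field")) F_field$values else F_field
  n <- length(lambda_m2)
  f <- rep_len(f, n)
  cap <- 1 - cfg$lambda_M
  out <- lambda_m2
  act <- f >= cfg$f_eps
  if (any(act)) {
    # d l2/dt = lambda_F F (1 - lambda_M - l2): relax toward cap at rate
    # lambda_F * F
    r <- cfg$lambda_F * f[act]
    out[act] <- cap + (lambda_m2[act] - cap) * exp(-r * dt)
  }
  if (any(!act)) out[!act] <- lambda_m2[!act] * exp(-cfg$lambda_rec * dt)
  pmin(pmax(out, 0), cap)
}

#' Update the effective viable-oxygen level
#'
#' `dQ_OL/dt = lambda_OL (1 - F)(Qbar_OL - Q_OL) - lambda_OT F (Q_OL -
#' Q_OL,min)`: with no M2 factor the viability bound drifts up toward the
#' quiescence ceiling (hypoxic tissue slowly loses viability); the M2
#' factor pulls it down toward the floor, keeping oxygen-starved tissue
#' alive. The linear ODE is advanced exactly over `dt` and the result
#' clamped to `[Q_OL,min, Qbar_OL]`.
#'
#' @param q_ol Per-site current effective level.
#' @param F_field M2 growth factor field or values.
#' @param dt Time step (day).
#' @param cfg Configuration list.
#' @return Updated per-site `Q_OL`.
#' @export
update_quiescence_threshold <- function(q_ol, F_field, dt,
                                        cfg = default_config()) {
  f <- if (inherits(F_field, "tamsim_field")) F_field$values else F_field
  f <- rep_len(f, length(q_ol))
  a <- cfg$lambda_OL * (1 - f)
  b <- cfg$lambda_OT * f
  r <- a + b
  qss <- ifelse(r > 0,
                (a * cfg$hypoxia_threshold + b * cfg$necrosis_threshold) / r,
                q_ol)
  out <- qss + (q_ol - qss) * exp(-r * dt)
  pmin(pmax(out, cfg$necrosis_threshold), cfg$hypoxia_threshold)
}

#' Advance the tumor interface by Darcy flow
#'
#' Solves the oncotic pressure Poisson problem `lap(P) = -lambda_p / mu` on
#' the tumor region (P = 0 in host tissue, zero-flux at the domain edge),
#' derives the Darcy velocity `v = -mu grad(P)`, and advances the volume
#' fraction by one conservative upwind advection step with the local source
#' `lambda_p * phi`. With uniform extracellular matrix the haptotaxis term
#' vanishes and interface speed reduces to the normal Darcy velocity.
#' Fully degraded necrotic sites (`phi < phi_degraded`) revert to host.
#'
#' @param state A `tamsim_tumor` state.
#' @param lambda_p Per-site net proliferation field (per day).
#' @param dt Time step (day).
#' @param cfg Configuration list.
#' @param tol,max_iter Pressure-solver controls.
#' @return The advanced state (with refreshed `pressure`); sets
#'   `state$extinct` if no tumor tissue remains.
#' @export
advance_interface <- function(state, lambda_p, dt, cfg = default_config(),
                              tol = 1e-7, max_iter = 20000) {
  g <- state$grid
  stopifnot(all(is.finite(lambda_p)))
  mask <- state$phi >= cfg$phi_tumor
  sol <- poisson_mask_solve_cpp(g$nx, g$ny, g$h, mask,
                                -lambda_p * state$phi / cfg$mu,
                                tol, max_iter, 1.7)
  if (!sol$converged)
    stop(sprintf("pressure solve did not converge: residual %.3g after %d sweeps",
                 sol$residual, sol$iterations))
  state$pressure <- scalar_field(g, sol$values, name = "pressure")
  phi <- advect_phi_cpp(g$nx, g$ny, g$h, cfg$mu, state$phi, sol$values,
                        lambda_p * state$phi, dt)
  # fully degraded necrotic sites revert to host (fresh sub-threshold
  # front accretion is kept: it is advancing interface, not debris)
  gone <- phi < cfg$phi_degraded & state$labels == REGION_N
  phi[gone] <- 0
  state$phi <- phi
  state$labels[gone] <- REGION_HOST
  state$extinct <- !any(phi >= cfg$phi_tumor)
  state
}

#' Tumor area, equivalent-disk radius and centroid
#'
#' Area integrates the volume fraction over sites; the radius is that of
#' the disk with the same area.
#'
#' @param state A `tamsim_tumor` state.
#' @return List with `area_um2`, `radius_um`, `radius_mm`, `centroid`
#'   (lattice coordinates) and `n_tumor_sites`.
#' @export
tumor_geometry <- function(state) {
  g <- state$grid
  a_site <- g$spacing^2
  area <- sum(state$phi) * a_site
  tumor <- state$phi >= 0.5
  if (any(tumor)) {
    xy <- site_xy(g, which(tumor))
    centroid <- c(mean(xy[, "x"]), mean(xy[, "y"]))
  } else centroid <- c(NA_real_, NA_real_)
  list(area_um2 = area,
       radius_um = sqrt(area / pi),
       radius_mm = sqrt(area / pi) / 1000,
       centroid = centroid,
       n_tumor_sites = sum(tumor))
}

#' Concentric centring field for M1 movement bias
#'
#' Value 1 at the tumor centre falling linearly to 0 at the tumor boundary
#' (equivalent-disk radius), 0 outside; added to the chemotaxis term for M1
#' agents so they penetrate deeper into the lesion.
#'
#' @param state A `tamsim_tumor` state.
#' @return A [scalar_field()].
#' @export
centering_field <- function(state) {
  g <- state$grid
  geom <- tumor_geometry(state)
  if (!is.finite(geom$centroid[1]) || geom$radius_um <= 0)
    return(scalar_field(g, 0, name = "centering"))
  xy <- site_xy(g, seq_len(n_sites(g)))
  d_um <- sqrt((xy[, "x"] - geom$centroid[1])^2 +
               (xy[, "y"] - geom$centroid[2])^2) * g$spacing
  scalar_field(g, pmax(0, 1 - d_um / geom$radius_um), name = "centering",
               bounds = c(0, 1))
}

#' Export region labels as a CSV matrix of integer codes
#'
#' Codes: 0 host, 1 proliferating, 2 hypoxic, 3 necrotic; row-major,
#' origin lower-left.
#'
#' @param state A `tamsim_tumor` state.
#' @param path Output path.
#' @export
write_regions_csv <- function(state, path) {
  f <- scalar_field(state$grid, as.numeric(state$labels), name = "regions")
  write_field_csv(f, path)
}
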