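#' Build the pre-existing capillary grid
#'
#' Horizontal and vertical capillary lines every `vessel_spacing_sites`
#' lattice sites (240 um at the default 20-um spacing, approximating the
#' 250-um capillary grid), spanning the whole domain and offset so the
#' domain centre falls mid-way between lines. Each pair of adjacent sites
#' along a line is one unit-length segment at radius `R_init`.
#'
#' @param grid A [make_grid()] lattice.
#' @param cfg Configuration list.
#' @return A `tamsim_network` object: a segment table (`i1`, `i2` site
#'   indices, `radius` um, `type`, `sprout` id, `perfusable`, `perfused`,
#'   `pressurized`), an active-tip table, and per-sprout visited-site
#'   registries.
#' @export
make_vessel_grid <- function(grid, cfg = default_config()) {
  sv <- cfg$vessel_spacing_sites
  stopifnot(sv >= 2, sv < grid$nx, sv < grid$ny)
  off_x <- line_offsets(grid$nx, sv)
  off_y <- line_offsets(grid$ny, sv)
  segs <- list()
  for (y in off_y) {                 # horizontal lines span x = 1..nx
    x <- seq_len(grid$nx - 1L)
    segs[[length(segs) + 1L]] <-
      cbind(site_index(grid, x, y), site_index(grid, x + 1L, y))
  }
  for (x in off_x) {                 # vertical lines span y = 1..ny
    y <- seq_len(grid$ny - 1L)
    segs[[length(segs) + 1L]] <-
      cbind(site_index(grid, x, y), site_index(grid, x, y + 1L))
  }
  m <- do.call(rbind, segs)
  net <- structure(list(
    grid = grid,
    segs = data.frame(i1 = m[, 1], i2 = m[, 2], radius = cfg$R_init,
                      type = "pre", sprout = 0L, perfusable = TRUE,
                      perfused = TRUE, pressurized = FALSE,
                      stringsAsFactors = FALSE),
    tips = data.frame(sprout = integer(), site = integer(),
                      age = integer(), active = logical()),
    sprout_sites = list(),
    next_sprout = 1L
  ), class = "tamsim_network")
  refresh_perfusion(net, cfg)
}

# line positions centred so the domain midpoint bisects a capillary cell
line_offsets <- function(n, sv) {
  mid <- (n + 1) / 2
  first <- round(mid - sv / 2)
  first <- ((first - 1) %% sv) + 1
  seq.int(first, n, by = sv)
}

#' All lattice sites occupied by vessel segments
#' @param network A `tamsim_network`.
#' @param type Optional filter, `"pre"` or `"neo"`.
#' @return Sorted unique site indices.
#' @export
vessel_sites <- function(network, type = NULL) {
  s <- network$segs
  if (!is.null(type)) s <- s[s$type == type, , drop = FALSE]
  sort(unique(c(s$i1, s$i2)))
}

#' Natural shrinking tendency of a vessel segment
#'
#' The basal-lamina shrinking stimulus is the constant `k_s` until the
#' local tumor pressure `P_C` exceeds the critical collapse pressure
#' `P_CT`, beyond which it grows proportionally with rate `k_PC`.
#'
#' @param P_C Local tumor (oncotic) pressure on the vessel.
#' @param cfg Configuration list.
#' @return The shrinking stimulus (vectorized over `P_C`).
#' @export
shrink_tendency <- function(P_C, cfg = default_config()) {
  cfg$k_s + cfg$k_PC * pmax(P_C - cfg$P_CT, 0)
}

#' Lumped positive growth stimulus of a segment
#'
#' Stand-in for the wall-shear, intravascular-pressure and hematocrit
#' stimuli of full structural-adaptation models, which enter this model
#' only as a lumped positive term: perfused (or pressurized, i.e. collapsed
#' but connected to flow) segments receive `k_s + k_R (1 - R/R_ref)`, a
#' restoring form with stable operating radius `R_ref`; unperfused segments
#' receive 0. The restoring excess is capped at `0.2 k_R` so the stimulus
#' stays bounded at small radii and sustained tumor pressure can drive a
#' segment all the way to collapse. Replaceable via
#' `cfg$growth_stimulus_fn` if a full adaptation closure is wanted.
#'
#' @param radius Segment radius, um (vectorized).
#' @param flow Logical: perfused or pressurized.
#' @param cfg Configuration list.
#' @return The stimulus `S_wss + S_p + S_m`.
#' @export
growth_stimulus <- function(radius, flow, cfg = default_config()) {
  fn <- cfg$growth_stimulus_fn
  if (!is.null(fn)) return(fn(radius, flow, cfg))
  ifelse(flow,
         cfg$k_s + pmin(cfg$k_R * (1 - radius / cfg$R_ref),
                        cfg$stim_clip * cfg$k_R),
         0)
}

#' Update one segment radius
#'
#' `R <- R + (S_wss + S_p + S_m - S_s (1 - 1_TEM)) R dt`: an adjacent TEM
#' removes the shrinking tendency entirely. Radii are floored at the small
#' recovery floor `R_floor` (a multiplicative law cannot leave an exact
#' zero), and a radius at or below `R_collapse` marks a collapsed,
#' non-conducting segment.
#'
#' @param radius Current radius, um (vectorized).
#' @param stimulus The lumped positive stimulus `S_wss + S_p + S_m`.
#' @param s_s Shrinking tendency from [shrink_tendency()].
#' @param tem_adjacent Logical: is a TEM at a matrix location adjacent to
#'   the segment?
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @return Updated radius, um.
#' @export
update_radius <- function(radius, stimulus, s_s, tem_adjacent, dt,
                          cfg = default_config()) {
  stopifnot(dt > 0, all(is.finite(stimulus)), all(is.finite(s_s)))
  r <- radius + (stimulus - s_s * (1 - as.numeric(tem_adjacent))) *
    radius * dt
  pmin(pmax(r, cfg$R_floor), cfg$R_max)
}

# sites within Chebyshev distance `range` of any of `sites`
sites_within <- function(grid, sites, range) {
  if (!length(sites)) return(integer())
  xy <- site_xy(grid, sites)
  dx <- seq.int(-range, range)
  out <- lapply(seq_along(sites), function(i) {
    gx <- pmin(pmax(xy[i, "x"] + dx, 1L), grid$nx)
    gy <- pmin(pmax(xy[i, "y"] + dx, 1L), grid$ny)
    as.vector(outer(gx, gy, function(a, b) site_index(grid, a, b)))
  })
  sort(unique(unlist(out)))
}

# logical per-segment: TEM at a site adjacent (Chebyshev <= 1) to either
# endpoint
segment_tem_adjacency <- function(network, tem_sites) {
  if (!length(tem_sites)) return(rep(FALSE, nrow(network$segs)))
  halo <- sites_within(network$grid, tem_sites, 1L)
  mask <- logical(n_sites(network$grid))
  mask[halo] <- TRUE
  mask[network$segs$i1] | mask[network$segs$i2]
}

#' Advance all segment radii one step
#'
#' Applies [update_radius()] with the per-segment shrink tendency from the
#' local tumor pressure (mean of the endpoint pressures) and the lumped
#' growth stimulus; TEM protection uses the active-TEM site set.
#'
#' @param network A `tamsim_network`.
#' @param pressure Tumor pressure [scalar_field()].
#' @param tem_sites Sites of active TEM agents.
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @return The network with updated radii and refreshed perfusion flags.
#' @export
update_network_radii <- function(network, pressure, tem_sites, dt,
                                 cfg = default_config()) {
  s <- network$segs
  p_c <- (pressure$values[s$i1] + pressure$values[s$i2]) / 2
  flow <- s$perfused | s$pressurized
  stim <- growth_stimulus(s$radius, flow, cfg)
  s_s <- shrink_tendency(p_c, cfg)
  tem <- segment_tem_adjacency(network, tem_sites)
  network$segs$radius <- update_radius(s$radius, stim, s_s, tem, dt, cfg)
  refresh_perfusion(network, cfg)
}

#' Recompute perfusion and pressurization flags
#'
#' A segment is perfused when it is non-collapsed, perfusable (pre-existing,
#' or a neovessel whose sprout has anastomosed) and connected through such
#' segments to the domain-boundary capillary grid. A collapsed segment with
#' a perfused-network endpoint is flagged pressurized: it carries the flow
#' stimulus and can reopen once tumor pressure relents.
#'
#' @param network A `tamsim_network`.
#' @param cfg Configuration list.
#' @return The network with `perfused` and `pressurized` columns updated.
#' @export
refresh_perfusion <- function(network, cfg = default_config()) {
  g <- network$grid
  s <- network$segs
  open <- s$radius > cfg$R_collapse & s$perfusable
  xy1 <- site_xy(g, s$i1); xy2 <- site_xy(g, s$i2)
  on_edge <- function(xy) xy[, "x"] == 1L | xy[, "x"] == g$nx |
    xy[, "y"] == 1L | xy[, "y"] == g$ny
  seed <- logical(n_sites(g))
  seed[s$i1[on_edge(xy1)]] <- TRUE
  seed[s$i2[on_edge(xy2)]] <- TRUE
  vis <- segment_bfs_cpp(n_sites(g), s$i1 - 1L, s$i2 - 1L, open, seed)
  reach <- function(i) vis[i]
  network$segs$perfused <- open & reach(s$i1) & reach(s$i2)
  network$segs$pressurized <- !open & s$perfusable &
    (reach(s$i1) | reach(s$i2))
  network
}

#' Sites of perfused vessel segments
#' @param network A `tamsim_network`.
#' @return Sorted unique site indices with flowing vessel.
#' @export
perfused_sites <- function(network) {
  s <- network$segs[network$segs$perfused, , drop = FALSE]
  sort(unique(c(s$i1, s$i2)))
}

#' Initiate new angiogenic sprout tips
#'
#' Pre-existing-vessel sites start a new tip with probability
#' `init_rate * dt * (TAF - taf_sprout_threshold)+`, one tip per site at a
#' time; TEM contact (an active TEM within `tem_range` sites) multiplies
#' the probability by `tem_sprout_gain`, the same sensitization that
#' accelerates tip extension. Draws consume one uniform per candidate site
#' in fixed site order, so runs are reproducible under a seed.
#'
#' @param network A `tamsim_network`.
#' @param taf TAF [scalar_field()].
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @param tem_sites Sites of active TEM agents.
#' @return The network with new tips appended.
#' @export
new_sprout_initiation <- function(network, taf, dt, cfg = default_config(),
                                  tem_sites = integer()) {
  cand <- vessel_sites(network, type = "pre")
  excess <- pmax(taf$values[cand] - cfg$taf_sprout_threshold, 0)
  gain <- rep(1, length(cand))
  if (length(tem_sites)) {
    halo <- logical(n_sites(network$grid))
    halo[sites_within(network$grid, tem_sites, cfg$tem_range)] <- TRUE
    gain[halo[cand]] <- cfg$tem_sprout_gain
  }
  p <- pmin(cfg$init_rate * dt * excess * gain, 1)
  u <- stats::runif(length(cand))
  new <- cand[u < p & !(cand %in% network$tips$site[network$tips$active])]
  budget <- cfg$tip_cap - sum(network$tips$active)
  if (length(new) > budget) new <- new[seq_len(max(budget, 0))]
  if (length(new)) {
    ids <- network$next_sprout + seq_along(new) - 1L
    network$next_sprout <- network$next_sprout + length(new)
    network$tips <- rbind(network$tips,
                          data.frame(sprout = ids, site = new, age = 0L,
                                     active = TRUE))
    for (k in seq_along(new)) network$sprout_sites[[ids[k]]] <- new[k]
  }
  network
}

#' Extend active sprout tips one lattice step
#'
#' Each active tip attempts one extension with probability
#' `sprout_rate * dt`, multiplied by `tem_sprout_gain` when an active TEM
#' lies within `tem_range` sites (TEM-secreted factors sensitize vascular
#' growth). The direction is drawn from the categorical distribution
#' proportional to the positive TAF gradient components toward the four
#' neighbours; sites already used by the same sprout are excluded. A tip
#' older than `sprout_min_age` extensions that steps onto another vessel
#' site fuses there (anastomosis): its sprout becomes perfusable and the
#' tip retires. Tips are processed in fixed index order.
#'
#' @param network A `tamsim_network`.
#' @param taf TAF [scalar_field()].
#' @param tem_sites Sites of active TEM agents.
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @param refresh Recompute perfusion flags afterwards (skip when a radius
#'   update, which refreshes anyway, follows in the same step).
#' @return The updated network.
#' @export
sprout_step <- function(network, taf, tem_sites, dt,
                        cfg = default_config(), refresh = TRUE) {
  if (!nrow(network$tips)) return(network)
  g <- network$grid
  tem_halo <- logical(n_sites(g))
  if (length(tem_sites))
    tem_halo[sites_within(g, tem_sites, cfg$tem_range)] <- TRUE
  vmask <- logical(n_sites(g))
  vmask[vessel_sites(network)] <- TRUE
  active_rows <- which(network$tips$active)
  tip_site <- network$tips$site
  tip_age <- network$tips$age
  tip_active <- network$tips$active
  new_i1 <- integer(); new_i2 <- integer(); new_sp <- integer()
  new_open <- logical()
  fused <- integer()
  for (r in active_rows) {
    s0 <- tip_site[r]
    sp <- network$tips$sprout[r]
    p_ext <- min(1, cfg$sprout_rate * dt *
                   (if (tem_halo[s0]) cfg$tem_sprout_gain else 1))
    if (stats::runif(1) >= p_ext) next
    nb <- neighbor_index(g, s0)[1, ]
    own <- network$sprout_sites[[sp]]
    w <- numeric(4)
    for (d in 1:4) {
      t_nb <- nb[d]
      if (is.na(t_nb) || t_nb %in% own) next
      w[d] <- max((taf$values[t_nb] - taf$values[s0]) / g$h, 0)
    }
    if (sum(w) <= 0) next
    dsel <- sample.int(4, 1, prob = w)
    target <- nb[dsel]
    if (vmask[target]) {
      if (tip_age[r] >= cfg$sprout_min_age) {
        # anastomosis: fuse and open the whole sprout to flow
        new_i1 <- c(new_i1, s0); new_i2 <- c(new_i2, target)
        new_sp <- c(new_sp, sp); new_open <- c(new_open, TRUE)
        fused <- c(fused, sp)
        tip_active[r] <- FALSE
        vmask[target] <- TRUE
      }
      next
    }
    new_i1 <- c(new_i1, s0); new_i2 <- c(new_i2, target)
    new_sp <- c(new_sp, sp); new_open <- c(new_open, FALSE)
    network$sprout_sites[[sp]] <- c(own, target)
    tip_site[r] <- target
    tip_age[r] <- tip_age[r] + 1L
    vmask[target] <- TRUE
  }
  network$tips$site <- tip_site
  network$tips$age <- tip_age
  network$tips$active <- tip_active
  if (length(new_i1)) {
    network$segs <- rbind(network$segs, data.frame(
      i1 = new_i1, i2 = new_i2, radius = cfg$R_sprout, type = "neo",
      sprout = new_sp, perfusable = new_open, perfused = FALSE,
      pressurized = FALSE, stringsAsFactors = FALSE))
    if (length(fused))
      network$segs$perfusable[network$segs$sprout %in% fused] <- TRUE
  }
  if (refresh) network <- refresh_perfusion(network, cfg)
  network
}

#' Vascular surface area
#'
#' Lateral (cylinder) surface area `2 pi r l` summed over non-collapsed
#' segments, with `r` the actual per-segment radius (`"actual_radii"`) or a
#' fixed 5-um radius / 10-um diameter (`"fixed_diameter"`). By default only
#' intratumoral segments count: those whose midpoint volume fraction
#' `(phi_1 + phi_2)/2` is at least `phi_tumor`.
#'
#' @param network A `tamsim_network`.
#' @param phi Tumor volume fraction per site (or NULL with
#'   `region = "all"`).
#' @param mode `"actual_radii"` or `"fixed_diameter"`.
#' @param region `"intratumoral"` or `"all"`.
#' @param cfg Configuration list.
#' @return Surface area in um^2.
#' @export
vascular_surface_area <- function(network, phi = NULL,
                                  mode = c("actual_radii", "fixed_diameter"),
                                  region = c("intratumoral", "all"),
                                  cfg = default_config()) {
  mode <- match.arg(mode)
  region <- match.arg(region)
  s <- network$segs
  keep <- s$radius > cfg$R_collapse
  if (region == "intratumoral") {
    stopifnot(!is.null(phi))
    keep <- keep & (phi[s$i1] + phi[s$i2]) / 2 >= cfg$phi_tumor
  }
  if (!any(keep)) return(0)
  r <- if (mode == "actual_radii") s$radius[keep] else rep(5, sum(keep))
  sum(2 * pi * r) * network$grid$spacing
}

#' Intratumoral vascular volume
#'
#' `pi r^2 l` summed over non-collapsed intratumoral segments, for the
#' vascular-to-tumor volume ratio metric.
#'
#' @inheritParams vascular_surface_area
#' @return Volume in um^3.
#' @export
vascular_volume <- function(network, phi, cfg = default_config()) {
  s <- network$segs
  keep <- s$radius > cfg$R_collapse &
    (phi[s$i1] + phi[s$i2]) / 2 >= cfg$phi_tumor
  if (!any(keep)) return(0)
  sum(pi * s$radius[keep]^2 * network$grid$spacing)
}

#' Angiopoietin-2 source sites
#'
#' Ang2 is secreted by the neovasculature only: returns the sites occupied
#' by neovessel segments (any radius; collapsed stumps are assumed
#' resorbed and excluded).
#'
#' @param network A `tamsim_network`.
#' @param cfg Configuration list.
#' @return Site indices forming the Ang2 production mask.
#' @export
secrete_ang2_sources <- function(network, cfg = default_config()) {
  s <- network$segs
  s <- s[s$type == "neo" & s$radius > cfg$R_collapse, , drop = FALSE]
  sort(unique(c(s$i1, s$i2)))
}

#' Export the network as an edge-list CSV
#'
#' One row per segment with endpoint lattice coordinates, radius, type and
#' perfusion flag.
#'
#' @param network A `tamsim_network`.
#' @param path Output path.
#' @export
write_network_csv <- function(network, path) {
  g <- network$grid
  s <- network$segs
  a <- site_xy(g, s$i1); b <- site_xy(g, s$i2)
  utils::write.csv(data.frame(
    x1 = a[, "x"], y1 = a[, "y"], x2 = b[, "x"], y2 = b[, "y"],
    radius_um = s$radius, type = s$type, perfused = s$perfused),
    path, row.names = FALSE)
  invisible(path)
}
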