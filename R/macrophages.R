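#' Empty macrophage agent table
#'
#' Agents are rows: lattice `site`, `state` (`"monocyte"`, `"M1"`, `"M2"`,
#' `"TEM"`), `active` (whether the subtype's effects are enabled in the
#' current case; monocytes differentiating into a disabled subtype become
#' inert agents that occupy space and move but exert no effect and are
#' excluded from differentiated counts), and `age` in days. At most one
#' agent per lattice site; agents may share a site with a vessel.
#'
#' @return A zero-row agent data frame.
#' @export
empty_agents <- function() {
  data.frame(site = integer(), state = character(), active = logical(),
             age = numeric(), stringsAsFactors = FALSE)
}

occupancy_mask <- function(grid, agents) {
  m <- logical(n_sites(grid))
  m[agents$site] <- TRUE
  m
}

#' Monocyte extravasation from the perfused vasculature
#'
#' Each unoccupied perfused-vessel site spawns a monocyte with probability
#' `extravasation_rate * dt * chemoattractant`, suppressed entirely while
#' the intratumoral macrophage count is at the density cap (the model
#' recruits ~25% of the in-vivo macrophage density, 2.78e4/mm^3). Draws
#' consume one uniform per candidate site in fixed site order so the
#' monocyte pool is reproducible and case-independent under a seed.
#'
#' @param network A `tamsim_network`.
#' @param chemo Chemoattractant [scalar_field()] (TAF).
#' @param agents Current agent table.
#' @param phi Tumor volume fraction (for the intratumoral cap).
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @return New monocyte agent rows (possibly zero rows).
#' @export
extravasate <- function(network, chemo, agents, phi, dt,
                        cfg = default_config()) {
  g <- network$grid
  sites <- perfused_sites(network)
  occ <- occupancy_mask(g, agents)
  tumor <- phi >= cfg$phi_tumor
  cap <- cfg$macro_density_cap * sum(tumor)
  n_in <- sum(tumor[agents$site])
  p <- pmin(cfg$extravasation_rate * dt * chemo$values[sites], 1)
  u <- stats::runif(length(sites))
  take <- u < p & !occ[sites]
  if (n_in >= cap) take[] <- FALSE
  if (!any(take)) return(empty_agents())
  data.frame(site = sites[take], state = "monocyte", active = TRUE,
             age = 0, stringsAsFactors = FALSE)
}

#' Differentiation weights from local factor concentrations
#'
#' `w_M1 = k_M1 C_M1f`; `w_M2 = k_M2 (C_M2f + k_T2M2 C_IL10)` (TEM-eluted
#' IL-10 biases monocytes toward M2); `w_TEM = k_T2 C_T2f + k_Ang2 C_Ang2`.
#'
#' @param c_m1f,c_m2f,c_il10,c_t2f,c_ang2 Local concentrations (vectors).
#' @param cfg Configuration list.
#' @return Matrix with columns `M1`, `M2`, `TEM`.
#' @export
differentiation_weights <- function(c_m1f, c_m2f, c_il10, c_t2f, c_ang2,
                                    cfg = default_config()) {
  cbind(M1 = cfg$k_M1 * c_m1f,
        M2 = cfg$k_M2 * (c_m2f + cfg$k_T2M2 * c_il10),
        TEM = cfg$k_T2 * c_t2f + cfg$k_Ang2 * c_ang2)
}

#' Monocyte differentiation draws
#'
#' Each monocyte converts its weights into probabilities `w_i * diff_rate *
#' dt` laid out as consecutive subintervals of `[0, 1]`; a single uniform
#' draw selects the subtype, and a draw beyond all intervals leaves the
#' cell a monocyte. The subtype is always drawn, even when the case
#' disables it: the agent then becomes inert rather than re-rolled, which
#' keeps the monocyte pool and draw sequence identical across cases.
#'
#' @param agents Agent table.
#' @param fields Named list of [scalar_field()]s: `M1f`, `M2f`, `IL10`,
#'   `T2f`, `Ang2`.
#' @param enabled Character vector of enabled subtypes, e.g.
#'   `c("M1", "TEM")`.
#' @param dt Time step (nondimensional day).
#' @param cfg Configuration list.
#' @return The agent table with new states/active flags.
#' @export
differentiate <- function(agents, fields, enabled, dt,
                          cfg = default_config()) {
  mono <- which(agents$state == "monocyte")
  if (!length(mono)) return(agents)
  s <- agents$site[mono]
  w <- differentiation_weights(fields$M1f$values[s], fields$M2f$values[s],
                               fields$IL10$values[s], fields$T2f$values[s],
                               fields$Ang2$values[s], cfg)
  p <- w * cfg$diff_rate * dt
  tot <- rowSums(p)
  over <- tot > 1
  if (any(over)) p[over, ] <- p[over, ] / tot[over]
  u <- stats::runif(length(mono))
  c1 <- p[, "M1"]; c2 <- c1 + p[, "M2"]; c3 <- c2 + p[, "TEM"]
  new_state <- ifelse(u < c1, "M1", ifelse(u < c2, "M2",
                ifelse(u < c3, "TEM", "monocyte")))
  changed <- new_state != "monocyte"
  agents$state[mono[changed]] <- new_state[changed]
  agents$active[mono[changed]] <- new_state[changed] %in% enabled
  agents
}

# per-agent movement scores toward +x,-x,+y,-y following the
# gradient-weighted semi-stochastic rule; TEM respond to Ang2 only
movement_scores <- function(agents, bundle, cfg) {
  g <- bundle$grid
  n <- nrow(agents)
  s <- agents$site
  d_o <- neighbor_deltas(g, bundle$oxygen)[s, , drop = FALSE]
  d_p <- neighbor_deltas(g, bundle$pressure)[s, , drop = FALSE]
  d_c <- neighbor_deltas(g, bundle$chemo)[s, , drop = FALSE]
  d_a <- neighbor_deltas(g, bundle$ang2)[s, , drop = FALSE]
  sc <- cfg$sign_O * cfg$M_O * d_o + cfg$sign_P * cfg$M_P * d_p +
    cfg$sign_C * cfg$M_C * d_c
  if (cfg$m1_center_bias && !is.null(bundle$centering)) {
    d_ctr <- neighbor_deltas(g, bundle$centering)[s, , drop = FALSE]
    m1 <- agents$state == "M1"
    sc[m1, ] <- sc[m1, ] + cfg$M_C * d_ctr[m1, ]
  }
  tem <- agents$state == "TEM"
  sc[tem, ] <- cfg$M_Ang2 * d_a[tem, , drop = FALSE]
  sc[is.na(sc)] <- 0       # off-domain directions never qualify
  pmax(sc, 0)
}

#' Move all agents one step
#'
#' Per-direction scores (oxygen, pressure and chemoattractant differences
#' for monocytes/M1/M2, with the concentric centring bias added to the
#' chemo term for M1; Ang2 differences for TEM) are clamped at zero,
#' scaled by `move_score_scale` into probabilities, and capped at total 1.
#' A uniform draw selects a direction or staying; directions scoring below
#' `move_min_score` never qualify, and a move onto an occupied site is
#' rejected (the agent stays). Agents are processed in a randomized order
#' each step.
#'
#' @param agents Agent table.
#' @param bundle List with `grid` and per-site value vectors `oxygen`,
#'   `pressure`, `chemo`, `ang2`, optional `centering`.
#' @param cfg Configuration list.
#' @return The agent table with updated sites.
#' @export
move_agents <- function(agents, bundle, cfg = default_config()) {
  n <- nrow(agents)
  if (!n) return(agents)
  g <- bundle$grid
  sc <- movement_scores(agents, bundle, cfg)
  sc[sc < cfg$move_min_score] <- 0
  p <- sc * cfg$move_score_scale
  tot <- rowSums(p)
  over <- tot > 1
  if (any(over)) p[over, ] <- p[over, ] / tot[over]
  nbs <- neighbor_index(g, agents$site)
  occ <- occupancy_mask(g, agents)
  ord <- sample.int(n)
  u <- stats::runif(n)
  for (idx in seq_len(n)) {
    i <- ord[idx]
    pi <- p[i, ]
    cum <- cumsum(pi)
    if (cum[4] <= 0 || u[idx] >= cum[4]) next
    d <- which(u[idx] < cum)[1]
    target <- nbs[i, d]
    if (is.na(target) || occ[target]) next
    occ[agents$site[i]] <- FALSE
    occ[target] <- TRUE
    agents$site[i] <- target
  }
  agents
}

#' Source masks contributed by the macrophage agents
#'
#' Only active (case-enabled) agents emit. The nitric-oxide mask is the
#' sites within the 4-neighbourhood of an M1 (NO has a short half-life and
#' acts in the immediate vicinity); the M2 growth factor F is produced at
#' M2 sites; IL-10 at TEM sites.
#'
#' @param agents Agent table.
#' @param grid Lattice.
#' @return List `no_mask` (logical per site), `f_sites`, `il10_sites`,
#'   `tem_sites` (site indices).
#' @export
emit_sources <- function(agents, grid) {
  act <- agents[agents$active, , drop = FALSE]
  m1 <- act$site[act$state == "M1"]
  no_mask <- logical(n_sites(grid))
  if (length(m1)) {
    no_mask[m1] <- TRUE
    nb <- neighbor_index(grid, m1)
    no_mask[nb[!is.na(nb)]] <- TRUE
  }
  list(no_mask = no_mask,
       f_sites = act$site[act$state == "M2"],
       il10_sites = act$site[act$state == "TEM"],
       tem_sites = act$site[act$state == "TEM"])
}

#' Map nondimensional IL-10 concentration to pg/mL
#'
#' Linear voxel-based map: each lattice site is treated as a 3D voxel and
#' the nondimensional concentration scaled by a configured molecule-count
#' factor into pg/mL. With the default calibration, TEM-present runs peak
#' within the observed 5.6-37 pg/mL range.
#'
#' @param il10 IL-10 [scalar_field()] (values in `[0, 1]`).
#' @param cfg Configuration list (uses `il10_pg_scale`).
#' @return Numeric per-site concentrations in pg/mL.
#' @export
il10_concentration_pg_ml <- function(il10, cfg = default_config()) {
  v <- if (inherits(il10, "tamsim_field")) il10$values else il10
  cfg$il10_pg_scale * v
}

#' Subtype counts of an agent table
#'
#' Inert (case-disabled) agents are not counted as differentiated.
#'
#' @param agents Agent table.
#' @return Named vector: monocytes, M1, M2, TEM (active only),
#'   inert, total.
#' @export
count_agents <- function(agents) {
  act <- agents$active
  c(monocytes = sum(agents$state == "monocyte"),
    M1 = sum(agents$state == "M1" & act),
    M2 = sum(agents$state == "M2" & act),
    TEM = sum(agents$state == "TEM" & act),
    inert = sum(agents$state != "monocyte" & !act),
    total = nrow(agents))
}
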