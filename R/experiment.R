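#' Macrophage-population cases
#'
#' The eight scenarios differ only in which macrophage subtypes are
#' enabled; monocytes differentiating into a disabled subtype become inert
#' agents, so the monocyte pool and differentiation draws stay consistent
#' across cases.
#'
#' @format Named list: case id -> character vector of enabled subtypes.
#' @export
CASE_SUBTYPES <- list(
  `1` = c("M1", "M2", "TEM"),
  `2` = c("M1", "TEM"),
  `3` = c("M1", "M2"),
  `4` = c("M2", "TEM"),
  `5` = "M1",
  `6` = character(0),
  `7` = "TEM",
  `8` = "M2"
)

#' Define a simulation case
#'
#' @param case_id Integer 1-8 selecting the enabled-subtype combination
#'   (1: M1+M2+TEM, 2: M1+TEM, 3: M1+M2, 4: M2+TEM, 5: M1, 6: none,
#'   7: TEM, 8: M2).
#' @param seed RNG seed.
#' @param days Simulated horizon in days (default: the configuration's
#'   `days`, 13).
#' @param record_every Metric-row cadence in steps.
#' @return A `tamsim_case` list.
#' @export
case_spec <- function(case_id, seed = 1L, days = NULL,
                      record_every = NULL) {
  stopifnot(case_id %in% 1:8)
  structure(list(case_id = as.integer(case_id),
                 enabled = CASE_SUBTYPES[[as.character(case_id)]],
                 seed = as.integer(seed), days = days,
                 record_every = record_every),
            class = "tamsim_case")
}

#' Run one simulation case
#'
#' Executes the coupled loop: steady-state oxygen solve and region
#' classification; TAF and cytokine solves; monocyte extravasation,
#' differentiation and movement (activated at hypoxia onset); source
#' emission; quiescence-threshold, M2-effect and Darcy interface updates;
#' sprout initiation/extension and vessel radius adaptation. Deterministic
#' given `(case_id, seed)` and the configuration.
#'
#' @param spec A [case_spec()] (or an integer case id).
#' @param cfg Configuration from [default_config()].
#' @param seed Seed override when `spec` is an integer id.
#' @param out_dir Optional directory for snapshot exports (field CSV/PNG,
#'   agent and vessel tables at each recorded time, plus `metrics.csv`).
#' @return List: `metrics` (one row per recorded time), `onset_day`
#'   (hypoxia-triggered monocyte onset), `onset_diameter_um`, final
#'   `state`, `network`, `agents`, `fields`, the `spec` and `cfg`.
#' @export
run_case <- function(spec, cfg = default_config(), seed = 1L,
                     out_dir = NULL) {
  if (is.numeric(spec)) spec <- case_spec(spec, seed = seed)
  grid <- make_grid(cfg$nx, cfg$ny, cfg$spacing)
  net <- make_vessel_grid(grid, cfg)
  state <- make_tumor_state(grid, cfg)
  streams <- make_streams(spec$seed)
  agents <- empty_agents()
  n <- n_sites(grid)
  zero_field <- function(nm) scalar_field(grid, 0, name = nm,
                                          bounds = c(0, 1))
  flds <- list(TAF = zero_field("TAF"), M1f = zero_field("M1f"),
               M2f = zero_field("M2f"), T2f = zero_field("T2f"),
               IL10 = zero_field("IL10"), Ang2 = zero_field("Ang2"),
               F = zero_field("F"))
  warm <- list()
  src <- emit_sources(agents, grid)
  cum <- list(M1 = 0L, M2 = 0L, TEM = 0L, inert = 0L)
  onset_day <- NA_real_
  onset_diam <- NA_real_
  nsteps <- ceiling((spec$days %||% cfg$days) / cfg$dt)
  rec_every <- spec$record_every %||% cfg$record_every
  dtn <- cfg$dt * cfg$clock_scale
  rows <- vector("list", nsteps %/% rec_every + 2L)
  nrow_out <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  oxy <- NULL
  for (step in seq_len(nsteps)) {
    time <- step * cfg$dt
    ## transport fields, re-solved to steady state on the field cadence
    if (step %% cfg$field_every == 0L || is.null(oxy))
      oxy <- solve_oxygen(state$labels, net, cfg,
                          pressure = state$pressure, init = warm$oxygen)
    state <- classify_regions(oxy, state, cfg)
    viable <- which(state$labels == REGION_P | state$labels == REGION_H)
    hyp <- which(state$labels == REGION_H)
    washout <- perfused_sites(net)
    if (is.na(onset_day) && length(hyp)) {
      onset_day <- time
      onset_diam <- 2 * tumor_geometry(state)$radius_um
    }
    macro_on <- !is.na(onset_day)
    resolve <- step %% cfg$field_every == 0L || step == 1L
    resolve_guidance <- step %% cfg$guidance_every == 0L || step == 1L ||
      (macro_on && is.na(warm$onset_seen %||% NA_real_))
    if (resolve_guidance)
      flds$TAF <- solve_cytokine("TAF", hyp, washout, grid, cfg,
                                 init = warm$TAF)
    if (macro_on && resolve_guidance)
      flds$Ang2 <- solve_cytokine("Ang2", secrete_ang2_sources(net, cfg),
                                  washout, grid, cfg, init = warm$Ang2)
    if (macro_on && resolve) {
      flds$M1f <- solve_cytokine("M1f", viable, washout, grid, cfg,
                                 init = warm$M1f)
      flds$M2f <- solve_cytokine("M2f", viable, washout, grid, cfg,
                                 init = warm$M2f)
      flds$T2f <- solve_cytokine("T2f", viable, washout, grid, cfg,
                                 init = warm$T2f)
      flds$IL10 <- solve_cytokine("IL10", src$il10_sites, washout, grid,
                                  cfg, init = warm$IL10)
      flds$F <- solve_cytokine("F", src$f_sites, washout, grid, cfg,
                               init = warm$F)
    }

    ## macrophage phase
    if (macro_on) {
      fresh <- with_stream(streams, "spawn",
        extravasate(net, flds$TAF, agents, state$phi, dtn, cfg))
      if (nrow(fresh)) agents <- rbind(agents, fresh)
      was_mono <- agents$state == "monocyte"
      agents <- with_stream(streams, "diff",
        differentiate(agents, flds, spec$enabled, dtn, cfg))
      new_diff <- was_mono & agents$state != "monocyte"
      dlog <- getOption("tamsim.diff_log")
      if (!is.null(dlog) && any(new_diff)) {
        geom <- tumor_geometry(state)
        xy <- site_xy(grid, agents$site[new_diff])
        d_um <- sqrt((xy[, "x"] - geom$centroid[1])^2 +
                     (xy[, "y"] - geom$centroid[2])^2) * grid$spacing
        dlog$events <- rbind(dlog$events, data.frame(
          time = time, state = agents$state[new_diff],
          active = agents$active[new_diff],
          depth_um = d_um - geom$radius_um,
          m1f = flds$M1f$values[agents$site[new_diff]],
          m2f = flds$M2f$values[agents$site[new_diff]],
          ang2 = flds$Ang2$values[agents$site[new_diff]],
          il10 = flds$IL10$values[agents$site[new_diff]]))
      }
      if (any(new_diff)) {
        for (st in c("M1", "M2", "TEM")) {
          hit <- sum(new_diff & agents$state == st & agents$active)
          cum[[st]] <- cum[[st]] + hit
        }
        cum$inert <- cum$inert + sum(new_diff & !agents$active)
      }
      ctr <- centering_field(state)
      pmax_ <- max(state$pressure$values)
      bundle <- list(grid = grid, oxygen = oxy$values,
                     pressure = if (pmax_ > 0)
                       state$pressure$values / pmax_ else
                       state$pressure$values,
                     chemo = flds$TAF$values, ang2 = flds$Ang2$values,
                     centering = ctr$values)
      agents <- with_stream(streams, "move",
        move_agents(agents, bundle, cfg))
      agents$age <- agents$age + cfg$dt
      agents <- agents[agents$age <= cfg$lifespan_days, , drop = FALSE]
    }
    src <- emit_sources(agents, grid)

    ## tumor phase
    state$q_ol <- update_quiescence_threshold(state$q_ol, flds$F, dtn, cfg)
    state$lambda_m2 <- update_m2_effect(state$lambda_m2, flds$F, dtn, cfg)
    lp <- net_proliferation(state$labels, oxy, state$lambda_m2,
                            src$no_mask, cfg)
    state <- advance_interface(state, lp, dtn, cfg)

    ## vasculature phase
    net <- with_stream(streams, "vessel", {
      net2 <- new_sprout_initiation(net, flds$TAF, dtn, cfg,
                                    src$tem_sites)
      sprout_step(net2, flds$TAF, src$tem_sites, dtn, cfg,
                  refresh = FALSE)
    })
    net <- update_network_radii(net, state$pressure, src$tem_sites, dtn,
                                cfg)

    warm <- list(oxygen = oxy$values, TAF = flds$TAF$values,
                 M1f = flds$M1f$values, M2f = flds$M2f$values,
                 T2f = flds$T2f$values, Ang2 = flds$Ang2$values,
                 IL10 = flds$IL10$values, F = flds$F$values,
                 onset_seen = onset_day)

    if (step %% rec_every == 0L || step == nsteps) {
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- compute_metrics(state, net, agents, cfg, time,
                                          onset_day, cum)
      if (!is.null(out_dir))
        export_snapshot(out_dir, time, state, net, agents, flds, oxy)
    }
  }
  metrics <- do.call(rbind, rows[seq_len(nrow_out)])
  if (!is.null(out_dir))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  list(metrics = metrics, onset_day = onset_day,
       onset_diameter_um = onset_diam, state = state, network = net,
       agents = agents, fields = flds, oxygen = oxy, spec = spec,
       cfg = cfg)
}

#' One row of the metric series
#'
#' Tumor equivalent-disk radius, intratumoral vascular surface areas
#' (actual radii and fixed 10-um diameter), subtype counts, TEM fraction
#' of (active) differentiated macrophages, M2:M1 ratio, and the ratio of
#' intratumoral vascular volume to tumor tissue volume (sites treated as
#' voxels of the configured depth).
#'
#' @param state Tumor state.
#' @param network Vessel network.
#' @param agents Agent table.
#' @param cfg Configuration list.
#' @param time Simulated day.
#' @param onset_day Hypoxia onset day (NA before onset).
#' @param cum Cumulative differentiation counts, list with `M1`, `M2`,
#'   `TEM`, `inert` (zeros if omitted). `fraction_TEM_cum` is the TEM share
#'   of all active differentiation events so far, robust to later agent
#'   death.
#' @return A one-row data frame.
#' @export
compute_metrics <- function(state, network, agents, cfg, time,
                            onset_day = NA_real_,
                            cum = list(M1 = 0L, M2 = 0L, TEM = 0L,
                                       inert = 0L)) {
  geom <- tumor_geometry(state)
  cnt <- count_agents(agents)
  ndiff <- cnt[["M1"]] + cnt[["M2"]] + cnt[["TEM"]]
  ncum <- cum$M1 + cum$M2 + cum$TEM
  vol_tumor <- geom$area_um2 * cfg$voxel_depth_um
  data.frame(
    time = time,
    tumor_radius_mm = geom$radius_mm,
    tumor_area_um2 = geom$area_um2,
    vascular_area_actual = vascular_surface_area(
      network, state$phi, "actual_radii", "intratumoral", cfg),
    vascular_area_fixed = vascular_surface_area(
      network, state$phi, "fixed_diameter", "intratumoral", cfg),
    n_prolif_sites = sum(state$labels == REGION_P),
    n_hypoxic_sites = sum(state$labels == REGION_H),
    n_necrotic_sites = sum(state$labels == REGION_N),
    n_monocytes = cnt[["monocytes"]], n_M1 = cnt[["M1"]],
    n_M2 = cnt[["M2"]], n_TEM = cnt[["TEM"]], n_inert = cnt[["inert"]],
    fraction_TEM = if (ndiff > 0) cnt[["TEM"]] / ndiff else NA_real_,
    cum_M1 = cum$M1, cum_M2 = cum$M2, cum_TEM = cum$TEM,
    cum_inert = cum$inert,
    fraction_TEM_cum = if (ncum > 0) cum$TEM / ncum else NA_real_,
    ratio_M2_M1 = if (cnt[["M1"]] == 0 && cnt[["M2"]] == 0) NA_real_
                  else cnt[["M2"]] / cnt[["M1"]],
    ratio_vasc_tumor_volume = if (vol_tumor > 0)
      vascular_volume(network, state$phi, cfg) / vol_tumor else 0,
    onset_day = onset_day
  )
}

export_snapshot <- function(out_dir, time, state, net, agents, flds, oxy) {
  tag <- sprintf("t%05.2f", time)
  write_regions_csv(state, file.path(out_dir,
                                     sprintf("regions_%s.csv", tag)))
  write_field_csv(oxy, file.path(out_dir, sprintf("oxygen_%s.csv", tag)))
  write_field_png(oxy, file.path(out_dir, sprintf("oxygen_%s.png", tag)))
  write_network_csv(net, file.path(out_dir,
                                   sprintf("vessels_%s.csv", tag)))
  g <- state$grid
  xy <- site_xy(g, agents$site)
  utils::write.csv(
    data.frame(x = xy[, "x"], y = xy[, "y"], state = agents$state,
               active = agents$active, age = agents$age),
    file.path(out_dir, sprintf("agents_%s.csv", tag)), row.names = FALSE)
}

#' Run several cases over several seeds and aggregate
#'
#' @param case_ids Case ids (1-8).
#' @param seeds Integer seeds; the same seed set is used for every case so
#'   cases can be compared pairwise on matched seeds.
#' @param cfg Configuration list.
#' @param days Horizon override.
#' @return List: `runs` (list of [run_case()] results indexed
#'   `case<i>.seed<s>`), `final` (data frame of final-time metrics per
#'   run), `summary` (per-case, per-time mean and SD of each metric).
#' @export
replicate_summary <- function(case_ids, seeds, cfg = default_config(),
                              days = NULL) {
  stopifnot(length(seeds) >= 1)
  runs <- list()
  final <- list()
  series <- list()
  for (cid in case_ids) {
    for (s in seeds) {
      key <- sprintf("case%d.seed%d", cid, s)
      sp <- case_spec(cid, seed = s, days = days %||% cfg$days)
      res <- run_case(sp, cfg)
      runs[[key]] <- res
      m <- res$metrics
      m$case <- cid; m$seed <- s
      series[[key]] <- m
      final[[key]] <- m[nrow(m), , drop = FALSE]
    }
  }
  all_series <- do.call(rbind, series)
  metric_cols <- setdiff(names(all_series), c("time", "case", "seed"))
  agg <- stats::aggregate(all_series[metric_cols],
                          by = all_series[c("case", "time")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  sdv <- stats::aggregate(all_series[metric_cols],
                          by = all_series[c("case", "time")],
                          FUN = function(v) stats::sd(v, na.rm = TRUE))
  names(sdv)[-(1:2)] <- paste0(names(sdv)[-(1:2)], "_sd")
  list(runs = runs, final = do.call(rbind, final),
       summary = merge(agg, sdv, by = c("case", "time")))
}

#' Fold change of a metric between two cases at the final recorded time
#'
#' Computes the per-seed ratio `case_a / case_b` on matched seeds and
#' returns the per-seed values with their median.
#'
#' @param summary_obj Result of [replicate_summary()].
#' @param case_a,case_b Case ids.
#' @param metric Metric column name.
#' @return List with `per_seed` (named vector) and `median`.
#' @export
fold_change <- function(summary_obj, case_a, case_b,
                        metric = "vascular_area_actual") {
  fin <- summary_obj$final
  a <- fin[fin$case == case_a, ]
  b <- fin[fin$case == case_b, ]
  a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
  stopifnot(identical(a$seed, b$seed))
  r <- a[[metric]] / b[[metric]]
  names(r) <- paste0("seed", a$seed)
  list(per_seed = r, median = stats::median(r))
}
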