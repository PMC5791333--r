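#' Default model configuration
#'
#' Returns the full parameter set of the simulator as a named list. Rates
#' flagged "nondimensional" follow the convention that diffusivities are
#' fractions of the oxygen diffusivity (1e-5 cm^2/s) over the 200-um length
#' unit, and biological rates are per simulated day unless noted. Entries
#' under `provenance` separate literature-anchored values from package
#' defaults chosen where the source models leave a quantity open; the methods
#' vignette discusses every default in the second group.
#'
#' @param ... Named overrides, e.g. `default_config(dt = 0.01)`. Unknown
#'   names are an error.
#' @return A named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    ## -- domain -------------------------------------------------------
    nx = 100L, ny = 100L, spacing = 20,   # 2 x 2 mm panel at 20 um/site
    vessel_spacing_sites = 12L,           # ~250 um capillary grid (240 um)
    voxel_depth_um = 20,                  # 3D voxel depth for volume metrics

    ## -- time ---------------------------------------------------------
    dt = 0.05,            # macro-timestep, day
    days = 13,            # simulated horizon
    record_every = 5L,    # metric rows every record_every steps
    clock_scale = 0.72,   # nondimensional-time -> day map; balances the
                          # hypoxia-onset day (monocyte activation, lands
                          # at 6.45 d vs the observed ~7.35 d) against the
                          # length of the post-onset dynamics window

    ## -- tumor (thresholds and proliferation) -------------------------
    hypoxia_threshold = 0.5750,   # oxygen level below which no proliferation
    necrosis_threshold = 0.5325,  # floor of the viable-oxygen level Q_OL
    lambda_M = 0.5,     # native mitosis rate, /day
    lambda_A = 0,       # apoptosis rate, /day (no literature value; default 0)
    G_N = 0.3,          # necrotic degradation rate
    lambda_OL = 0.05,   # recovery rate of Q_OL toward its quiescence ceiling
    lambda_OT = 200,    # M2-factor strength lowering the viable-O2 threshold
    lambda_F = 1000,    # M2-factor strength raising proliferation
    lambda_rec = 0.1,   # relaxation of the M2 proliferation boost to zero
    lambda_NO = 0.16,    # M1 nitric-oxide kill rate on M1-adjacent sites,
                        # /day; the table's per-second strengths are
                        # reconciled individually (vignette): this one sets
                        # a rate directly and is calibrated so M1-driven
                        # growth arrest plateaus rather than extinguishes
    f_eps = 0.01,       # F below this counts as absent (lambda_rec regime)
    mu = 0.3,           # Darcy tissue mobility
    phi_tumor = 0.5,    # volume fraction at/above which a site is tumor
    phi_degraded = 0.05,# necrotic sites below this revert to host

    ## -- oxygen -------------------------------------------------------
    lambda_ev = 5,        # transfer rate from vasculature
    lambda_tumor = 1.5,   # uptake, proliferating tumor
    q_sigma = 1.3,        # uptake, hypoxic tumor
    lambda_tissue = 0.12, # uptake, host tissue
    lambda_N = 0.35,      # decay in necrotic tissue
    oxy_uptake_scale = 1.45, # single scale reconciling the uptake rates with
                          # the 200-um unit: sets the tumor oxygen
                          # diffusion length (~115 um) below the capillary
                          # half-spacing so hypoxic interiors persist
    H_D = 0.45,           # normal hematocrit (package default)
    H_neo = 0.19,         # hematocrit in immature neovessels (low-flow)
    h_min = 0.2,          # minimum hematocrit fraction for extravasation
    k_Pi = 0.1,           # convective weight of interstitial pressure
    p_e = 0.5,            # effective pressure scale for the p_i/p_e term

    ## -- cytokines ----------------------------------------------------
    # macrophage-cytokine rates are the table values expressed on the
    # 20-um pixel scale of the proteomic source model (x100 relative to
    # the 200-um transport unit); TAF, an angiogenesis-model field, keeps
    # the long-range transport-unit rates
    cyto_production = 0.05, # tumor-sourced factors (M1f, M2f, T2f, F):
                            # low-saturation regime with local
                            # concentrations O(0.1), so higher-MW
                            # (faster-diffusing) factors dilute further
    cyto_production_eluted = 1.0, # TEM-eluted IL-10 (anchored by its
                            # 5.6-37 pg/mL range) and neovascular Ang2
    cyto_washout = 0.6,
    cyto_decay = 0.1,
    taf_washout = 0.006,
    taf_decay = 0.001,
    D_M1f = 0.005, D_M2f = 0.01880, D_IL10 = 0.01880,
    D_T2f = 0.005, D_Ang2 = 0.00133,
    D_TAF = 0.005,          # TAF molecule sets the cytokine diffusivity scale
    D_F = 0.01880,          # M2 growth factor: similar MW to M2f/IL-10
    field_tol = 1e-7, field_max_iter = 40000L,
    oxygen_tol = 1e-6,      # oxygen residual tolerance (source scale ~5)
    field_every = 3L,       # oxygen/cytokine re-solve cadence (steps)
    guidance_every = 6L,    # TAF and Ang2 re-solve cadence (steps): smooth
                            # long-range guidance fields with slowly moving
                            # sources

    ## -- vasculature --------------------------------------------------
    k_s = 2.24,         # natural shrinking tendency of vessel radius
    k_PC = 0.76,        # response rate of radius to tumor pressure
    P_CT = 1.0,        # critical collapse pressure (not in source tables)
    k_R = 2.24,         # restoring gain of the lumped growth stimulus
    stim_clip = 0.05,   # cap on the restoring excess (fraction of k_R);
                        # sets the tumor pressure at which collapse wins:
                        # P_CT + stim_clip*k_R/k_PC
    R_ref = 5,          # operating capillary radius, um
    R_init = 5,         # pre-existing capillary radius, um
    R_sprout = 3,       # radius of a newly formed sprout segment, um
    R_floor = 0.1,      # recovery floor for collapsed radii, um
    R_collapse = 0.5,   # below this a segment is collapsed (no flow), um
    R_max = 6.5,        # physical ceiling on capillary radius, um
    sprout_rate = 14,   # tip extension attempts per nondimensional day
    tem_sprout_gain = 4.5,# sprouting multiplier when a TEM is within range
    tem_range = 3,      # TEM influence radius, sites (Chebyshev)
    init_rate = 0.7,    # new-tip initiation rate per vessel site per day
    taf_sprout_threshold = 0.05,  # TAF level required to initiate a sprout
    sprout_min_age = 6L,         # extensions before a tip may anastomose
    tip_cap = 300L,              # active-tip budget (numerical guard)

    ## -- macrophages --------------------------------------------------
    k_M1 = 20, k_M2 = 20, k_T2 = 8.21, k_Ang2 = 0.95, k_T2M2 = 0.006,
    M_O = 1000, M_P = 350, M_C = 500, M_Ang2 = 1000,
    sign_O = -1, sign_P = 1, sign_C = 1,  # movement score orientations
    move_score_scale = 0.12,  # maps movement scores to per-step probabilities
    move_min_score = 1e-4,    # below this no direction interval qualifies
    diff_rate = 1.7,          # differentiation probability scale, /day
    extravasation_rate = 16,   # monocyte spawn rate scale, /day per unit TAF
    macro_density_cap = 0.2224, # intratumoral macrophages per site
                                # (2.78e4 / mm^3 over a 20-um voxel)
    lifespan_days = 7,        # agent removal age
    il10_pg_scale = 20,       # nondimensional IL-10 -> pg/mL map
    m1_center_bias = TRUE,    # M1 concentric-field bias switch

    ## -- initial condition --------------------------------------------
    lesion_radius_um = 50     # 100-um-diameter proliferating disk
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}
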