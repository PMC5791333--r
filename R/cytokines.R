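#' Reaction specifications for the model's diffusible factors
#'
#' Returns the [reaction_spec()] for each cytokine/factor: the
#' M1-differentiation factor (IL-6-like), M2-differentiation factor and
#' TEM-eluted IL-10 (both IL-10-like molecular weight), TEM-differentiation
#' factor, angiopoietin-2, the tumor angiogenic factor (TAF, VEGF-like) and
#' the M2 growth factor F. All share the generic production, wash-out and
#' decay rates; diffusivities differ by molecular weight.
#'
#' @param cfg Configuration list.
#' @return Named list of `tamsim_reaction` objects.
#' @export
cytokine_specs <- function(cfg = default_config()) {
  mk <- function(D, prod = cfg$cyto_production)
    reaction_spec(diffusivity = D, production = prod,
                  sink_linear = cfg$cyto_decay,
                  vessel_sink = cfg$cyto_washout)
  # TAF and Ang2 belong to the angiogenesis model (tumor- and
  # vasculature-sourced guidance fields acting over hundreds of um) and use
  # the long-range transport-unit rates; the macrophage-associated factors
  # use the pixel-scale proteomic rates (short halos around their sources)
  # guidance fields are O(1) concentrations like IL-10
  mk_long <- function(D) reaction_spec(diffusivity = D,
                                       production = cfg$cyto_production_eluted,
                                       sink_linear = cfg$taf_decay,
                                       vessel_sink = cfg$taf_washout)
  list(M1f = mk(cfg$D_M1f), M2f = mk(cfg$D_M2f),
       IL10 = mk(cfg$D_IL10, cfg$cyto_production_eluted),
       T2f = mk(cfg$D_T2f), Ang2 = mk_long(cfg$D_Ang2),
       TAF = mk_long(cfg$D_TAF), F = mk(cfg$D_F))
}

#' Solve one cytokine field given its source mask
#'
#' Thin wrapper over [solve_steady()] that returns an all-zero field
#' without solving when the source mask is empty (no production anywhere
#' means the only steady state is zero).
#'
#' @param name Cytokine name from [cytokine_specs()].
#' @param source_sites Production site indices.
#' @param vessel_sites_idx Wash-out (vessel) site indices.
#' @param grid Lattice.
#' @param cfg Configuration list.
#' @param init Warm start.
#' @return A [scalar_field()].
#' @export
solve_cytokine <- function(name, source_sites, vessel_sites_idx, grid,
                           cfg = default_config(), init = NULL) {
  if (!length(source_sites))
    return(scalar_field(grid, 0, name = name, bounds = c(0, 1)))
  spec <- cytokine_specs(cfg)[[name]]
  solve_steady(spec, source_sites, vessel_sites_idx, grid,
               tol = cfg$field_tol, max_iter = cfg$field_max_iter,
               init = init, name = name)
}
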