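#' Extravasation source coefficient at a vessel site
#'
#' The oxygen delivered by a perfused vessel is
#' `lambda_ev * (h/H_D - h_min)+ * (1 - k_Pi * p_i/p_e) * (1 - sigma)`:
#' hematocrit below the minimum fraction shuts the source off (the positive
#' part), and high interstitial pressure suppresses the convective
#' component. This helper returns the coefficient multiplying `(1 - sigma)`.
#'
#' @param h Local hematocrit (0 for unperfused vessel).
#' @param p_ratio Interstitial over effective pressure `p_i / p_e`.
#' @param cfg Configuration list.
#' @return The source coefficient (vectorized).
#' @export
extravasation_coefficient <- function(h, p_ratio = 0,
                                      cfg = default_config()) {
  cfg$lambda_ev * pmax(h / cfg$H_D - cfg$h_min, 0) *
    pmax(1 - cfg$k_Pi * p_ratio, 0)
}

#' Solve the steady-state oxygen field
#'
#' `0 = D lap(sigma) - lambda(sigma) sigma + lambda_ev(x)(1 - sigma)` with
#' region-dependent uptake (host tissue, proliferating, hypoxic, necrotic
#' rates) and hematocrit-gated extravasation at perfused vessel sites.
#' Interstitial pressure is approximated by the tumor oncotic pressure
#' scaled by `p_e` (capped at 1), preserving the qualitative
#' pressure-inhibited extravasation.
#'
#' @param labels Integer region labels (0 host, 1 P, 2 H, 3 N).
#' @param network A `tamsim_network` (perfused segments are the sources).
#' @param cfg Configuration list.
#' @param pressure Optional tumor pressure [scalar_field()].
#' @param init Warm-start values.
#' @param tol,max_iter,omega Solver controls (defaults from `cfg`).
#' @return Oxygen [scalar_field()] in `[0, 1]`.
#' @export
solve_oxygen <- function(labels, network, cfg = default_config(),
                         pressure = NULL, init = NULL,
                         tol = cfg$oxygen_tol, max_iter = cfg$field_max_iter,
                         omega = NULL) {
  g <- network$grid
  n <- n_sites(g)
  uptake <- numeric(n)
  uptake[labels == REGION_HOST] <- cfg$lambda_tissue
  uptake[labels == REGION_P] <- cfg$lambda_tumor
  uptake[labels == REGION_H] <- cfg$q_sigma
  uptake[labels == REGION_N] <- cfg$lambda_N
  uptake <- uptake * cfg$oxy_uptake_scale
  src_coef <- numeric(n)
  s <- network$segs[network$segs$perfused, , drop = FALSE]
  if (nrow(s)) {
    # effective hematocrit at a site: vessel-type hematocrit (normal for
    # the mature grid, low-flow for immature neovessels) scaled by a
    # Poiseuille-flavoured caliber factor (R/R_ref)^2, so partially
    # collapsed or recovering segments deliver little oxygen until they
    # regain operating caliber; a site on several segments takes the max
    h_seg <- ifelse(s$type == "neo", cfg$H_neo, cfg$H_D) *
      pmin((s$radius / cfg$R_ref)^2, 1)
    h_site <- numeric(n)
    idx <- c(s$i1, s$i2); val <- c(h_seg, h_seg)
    o <- order(val)                 # ascending assignment leaves the max
    h_site[idx[o]] <- val[o]
    ps <- which(h_site > 0)
    p_ratio <- if (is.null(pressure)) 0 else
      pmin(pmax(pressure$values[ps], 0) / cfg$p_e, 1)
    src_coef[ps] <- extravasation_coefficient(h_site[ps], p_ratio, cfg)
  }
  if (is.null(init)) init <- numeric(n)
  if (is.null(omega))
    omega <- sor_omega(1.0, cfg$lambda_tissue * cfg$oxy_uptake_scale, g)
  sol <- rd_gs_solve_cpp(g$nx, g$ny, g$h, 1.0,
                         src_coef, src_coef + uptake, init, tol, max_iter,
                         omega)
  log_solver("oxygen", sol$iterations)
  if (!sol$converged)
    stop(sprintf("steady-state solve for 'oxygen' did not converge: residual %.3g after %d sweeps",
                 sol$residual, sol$iterations))
  scalar_field(g, sol$values, name = "oxygen", bounds = c(0, 1))
}
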