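#' Radially decreasing synthetic field
#'
#' `peak * max(0, 1 - d/r0)` with `d` the Euclidean lattice distance from
#' `center`; closed form, used as a deterministic test field.
#'
#' @param grid A [make_grid()] lattice.
#' @param center `c(x, y)` lattice coordinates.
#' @param peak Value at the centre (in `[0, 1]`).
#' @param r0 Radius (in sites) at which the field reaches 0 (default:
#'   half the smaller grid dimension).
#' @return A [scalar_field()].
#' @export
make_radial_field <- function(grid, center = NULL, peak = 1, r0 = NULL) {
  stopifnot(peak >= 0, peak <= 1)
  if (is.null(center)) center <- c((grid$nx + 1) / 2, (grid$ny + 1) / 2)
  if (is.null(r0)) r0 <- min(grid$nx, grid$ny) / 2
  xy <- site_xy(grid, seq_len(n_sites(grid)))
  d <- sqrt((xy[, "x"] - center[1])^2 + (xy[, "y"] - center[2])^2)
  scalar_field(grid, peak * pmax(0, 1 - d / r0), name = "radial",
               bounds = c(0, 1))
}

#' Miniature deterministic scenarios for testing
#'
#' Registry of tiny, fully specified state bundles usable by any module:
#' \describe{
#'   \item{disk-growth}{25x25 grid, a 200-um-radius tumor disk with a
#'     uniform prescribed proliferation rate, for the analytic
#'     `dR/dt = lambda_p R / 2` growth oracle.}
#'   \item{tem-shield}{5x5 grid, one vessel segment with a TEM agent on an
#'     adjacent site, for the TEM radius-protection branch.}
#'   \item{collapse}{5x5 grid, one vessel segment under a tumor pressure
#'     above the critical collapse pressure.}
#'   \item{mini-case}{25x25 grid with a small tumor disk, a sparse
#'     capillary grid and a handful of agents of each subtype.}
#' }
#'
#' @param name Fixture name.
#' @param cfg Configuration list.
#' @return A named list bundle; contents depend on the fixture.
#' @export
make_mini_case <- function(name, cfg = default_config()) {
  registry <- c("disk-growth", "tem-shield", "collapse", "mini-case")
  if (!name %in% registry)
    stop("unknown fixture '", name, "'; available: ",
         paste(registry, collapse = ", "))
  switch(name,
    "disk-growth" = {
      grid <- make_grid(25, 25, 20)
      state <- make_tumor_state(grid, cfg, radius_um = 200)
      lambda_p <- 0.2
      list(grid = grid, state = state,
           lambda_p = rep(lambda_p, n_sites(grid)) *
             (state$phi > 0),
           rate = lambda_p,
           expected = "dR/dt = lambda_p * R / 2")
    },
    "tem-shield" = {
      grid <- make_grid(5, 5, 20)
      seg <- data.frame(i1 = site_index(grid, 2L, 3L),
                        i2 = site_index(grid, 3L, 3L),
                        radius = cfg$R_init, type = "pre", sprout = 0L,
                        perfusable = TRUE, perfused = TRUE,
                        pressurized = FALSE, stringsAsFactors = FALSE)
      net <- structure(list(grid = grid, segs = seg,
                            tips = empty_tips(), sprout_sites = list(),
                            next_sprout = 1L),
                       class = "tamsim_network")
      tem <- data.frame(site = site_index(grid, 3L, 4L), state = "TEM",
                        active = TRUE, age = 0, stringsAsFactors = FALSE)
      list(grid = grid, network = net, agents = tem,
           tem_sites = tem$site)
    },
    "collapse" = {
      grid <- make_grid(5, 5, 20)
      seg <- data.frame(i1 = site_index(grid, 2L, 3L),
                        i2 = site_index(grid, 3L, 3L),
                        radius = cfg$R_init, type = "pre", sprout = 0L,
                        perfusable = TRUE, perfused = TRUE,
                        pressurized = FALSE, stringsAsFactors = FALSE)
      net <- structure(list(grid = grid, segs = seg,
                            tips = empty_tips(), sprout_sites = list(),
                            next_sprout = 1L),
                       class = "tamsim_network")
      p_c <- cfg$P_CT + 1
      list(grid = grid, network = net, P_C = p_c,
           expected_S_s = cfg$k_s + cfg$k_PC * (p_c - cfg$P_CT))
    },
    "mini-case" = {
      grid <- make_grid(25, 25, 20)
      mini_cfg <- cfg
      mini_cfg$vessel_spacing_sites <- 8L
      net <- make_vessel_grid(grid, mini_cfg)
      state <- make_tumor_state(grid, cfg, radius_um = 100)
      agents <- data.frame(
        site = site_index(grid, c(5L, 6L, 7L, 18L, 19L, 20L),
                          c(5L, 6L, 7L, 18L, 19L, 20L)),
        state = c("monocyte", "M1", "M2", "TEM", "monocyte", "M1"),
        active = TRUE, age = 0, stringsAsFactors = FALSE)
      list(grid = grid, network = net, state = state, agents = agents,
           cfg = mini_cfg)
    })
}

empty_tips <- function() {
  data.frame(sprout = integer(), site = integer(), age = integer(),
             active = logical())
}

#' List the available miniature fixtures
#' @return Character vector of fixture names.
#' @export
list_fixtures <- function() {
  c("disk-growth", "tem-shield", "collapse", "mini-case")
}
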