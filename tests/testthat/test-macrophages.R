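uniform_fields <- function(grid, m1f = 0, m2f = 0, il10 = 0, t2f = 0,
                           ang2 = 0) {
  list(M1f = scalar_field(grid, m1f, bounds = c(0, 1)),
       M2f = scalar_field(grid, m2f, bounds = c(0, 1)),
       IL10 = scalar_field(grid, il10, bounds = c(0, 1)),
       T2f = scalar_field(grid, t2f, bounds = c(0, 1)),
       Ang2 = scalar_field(grid, ang2, bounds = c(0, 1)))
}

mono_agents <- function(sites) {
  data.frame(site = sites, state = "monocyte", active = TRUE, age = 0,
             stringsAsFactors = FALSE)
}

test_that("extravasation requires chemoattractant and an unoccupied site", {
  cfg <- default_config()
  g <- make_grid(9, 9)
  net <- full_perfusion_net(g)
  phi <- numeric(81)
  none <- extravasate(net, scalar_field(g, 0, bounds = c(0, 1)),
                      empty_agents(), phi, dt = 1, cfg)
  expect_identical(nrow(none), 0L)
  # a fully occupied vasculature cannot spawn regardless of concentration
  occupied <- mono_agents(seq_len(81))
  full <- extravasate(net, scalar_field(g, 1, bounds = c(0, 1)),
                      occupied, phi, dt = 10, cfg)
  expect_identical(nrow(full), 0L)
})

test_that("extravasation counts follow the binomial rate over many replicates", {
  cfg <- default_config(extravasation_rate = 4)
  g <- make_grid(9, 9)
  net <- full_perfusion_net(g)
  phi <- numeric(81)
  chemo <- scalar_field(g, 0.1, bounds = c(0, 1))
  p <- 4 * 0.05 * 0.1
  set.seed(21)
  n <- replicate(1000, nrow(extravasate(net, chemo, empty_agents(), phi,
                                        dt = 0.05, cfg)))
  n_trials <- 1000 * 81
  expect_equal(sum(n) / n_trials, p,
               tolerance = 3 * sqrt(p * (1 - p) / n_trials) / p)
})

test_that("differentiation weights implement the factor-concentration law", {
  cfg <- default_config()
  w <- differentiation_weights(0.1, 0.1, 0.5, 0.2, 0.3, cfg)
  expect_equal(unname(w[1, "M1"]), 20 * 0.1)
  expect_equal(unname(w[1, "M2"]), 20 * (0.1 + 0.006 * 0.5))
  expect_equal(unname(w[1, "TEM"]), 8.21 * 0.2 + 0.95 * 0.3)
  # equal M1/M2 factor fields give exactly equal weights
  w2 <- differentiation_weights(0.25, 0.25, 0, 0, 0, cfg)
  expect_identical(unname(w2[1, "M1"]), unname(w2[1, "M2"]))
})

test_that("zero factor concentrations leave monocytes undifferentiated", {
  cfg <- default_config()
  g <- make_grid(9, 9)
  agents <- mono_agents(1:30)
  set.seed(5)
  out <- differentiate(agents, uniform_fields(g), c("M1", "M2", "TEM"),
                       dt = 1, cfg)
  expect_true(all(out$state == "monocyte"))
})

test_that("differentiation frequencies match the categorical oracle", {
  # frozen example: weights 2.0, 2.06, 1.927 laid out as subintervals
  cfg <- default_config(diff_rate = 1)
  g <- make_grid(320, 320)
  flds <- uniform_fields(g, m1f = 0.1, m2f = 0.1, il10 = 0.5, t2f = 0.2,
                         ang2 = 0.3)
  agents <- mono_agents(seq_len(100000))
  set.seed(8)
  out <- differentiate(agents, flds, c("M1", "M2", "TEM"), dt = 0.1, cfg)
  w <- c(M1 = 2.0, M2 = 2.06, TEM = 8.21 * 0.2 + 0.95 * 0.3)
  p <- c(w * 0.1, none = 1 - sum(w) * 0.1)
  obs <- c(sum(out$state == "M1"), sum(out$state == "M2"),
           sum(out$state == "TEM"), sum(out$state == "monocyte"))
  chisq <- sum((obs - 1e5 * p)^2 / (1e5 * p))
  expect_lt(chisq, qchisq(0.99, df = 3))
})

test_that("disabled subtypes are drawn but rendered inert, not re-rolled", {
  cfg <- default_config(diff_rate = 1)
  g <- make_grid(110, 110)
  flds <- uniform_fields(g, m1f = 0.3, m2f = 0.3, t2f = 0.3, ang2 = 0.5)
  agents <- mono_agents(seq_len(5000))
  set.seed(13)
  all_on <- differentiate(agents, flds, c("M1", "M2", "TEM"), 0.05, cfg)
  set.seed(13)
  none_on <- differentiate(agents, flds, character(0), 0.05, cfg)
  expect_identical(all_on$state, none_on$state)
  expect_true(all(none_on$active[none_on$state != "monocyte"] == FALSE))
  expect_true(all(all_on$active))
})

test_that("agents stay put without gradients and follow a lone gradient", {
  cfg <- default_config()
  g <- make_grid(9, 9)
  flat <- list(grid = g, oxygen = rep(0.5, 81), pressure = numeric(81),
               chemo = rep(0.2, 81), ang2 = numeric(81),
               centering = numeric(81))
  a <- mono_agents(sidx(g, 5L, 5L))
  set.seed(2)
  for (i in 1:20) a <- move_agents(a, flat, cfg)
  expect_identical(a$site, sidx(g, 5L, 5L))
  # a single positive chemo direction forces that move
  cfg2 <- default_config(move_score_scale = 1)
  graded <- flat
  graded$chemo <- numeric(81)
  graded$chemo[sidx(g, 6L, 5L)] <- 0.5
  b <- mono_agents(sidx(g, 5L, 5L))
  b <- move_agents(b, graded, cfg2)
  expect_identical(b$site, sidx(g, 6L, 5L))
})

test_that("TEM drift follows the angiopoietin-2 gradient", {
  cfg <- default_config()
  g <- make_grid(41, 41)
  ang2 <- make_radial_field(g, center = c(21, 21), peak = 1, r0 = 30)
  bundle <- list(grid = g, oxygen = rep(0.5, 41^2), pressure = numeric(41^2),
                 chemo = numeric(41^2), ang2 = ang2$values,
                 centering = numeric(41^2))
  start <- sidx(g, 35L, 21L)
  tem <- data.frame(site = start, state = "TEM", active = TRUE, age = 0)
  set.seed(4)
  proj <- replicate(200, {
    a <- tem
    for (i in 1:25) a <- move_agents(a, bundle, cfg)
    x0 <- (start - 1) %% 41 + 1
    x1 <- (a$site - 1) %% 41 + 1
    x0 - x1            # positive = toward the centre source
  })
  # mean displacement toward the source, strongly nonzero (99% confidence)
  expect_gt(mean(proj) / (sd(proj) / sqrt(length(proj))), qnorm(0.99))
})

test_that("occupancy exclusion survives crowded movement", {
  cfg <- default_config(move_score_scale = 1)
  g <- make_grid(11, 11)
  chemo <- make_radial_field(g, center = c(6, 6), peak = 1, r0 = 10)
  bundle <- list(grid = g, oxygen = rep(0.5, 121), pressure = numeric(121),
                 chemo = chemo$values, ang2 = numeric(121),
                 centering = numeric(121))
  a <- mono_agents(seq_len(60))
  set.seed(6)
  for (i in 1:30) {
    a <- move_agents(a, bundle, cfg)
    expect_false(any(duplicated(a$site)))
  }
  expect_identical(nrow(a), 60L)
})

test_that("source masks map subtypes to their secreted factors", {
  g <- make_grid(9, 9)
  none <- emit_sources(empty_agents(), g)
  expect_length(none$f_sites, 0)
  expect_length(none$il10_sites, 0)
  expect_false(any(none$no_mask))
  m1 <- data.frame(site = sidx(g, 5L, 5L), state = "M1", active = TRUE,
                   age = 0)
  src <- emit_sources(m1, g)
  hood <- c(sidx(g, 5L, 5L), sidx(g, 6L, 5L), sidx(g, 4L, 5L),
            sidx(g, 5L, 6L), sidx(g, 5L, 4L))
  expect_setequal(which(src$no_mask), hood)
  tem <- data.frame(site = sidx(g, 3L, 3L), state = "TEM", active = TRUE,
                    age = 0)
  src2 <- emit_sources(tem, g)
  expect_length(src2$f_sites, 0)
  expect_identical(src2$il10_sites, sidx(g, 3L, 3L))
  # inert agents emit nothing
  m1$active <- FALSE
  expect_false(any(emit_sources(m1, g)$no_mask))
})

test_that("the IL-10 concentration map is linear in its scale", {
  cfg <- default_config()
  g <- make_grid(5, 5)
  f <- scalar_field(g, seq(0, 1, length.out = 25), bounds = c(0, 1))
  expect_equal(il10_concentration_pg_ml(scalar_field(g, 0), cfg),
               rep(0, 25))
  a <- il10_concentration_pg_ml(f, cfg)
  b <- il10_concentration_pg_ml(f, default_config(il10_pg_scale = 40))
  expect_equal(b, 2 * a)
})

test_that("named RNG streams are isolated and reproducible", {
  s1 <- make_streams(123)
  s2 <- make_streams(123)
  a1 <- with_stream(s1, "spawn", runif(5))
  # consuming another stream does not perturb the first
  invisible(with_stream(s2, "move", runif(100)))
  a2 <- with_stream(s2, "spawn", runif(5))
  expect_identical(a1, a2)
  b1 <- with_stream(s1, "diff", runif(3))
  b2 <- with_stream(s2, "diff", runif(3))
  expect_identical(b1, b2)
  expect_false(identical(a1[1:3], b1))
})
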