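test_that("build_geometry assembles the telescoping duct correctly", {
  g <- build_geometry(0.200)
  expect_length(g$sections, 2L)
  expect_equal(g$sections[[1]]$length, 0.080)
  expect_equal(g$sections[[1]]$area, 0.018 * 0.015)
  expect_equal(g$sections[[2]]$length, 0.120)
  expect_equal(g$sections[[2]]$area, pi * 0.016^2)

  g1 <- build_geometry(0.080)
  expect_length(g1$sections, 1L)
  expect_equal(g1$total_length, 0.080)

  g3 <- build_geometry(0.800)
  expect_length(g3$sections, 3L)
  expect_equal(vapply(g3$sections, `[[`, numeric(1), "length"),
               c(0.080, 0.120, 0.600))
  expect_equal(g3$total_length, 0.800, tolerance = 1e-12)

  expect_error(build_geometry(0.05), "invalid geometry")
})

test_that("section chain matrices obey the identity, quarter-wave and reciprocity contracts", {
  consts <- acoustic_constants()
  s_tiny <- tube_section(1e-12, 1)
  expect_equal(unclass(section_chain_matrix(500, s_tiny, consts)),
               diag(2) + 0i, tolerance = 1e-6)

  # k l = pi/2: quarter-wave phase zeroes the diagonal
  l <- consts$c0 / (4 * 500)
  K <- section_chain_matrix(500, tube_section(l, 1e-3), consts)
  expect_equal(abs(K[1, 1]), 0, tolerance = 1e-12)
  expect_equal(abs(K[2, 2]), 0, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    s <- tube_section(stats::runif(1, 0.01, 1), stats::runif(1, 1e-4, 1e-2))
    f <- stats::runif(1, 20, 5000)
    K <- section_chain_matrix(f, s, consts)
    expect_lt(abs(abs(K[1, 1] * K[2, 2] - K[1, 2] * K[2, 1]) - 1), 1e-6)
  }

  expect_error(section_chain_matrix(-5, s_tiny), "positive")
})

test_that("tract chain product is associative over section splits", {
  consts <- acoustic_constants()
  g1 <- tract_geometry(list(circ_section(0.30, 0.032)))
  g2 <- tract_geometry(list(circ_section(0.15, 0.032), circ_section(0.15, 0.032)))
  K1 <- tract_chain_matrix(777, g1, consts)
  K2 <- tract_chain_matrix(777, g2, consts)
  expect_equal(unclass(K1), unclass(K2), tolerance = 1e-9)

  expect_equal(unclass(tract_chain_matrix(300, g1, consts)),
               unclass(section_chain_matrix(300, g1$sections[[1]], consts)))

  expect_error(tract_chain_matrix(300, list(), consts), "invalid geometry")

  # splitting any section arbitrarily leaves Zin unchanged
  set.seed(7)
  base <- build_geometry(0.5)
  f <- seq(50, 900, by = 50)
  z0 <- input_impedance(f, base, consts)
  for (rep in 1:10) {
    secs <- list()
    for (s in base$sections) {
      frac <- stats::runif(1, 0.1, 0.9)
      secs <- c(secs, list(
        tube_section(s$length * frac, s$area, s$shape),
        tube_section(s$length * (1 - frac), s$area, s$shape)))
    }
    z1 <- input_impedance(f, tract_geometry(secs), consts)
    expect_lt(max(Mod(z1 - z0) / Mod(z0)), 1e-6)
  }
})

test_that("radiation impedance matches the piston limits", {
  consts <- acoustic_constants()
  S <- pi * 0.016^2
  z_lo <- radiation_impedance(1e-3, S, consts)
  expect_lt(Mod(z_lo) / (consts$rho0 * consts$c0 / S), 1e-5)

  # ka = 0.1: resistive part (ka)^2/2 = 0.005 of the characteristic impedance
  a <- sqrt(S / pi)
  f_ka01 <- 0.1 * consts$c0 / (2 * pi * a)
  z <- radiation_impedance(f_ka01, S, consts)
  expect_equal(Re(z), 0.005 * consts$rho0 * consts$c0 / S, tolerance = 1e-10)
  expect_equal(Im(z), (8 * 0.1 / (3 * pi)) * consts$rho0 * consts$c0 / S,
               tolerance = 1e-10)

  # full Bessel/Struve form agrees with the low-ka series below ka = 0.2
  ka <- seq(0.02, 0.18, by = 0.02)
  f <- ka * consts$c0 / (2 * pi * a)
  z_lo <- radiation_impedance(f, S, consts, method = "low_ka")
  z_ex <- radiation_impedance(f, S, consts, method = "exact")
  expect_lt(max(Mod(z_ex - z_lo) / Mod(z_ex)), 0.01)
})

test_that("input impedance reduces to the closed-open tube law", {
  consts <- acoustic_constants()
  l <- 0.40; S <- 1e-3
  g <- tract_geometry(list(tube_section(l, S)))
  f <- c(100, 150, 190)
  z <- input_impedance(f, g, consts, load = "none")
  zc <- consts$rho0 * consts$c0 / S
  expect_equal(Mod(z), zc * abs(tan(2 * pi * f / consts$c0 * l)),
               tolerance = 1e-10)

  # vanishing tract: Zin -> Zout
  g0 <- tract_geometry(list(tube_section(1e-9, S)))
  zout <- radiation_impedance(500, S, consts)
  expect_equal(input_impedance(500, g0, consts), zout, tolerance = 1e-6)

  # first peak of the quarter-wave resonator at c0 / (4 l)
  sp <- impedance_spectrum(g, seq(20, 1000, by = 0.25), consts, load = "none")
  r <- find_resonances(sp)$resonances
  expect_lt(abs(r[1] - consts$c0 / (4 * l)), 0.25)
})

test_that("impedance spectra are deterministic and reject bad grids", {
  g <- build_geometry(0.3)
  s1 <- impedance_spectrum(g, seq(20, 500, by = 0.5))
  s2 <- impedance_spectrum(g, seq(20, 500, by = 0.5))
  expect_identical(s1$Zin, s2$Zin)
  expect_true(all(is.finite(Mod(s1$Zin))))
  expect_error(impedance_spectrum(g, c(100, 50, 200)), "increasing")
})

test_that("parabolic refinement recovers an analytic Lorentzian peak", {
  f <- seq(100, 300, by = 1)
  fp <- 201.37
  sp <- lorentzian_spectrum(f, fp, gamma = 8)
  r <- find_resonances(sp)$resonances
  expect_lt(abs(r[which.min(abs(r - fp))] - fp), 0.2) # well under the 1 Hz grid
})

test_that("resonances shift down with tract length and scale with uniform-tube length", {
  m <- impedance_map(seq(0.2, 0.8, by = 0.1), seq(20, 1000, by = 0.5))
  fr1 <- m$resonances$fR1_Hz
  expect_true(all(diff(fr1) < 0))

  # single-length map equals the plain spectrum
  m1 <- impedance_map(0.3, seq(20, 1000, by = 0.5))
  sp <- impedance_spectrum(build_geometry(0.3), seq(20, 1000, by = 0.5))
  expect_equal(as.numeric(m1$magnitude[1, ]), Mod(sp$Zin))

  # halving a uniform closed-open tube doubles its first resonance
  fr <- function(l) {
    g <- tract_geometry(list(tube_section(l, 1e-3)))
    find_resonances(impedance_spectrum(g, seq(20, 1000, by = 0.25),
                                       load = "none"))$resonances[1]
  }
  expect_equal(fr(0.4) / fr(0.8), 2, tolerance = 5e-3)
})

test_that("geometry round-trips through the text config format", {
  g <- build_geometry(0.5)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(g, p)
  g2 <- read_geometry(p)
  expect_equal(g2$total_length, g$total_length, tolerance = 1e-6)
  expect_equal(vapply(g2$sections, `[[`, numeric(1), "area"),
               vapply(g$sections, `[[`, numeric(1), "area"), tolerance = 1e-6)
})
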