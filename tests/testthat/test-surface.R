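# Shrake-Rupley SASA and inter-chain interaction area

single_carbon <- function() point_structure(matrix(0, 1, 3))

test_that("SASA of an isolated carbon matches the analytic sphere", {
  s <- sasa(single_carbon())
  expect_equal(s$total, 4 * pi * (0.17 + 0.14)^2, tolerance = 0.01)
  # exact for any quadrature: no occlusion means every point is exposed
  expect_equal(sasa(single_carbon(), n_points = 60)$total, s$total,
               tolerance = 1e-9)
})

test_that("SASA is additive for well-separated atoms and converges in n_points", {
  two <- point_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  s <- sasa(two)
  iso <- 4 * pi * 0.31^2
  expect_equal(s$atom_area[1], iso, tolerance = 0.01)
  expect_equal(s$atom_area[2], iso, tolerance = 0.01)

  # doubling the quadrature changes the single-atom area by < 0.5%
  a1 <- sasa(single_carbon(), n_points = 960)$total
  a2 <- sasa(single_carbon(), n_points = 1920)$total
  expect_lt(abs(a2 - a1) / a1, 0.005)
  # and a partially occluded atom stays within quadrature noise
  close_pair <- point_structure(rbind(c(0, 0, 0), c(0.45, 0, 0)))
  b1 <- sasa(close_pair, n_points = 960)$atom_area[1]
  b2 <- sasa(close_pair, n_points = 1920)$atom_area[1]
  expect_lt(abs(b2 - b1) / b1, 0.01)
})

test_that("a fully caged atom has essentially zero accessible area", {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- point_structure(rbind(c(0, 0, 0), dirs * 0.3))
  s <- sasa(cage)
  expect_lt(s$atom_area[1], 0.01)
})

test_that("SASA is invariant under rigid transforms within quadrature tolerance", {
  fib <- small_fibril(2)
  base <- sasa(fib, n_points = 480)$total
  set.seed(101)
  moved <- sweep(coords(fib) %*% t(random_rot()), 2, c(3, -1, 4), "+")
  expect_equal(sasa(fib, moved, n_points = 480)$total, base,
               tolerance = 0.01)
})

test_that("sasa validates its inputs", {
  expect_error(sasa(single_carbon(), n_points = 10), ">= 60")
  weird <- point_structure(matrix(0, 1, 3), element = "XX")
  expect_error(sasa(weird), "XX")
})

test_that("buried area is symmetric, zero at separation, monotone in approach", {
  fib <- small_fibril(2)
  a <- select_atoms(fib, chains = "A")
  b <- select_atoms(fib, chains = "B")
  ab <- buried_area(fib, mask_a = a, mask_b = b, n_points = 480)
  ba <- buried_area(fib, mask_a = b, mask_b = a, n_points = 480)
  expect_identical(ab, ba)  # exact symmetry by construction
  expect_gt(ab, 0)
  expect_error(buried_area(fib, mask_a = a, mask_b = a), "disjoint")

  # pull chain B away along the fibril axis: area decreases, then vanishes
  xyz <- coords(fib)
  shifted <- function(dz) {
    out <- xyz
    out[b, 3] <- out[b, 3] + dz
    out
  }
  # within occlusion reach the area decreases strictly with separation,
  # and vanishes once the chains are fully apart (2x the stacking rise
  # already puts every atom pair beyond probe contact)
  a1 <- buried_area(fib, shifted(0.1), a, b, n_points = 480)
  a2 <- buried_area(fib, shifted(0.25), a, b, n_points = 480)
  a3 <- buried_area(fib, shifted(0.48), a, b, n_points = 480)
  a5 <- buried_area(fib, shifted(5.0), a, b, n_points = 480)
  expect_gt(ab, a1)
  expect_gt(a1, a2)
  expect_gte(a2, a3)
  expect_lt(a3, 1e-6)
  expect_lt(a5, 1e-6)
})

test_that("interchain series sums adjacent pairs and flags a removed chain", {
  fib <- build_ideal_fibril(fibril_spec(n_chains = 3))
  xyz <- coords(fib)
  far <- xyz
  csel <- select_atoms(fib, chains = "C")
  far[csel, 3] <- far[csel, 3] + 5  # chain C removed to 5 nm
  tr <- coords_trajectory(fib, list(xyz, far))
  # the ideal backbone's closest heavy-atom pair sits at 0.357 nm, so use a
  # 0.4 nm count cutoff to exercise the secondary contact metric
  ser <- interchain_area_series(tr, n_points = 240, contact_cutoff = 0.4)
  f1 <- ser[ser$frame == 1, ]
  expect_equal(nrow(f1), 2L)  # pairs A-B and B-C
  expect_true(all(f1$buried_area_nm2 > 0))
  f2 <- ser[ser$frame == 2, ]
  expect_lt(f2$buried_area_nm2[f2$chain_j == "C"], 1e-6)
  expect_gt(f2$buried_area_nm2[f2$chain_j == "B"], 1)
  totals <- attr(ser, "totals")
  expect_equal(totals$total_area_nm2,
               c(sum(f1$buried_area_nm2), sum(f2$buried_area_nm2)))
  # contact-pair counts mirror the same geometry
  expect_gt(f1$contact_pairs[1], 0)
  expect_equal(f2$contact_pairs[f2$chain_j == "C"], 0L)

  one <- build_ideal_fibril(fibril_spec(n_chains = 1))
  tr1 <- make_trajectory(one, "stable", amplitude = 0, n_frames = 2)
  expect_error(interchain_area_series(tr1), "2 protein chains")
})

test_that("a stable run keeps the interaction area nearly constant", {
  fib <- small_fibril()
  tr <- make_trajectory(fib, "stable", amplitude = 0.01, n_frames = 10,
                        seed = 3)
  ser <- interchain_area_series(tr, n_points = 240)
  totals <- attr(ser, "totals")$total_area_nm2
  expect_lt(sd(totals) / mean(totals), 0.1)  # CV under 10%
})
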