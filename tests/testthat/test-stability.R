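# order parameter, bound-frame masking, contact probability, report

test_that("order parameter is exactly 1 on self-referential trajectories", {
  fib <- small_fibril()
  tr <- make_trajectory(fib, "stable", amplitude = 0, n_frames = 4)
  op <- order_parameter(tr)
  expect_equal(op$ordp, rep(1, 4), tolerance = 1e-9)
  expect_equal(attr(op, "mean"), 1, tolerance = 1e-9)
})

test_that("per-chain 90-degree rotation about z gives ordP 0 with fit off", {
  fib <- small_fibril()
  xyz <- coords(fib)
  a <- fib$atoms
  rotated <- xyz
  rot <- rotation_about_z(pi / 2)
  for (ch in unique(a$chain)) {
    sel <- which(a$chain == ch)
    cm <- colMeans(xyz[a$chain == ch & a$name == "CA", , drop = FALSE])
    rotated[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2, cm) %*%
                              t(rot), 2, cm, "+")
  }
  tr <- coords_trajectory(fib, list(xyz, rotated))
  op <- order_parameter(tr, fit = FALSE)
  # chains are planar, all connecting vectors lie in xy: rotating each chain
  # 90 degrees about its own centre makes every vector orthogonal
  expect_equal(op$ordp[2], 0, tolerance = 1e-9)
})

test_that("fitting removes arbitrary global rigid transforms", {
  fib <- small_fibril()
  xyz <- coords(fib)
  set.seed(111)
  frames <- c(list(xyz), lapply(1:4, function(i) {
    sweep(xyz %*% t(random_rot()), 2, stats::rnorm(3, sd = 5), "+")
  }))
  tr <- coords_trajectory(fib, frames)
  op_fit <- order_parameter(tr, fit = TRUE)
  expect_equal(op_fit$ordp, rep(1, 5), tolerance = 1e-9)
  op_raw <- order_parameter(tr, fit = FALSE)
  expect_lt(min(op_raw$ordp), 0.99)  # without fitting the transforms show up
})

test_that("scrambled chain orientations average to zero order", {
  fib <- small_fibril()
  tr <- make_trajectory(fib, "scramble", n_frames = 300, seed = 13)
  op <- order_parameter(tr, fit = FALSE)
  vals <- op$ordp[-1]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
  expect_true(all(abs(op$ordp) <= 1 + 1e-12))
})

test_that("order degrades monotonically with jitter amplitude", {
  fib <- small_fibril()
  means <- vapply(c(0.01, 0.05, 0.1, 0.2), function(amp) {
    tr <- make_trajectory(fib, "stable", amplitude = amp, n_frames = 20,
                          seed = 17)
    attr(order_parameter(tr), "mean")
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("residue-centre mode is available and bounded", {
  fib <- small_fibril(2)
  tr <- make_trajectory(fib, "stable", amplitude = 0.05, n_frames = 5,
                        seed = 19)
  op <- order_parameter(tr, com_mode = "residue")
  expect_true(all(op$ordp >= -1 - 1e-12 & op$ordp <= 1 + 1e-12))
  expect_equal(op$ordp[1], 1, tolerance = 1e-9)
})

test_that("bound_frames applies a strict cutoff per frame", {
  topo <- fibril_structure(tibble::tibble(
    serial = 1:3, name = c("CA", "CA", "C1"),
    element = "C", resname = c("GLY", "GLY", "LIG"),
    resid = c(1L, 2L, 9L), chain = c("A", "A", "L"),
    x = 0, y = 0, z = 0, hetero = c(FALSE, FALSE, TRUE)))
  # cutoff 0.25 nm is exactly representable in binary, so the boundary
  # frame sits at exactly the cutoff distance
  near <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0, 0, 0.2))
  exact <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0, 0, 0.25))
  far <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0, 0, 5))
  tr <- coords_trajectory(topo, list(near, exact, far))
  b <- bound_frames(tr, ligand_mask = 3L, receptor_mask = 1:2,
                    cutoff = 0.25)
  expect_identical(b, c(TRUE, FALSE, FALSE))  # boundary case excluded
  expect_error(bound_frames(tr, integer(), 1:2), "empty")
  expect_error(bound_frames(tr, 2:3, 1:3), "disjoint")
})

test_that("a ligand glued in the pocket is bound in every frame", {
  fib <- plant_ligand(small_fibril(), "pocket", seed = 5)
  tr <- make_trajectory(fib, "stable", amplitude = 0.005, n_frames = 6,
                        seed = 5)
  lig <- select_atoms(fib, hetero = TRUE)
  rec <- select_atoms(fib, hetero = FALSE)
  expect_true(all(bound_frames(tr, lig, rec)))
})

test_that("contact probabilities match the per-chain exhaustive oracle", {
  set.seed(131)
  for (trial in 1:8) {
    fib <- plant_ligand(small_fibril(2), "pocket", n_atoms = 5, seed = trial)
    tr <- make_trajectory(fib, "stable", amplitude = 0.3, n_frames = 5,
                          seed = trial)
    lig <- select_atoms(fib, hetero = TRUE)
    got <- residue_contact_probability(tr, lig)
    want <- oracle_contact_probability(tr, lig, 0.35)
    expect_equal(setNames(got$probability,
                          paste0(got$resid, "|", got$resname)),
                 want[paste0(got$resid, "|", got$resname)])
  }
})

test_that("contact probability arithmetic and any-chain pooling behave", {
  # ligand permanently 0.3 nm from residue 2 of chain B only
  topo <- fibril_structure(tibble::tibble(
    serial = 1:5, name = c("CA", "CA", "CA", "CA", "C1"),
    element = "C", resname = c("GLY", "PHE", "GLY", "PHE", "LIG"),
    resid = c(1L, 2L, 1L, 2L, 9L), chain = c("A", "A", "B", "B", "L"),
    x = c(0, 0.4, 0, 0.4, 0.7), y = c(0, 0, 0, 0, 0),
    z = c(0, 0, 2, 2, 2), hetero = c(FALSE, FALSE, FALSE, FALSE, TRUE)))
  xyz <- coords(topo)
  away <- xyz
  away[5, 3] <- 50
  tr <- coords_trajectory(topo, list(xyz, xyz, xyz, away, away,
                                     away, away, away, away, away))
  cm <- residue_contact_probability(tr, 5L)
  # contact with chain B's copy counts for the chain-agnostic identity
  expect_equal(cm$probability[cm$resid == 2], 0.3)  # 3 of 10 frames
  expect_equal(cm$probability[cm$resid == 1], 0)
  expect_equal(attr(cm, "n_frames"), 10L)

  # frame-mask consistency: P over the union of disjoint masks is the
  # count-weighted mean of the parts
  p_a <- residue_contact_probability(tr, 5L, frames = 1:3)
  p_b <- residue_contact_probability(tr, 5L, frames = 4:10)
  pooled <- (3 * p_a$probability + 7 * p_b$probability) / 10
  expect_equal(cm$probability, pooled)
  expect_error(residue_contact_probability(tr, 5L, frames = integer()),
               "no bound frames")
})

test_that("summarize_complex runs all metrics on one window and frame set", {
  fib <- plant_ligand(small_fibril(), "pocket", seed = 7)
  tr <- make_trajectory(fib, "stable", amplitude = 0.01, n_frames = 12,
                        seed = 7)
  cfg <- analysis_config(analysis_window_ns = 6, sasa_points = 240)
  rep <- summarize_complex(tr, config = cfg)
  expect_s3_class(rep, "stability_report")
  expect_equal(rep$n_frames, 6L)
  expect_equal(nrow(rep$per_frame), 6L)
  expect_gt(nrow(rep$contact_map), 0L)
  expect_true(all(rep$contact_map$probability >= 0 &
                    rep$contact_map$probability <= 1))
  g <- glance(rep)
  expect_equal(g$beta_pct_mean, 100 * mean(rep$per_frame$beta_fraction))
  expect_equal(tidy(rep), rep$per_frame)

  # ligand-free input: wild-type report with an empty contact map
  apo <- make_trajectory(small_fibril(), "stable", amplitude = 0.01,
                         n_frames = 12, seed = 7)
  rep0 <- summarize_complex(apo, config = cfg)
  expect_false(rep0$has_ligand)
  expect_equal(nrow(rep0$contact_map), 0L)
  expect_gt(rep0$beta_pct_mean, 0)

  expect_error(summarize_complex(apo, config = analysis_config(
    analysis_window_ns = 99)), "window")
})

test_that("a pocket ligand's hottest contacts lie in the planted pocket strand", {
  fib <- plant_ligand(build_ideal_fibril(), "pocket", seed = 11)
  tr <- make_trajectory(fib, "stable", amplitude = 0.01, n_frames = 6,
                        seed = 11)
  lig <- select_atoms(fib, hetero = TRUE)
  cm <- residue_contact_probability(tr, lig)
  hot <- cm$resid[cm$probability >= 0.5]
  expect_gt(length(hot), 0)
  # the pocket centre sits on the middle meander strand (residues 22-31)
  expect_true(all(hot >= 20 & hot <= 33))
})
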