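test_that("anisotropic point-source potential has the analytic limits", {
  iso <- tissue_conductivities(endoneurium = c(1, 1, 1 + 1e-12))
  v <- extracellular_potential(c(0, 0, 0), 1, c(1, 0, 0), iso)
  expect_equal(v, 1 / (4 * pi), tolerance = 1e-12)
  # linearity in current
  cond <- tissue_conductivities()
  p <- c(0.3, -0.2, 0.5)
  expect_equal(extracellular_potential(c(0, 0, 0), 2, p, cond),
               2 * extracellular_potential(c(0, 0, 0), 1, p, cond))
  # x/y symmetry of the transversely isotropic tensor; z decays slower
  vx <- extracellular_potential(c(0, 0, 0), 1, c(1, 0, 0), cond)
  vy <- extracellular_potential(c(0, 0, 0), 1, c(0, 1, 0), cond)
  vz <- extracellular_potential(c(0, 0, 0), 1, c(0, 0, 1), cond)
  expect_equal(vx, vy)
  expect_gt(vz, vx)
  # 1/r decay along a principal axis
  r <- c(0.5, 1, 2, 4)
  vr <- extracellular_potential(c(0, 0, 0), 1, cbind(r, 0, 0), cond)
  expect_equal(vr * r, rep(vr[2], 4), tolerance = 1e-12)
  # perineurium attenuation per crossing
  expect_equal(extracellular_potential(c(0, 0, 0), 1, p, cond, crossings = 2),
               0.09 * extracellular_potential(c(0, 0, 0), 1, p, cond))
  expect_error(extracellular_potential(c(1, 2, 3), 1, c(1, 2, 3)), "coincides")
})

test_that("potential agrees with a finite-difference Poisson solve", {
  skip_if_not_installed("Matrix")
  sig <- tissue_conductivities()$endoneurium
  n <- 21; h <- 0.15
  xs <- (seq_len(n) - (n + 1) / 2) * h
  idx <- function(i, j, k) (k - 1) * n * n + (j - 1) * n + i
  N <- n^3
  coords <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  x <- xs[coords$i]; y <- xs[coords$j]; z <- xs[coords$k]
  interior <- coords$i > 1 & coords$i < n & coords$j > 1 & coords$j < n &
    coords$k > 1 & coords$k < n
  src_id <- idx((n + 1) / 2, (n + 1) / 2, (n + 1) / 2)
  pts <- cbind(x, y, z); pts[src_id, ] <- c(10, 10, 10)
  ana <- extracellular_potential(c(0, 0, 0), 1, pts)
  ana[src_id] <- 0
  ii <- which(interior)
  rows <- rep(ii, each = 7)
  cols <- as.vector(t(cbind(ii,
                            ii - 1, ii + 1,
                            ii - n, ii + n,
                            ii - n * n, ii + n * n)))
  vals <- rep(c(-2 * sum(sig), sig[1], sig[1], sig[2], sig[2],
                sig[3], sig[3]), length(ii))
  rows <- c(rows, which(!interior))
  cols <- c(cols, which(!interior))
  vals <- c(vals, rep(1, sum(!interior)))
  b <- numeric(N)
  b[!interior] <- ana[!interior]
  b[src_id] <- b[src_id] - 1 / h
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  V <- as.numeric(Matrix::solve(A, b))
  # off-axis and transverse points: <= 2% relative error; the point on the
  # high-conductivity axis carries more source-discretisation error
  check <- function(pt, tol) {
    j <- which.min((x - pt[1])^2 + (y - pt[2])^2 + (z - pt[3])^2)
    va <- extracellular_potential(c(0, 0, 0), 1,
                                  matrix(c(x[j], y[j], z[j]), ncol = 3))
    expect_lt(abs(V[j] - va) / abs(va), tol)
  }
  check(c(0.6, 0, 0), 0.02)
  check(c(0, 0.6, 0), 0.02)
  check(c(0.45, 0.45, 0.45), 0.02)
  check(c(-0.45, 0.3, 0.3), 0.02)
  check(c(0, 0, 1.2), 0.05)
})

test_that("axon recruitment thresholds behave like a cable model", {
  el <- electrode_model("needle", position = c(0.4, 0, 0))
  fib <- function(D, x = 0) data.frame(x = x, y = 0, diameter = D,
                                       z_offset = 0.1)
  ve <- fiber_node_potentials(fib(9), el)
  expect_length(ve, 21)
  # zero amplitude never recruits
  expect_false(axon_recruited_cpp(ve, 0, 9, 100))
  # threshold decreases with fiber diameter
  thr <- vapply(c(5, 7, 9, 12), function(D)
    fiber_threshold(fib(D), el), numeric(1))
  expect_true(all(diff(thr) < 0))
  # threshold increases with electrode-fiber distance
  thr_d <- vapply(c(0.2, 0.5, 1.0), function(d)
    fiber_threshold(fib(9), electrode_model("needle", position = c(d, 0, 0))),
    numeric(1))
  expect_true(all(diff(thr_d) > 0))
})

test_that("fiber populations respect counts, nesting and determinism", {
  p1 <- sample_population("large", 1, seed = 5, n_fibers = 100)
  expect_equal(nrow(p1$fibers), 100)
  rad <- sqrt(p1$fibers$x^2 + p1$fibers$y^2)
  expect_true(all(rad <= p1$fascicle_radius + 1e-9))
  expect_true(all(p1$fibers$diameter >= 3))

  p9 <- sample_population("large", 9, seed = 5, n_fibers = 100)
  expect_lt(p9$extent_radius, p1$extent_radius)
  # nested extents stay inside the fascicle
  rad9 <- sqrt((p9$fibers$x - p9$centroid[1])^2 +
                 (p9$fibers$y - p9$centroid[2])^2)
  expect_true(all(rad9 <= p9$extent_radius + 1e-9))
  expect_true(all(sqrt(p9$fibers$x^2 + p9$fibers$y^2) <=
                    p9$fascicle_radius + 1e-9))
  # monotone nesting of extents across ids
  ext <- vapply(1:9, function(id)
    sample_population("large", id, seed = 1, n_fibers = 2)$extent_radius,
    numeric(1))
  expect_true(all(diff(ext) < 0))

  expect_identical(sample_population("medium", 3, seed = 2)$fibers,
                   sample_population("medium", 3, seed = 2)$fibers)
  expect_error(sample_population("small", 2, seed = 1), "1..1")
  expect_error(sample_population("medium", 6, seed = 1), "1..5")
})

test_that("the simulation plan enumerates 45 needle and 90 TIME cases", {
  plan <- enumerate_simulation_plan()
  expect_equal(sum(plan$device == "needle"), 45)
  expect_equal(sum(plan$device == "TIME"), 90)
  expect_equal(nrow(plan), 135)
  expect_equal(anyDuplicated(plan$case), 0)
  expect_equal(sort(unique(plan$placement)),
               c("adjacent", "shielded", "within"))
  # population ensembles: 9 large + 5 medium + 1 small per placement
  expect_equal(sum(plan$device == "needle" & plan$placement == "within"), 15)
})

test_that("recruitment curves are monotone and placement-ordered", {
  pop <- sample_population("large", 5, seed = 9, n_fibers = 8)
  el <- electrode_model("needle")
  grid <- c(seq(0, 100, by = 2), seq(105, 1500, by = 5))
  cur_w <- recruitment_curve(pop, el, placement = "within", charge_grid = grid)
  expect_equal(cur_w$fraction_recruited[1], 0)
  expect_true(all(diff(cur_w$fraction_recruited) >= 0))
  expect_true(all(cur_w$fraction_recruited >= 0 & cur_w$fraction_recruited <= 1))
  cur_s <- recruitment_curve(pop, el, placement = "shielded", charge_grid = grid)
  q_w <- charge_at_recruitment(cur_w, 0.10)
  q_s <- charge_at_recruitment(cur_s, 0.10)
  expect_lt(q_w, q_s)
  expect_error(recruitment_curve(pop, el, charge_grid = c(1, 1, 2)),
               "increasing")
})

test_that("device comparison detects shifts and tolerates ties", {
  same <- data.frame(device = rep(c("needle", "TIME"), each = 10),
                     charge_at_level = rep(1:10, 2))
  r <- compare_devices(same)
  expect_gt(r$p_value, 0.9)
  expect_false(r$significant)

  shifted <- same
  shifted$charge_at_level[shifted$device == "TIME"] <-
    10 * shifted$charge_at_level[shifted$device == "TIME"]
  r2 <- compare_devices(shifted)
  expect_lt(r2$p_value, 0.05)
  expect_true(r2$significant)

  with_na <- same
  with_na$charge_at_level[1] <- NA
  expect_equal(compare_devices(with_na)$n_excluded, 1)
  expect_error(compare_devices(same[same$device == "TIME", ]), "nonempty")
})

test_that("needle tip-exposure variants give comparable thresholds", {
  pop <- sample_population("large", 5, seed = 13, n_fibers = 6)
  thr <- lapply(c(50, 150), function(exp_um) {
    el <- electrode_model("needle", tip_exposure_um = exp_um)
    cur <- recruitment_curve(pop, el, placement = "within")
    cur$thresholds_nC
  })
  expect_equal(thr[[1]], thr[[2]], tolerance = 0.25)
  p <- kruskal.test(list(thr[[1]], thr[[2]]))$p.value
  expect_gt(p, 0.05)
})
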