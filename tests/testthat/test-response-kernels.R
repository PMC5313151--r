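test_that("growing degree days accumulate positive exceedances only", {
  expect_equal(growing_degree_days(c(4, 6, 10), t_base = 5), 6)
  expect_equal(growing_degree_days(c(-3, 0, 5, 4.9)), 0)
  expect_equal(growing_degree_days(rep(15, 10), t_base = 5), 100)
  expect_error(growing_degree_days(numeric()), "empty")
  expect_error(growing_degree_days(c(10, NA)), "non-finite")
  expect_error(growing_degree_days(c(10, Inf)), "non-finite")
})

test_that("degree-day accumulation is additive over season blocks", {
  set.seed(42)
  for (i in 1:20) {
    temps <- runif(60, -5, 25)
    cut <- sample(1:59, 1)
    expect_equal(growing_degree_days(temps),
                 growing_degree_days(temps[1:cut]) +
                   growing_degree_days(temps[(cut + 1):60]))
  }
})

test_that("light response matches closed form and clamps to [0, 1]", {
  p <- ref_kernel()
  expect_equal(response_par(p$cp, p), 0)
  # 1 - exp(-4.64 * 0.95) by direct arithmetic
  expect_equal(response_par(1, p), 1 - exp(-4.64 * 0.95), tolerance = 1e-12)
  expect_equal(response_par(1, p), 0.98782, tolerance = 1e-4)
  expect_equal(response_par(0.02, p), 0)  # below compensation point
  # c1 > 1 saturates at 1 rather than exceeding it
  p2 <- species_params("i", 2.24, 1.136, 0.08, 0, 1, 0.5, 1000, 3000, 1)
  expect_equal(response_par(1, p2), 1)
})

test_that("soil-water response is exactly 1 at the optimum and 0 at limits", {
  p <- ref_kernel()
  expect_equal(response_swc(0.5, p), 1)
  expect_equal(response_swc(0.25, p), 0.75)  # alpha = 1, kappa = 4
  expect_equal(response_swc(0, p), 0)
  expect_equal(response_swc(1, p), 0)
  expect_equal(response_swc(-0.2, p), 0)
  set.seed(7)
  for (i in 1:25) {
    q <- random_kernel()
    expect_equal(response_swc(q$psi, q), 1, tolerance = 1e-12)
    expect_equal(response_swc(q$swc_min, q), 0)
    expect_equal(response_swc(q$swc_max, q), 0)
  }
})

test_that("soil-water response is unimodal about the optimum", {
  set.seed(11)
  for (i in 1:10) {
    q <- random_kernel()
    up <- seq(q$swc_min + 1e-6, q$psi, length.out = 200)
    dn <- seq(q$psi, q$swc_max - 1e-6, length.out = 200)
    expect_true(all(diff(response_swc(up, q)) > -1e-12))
    expect_true(all(diff(response_swc(dn, q)) < 1e-12))
  }
})

test_that("degree-day response is a symmetric clamped parabola", {
  p <- ref_kernel()
  expect_equal(response_gdd(2000, p), 1)
  expect_equal(response_gdd(1500, p), 0.75)  # 4*500*1500/2000^2
  expect_equal(response_gdd(1000, p), 0)
  expect_equal(response_gdd(3000, p), 0)
  expect_equal(response_gdd(500, p), 0)
  expect_equal(response_gdd(5000, p), 0)
  set.seed(13)
  for (i in 1:10) {
    q <- random_kernel()
    mid <- (q$gdd_min + q$gdd_max) / 2
    d <- runif(5, 0, (q$gdd_max - q$gdd_min))
    expect_equal(response_gdd(mid + d, q), response_gdd(mid - d, q))
  }
})

test_that("all kernels stay in [0, 1] and light response is monotone above cp", {
  set.seed(17)
  for (i in 1:15) {
    q <- random_kernel()
    x <- runif(100, -0.5, 1.5)
    g <- runif(100, 0, 6000)
    for (r in list(response_par(pmin(pmax(x, 0), 1), q), response_swc(x, q),
                   response_gdd(g, q))) {
      expect_true(all(r >= 0 & r <= 1))
    }
    grid <- seq(q$cp, 1, length.out = 100)
    expect_true(all(diff(response_par(grid, q)) > -1e-12))
  }
})

test_that("kernels vectorize over rasters and propagate nodata", {
  p <- ref_kernel()
  m <- matrix(c(0.5, NA, 0.9, 0.1), 2, 2)  # NA sits at [2, 1]
  r <- tiny_raster(m)
  out <- response_swc(r, p)
  expect_s3_class(out, "raster_surface")
  expect_true(is.na(out$grid[2, 1]))
  expect_equal(out$grid[1, 1], response_swc(0.5, p))
  out2 <- response_par(r, p)
  expect_true(is.na(out2$grid[2, 1]))
  out3 <- response_gdd(tiny_raster(m * 2000), p)
  expect_true(is.na(out3$grid[2, 1]))
  expect_false(anyNA(out3$grid[, 2]))
})

test_that("parameter validation rejects inconsistent kernels", {
  expect_error(species_params("x", 1, 4, 0.05, 0.6, 0.4, 0.5, 100, 200),
               "swc_min < psi < swc_max")
  expect_error(species_params("x", 1, 4, 0.05, 0, 1, 0.5, 300, 200),
               "gdd_min < gdd_max")
  expect_error(species_params("x", 1, -4, 0.05, 0, 1, 0.5, 100, 200),
               "c2")
  expect_error(species_params("x", 1, 4, 1.2, 0, 1, 0.5, 100, 200), "cp")
  expect_error(species_params("x", 1, 4, 0.05, 0, 1, 0.5, 100, 200,
                              shade_tolerance_class = 9), "1..5")
})

test_that("swc shape constants obey their defining identities", {
  set.seed(23)
  for (i in 1:10) {
    q <- random_kernel()
    sh <- swc_shape(q)
    expect_gt(sh$chi, 0); expect_lt(sh$chi, 1)
    expect_equal(sh$alpha, sh$chi / (1 - sh$chi))
    expect_equal(sh$kappa_norm * sh$chi^sh$alpha * (1 - sh$chi)^(1 / sh$alpha),
                 1, tolerance = 1e-12)
  }
})

test_that("species parameter tables round-trip with validation", {
  set.seed(99)
  p <- list(a = ref_kernel("a"), b = random_kernel("b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_species_params(p, path)
  back <- read_species_params(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a[names(back$a) != "species_code"],
               p$a[names(p$a) != "species_code"])
  # corrupt a row: error cites the line
  df <- read.csv(path)
  df$psi[2] <- 2
  write.csv(df, path, row.names = FALSE)
  expect_error(read_species_params(path), "line 3")
})
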