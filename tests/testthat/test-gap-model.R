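test_that("height allometry hits breast height and the maximum exactly", {
  g <- ref_growth()
  expect_equal(height_from_dbh(g$d_max, g), g$h_max)
  expect_equal(height_from_dbh(10, g), 1167.68)  # 137 + 114.52*10 - 1.1452*100
  expect_equal(height_from_dbh(1e-9, g), 137, tolerance = 1e-4)
  expect_error(height_from_dbh(0, g), "dbh")
})

test_that("optimal increment matches the growth equation and vanishes at d_max", {
  g <- ref_growth()
  expect_equal(optimal_increment(g$d_max, g), 0)
  expect_equal(optimal_increment(10, g), 1567.66 / 3251.52, tolerance = 1e-4)
  d <- seq(0.5, 50, by = 0.5)
  expect_true(all(optimal_increment(d, g) >= 0))
})

test_that("biomass allometry is a power law", {
  g <- ref_growth(biomass_a = 0.1, biomass_b = 2.4)
  expect_equal(aboveground_biomass(10, g), 0.1 * 10^2.4)
  expect_equal(aboveground_biomass(10, g), 25.119, tolerance = 1e-4)
  expect_equal(aboveground_biomass(20, g) / aboveground_biomass(10, g), 2^2.4)
})

test_that("light multiplier follows Beer-Lambert shading and tolerance class", {
  expect_equal(exp(-0.4 * 2), 0.4493, tolerance = 1e-4)
  full <- light_multiplier(0, 5)
  expect_gt(full, 0.95)   # unshaded tolerant crown near maximum
  expect_gt(light_multiplier(0, 5), light_multiplier(2, 5))
  # deep shade: available light below the intolerant compensation point
  deep_lai <- -log(0.065) / 0.4  # AL = 0.065 < cp of class 1 (0.08)
  expect_equal(light_multiplier(deep_lai, 1), 0)
  expect_gt(light_multiplier(deep_lai, 5), 0)  # tolerant still grows
  expect_error(light_multiplier(1, 3, extinction_k = 0), "extinction_k")
})

test_that("growth step applies multipliers and shades only shorter trees", {
  g <- ref_growth()
  pt <- list(ref = g)
  site_opt <- site_conditions(gdd = 2000, swc = 0.5, nutrient_index = 1,
                              plot_area = 1e9)  # negligible LAI: no shading
  s1 <- make_stand("ref", 10)
  out <- annual_growth_step(s1, site_opt, pt)
  r_swc <- response_swc(0.5, species_params("ref", 1, 4.64, 0.05, 0.05, 0.95,
                                            0.5, 1000, 3000, 3))
  # single tree at an optimal site: realized = optimal x f_light(unshaded)
  exp_mult <- light_multiplier(0, 3) * 1 * response_swc(0.5, g) *
    1
  expect_equal(out$dbh - 10, optimal_increment(10, g) * exp_mult,
               tolerance = 1e-10)
  expect_equal(out$age, 1)
  # site outside the degree-day window: zero growth
  site_cold <- site_conditions(gdd = 500, swc = 0.5)
  out2 <- annual_growth_step(s1, site_cold, pt)
  expect_equal(out2$dbh, 10)
  expect_equal(out2$slow_years, 1L)
  # two trees: the taller is unaffected by the shorter
  s2 <- make_stand(c("ref", "ref"), c(30, 5))
  out3 <- annual_growth_step(s2, site_opt, pt)
  solo <- annual_growth_step(make_stand("ref", 30), site_opt, pt)
  expect_equal(out3$dbh[1], solo$dbh[1])
  # the shorter tree is shaded by the taller one's leaf area
  site_small <- site_conditions(gdd = 2000, swc = 0.5, plot_area = 100)
  out4 <- annual_growth_step(s2, site_small, pt)
  lai_tall <- 0.16 * 30^2 / 100
  exp_short <- optimal_increment(5, g) *
    light_multiplier(lai_tall, 3) * response_swc(0.5, g)
  expect_equal(out4$dbh[2] - 5, exp_short, tolerance = 1e-10)
  expect_error(annual_growth_step(make_stand("zz", 10), site_opt, pt),
               "unknown species")
})

test_that("dbh never exceeds d_max over a long simulated run", {
  g <- ref_growth()
  set.seed(61)
  traj <- simulate_stand(make_stand(rep("ref", 10), runif(10, 30, 49)),
                         site_conditions(2000, 0.5), list(ref = g),
                         years = 120)
  fin <- attr(traj, "final_stand")
  expect_true(all(fin$dbh <= g$d_max + 1e-9))
  expect_true(all(traj$biomass >= 0 & is.finite(traj$biomass)))
  expect_true(all(traj$basal_area >= 0))
})

test_that("mortality Monte-Carlo matches the closed-form rates", {
  g <- ref_growth(recruit_rate = 0)
  g$age_max <- 400
  pt <- list(ref = g)
  expect_equal(4 / g$age_max, 0.01)
  n <- 20000
  set.seed(67)
  # intrinsic: one year of baseline mortality
  alive <- nrow(mortality_step(make_stand(rep("ref", n), rep(10, n)), pt))
  expect_gt(stats::binom.test(n - alive, n, p = 0.01)$p.value, 0.01)
  # cohort survival to age_max ~ exp(-4)
  set.seed(68)
  surv <- make_stand(rep("ref", 5000), rep(10, 5000))
  for (i in seq_len(g$age_max)) surv <- mortality_step(surv, pt)
  expect_gt(stats::binom.test(nrow(surv), 5000, p = (1 - 0.01)^400)$p.value,
            0.01)
  expect_equal(nrow(surv) / 5000, exp(-4), tolerance = 0.35)
  # stressed cohort: 10-year survival ~ 0.01
  set.seed(69)
  stressed <- make_stand(rep("ref", 20000), rep(10, 20000))
  stressed$slow_years <- 2L
  p_ann <- 0.01 + 0.99 * 0.368
  for (i in 1:10) stressed <- mortality_step(stressed, pt)
  expect_gt(stats::binom.test(nrow(stressed), 20000,
                              p = (1 - p_ann)^10)$p.value, 0.01)
  expect_equal(nrow(stressed) / 20000, 0.010, tolerance = 0.35)
})

test_that("establishment honours eligibility filters and the recruit rate", {
  g <- ref_growth(recruit_rate = 2)
  pt <- list(ref = g)
  empty <- make_stand()
  # ineligible site: degree-days below the window
  set.seed(71)
  expect_equal(nrow(establishment_step(empty, site_conditions(500, 0.5), pt)),
               0L)
  # closed canopy blocks recruitment below the compensation point
  canopy <- make_stand(rep("ref", 30), rep(40, 30))  # total LAI >> 1
  expect_equal(nrow(establishment_step(canopy, site_conditions(2000, 0.5),
                                       pt)) - 30L, 0L)
  # empty plot, eligible: mean recruits per year = recruit_rate
  set.seed(73)
  n_rec <- replicate(600, nrow(establishment_step(
    empty, site_conditions(2000, 0.5), pt)))
  se <- sqrt(2 / 600)
  expect_lt(abs(mean(n_rec) - 2), 3 * se)
  one <- establishment_step(empty, site_conditions(2000, 0.5), pt)
  if (nrow(one)) {
    expect_true(all(one$dbh >= 0.5 & one$dbh <= 2.5))
    expect_true(all(one$age == 0))
  }
})

test_that("species outside their degree-day window only decline", {
  g <- ref_growth(recruit_rate = 5)
  pt <- list(ref = g)
  set.seed(79)
  traj <- simulate_stand(make_stand(rep("ref", 20), runif(20, 5, 20)),
                         site_conditions(gdd = 100, swc = 0.5), pt,
                         years = 60)
  b <- traj$biomass[traj$species_code == "ref"]
  expect_true(all(diff(b) <= 1e-9))
  expect_equal(traj$stems[traj$year == 60], 0)  # stress mortality clears it
})

test_that("replicate means are deterministic given the seed", {
  pt <- succession_pair()
  site <- site_conditions(1750, 0.5)
  stand <- make_stand(c("fast", "slow"), c(5, 5))
  m1 <- replicate_mean_biomass(stand, site, pt, years = 15, n_reps = 4,
                               seed = 42)
  m2 <- replicate_mean_biomass(stand, site, pt, years = 15, n_reps = 4,
                               seed = 42)
  expect_identical(m1, m2)
  m3 <- replicate_mean_biomass(stand, site, pt, years = 15, n_reps = 4,
                               seed = 43)
  expect_false(identical(m1, m3))
  # n_reps = 1 equals a single trajectory's final year
  set.seed(42 + 1)
  traj <- simulate_stand(stand, site, pt, years = 15)
  fin <- traj[traj$year == 15, ]
  single <- replicate_mean_biomass(stand, site, pt, years = 15, n_reps = 1,
                                   seed = 42)
  expect_equal(unname(single[fin$species_code]), fin$biomass)
  # with mortality and establishment disabled the replicates are identical
  det <- replicate_mean_biomass(stand, site, pt, years = 10, n_reps = 3,
                                seed = 1,
                                control = list(mortality = FALSE,
                                               establishment = FALSE))
  set.seed(99)
  det2 <- replicate_mean_biomass(stand, site, pt, years = 10, n_reps = 3,
                                 seed = 5,
                                 control = list(mortality = FALSE,
                                                establishment = FALSE))
  expect_equal(det, det2)
})

test_that("shade-tolerant species gain biomass share as succession proceeds", {
  pt <- succession_pair()
  site <- site_conditions(1750, 0.5)
  gains <- logical(10)
  for (s in seq_along(gains)) {
    set.seed(700 + s)
    traj <- simulate_stand(make_stand(), site, pt, years = 100)
    b10 <- traj[traj$year == 10, ]
    b100 <- traj[traj$year == 100, ]
    share <- function(b) {
      tot <- sum(b$biomass)
      if (tot == 0) 0 else b$biomass[b$species_code == "slow"] / tot
    }
    gains[s] <- share(b100) > share(b10)
  }
  expect_gte(mean(gains), 0.9)
})

test_that("stand tables round-trip and counts expand to individuals", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_code,dbh_cm,count", "bF,10,3", "rS,20,1"), path)
  s <- read_stand(path)
  expect_equal(nrow(s), 4L)
  expect_equal(sum(s$species_code == "bF"), 3L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_stand(s, out)
  expect_equal(nrow(read_stand(out)), 4L)
  g <- list(ref = ref_growth())
  gp <- withr::local_tempfile(fileext = ".csv")
  write_growth_params(g, gp)
  back <- read_growth_params(gp)
  expect_equal(back$ref[names(back$ref) != "species_code"],
               g$ref[names(g$ref) != "species_code"])
})
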