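test_that("the main-experiment generator reproduces the factorial design", {
  cfg <- generator_config(seed = 31)
  juv <- simulate_main_experiment(cfg)
  # 2 clones x 4 treatments x 6 mothers
  expect_equal(length(unique(juv$mother_uid)), 48)
  expect_true(all(table(juv$clone, juv$kairomone, juv$uvr) > 0))
  # clutch sizes within the configured range at instar 1 (missing design
  # cell excluded: its instar-1 records are dropped by construction)
  i1 <- juv[juv$instar == 1, ]
  counts <- table(i1$mother_uid)
  expect_true(all(counts >= 5 & counts <= 10))
  # no UVR mortality without UVR; instar-2 rows only for survivors
  expect_true(all(juv$survived_to_instar2[!juv$uvr]))
  expect_true(all(juv$survived_to_instar2[juv$instar == 2]))
  # missing design cell
  expect_equal(sum(juv$clone == "P5" & juv$instar == 1 & juv$kairomone &
                     juv$uvr), 0)
  expect_gt(sum(juv$clone == "P5" & juv$instar == 2 & juv$kairomone &
                  juv$uvr), 0)
  with_cell <- simulate_main_experiment(
    generator_config(seed = 31, include_missing_cell = FALSE))
  expect_gt(sum(with_cell$clone == "P5" & with_cell$instar == 1 &
                  with_cell$kairomone & with_cell$uvr), 0)
})

test_that("generated morphometrics respect the calibrated ranges", {
  juv <- simulate_main_experiment(generator_config(seed = 32))
  len1 <- juv$body_length_mm[juv$instar == 1]
  len2 <- juv$body_length_mm[juv$instar == 2]
  expect_true(all(len1 >= 0.55 & len1 <= 0.80))
  expect_true(all(len2 >= 0.75 & len2 <= 1.00))
  expect_true(all(juv$body_width_mm > 0))
  expect_true(all(juv$spina_length_mm > 0))
})

test_that("UVR arms lose at least half of their juveniles before instar 2", {
  cfg <- generator_config(seed = 33, mothers_per_treatment = 30)
  juv <- simulate_main_experiment(cfg)
  uvr1 <- juv[juv$uvr & juv$instar == 1 & !(juv$clone == "P5" & juv$kairomone), ]
  expect_gte(mean(!uvr1$survived_to_instar2), 0.5)
})

test_that("the effectivity generator emits 10 juveniles per cell, deterministically", {
  cfg <- generator_config(seed = 34)
  eff <- simulate_effectivity_experiment(cfg)
  expect_equal(nrow(eff), 120)
  cells <- table(eff$treatment, eff$exposure_hours)
  expect_true(all(cells == 10))
  expect_equal(length(unique(eff$mother_uid)), 24)  # 2 mothers per cell
  eff2 <- simulate_effectivity_experiment(cfg)
  expect_identical(eff, eff2)
  juv2 <- simulate_main_experiment(cfg)
  expect_identical(juv2, simulate_main_experiment(cfg))
})

test_that("per-cell substreams make cells independent of the factor set", {
  base <- simulate_effectivity_experiment(generator_config(seed = 35))
  # regenerating must give identical PAR records even though other cells
  # consumed random numbers in between
  par_rows <- base[base$treatment == "PAR", ]
  again <- simulate_effectivity_experiment(generator_config(seed = 35))
  expect_identical(par_rows, again[again$treatment == "PAR", ])
})

test_that("default true parameters reproduce the qualitative trait patterns", {
  juv <- simulate_main_experiment(generator_config(seed = 36,
                                                   mothers_per_treatment = 12))
  modal <- function(x) as.integer(names(which.max(table(x))))
  # instar 1: canalized neckteeth, mostly 1-3 teeth with or without kairomone
  i1 <- juv[juv$instar == 1, ]
  expect_true(modal(i1$neckteeth[!i1$kairomone]) %in% 1:3)
  expect_true(modal(i1$neckteeth[i1$kairomone]) %in% 1:3)
  # instar 2: neckteeth only under kairomone
  i2 <- juv[juv$instar == 2, ]
  expect_equal(modal(i2$neckteeth[!i2$kairomone]), 0)
  uni_k <- i2[i2$clone == "UNI" & i2$kairomone & !i2$uvr, ]
  expect_true(modal(uni_k$neckteeth) %in% 2:3)
  # pedestal induction suppressed by UVR in instar 1
  ped_score <- function(p) mean(as.integer(factor(p, c("A", "B", "C"))))
  k1 <- i1[i1$kairomone, ]
  expect_gt(ped_score(k1$pedestal[!k1$uvr]), ped_score(k1$pedestal[k1$uvr]))
})

test_that("simulated trait frequencies match the analytic model probabilities", {
  # one cell at large n; the oracle integrates the binomial over the
  # maternal random effect, and the cluster structure enters the MC error
  cfg <- generator_config(seed = 37, clones = "UNI",
                          mothers_per_treatment = 250)
  juv <- simulate_main_experiment(cfg)
  cell <- juv[juv$instar == 1 & !juv$kairomone & !juv$uvr, ]
  expect_gt(nrow(cell), 1500)
  tp <- default_true_params(1)$defense
  eta0 <- unname(tp$beta_N["(Intercept)"] + tp$beta_N["cloneUNI"])
  oracle <- vapply(0:5, function(k) {
    integrate(function(u) dnorm(u, 0, tp$sigma_N) *
                dbinom(k, 5, plogis(eta0 + u)), -Inf, Inf)$value
  }, numeric(1))
  expect_equal(sum(oracle), 1, tolerance = 1e-6)
  for (k in 0:5) {
    per_mother <- tapply(cell$neckteeth == k, cell$mother_uid, mean)
    n_m <- tapply(cell$neckteeth, cell$mother_uid, length)
    p_hat <- sum(per_mother * n_m) / sum(n_m)
    se <- sqrt(sum(n_m^2 * (per_mother - p_hat)^2)) / sum(n_m)
    expect_lt(abs(p_hat - oracle[k + 1]), 3 * se + 1e-3)
  }
})

test_that("maternal clustering produces positive intraclass correlation", {
  icc <- function(juv) {
    i1 <- juv[juv$instar == 1 & juv$kairomone & !juv$uvr, ]
    grp <- factor(i1$mother_uid)
    fit <- anova(lm(i1$neckteeth ~ grp))
    msb <- fit$`Mean Sq`[1]
    msw <- fit$`Mean Sq`[2]
    n0 <- mean(table(grp))
    (msb - msw) / (msb + (n0 - 1) * msw)
  }
  clustered <- simulate_main_experiment(
    generator_config(seed = 38, mothers_per_treatment = 25))
  expect_gt(icc(clustered), 0.05)

  tp1 <- default_true_params(1)
  tp1$defense$sigma_N <- 1e-9
  tp1$defense$sigma_P <- 1e-9
  tp2 <- default_true_params(2)
  tp2$defense$sigma_N <- 1e-9
  tp2$defense$sigma_P <- 1e-9
  unclustered <- simulate_main_experiment(
    generator_config(seed = 38, mothers_per_treatment = 25,
                     true_params_instar1 = tp1, true_params_instar2 = tp2))
  expect_lt(abs(icc(unclustered)), 0.05)
})

test_that("generator configs validate and load from YAML", {
  expect_error(generator_config(uvr_instar2_mortality = 1.5),
               "uvr_instar2_mortality")
  expect_error(generator_config(body_length_ranges = list(`1` = c(1, 0.5),
                                                          `2` = c(0.75, 1))),
               "width")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mothers_per_treatment: 3", "seed: 77",
               "uvr_instar2_mortality: 0.6"), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$mothers_per_treatment, 3L)
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$uvr_instar2_mortality, 0.6)
  writeLines("unknown_field: 1", path)
  expect_error(read_generator_config(path), "unknown_field")
})
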