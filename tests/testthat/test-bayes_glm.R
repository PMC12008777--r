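test_that("the design expands every effect family and records holes", {
  tab <- simulate_cell_observations(n_participants = 17, electrodes = NULL,
                                    noise_sd = 0, seed = 1)
  d <- build_design(tab)
  expect_equal(length(d$families), 2^4 - 1)
  expect_equal(length(d$y), 8 * 17)
  expect_equal(d$n_missing, 0)

  mont <- default_montage()
  tab5 <- simulate_cell_observations(n_participants = 17,
                                     electrodes = mont$label,
                                     noise_sd = 0, seed = 1)
  d5 <- build_design(tab5)
  expect_equal(length(d5$families), 2^5 - 1)
  expect_equal(length(d5$y), 2 * 2 * 2 * 30 * 17)

  # an excluded participant-condition leaves a recorded hole
  hole <- tab[!(tab$participant == "P3" & tab$frequency == "3Hz" &
                  tab$modality == "VIS" & tab$rhythmicity == "POLY"), ]
  expect_equal(build_design(hole)$n_missing, 1)
  expect_error(build_design(rbind(tab, tab[1, ])), "duplicate")
})

test_that("the HDI is the shortest interval with the requested mass", {
  set.seed(51)
  x <- rnorm(100000)
  h <- hdi(x, 0.99)
  expect_equal(h[1], -2.576, tolerance = 0.05)
  expect_equal(h[2], 2.576, tolerance = 0.05)
  expect_equal(hdi(rep(3.2, 2000)), c(3.2, 3.2))
  he <- hdi(rexp(100000), 0.95)
  expect_lt(he[1], 0.01)  # HDI hugs zero, unlike the equal-tailed interval
  expect_lt(he[2], qexp(0.975) + 0.2)
  expect_error(hdi(x, 1.2), "mass")
})

test_that("the 12 planned comparisons differ in exactly one characteristic", {
  cmp <- comparisons_of_interest()
  expect_equal(nrow(cmp), 12)
  expect_equal(as.vector(table(cmp$characteristic)[c("frequency", "modality",
                                                     "rhythmicity")]),
               c(4L, 4L, 4L))
  expect_true(any(cmp$condition_a == "AUD-ISO-1Hz" &
                    cmp$condition_b == "AUD-ISO-3Hz"))
  split3 <- function(x) strsplit(x, "-", fixed = TRUE)
  for (i in seq_len(12)) {
    a <- split3(cmp$condition_a[i])[[1]]
    b <- split3(cmp$condition_b[i])[[1]]
    expect_equal(sum(a != b), 1)
  }
  expect_false(any(duplicated(paste(cmp$condition_a, cmp$condition_b))))
})

test_that("null data yields null posteriors", {
  tab <- simulate_cell_observations(n_participants = 17, electrodes = NULL,
                                    beta0 = 2, noise_sd = 1e-6, seed = 52)
  fit <- fit_model(build_design(tab), chains = 2, warmup = 200, draws = 300,
                   seed = 1)
  expect_equal(mean(fit$beta0), 2, tolerance = 0.02)
  for (fam in c("F", "M", "R")) {
    expect_lt(max(abs(colMeans(effect_draws(fit, fam)))), 0.02)
  }
})

test_that("a planted frequency effect is recovered with coverage", {
  tab <- simulate_cell_observations(n_participants = 17, electrodes = NULL,
                                    beta0 = 1,
                                    effects = list(F = c(-0.5, 0.5)),
                                    noise_sd = 0.1, seed = 53)
  fit <- fit_model(build_design(tab), chains = 2, warmup = 300, draws = 500,
                   seed = 2)
  ef <- colMeans(effect_draws(fit, "F"))
  expect_equal(unname(ef), c(-0.5, 0.5), tolerance = 0.1)
  ct <- contrast(fit, "AUD-ISO-1Hz", "AUD-ISO-3Hz")
  expect_lt(ct$hdi_low, -1)
  expect_gt(ct$hdi_high, -1)
  expect_true(ct$significant)
  expect_lt(fit$diagnostics$max_rhat, 1.05)
})

test_that("posterior cell means agree with ordinary cell means when the
           signal is strong and balanced", {
  mont <- default_montage()
  fe <- outer(c(-1, 1), scale(rnorm(30), scale = FALSE)[, 1])
  tab <- simulate_cell_observations(n_participants = 17,
                                    electrodes = mont$label,
                                    effects = list(`F:E` = fe),
                                    noise_sd = 0.2, seed = 54)
  fit <- fit_model(build_design(tab), chains = 2, warmup = 300, draws = 400,
                   seed = 3)
  # compare a handful of cells against their sample means
  for (el in c("C3", "Fz", "P4")) {
    sub <- tab[tab$frequency == "1Hz" & tab$modality == "AUD" &
                 tab$rhythmicity == "ISO" & tab$electrode == el, ]
    se <- sd(sub$value) / sqrt(nrow(sub))
    post <- cell_posterior(fit, "AUD-ISO-1Hz", el)
    expect_lt(abs(post$mean - mean(sub$value)), 2 * se)
  }
})

test_that("an electrode-specific interaction is recovered and shrunk
           elsewhere", {
  mont <- default_montage()
  i_c3 <- match("C3", mont$label)
  fe <- matrix(0, 2, 30)
  fe[, i_c3] <- c(-0.5, 0.5)
  fe <- fe - rowMeans(fe)
  fe <- sweep(fe, 2, colMeans(fe))
  tab <- simulate_cell_observations(n_participants = 17,
                                    electrodes = mont$label,
                                    effects = list(`F:E` = fe),
                                    noise_sd = 0.3, seed = 55)
  fit <- fit_model(build_design(tab), chains = 2, warmup = 300, draws = 500,
                   seed = 4)
  ef <- matrix(colMeans(effect_draws(fit, "F:E")), 2, 30)
  expect_equal(ef[1, i_c3], fe[1, i_c3], tolerance = 0.2)
  expect_lt(max(abs(ef[, -i_c3])), max(abs(fe[1, -i_c3])) + 0.15)
})

test_that("the significance rule combines the HDI, the 0.4-dB floor and
           the blacklist", {
  # a handcrafted fit: two conditions at two electrodes with known draws
  set.seed(56)
  nd <- 4000
  cells <- cbind(rnorm(nd, 1.0, 0.1), rnorm(nd, 0, 0.1),   # C3: diff 1.0
                 rnorm(nd, 0.3, 0.05), rnorm(nd, 0, 0.05), # Cz: diff 0.3
                 rnorm(nd, 1.0, 0.1), rnorm(nd, 0, 0.1))   # Fp1 (edge)
  info <- data.frame(
    frequency = rep(c("1Hz", "3Hz"), 3),
    modality = "AUD", rhythmicity = "ISO",
    electrode = rep(c("C3", "Cz", "Fp1"), each = 2)
  )
  info$condition <- paste(info$modality, info$rhythmicity, info$frequency,
                          sep = "-")
  fit <- structure(list(cells = cells, cell_info = info, model = "power"),
                   class = "sms_bglm")

  strong <- contrast(fit, "AUD-ISO-1Hz", "AUD-ISO-3Hz", electrode = "C3")
  expect_true(strong$significant)
  small <- contrast(fit, "AUD-ISO-1Hz", "AUD-ISO-3Hz", electrode = "Cz")
  expect_false(small$significant)  # HDI excludes 0 but fails the floor
  expect_true(small$hdi_low > 0)
  edge <- contrast(fit, "AUD-ISO-1Hz", "AUD-ISO-3Hz", electrode = "Fp1")
  expect_false(edge$significant)   # blacklisted despite a strong effect
  expect_true(edge$blacklisted)
  same <- contrast(fit, "AUD-ISO-1Hz", "AUD-ISO-1Hz", electrode = "C3")
  expect_equal(same$diff_mean, 0)
  expect_false(same$significant)
})

test_that("chain count does not move the posterior (within MC error)", {
  tab <- simulate_cell_observations(n_participants = 17, electrodes = NULL,
                                    effects = list(F = c(-0.5, 0.5)),
                                    noise_sd = 0.2, seed = 57)
  f2 <- fit_model(build_design(tab), chains = 2, warmup = 300, draws = 600,
                  seed = 5)
  f4 <- fit_model(build_design(tab), chains = 4, warmup = 300, draws = 300,
                  seed = 6)
  c2 <- contrast(f2, "AUD-ISO-1Hz", "AUD-ISO-3Hz")
  c4 <- contrast(f4, "AUD-ISO-1Hz", "AUD-ISO-3Hz")
  expect_equal(c2$diff_mean, c4$diff_mean, tolerance = 0.05)
})

test_that("identical seeds reproduce the fit exactly", {
  tab <- simulate_cell_observations(n_participants = 5, electrodes = NULL,
                                    noise_sd = 0.2, seed = 58)
  f1 <- fit_model(build_design(tab), chains = 2, warmup = 100, draws = 200,
                  seed = 9)
  f2 <- fit_model(build_design(tab), chains = 2, warmup = 100, draws = 200,
                  seed = 9)
  expect_identical(f1$cells, f2$cells)
})
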