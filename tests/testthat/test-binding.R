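test_that("bound_complex matches an independent equilibrium oracle", {
  expect_equal(bound_complex(0, 5, 3.2), 0)
  # stoichiometric saturation: kd -> 0 with excess protein gives c -> n
  expect_equal(bound_complex(10, 5, 1e-9), 5, tolerance = 1e-6)
  a <- c(0.5, 2, 5, 20, 100, 200, 400)
  expect_equal(bound_complex(a, 5, 3.2), bound_complex_oracle(a, 5, 3.2),
               tolerance = 1e-10)
  expect_equal(bound_complex(200, 5, 3.2), 4.919306, tolerance = 1e-6)
  # monotone in a, antitone in kd, bounded by min(n, a)
  cc <- bound_complex(a, 5, 3.2)
  expect_true(all(diff(cc) > 0))
  expect_true(all(bound_complex(a, 5, 10) < cc))
  expect_true(all(cc <= pmin(5, a) + 1e-12))
})

test_that("titration model curves evaluate as declared", {
  wt <- binding_params(kd = 3.2, n = 5, b = 1, c = 0, k = 0.001)
  expect_equal(quadratic_model(0, wt), 0)
  expect_equal(quadratic_model(200, wt), 0.2 + 4.919306 / 5,
               tolerance = 1e-6)
  # saturation: kd << n, a >> n, no drift
  sat <- binding_params(kd = 1e-6, n = 5, b = 2, c = 0.3, k = 0)
  expect_equal(quadratic_model(1e4, sat), 2.3, tolerance = 1e-6)
  hp <- binding_params(kd = 3.2, n = 5, b = 1, c = 0, k = 0)
  expect_equal(hyperbolic_model(3.2, hp), 0.5)
  expect_equal(hyperbolic_model(0, hp), 0)
  expect_equal(hyperbolic_model(200, hp), 200 / 203.2)
})

test_that("quadratic model converges to the hyperbolic model as n/kd -> 0", {
  kd <- 100
  p <- binding_params(kd = kd, n = kd * 1e-3, b = 1, c = 0.1, k = 0.001)
  a <- seq(0, 10 * kd, length.out = 200)
  dev <- max(abs(quadratic_model(a, p) - hyperbolic_model(a, p)))
  expect_lt(dev, 1e-3 * p$b)
})

test_that("noise-free titrations recover the generating K_D to 1e-6", {
  for (nm in c("wt_fbw7g", "e39a_fbw7g", "quad_e121a_fbw7g")) {
    p <- binding_presets()[[nm]]$params
    a_max <- if (p$kd <= 10) 200 else 400
    cur <- make_titration(p, titration_design(
      seq(0, a_max, length.out = 25), replicates = 1L, noise_cv = 0))
    fit <- fit_titration(cur)
    expect_true(fit$converged)
    expect_equal(fit$kd_mean, p$kd, tolerance = 1e-6)
    expect_equal(coef(fit)[["b"]], 1, tolerance = 1e-4)
    expect_equal(coef(fit)[["k"]], 0.001, tolerance = 1e-4)
  }
})

test_that("a quadratic fit recovers hyperbolic-limit data within 2%", {
  # data generated by the pseudo-first-order model at n/kd = 0.01
  p <- binding_params(kd = 100, n = 1, b = 1, c = 0.2, k = 0.002)
  a <- seq(0, 1000, length.out = 30)
  cur <- titration_curve(data.frame(a_uM = a,
                                    fluorescence = hyperbolic_model(a, p)),
                         n_fixed = 1)
  fit <- fit_titration(cur, model = "quadratic")
  expect_equal(fit$kd_mean, 100, tolerance = 0.02)
  # and the hyperbolic fit recovers it exactly
  fit_h <- fit_titration(cur, model = "hyperbolic")
  expect_equal(fit_h$kd_mean, 100, tolerance = 1e-6)
})

test_that("flat titrations are flagged as no interaction, not fitted", {
  a <- seq(0, 200, length.out = 10)
  flat <- titration_curve(data.frame(a_uM = a, fluorescence = rep(2, 10)))
  fit <- fit_titration(flat)
  expect_true(fit$no_interaction)
  expect_true(is.na(fit$kd_mean))
  # purely linear drift is also "no interaction beyond a line"
  lin <- titration_curve(data.frame(a_uM = a, fluorescence = 1 + 0.01 * a))
  expect_true(fit_titration(lin)$no_interaction)
})

test_that("fitting is invariant under affine rescaling of fluorescence", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  cur <- make_titration(wt, titration_design(seq(0, 200, length.out = 25),
                                             replicates = 1L,
                                             noise_cv = 0.02, seed = 3))
  f1 <- fit_titration(cur)
  cur2 <- cur
  cur2$fluorescence <- 7 * cur2$fluorescence + 11
  f2 <- fit_titration(cur2)
  expect_equal(f1$kd_mean, f2$kd_mean, tolerance = 1e-6)
  expect_equal(coef(f2)[["b"]], 7 * coef(f1)[["b"]], tolerance = 1e-5)
  expect_equal(coef(f2)[["c"]], 7 * coef(f1)[["c"]] + 11, tolerance = 1e-4)
})

test_that("replicate fits aggregate as mean +/- sd of K_D", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  cur <- make_titration(wt, titration_design(seq(0, 200, length.out = 20),
                                             replicates = 3L,
                                             noise_cv = 0.02, seed = 11))
  fit <- fit_titration(cur)
  expect_length(fit$kd_replicates, 3L)
  expect_equal(fit$kd_mean, mean(fit$kd_replicates))
  expect_equal(fit$kd_sd, sd(fit$kd_replicates))
  # methods on the fitted object
  expect_equal(unname(coef(fit)["kd"]), fit$kd_mean)
  expect_length(predict(fit, c(0, 50, 100)), 3L)
  expect_equal(predict(fit, 0), coef(fit)[["c"]], ignore_attr = TRUE)
  expect_length(residuals(fit), nrow(cur))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_s3_class(sim, "titration_curve")
  expect_equal(sort(unique(sim$replicate)), 1:2)
})

test_that("stoichiometry multiplier is recovered as 1 on 1:1 data", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  cur <- make_titration(wt, titration_design(seq(0, 200, length.out = 25),
                                             replicates = 1L, noise_cv = 0))
  fit <- fit_titration(cur, stoichiometry = TRUE)
  expect_equal(coef(fit)[["m"]], 1, tolerance = 1e-4)
  expect_equal(fit$kd_mean, 3.2, tolerance = 1e-4)
})

test_that("fold changes reproduce the measured mutant ratios", {
  fc <- fold_change(22.0, 3.2)
  expect_equal(fc$ratio, 6.875)
  expect_equal(fc$rounded, 7)
  expect_equal(fold_change(3.2, 3.2)$ratio, 1)
  expect_equal(fold_change(653.7, 3.2)$ratio, 204.28125)
  expect_equal(fold_change(151.5, 3.2)$rounded, 50)
  expect_equal(fold_change(224.3, 3.2)$rounded, 70)
  # works on fitted objects too
  wt <- binding_presets()[["wt_fbw7g"]]$params
  tri <- binding_presets()[["triple_fbw7g"]]$params
  d <- titration_design(seq(0, 400, length.out = 25), replicates = 1L,
                        noise_cv = 0)
  f_wt <- fit_titration(make_titration(wt, d))
  f_tri <- fit_titration(make_titration(tri, d))
  expect_equal(fold_change(f_tri, f_wt)$rounded, 7)
})
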