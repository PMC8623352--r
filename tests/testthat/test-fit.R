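cons <- amp_constants()
rc <- cons$states$ground$rc
dd <- cons$states$ground$dist
model <- spectrum_model(rc, dd, mu = c(0.166, 0.86, 0))

perturbed_model <- function(f = 1.001) {
  spectrum_model(rotational_constants(rc$A * f, rc$B * f, rc$C * f),
                 dd, mu = model$mu)
}

test_that("noise-free synthetic lines are recovered exactly", {
  ll <- simulate_linelist(model, J_range = c(0, 5),
                          noise = noise_spec(freq_sigma = c(FTMW = 0),
                                             seed = 3),
                          n_max = 60)
  fit <- fit_constants(ll, perturbed_model(), free = c("A", "B", "C"))
  expect_lt(max(abs(fit$params[c("A", "B", "C")] -
                      c(rc$A, rc$B, rc$C))), 1e-6)   # <= 1 Hz
  expect_lt(fit$sigma_fit[["overall"]], 1e-6)
})

test_that("a fit with every parameter fixed only evaluates residuals", {
  ll <- simulate_linelist(model, J_range = c(0, 4), noise = noise_spec(seed = 4),
                          n_max = 30)
  fit <- fit_constants(ll, model, free = character(0))
  expect_equal(fit$residuals$omc, ll$frequency - ll$true_frequency,
               tolerance = 1e-9)
  expect_equal(fit$niter, 0L)
})

test_that("weighted-fit scaling: doubling uncertainties doubles the errors", {
  ll <- simulate_linelist(model, J_range = c(0, 5), noise = noise_spec(seed = 8),
                          n_max = 80)
  f1 <- fit_constants(ll, perturbed_model(), free = c("A", "B", "C"))
  ll2 <- ll
  ll2$uncertainty <- 2 * ll2$uncertainty
  f2 <- fit_constants(ll2, perturbed_model(), free = c("A", "B", "C"))
  expect_equal(unname(f2$params), unname(f1$params), tolerance = 1e-10)
  expect_equal(unname(f2$se / f1$se), rep(2, 3), tolerance = 1e-6)
  # sigma_fit is a plain rms: invariant under line reordering
  ll3 <- ll[sample.int(nrow(ll)), ]
  f3 <- fit_constants(ll3, perturbed_model(), free = c("A", "B", "C"))
  expect_equal(f3$sigma_fit[["overall"]], f1$sigma_fit[["overall"]],
               tolerance = 1e-9)
})

test_that("dual-accuracy subsets report separate deviations of fit", {
  llf <- simulate_linelist(model, J_range = c(0, 4),
                           noise = noise_spec(seed = 21), source = "FTMW",
                           n_max = 40)
  llm <- simulate_linelist(model, J_range = c(5, 8),
                           noise = noise_spec(seed = 22), source = "MMW",
                           n_max = 60)
  fit <- fit_constants(rbind(llf, llm), perturbed_model(),
                       free = c("A", "B", "C", "DJ"))
  expect_true(fit$sigma_fit[["FTMW"]] > 0.5 && fit$sigma_fit[["FTMW"]] < 5)
  expect_true(fit$sigma_fit[["MMW"]] > 25 && fit$sigma_fit[["MMW"]] < 90)
})

test_that("hyperfine parameters are fitted from resolved components", {
  mhf <- spectrum_model(rc, dd, mu = model$mu,
                        tensors = unname(cons$tensors))
  ll <- simulate_linelist(mhf, J_range = c(0, 2),
                          noise = noise_spec(seed = 13), hyperfine = TRUE,
                          n_max = 150)
  start <- spectrum_model(rc, dd, mu = model$mu,
                          tensors = list(
                            tensor_from_fit_params(3.5, 1.45, nucleus = "Na"),
                            tensor_from_fit_params(-0.1, -1.1, chi_ab = 2.92,
                                                   nucleus = "Nr")))
  fit <- fit_constants(ll, start,
                       free = c("N1_32chiaa", "N1_bbcc4",
                                "N2_32chiaa", "N2_bbcc4"))
  truth <- c(3.5854, 1.50413, -0.0789, -1.15823)
  dev <- abs(unname(fit$params[c("N1_32chiaa", "N1_bbcc4",
                                 "N2_32chiaa", "N2_bbcc4")]) - truth)
  expect_true(all(dev < pmax(3 * unname(fit$se), 0.01)))
})

test_that("blended lines are matched to the intensity-weighted centroid", {
  mhf <- spectrum_model(rc, dd, mu = model$mu, tensors = unname(cons$tensors))
  ll <- simulate_linelist(mhf, J_range = c(1, 1),
                          noise = noise_spec(freq_sigma = c(FTMW = 0)),
                          hyperfine = TRUE)
  grp <- ll[ll$J_up == 2 & ll$Ka_up == 0, ][1:3, ]
  grp$blend <- 1L
  cen <- fit_constants(grp, mhf, free = character(0))
  # one observation; its calc must be a weighted mean inside the component span
  expect_equal(nrow(cen$residuals), 1)
  expect_gte(cen$residuals$calc, min(grp$true_frequency))
  expect_lte(cen$residuals$calc, max(grp$true_frequency))
})

test_that("degenerate problems raise structured errors", {
  ll <- simulate_linelist(model, J_range = c(0, 1), noise = noise_spec(seed = 5))
  expect_error(fit_constants(ll, model, free = c("A", "nonsense")), "unknown")
  # at J <= 1 the k^2 and k^6 operators are exactly collinear: freeing A and
  # HK together is rank deficient and must be reported as such
  expect_error(fit_constants(ll, model, free = c("A", "B", "C", "HK")),
               "rank|singular|unconstrained", ignore.case = TRUE)
  ll$uncertainty <- 0
  expect_error(fit_constants(ll, model), "positive")
})
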