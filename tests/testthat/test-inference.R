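test_that("annealing schedule is geometric, decreasing, and ends at 1", {
  s <- anneal_schedule(20, 50)
  expect_length(s, 50)
  expect_equal(s[1], 20)
  expect_equal(s[50], 1)
  expect_true(all(diff(s) < 0))
  expect_equal(diff(log(s))[1:48], rep(log(1 / 20) / 49, 48),
               tolerance = 1e-12)
  expect_equal(anneal_schedule(7, 1), 1)
  expect_equal(anneal_schedule(4, 3), c(4, 2, 1))
  expect_error(anneal_schedule(0.5, 10), "T_init")
})

test_that("sparsity prior elicitation follows the Beta mean identity", {
  ab <- elicit_sparsity_prior(1000, 100, 10, 2)
  expect_equal(ab$a_s, 1)
  expect_equal(ab$b_s, 1 / 2e-4 - 1)
  # doubling q at fixed expectations halves the prior mean
  ab2 <- elicit_sparsity_prior(1000, 200, 10, 2)
  m1 <- ab$a_s / (ab$a_s + ab$b_s)
  m2 <- ab2$a_s / (ab2$a_s + ab2$b_s)
  expect_equal(m2, m1 / 2, tolerance = 1e-12)
  # omega_s rarely exceeds twice its prior mean
  expect_lt(pbeta(2 * m1, ab$a_s, ab$b_s, lower.tail = FALSE), 0.15)
  expect_error(elicit_sparsity_prior(10, 5, 10, 5), "< 1")
  expect_error(elicit_sparsity_prior(10, 5, 0, 1), "expected_active_snps")
})

test_that("initial state is deterministic, prior-mean based, and validated", {
  inst <- random_instance(seed = 2)
  ctl <- jqtl_control(a_s = 1, b_s = 19)
  s1 <- jqtl_init(inst$X, inst$Y, ctl)
  s2 <- jqtl_init(inst$X, inst$Y, ctl)
  expect_identical(s1, s2)
  expect_true(all(s1$g == 0.05))
  expect_true(all(s1$mu == 0))
  expect_error(jqtl_init(inst$X + 1, inst$Y, ctl), "center_columns")
  expect_error(jqtl_init(inst$X, inst$Y[-1, , drop = FALSE], ctl),
               "dimension")
})

test_that("single-pair fit matches the exact Bayes-factor posterior", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    x <- rnorm(n); x <- x - mean(x)
    b <- sample(c(0, 0.4), 1)
    y <- b * x + rnorm(n); y <- y - mean(y)
    tau <- runif(1, 0.5, 2); sig2 <- runif(1, 0.2, 1.5)
    omega <- runif(1, 0.02, 0.3)
    oracle <- exact_single_ppi(x, y, tau, sig2, omega)
    fit <- jqtl(matrix(x), matrix(y),
                control = jqtl_control(fix_tau = tau,
                                       fix_sigma2_inv = 1 / sig2,
                                       fix_omega = omega, anneal = FALSE,
                                       tol = 1e-10, max_iter = 300))
    expect_equal(fit$ppi[1, 1], oracle, tolerance = 1e-6)
  }
})

test_that("variational PPIs agree with the 2^(pq) enumeration oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 40; p <- 3; q <- 2
    X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    B <- matrix(0, p, q); B[1, 1] <- 0.6; B[2, 2] <- 0.4
    Y <- scale(X %*% B + matrix(rnorm(n * q), n, q), scale = FALSE)
    tau <- 1; sig2 <- 0.5; omega <- 0.2
    oracle <- enum_ppi(X, Y, sig2, omega, tau)
    fit <- jqtl(X, Y, control = jqtl_control(fix_tau = tau,
                                             fix_sigma2_inv = 1 / sig2,
                                             fix_omega = omega,
                                             tol = 1e-8, max_iter = 500))
    expect_lt(max(abs(oracle - fit$ppi)), 0.15)
    # identical ranking wherever the exact PPIs are not essentially tied
    ex <- as.vector(oracle); vb <- as.vector(fit$ppi)
    for (i in seq_along(ex)) for (j in seq_len(i - 1))
      if (abs(ex[i] - ex[j]) > 0.01)
        expect_equal(sign(vb[i] - vb[j]), sign(ex[i] - ex[j]))
  }
})

test_that("temperature-1 sweeps never decrease the objective", {
  worst <- Inf
  for (seed in 1:25) {
    inst <- random_instance(n = 40, p = 8, q = 3,
                            n_signal = sample(0:3, 1), seed = seed)
    ctl <- jqtl_control(anneal = FALSE, max_iter = 25, tol = 1e-300)
    fit <- suppressWarnings(jqtl(inst$X, inst$Y, control = ctl))
    worst <- min(worst, diff(fit$diagnostics$trace_objective))
  }
  expect_gt(worst, -1e-8)
})

test_that("the optimized sweep matches a pure-R reference sweep", {
  for (seed in 1:4) {
    inst <- random_instance(n = 35, p = 7, q = 3, seed = seed)
    Y <- inst$Y
    if (seed %% 2 == 0) Y[c(3, 40)] <- NA  # exercise the masked path
    Y <- center_columns(Y)
    ctl <- jqtl_control()
    st <- jqtl_init(inst$X, Y, ctl)
    # put the conjugate factors somewhere generic
    st$tau_shape <- st$eta + colSums(is.finite(Y)) / 2
    st$tau_rate <- st$kappa + colSums(Y^2, na.rm = TRUE) / 2
    st$sigma2inv_shape <- ctl$lambda + 1
    st$sigma2inv_rate <- ctl$nu + 1
    for (temp in c(1, 3.7)) {
      got <- jqtl_sweep(st, inst$X, Y, ctl, temperature = temp)
      want <- reference_sweep(st, inst$X, Y, ctl, temperature = temp)
      expect_equal(got$g, want$g, tolerance = 1e-9)
      expect_equal(got$mu, want$mu, tolerance = 1e-9)
      expect_equal(got$tau_rate, want$tau_rate, tolerance = 1e-9)
      expect_equal(got$sigma2inv_rate, want$sigma2inv_rate,
                   tolerance = 1e-9)
    }
  }
})

test_that("an orthogonal predictor keeps prior-level inclusion", {
  set.seed(4)
  n <- 100
  x <- rep(c(-1, 1), n / 2)
  y <- rep(c(-1, -1, 1, 1), n / 4)  # exactly orthogonal to x
  stopifnot(sum(x * y) == 0)
  fit <- jqtl(matrix(x), matrix(y),
              control = jqtl_control(fix_tau = 1, fix_sigma2_inv = 1,
                                     fix_omega = 0.01, anneal = FALSE))
  expect_lt(fit$ppi[1, 1], 0.01)
})

test_that("tied duplicate SNPs receive identical updates", {
  set.seed(9)
  n <- 80
  x <- rbinom(n, 2, 0.4)
  y <- 0.5 * x + rnorm(n)
  X <- cbind(x, x)
  fit <- jqtl(X, matrix(y), control = jqtl_control(anneal = FALSE))
  # one sweep from a symmetric state treats both columns identically
  st <- jqtl_init(scale(X, scale = FALSE), scale(y, scale = FALSE))
  sw <- jqtl_sweep(st, scale(X, scale = FALSE), scale(y, scale = FALSE))
  expect_equal(sw$s2[1, 1], sw$s2[2, 1], tolerance = 1e-12)
})

test_that("missing trait entries are handled by masking, not imputation", {
  set.seed(10)
  n <- 120
  x <- rbinom(n, 2, 0.3)
  y <- 0.6 * x + rnorm(n)
  y_mis <- y; y_mis[101:120] <- NA
  ctl <- jqtl_control(anneal = FALSE)
  f_mis <- jqtl(matrix(x), matrix(y_mis), control = ctl)
  f_sub <- jqtl(matrix(x[1:100]), matrix(y[1:100]), control = ctl)
  # inference on the masked data equals inference on the observed subset
  # up to the different centering of x (all samples vs subset)
  expect_equal(f_mis$ppi[1, 1], f_sub$ppi[1, 1], tolerance = 0.05)
  expect_true(f_mis$diagnostics$converged)
})

test_that("fits are deterministic and flag non-convergence", {
  inst <- random_instance(n = 50, p = 10, q = 4, seed = 12)
  f1 <- jqtl(inst$X, inst$Y)
  f2 <- jqtl(inst$X, inst$Y)
  expect_identical(f1$ppi, f2$ppi)
  expect_identical(f1$diagnostics$objective, f2$diagnostics$objective)
  expect_warning(
    f3 <- jqtl(inst$X, inst$Y,
               control = jqtl_control(anneal = FALSE, max_iter = 1,
                                      tol = 1e-12)),
    "converge")
  expect_false(f3$diagnostics$converged)
})

test_that("fit object methods are coherent", {
  inst <- random_instance(n = 60, p = 8, q = 3, n_signal = 3, pve = 0.3,
                          seed = 13)
  fit <- jqtl(inst$X, inst$Y)
  expect_s3_class(fit, "jqtl")
  expect_equal(coef(fit), fit$ppi * fit$mu, ignore_attr = TRUE)
  expect_equal(dim(fitted(fit)), dim(inst$Y))
  r <- residuals(fit)
  expect_equal(fitted(fit) + r, inst$Y, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(predict(fit, inst$X), fitted(fit), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(inst$Y))
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), prod(dim(fit$ppi)))
  expect_true(all(diff(tab$ppi) <= 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.jqtl")
  expect_output(print(fit), "Joint spike-and-slab")
  expect_output(print(s), "Discoveries")
})

test_that("fit report and association tables serialize to disk", {
  inst <- random_instance(n = 50, p = 6, q = 2, seed = 14)
  fit <- jqtl(inst$X, inst$Y)
  dir <- withr::local_tempdir()
  write_results(fit, dir, ppi_min = 0)
  expect_true(file.exists(file.path(dir, "associations.tsv")))
  expect_true(file.exists(file.path(dir, "hotspots.tsv")))
  rep <- jsonlite::read_json(file.path(dir, "fit_report.json"))
  expect_equal(rep$converged, TRUE)
  expect_equal(length(rep$objective_trace),
               fit$diagnostics$n_sweeps_total)
})

test_that("a single causal pair is recovered cleanly among independent SNPs", {
  set.seed(15)
  n <- 300; p <- 50; q <- 10
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  Y[, 1] <- sqrt(0.25 / var(X[, 1])) * X[, 1] + sqrt(0.75) * rnorm(n)
  fit <- jqtl(X, Y)
  expect_gt(fit$ppi[1, 1], 0.95)
  expect_lt(median(fit$ppi[-1, ]), 0.05)
})

test_that("pure-noise traits yield almost no discoveries at FDR 5%", {
  nsel <- vapply(1:20, function(s) {
    set.seed(500 + s)
    X <- matrix(rbinom(300 * 50, 2, 0.3), 300, 50)
    Y <- matrix(rnorm(300 * 10), 300, 10)
    fit <- jqtl(X, Y)
    nrow(bayesian_fdr_select(fit, level = 0.05))
  }, numeric(1))
  expect_lte(mean(nsel), 1)
})
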