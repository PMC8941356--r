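make_patients <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    sex = c("female", "male", "female"),
    race = c("white", "black", "white"),
    stroke = c(0L, 1L, 0L),
    renal_disease = 0L,
    prior_cardiac_procedure = 0L,
    myocardial_infarction = 0L,
    hypercholesterolemia = c(0L, 1L, 0L),
    dialysis = 0L,
    diabetes = c("none", "type_1", "none"),
    prior_procedure_index_leg = 0L,
    prior_procedure_nonindex_leg = 0L,
    smoking = c("never", "current", "never"),
    rest_pain = c(1L, 0L, 1L),
    bypass_target = c("tibial", "pedal", "tibial"),
    stringsAsFactors = FALSE)
}

test_that("tokenization encodes present features and keeps demographics out", {
  pats <- make_patients()
  grades <- data.frame(patient_id = pats$patient_id, wound_grade = c(2L, 0L, 2L))
  corp <- tokenize_cohort(pats, grades, y = c(1L, 0L, 1L))
  toks1 <- corp$vocabulary[corp$documents[[1]]]
  expect_true(all(c("rest_pain", "wound_grade_2") %in% toks1))
  # sex/race never appear as tokens, only in X
  expect_false(any(grepl("sex|race|male|white", corp$vocabulary)))
  expect_equal(corp$X[, "sex_male"], c(0, 1, 0))
  # wound grade 0 emits no wound token
  toks2 <- corp$vocabulary[corp$documents[[2]]]
  expect_false(any(grepl("wound_grade", toks2)))
  # identical feature rows give identical documents
  expect_identical(corp$documents[[1]], corp$documents[[3]])
})

test_that("token conditional matches brute-force enumeration of the joint", {
  corp <- tiny_corpus()
  hp <- slda_hyperparams(K = 2, alpha = 0.7, beta = 0.4, seed = 1)
  z <- list(c(1L, 2L, 1L), c(2L, 1L), 1L)
  y_star <- c(0.8, -0.3, 1.2)
  eta <- c(0.9, -0.4); gamma <- 0.5
  state <- list(z = z, y_star = y_star, eta = eta, gamma = gamma)
  for (d in 1:3) for (i in seq_along(corp$documents[[d]])) {
    got <- conditional_z_distribution(state, corp, d, i, hp)
    # oracle: joint over the two values of z_{di}, all else fixed
    flat <- unlist(z); pos <- cumsum(lengths(corp$documents))[d] -
      length(corp$documents[[d]]) + i
    lj <- sapply(1:2, function(k) {
      zv <- flat; zv[pos] <- k
      oracle_log_joint(zv, corp$documents, V = 3, K = 2, alpha = hp$alpha,
                       beta = hp$beta, y_star = y_star, eta = eta,
                       gamma = gamma, X = corp$X)
    })
    want <- exp(lj - max(lj)); want <- want / sum(want)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("token conditional is symmetric and response-monotone", {
  corp <- slda_corpus(list(1L), y = 1L, vocabulary = c("a", "b"))
  hp <- slda_hyperparams(K = 2, alpha = 1, beta = 0.5, seed = 1)
  state <- list(z = list(1L), y_star = 3, eta = c(0, 0), gamma = numeric(0))
  expect_equal(conditional_z_distribution(state, corp, 1, 1, hp), c(0.5, 0.5))
  # raising eta_1 toward a positive utility pulls probability onto topic 1
  # (the Gaussian response term peaks at eta = y*, so stay below it)
  p_prev <- 0.5
  for (e1 in c(0.5, 1, 2)) {
    state$eta <- c(e1, 0)
    p1 <- conditional_z_distribution(state, corp, 1, 1, hp)[1]
    expect_gt(p1, p_prev)
    p_prev <- p1
  }
})

test_that("latent utilities respect truncation and the closed-form mean", {
  corp <- cluster_study_config(n_docs = 400, seed = 2) |> generate_slda_corpus()
  fit0 <- list(n_dk = matrix(1, 400, 3), eta = rep(0, 3), gamma = 0.0)
  # truncation contract
  set.seed(5)
  state <- list(n_dk = matrix(1, 400, 3), eta = c(1, 0, -1), gamma = 0.4)
  ys <- sample_latent_utilities(state, corp$corpus)
  expect_true(all(ys[corp$corpus$y == 1] > 0))
  expect_true(all(ys[corp$corpus$y == 0] <= 0))

  # Monte-Carlo mean at mu = 0, y = 1: phi(0)/Phi(0) = 0.7979
  n <- 1e5
  corp1 <- slda_corpus(rep(list(1L), n), y = rep(1L, n),
                       vocabulary = "a")
  st <- list(n_dk = matrix(c(1, 0), n, 2, byrow = TRUE), eta = c(0, 0),
             gamma = numeric(0))
  set.seed(6)
  draws <- sample_latent_utilities(st, corp1)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - oracle_truncated_mean_pos(0)), 3 * se)

  # mu = +5: truncation negligible
  st$eta <- c(5, 5)
  set.seed(7)
  draws <- sample_latent_utilities(st, corp1)
  expect_lt(abs(mean(draws) - 5), 0.02)
})

test_that("coefficient draws have the ridge/OLS posterior mean", {
  set.seed(8)
  n <- 150
  zbar <- matrix(rgamma(n * 2, 1), n, 2); zbar <- zbar / rowSums(zbar)
  X <- matrix(rbinom(n, 1, 0.5), n, 1)
  y_star <- rnorm(n, zbar %*% c(1, -1) + 0.5 * X)
  docs <- rep(list(c(1L, 2L)), n)  # doc lengths 2 (zbar recomputed below)
  corp <- slda_corpus(docs, y = as.integer(y_star > 0), X = X,
                      vocabulary = c("a", "b"))
  n_dk <- round(zbar * 2); n_dk <- cbind(n_dk[, 1], 2 - n_dk[, 1])
  state <- list(n_dk = n_dk, y_star = y_star)
  A <- cbind(n_dk / 2, X)

  hp <- slda_hyperparams(K = 2, coef_prior_var = Inf, seed = 1)
  draws <- replicate(3000, unlist(sample_coefficients(state, corp, hp)))
  ols <- qr.solve(A, y_star)
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - ols) < 4 * mc_se))

  # vanishing prior variance collapses the draw to zero
  hp0 <- slda_hyperparams(K = 2, coef_prior_var = 1e-12, seed = 1)
  expect_lt(max(abs(unlist(sample_coefficients(state, corp, hp0)))), 1e-3)

  # empty design draws from the prior
  corp0 <- slda_corpus(list(), y = integer(0),
                       X = matrix(0, 0, 1), vocabulary = c("a", "b"))
  hp1 <- slda_hyperparams(K = 2, coef_prior_var = 4, seed = 1)
  set.seed(10)
  pd <- replicate(4000, unlist(sample_coefficients(list(n_dk = matrix(0, 0, 2)),
                                                   corp0, hp1)))
  expect_lt(abs(sd(pd) - 2), 0.1)
})

test_that("probit prediction applies the standard normal CDF", {
  model <- structure(list(eta_hat = c(0, 0), gamma_hat = 0,
                          hp = list(K = 2, alpha = 1)), class = "slda_fit")
  expect_equal(predict_outcome_probability(model, c(0.5, 0.5), 0), 0.5)
  model$eta_hat <- c(1.96, 1.96)
  expect_equal(predict_outcome_probability(model, c(0.5, 0.5), 0),
               pnorm(1.96), tolerance = 1e-12)
  # monotone in the linear predictor
  model$eta_hat <- c(2, 0)
  p <- sapply(c(0.2, 0.5, 0.8), function(t)
    predict_outcome_probability(model, c(t, 1 - t), 0))
  expect_true(all(diff(p) > 0))
})

test_that("fits are deterministic under a seed and keep counts consistent", {
  sim <- generate_slda_corpus(cluster_study_config(n_docs = 80, seed = 14))
  hp <- slda_hyperparams(K = 3, n_sweeps = 60, burn_in = 30, thin = 3, seed = 2)
  f1 <- slda_fit(sim$corpus, hp)
  f2 <- slda_fit(sim$corpus, hp)
  expect_identical(f1$phi_hat, f2$phi_hat)
  expect_identical(f1$eta_hat, f2$eta_hat)
  expect_identical(f1$state$z, f2$state$z)

  # count consistency: final count matrices equal a recount from z
  z <- unlist(f1$state$z); w <- unlist(sim$corpus$documents)
  n_kv <- matrix(0L, 3, length(sim$corpus$vocabulary))
  for (t in seq_along(z)) n_kv[z[t], w[t]] <- n_kv[z[t], w[t]] + 1L
  expect_identical(unname(f1$state$n_kv), n_kv)
  expect_identical(f1$state$n_k, as.integer(rowSums(n_kv)))
  expect_identical(as.integer(rowSums(f1$state$n_dk)),
                   as.integer(lengths(sim$corpus$documents)))
  # simplex invariants of the point estimates
  expect_lt(max(abs(rowSums(f1$phi_hat) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(f1$theta_hat) - 1)), 1e-10)
  # utilities agree in sign with the response
  expect_true(all(f1$state$y_star[sim$corpus$y == 1] > 0))

  expect_error(slda_hyperparams(K = 1), "K")
})

test_that("relabeling topics leaves the collapsed likelihood invariant", {
  sim <- generate_slda_corpus(cluster_study_config(n_docs = 50, seed = 3))
  hp <- slda_hyperparams(K = 3, n_sweeps = 20, burn_in = 10, thin = 1, seed = 4)
  f <- slda_fit(sim$corpus, hp)
  perm <- c(3L, 1L, 2L)
  ll <- log_likelihood_given_z(f$state$n_kv, f$state$n_k, hp$beta)
  ll_perm <- log_likelihood_given_z(f$state$n_kv[perm, ], f$state$n_k[perm],
                                    hp$beta)
  expect_equal(ll, ll_perm)
})

test_that("topic-word recovery bias shrinks with corpus size", {
  err <- sapply(c(200, 1200), function(nd) {
    sim <- generate_slda_corpus(cluster_study_config(n_docs = nd, seed = 15))
    hp <- slda_hyperparams(K = 3, n_sweeps = 400, burn_in = 200, thin = 2,
                           seed = 5)
    fit <- slda_fit(sim$corpus, hp)
    perm <- align_topics(fit$phi_hat, sim$truth$phi)
    max(abs(fit$phi_hat[perm, ] - sim$truth$phi))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("supervision improves held-out outcome discrimination", {
  cfg <- cluster_study_config(n_docs = 900, seed = 16,
                              gamma_true = numeric(0),
                              covariate_probs = numeric(0))
  sim <- generate_slda_corpus(cfg)
  train <- 1:700; test <- 701:900
  sub <- function(idx) slda_corpus(sim$corpus$documents[idx],
                                   y = sim$corpus$y[idx],
                                   vocabulary = sim$corpus$vocabulary)
  hp <- slda_hyperparams(K = 3, alpha = 0.5, n_sweeps = 400, burn_in = 200,
                         thin = 2, seed = 6)
  fit_s <- slda_fit(sub(train), hp)
  fit_u <- slda_fit(sub(train), hp, supervised = FALSE)
  score <- function(fit) sapply(test, function(d)
    predict_outcome_probability(fit, infer_theta(fit, sim$corpus$documents[[d]])))
  auc_s <- oracle_auc(score(fit_s), sim$corpus$y[test])
  auc_u <- oracle_auc(score(fit_u), sim$corpus$y[test])
  expect_gt(auc_s, auc_u)
  expect_gt(auc_s, 0.6)
})
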