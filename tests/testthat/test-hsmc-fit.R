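test_that("the deterministic initializer reflects block structure", {
  # K = 1: emissions are the pooled frequencies
  df <- dplyr::bind_rows(
    make_seq_tbl(c("L", "L", "F", "V"), shoot_id = "a"),
    make_seq_tbl(c("L", "F"), shoot_id = "b")
  )
  seqs <- as_shoot_sequences(df)
  m1 <- initialize_hsmc(seqs, K = 1, D_max = 10)
  raw <- c(L = 3, V = 1, F = 2) / 6
  floored <- pmax(raw, 1e-3); floored <- floored / sum(floored)
  expect_equal(unname(m1$b[[1]]$fate), unname(floored), tolerance = 1e-12)
  expect_equal(m1$pi, 1)

  # K = 3 on L...F...V block sequences: state 1 L-dominated, state 3 V-dominated
  df3 <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_seq_tbl(rep(c("L", "F", "V"), each = 3), shoot_id = paste0("s", i))
  }))
  m3 <- initialize_hsmc(as_shoot_sequences(df3), K = 3, D_max = 10)
  expect_equal(names(which.max(m3$b[[1]]$fate)), "L")
  expect_equal(names(which.max(m3$b[[2]]$fate)), "F")
  expect_equal(names(which.max(m3$b[[3]]$fate)), "V")

  expect_error(initialize_hsmc(seqs[0, ], K = 1), "No sequences")
  expect_error(initialize_hsmc(seqs, K = 7), "exceeds every sequence length")
})

test_that("EM at a deterministic generating model is a fixed point", {
  m <- delta_model(dur = 4)
  seqs <- obs_to_seqs(list(fate = rep("L", 4), flower = rep("0", 4)))
  fit <- hsmc_fit(seqs, init = m)
  expect_equal(fit$n_iter, 1L)
  expect_true(fit$converged)
  expect_equal(fit$loglik, 0)
})

test_that("tol = Inf performs exactly one EM iteration", {
  sim <- generate_dataset(make_preset("low-flowering"), n_per_group = 20,
                          years = "Y1", seed = 2)
  fit <- hsmc_fit(sim$sequences, K = 3, tol = Inf)
  expect_equal(fit$n_iter, 1L)
  expect_length(fit$loglik_trace, 2L)
})

test_that("log-likelihood is nondecreasing and left-right zeros are preserved", {
  for (s in 1:4) {
    preset <- make_preset(c("high-flowering", "low-flowering",
                            "median-skipping")[1 + s %% 3])
    sim <- generate_dataset(preset, n_per_group = 40, years = "Y1", seed = s)
    fit <- hsmc_fit(sim$sequences, K = 3, max_iter = 60)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    A <- fit$model$A
    for (j in 1:3) expect_identical(unname(A[j, seq_len(j)]), rep(0, j))
    expect_s3_class(validate_hsmc(fit$model), "hsmc_model")
  }
})

test_that("E-step posterior mass assigns each node to exactly one state", {
  set.seed(88)
  m <- random_model(3, D_max = 6)
  for (trial in 1:10) {
    obs <- random_obs(sample(3:8, 1))
    post <- posterior_states(obs_to_seqs(obs), m)
    tot <- sum(post$prob)
    expect_equal(tot, length(obs$fate), tolerance = 1e-9)
    per_node <- tapply(post$prob, post$node_rank, sum)
    expect_true(all(abs(per_node - 1) < 1e-9))
  }
})

test_that("one M-step on the model's own expected counts is a fixed point", {
  # infinite-data EM: weight per-sequence expected counts by the sequence's
  # own probability, summed over every sequence the capped model can emit
  set.seed(12)
  K <- 2; D_max <- 2
  A <- rbind(c(0, 0.6, 0.4), c(0, 0, 1))
  m <- hsmc_model(
    pi = c(0.8, 0.2), A = A,
    d = rbind(c(0.3, 0.7), c(0.5, 0.5)),
    b = list(
      list(fate = setNames(c(0.7, 0.2, 0.1), c("L", "V", "F")),
           flower = setNames(c(0.6, 0.3, 0.1), c("0", "1", "2+"))),
      list(fate = setNames(c(0.1, 0.6, 0.3), c("L", "V", "F")),
           flower = setNames(c(0.2, 0.3, 0.5), c("0", "1", "2+")))
    )
  )
  acc <- list(init = numeric(K), trans = matrix(0, K, K + 1),
              dur = matrix(0, K, D_max), fate = matrix(0, K, 3),
              flower = matrix(0, K, 3))
  lp <- budzones:::model_logparams(m)
  total_p <- 0
  for (T_len in 1:4) {  # max length = K * D_max
    for (obs in all_obs(T_len)) {
      fate_i <- match(obs$fate, c("L", "V", "F"))
      flw_i <- match(obs$flower, c("0", "1", "2+"))
      logB <- budzones:::emission_logprob(m, fate_i, flw_i)
      e <- budzones:::hsmc_estep_cpp(lp$logpi, lp$logA, lp$logd, logB)
      if (!is.finite(e$loglik)) next
      w <- exp(e$loglik)
      total_p <- total_p + w
      acc$init <- acc$init + w * e$init
      acc$trans <- acc$trans + w * e$trans
      acc$dur <- acc$dur + w * e$dur
      for (c in 1:3) {
        acc$fate[, c] <- acc$fate[, c] +
          w * rowSums(e$gamma[, fate_i == c, drop = FALSE])
        acc$flower[, c] <- acc$flower[, c] +
          w * rowSums(e$gamma[, flw_i == c, drop = FALSE])
      }
    }
  }
  expect_equal(total_p, 1, tolerance = 1e-12)  # the model is capped at T = 4
  m2 <- budzones:::em_mstep(m, acc)
  expect_equal(m2$pi, m$pi, tolerance = 1e-10)
  expect_equal(m2$A, m$A, tolerance = 1e-10)
  expect_equal(m2$d, m$d, tolerance = 1e-10)
  for (j in 1:K) {
    expect_equal(m2$b[[j]]$fate, m$b[[j]]$fate, tolerance = 1e-10)
    expect_equal(m2$b[[j]]$flower, m$b[[j]]$flower, tolerance = 1e-10)
  }
})

test_that("a zero-probability start errors with advice to floor emissions", {
  m <- delta_model(dur = 2)
  seqs <- obs_to_seqs(list(fate = c("L", "V"), flower = c("0", "0")))
  expect_error(hsmc_fit(seqs, init = m), "floor")
})

test_that("per-genotype pooling fits one model per group", {
  sim <- generate_dataset(list(make_preset("high-flowering"),
                               make_preset("median-skipping")),
                          n_per_group = 30, years = "Y1", seed = 4)
  fits <- hsmc_fit_by(sim$sequences, group_by = "genotype", K = 3,
                      max_iter = 40)
  expect_equal(nrow(fits), 2L)
  expect_setequal(fits$genotype, c("high-flowering", "median-skipping"))
  expect_true(all(vapply(fits$fit, function(f) inherits(f, "hsmc_fit"), TRUE)))
  expect_error(hsmc_fit_by(sim$sequences, group_by = "nope"), "Unknown grouping")
})
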