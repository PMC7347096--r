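test_that("presets encode the documented zone structure", {
  for (nm in c("high-flowering", "low-flowering", "median-skipping")) {
    p <- make_preset(nm)
    m <- p$model
    # basal zone: latent buds exclusively
    expect_equal(unname(m$b[[1]]$fate[["L"]]), 1)
    # median floral-dominated, distal vegetative-dominated
    expect_equal(names(which.max(m$b[[2]]$fate)), "F")
    expect_equal(names(which.max(m$b[[3]]$fate)), "V")
    # both later zones skippable
    expect_gt(m$A[1, 3], 0)
    expect_gt(m$A[2, 4], 0)
    # no backward transition mass; all mass starts in state 1
    sub <- m$A[, 1:3]
    expect_true(all(sub[lower.tri(sub, diag = TRUE)] == 0))
    expect_equal(m$pi, c(1, 0, 0))
    # basal occupancy support starts at 2 metamers
    expect_equal(m$d[1, 1], 0)
  }
  hf <- make_preset("high-flowering")
  expect_gt(hf$model$A[1, 2], 0.8)
  expect_gt(occupancy_means(hf$model)[2], 2)
  expect_error(make_preset("ultra-flowering"), "arg")
})

test_that("generation is byte-identical for identical preset and seed", {
  a <- generate_dataset(make_preset("low-flowering"), n_per_group = 25, seed = 6)
  b <- generate_dataset(make_preset("low-flowering"), n_per_group = 25, seed = 6)
  expect_identical(a, b)
  c2 <- generate_dataset(make_preset("low-flowering"), n_per_group = 25, seed = 7)
  expect_false(identical(a$sequences, c2$sequences))
})

test_that("generated datasets respect structural bounds and stratification", {
  presets <- lapply(c("high-flowering", "low-flowering", "median-skipping"),
                    make_preset)
  sim <- generate_dataset(presets, n_per_group = 60, years = c("Y1", "Y2"),
                          seed = 10)
  lens <- table(sim$sequences$shoot_id)
  expect_equal(length(lens), 3 * 60 * 2)
  expect_true(all(lens >= 2))
  expect_true(all(lens <= 30 * 3))
  # the metamer-to-cm map exercises all three shoot-type classes
  meta <- shoot_summaries(sim$sequences)
  expect_setequal(as.character(unique(meta$shoot_type)), c("SS", "MS", "LS"))
  # basal zone always present in the generating truth
  basal_ids <- unique(sim$truth$shoot_id[sim$truth$state == 1])
  expect_setequal(basal_ids, unique(sim$sequences$shoot_id))
})

test_that("the injected year effect shortens second-year shoots", {
  p <- make_preset("high-flowering")
  mu1 <- expected_shoot_length(p$model)
  m2 <- budzones:::apply_year_effect(p)
  mu2 <- expected_shoot_length(m2)
  expect_lt(mu2, mu1)
  # and the median-zone entry probability drops
  expect_lt(m2$A[1, 2], p$model$A[1, 2])

  sim <- generate_dataset(p, n_per_group = 1000, years = c("Y1", "Y2"),
                          seed = 20)
  meta <- shoot_summaries(sim$sequences)
  l1 <- meta$n_metamers[meta$year == "Y1"]
  l2 <- meta$n_metamers[meta$year == "Y2"]
  se <- sqrt(var(l1) / length(l1) + var(l2) / length(l2))
  expect_gt(mean(l1) - mean(l2), 3 * se)
})

test_that("per-state emission frequencies over true segments converge to the
           preset pmfs", {
  p <- make_preset("high-flowering")
  sim <- generate_dataset(p, n_per_group = 1200, years = "Y1", seed = 30)
  expect_gt(nrow(sim$sequences), 10000)
  node_state <- integer(nrow(sim$sequences))
  key <- paste(sim$sequences$shoot_id, sim$sequences$node_rank)
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    ranks <- tr$start_rank:(tr$start_rank + tr$length - 1)
    node_state[match(paste(tr$shoot_id, ranks), key)] <- tr$state
  }
  expect_true(all(node_state > 0))
  for (j in 1:3) {
    emp <- table(factor(sim$sequences$bud_fate[node_state == j],
                        levels = c("L", "V", "F")))
    emp <- as.numeric(emp) / sum(emp)
    expect_true(all(abs(emp - unname(p$model$b[[j]]$fate)) < 0.02))
  }
})

test_that("recovery error shrinks with sample size and reports all free
           parameters", {
  p <- make_preset("high-flowering")
  reps <- lapply(1:10, function(r) {
    rep <- recovery_experiment(p, n_grid = c(50, 500, 5000),
                               seed = 100 + r, max_iter = 100)
    rep$replicate <- r
    rep
  })
  rep <- dplyr::bind_rows(reps)
  # every free parameter reported at every n
  per_n <- table(rep$n) / 10
  expect_true(all(per_n == per_n[[1]]))
  expect_equal(length(unique(rep$parameter)), as.integer(per_n[[1]]))
  med <- tapply(rep$abs_error / pmax(rep$tolerance, 1e-12), rep$n, median)
  med <- med[order(as.integer(names(med)))]
  expect_true(all(diff(med) < 0))
  # per-parameter: median error at n = 5000 no worse than at n = 50, up to a
  # 0.005 floor for boundary parameters recovered (near-)exactly at every n
  by_par <- rep |>
    dplyr::group_by(.data$parameter, .data$n) |>
    dplyr::summarise(e = median(.data$abs_error), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "n", values_from = "e")
  expect_true(all(by_par$`5000` <= pmax(by_par$`50` + 1e-9, 0.005)))
})

test_that("state alignment refuses ambiguous argmaxes", {
  p <- make_preset("high-flowering")
  est <- p$model
  est$b[[3]]$fate <- est$b[[2]]$fate
  expect_error(budzones:::align_states(est, p$model), "not unique")
})
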