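test_that("Kruskal-Wallis handles identical, separated and fully tied groups", {
  d_same <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3),
                           g = rep(c("a", "b"), each = 3))
  kw <- kruskal_wallis(d_same, "v", "g")
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)

  d_sep <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                          g = rep(c("a", "b"), each = 3))
  kw2 <- kruskal_wallis(d_sep, "v", "g")
  expect_equal(kw2$statistic, hand_kw(d_sep$v, d_sep$g), tolerance = 1e-12)

  d_tied <- tibble::tibble(v = rep(5, 6), g = rep(c("a", "b"), each = 3))
  kw3 <- kruskal_wallis(d_tied, "v", "g")
  expect_equal(kw3$statistic, 0)
  expect_equal(kw3$p_value, 1)

  expect_error(kruskal_wallis(tibble::tibble(v = 1:3, g = "a"), "v", "g"),
               "two groups")
})

test_that("rank tests agree with from-scratch textbook formulas", {
  set.seed(61)
  for (trial in 1:50) {
    n <- sample(36:60, 1)  # > 10 per group, so the normal approximation runs
    x <- sample(1:8, n, replace = TRUE) + round(runif(n), 1)
    g <- rep(c("a", "b", "c"), length.out = n)
    kw <- kruskal_wallis(tibble::tibble(v = x, g = g), "v", "g")
    expect_equal(kw$statistic, hand_kw(x, g), tolerance = 1e-8)

    p_pkg <- budzones:::wmw_p(x[g == "a"], x[g == "b"])
    p_hand <- hand_wmw_p(x[g == "a"], x[g == "b"])
    expect_equal(p_pkg, p_hand, tolerance = 1e-8)
  }
})

test_that("small untied samples use the exact rank-sum distribution", {
  # oracle: enumerate every assignment of the pooled ranks to group 1
  exact_wmw_p <- function(x, y) {
    n1 <- length(x); N <- n1 + length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(utils::combn(N, n1), 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    if (u_obs > mean(us)) min(1, 2 * mean(us >= u_obs))
    else min(1, 2 * mean(us <= u_obs))
  }
  set.seed(62)
  for (trial in 1:10) {
    x <- sample(seq(0.1, 50, by = 0.1), sample(4:8, 1))
    y <- sample(setdiff(seq(0.1, 50, by = 0.1), x), sample(4:8, 1))
    expect_equal(budzones:::wmw_p(x, y), exact_wmw_p(x, y), tolerance = 1e-10)
  }
})

test_that("compact letters reproduce the canonical patterns", {
  sep <- tibble::tibble(v = c(1:6, 101:106),
                        g = rep(c("a", "b"), each = 6))
  cmp <- pairwise_wilcoxon_letters(sep, "v", "g")
  expect_equal(unname(cmp$groups$letters), c("a", "b"))

  # A ~ B, B ~ C, A != C  ->  a, ab, b
  P <- matrix(c(NA, 0.5, 0.01,
                0.5, NA, 0.5,
                0.01, 0.5, NA), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(compact_letters(P)), c("a", "ab", "b"))
})

test_that("compact letters form a valid clique cover on random graphs", {
  set.seed(71)
  for (trial in 1:50) {
    g <- sample(3:8, 1)
    P <- matrix(NA_real_, g, g, dimnames = list(letters[1:g], letters[1:g]))
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      P[i, j] <- P[j, i] <- ifelse(runif(1) < 0.4, runif(1, 0, 0.049),
                                   runif(1, 0.051, 1))
    }
    lab <- compact_letters(P, alpha = 0.05)
    expect_true(letters_valid(lab, P, alpha = 0.05))
  }
})

test_that("letter display agrees with an independent all-pairs re-test", {
  set.seed(81)
  d <- tibble::tibble(
    v = c(rnorm(20, 0), rnorm(20, 0.2), rnorm(20, 3), rnorm(20, 3.1),
          rnorm(20, 8), rnorm(20, 0.1), rnorm(20, 8.2), rnorm(20, 2.9)),
    g = rep(paste0("g", 1:8), each = 20)
  )
  cmp <- pairwise_wilcoxon_letters(d, "v", "g")
  lv <- cmp$groups$group
  P <- matrix(NA_real_, 8, 8, dimnames = list(lv, lv))
  for (i in 1:7) for (j in (i + 1):8) {
    P[i, j] <- P[j, i] <- hand_wmw_p(d$v[d$g == lv[i]], d$v[d$g == lv[j]])
  }
  expect_equal(cmp$p_matrix, P, tolerance = 1e-8)
  lab <- setNames(cmp$groups$letters, cmp$groups$group)
  expect_true(letters_valid(lab, P, alpha = 0.05))
})

test_that("Pearson chi-squared matches closed forms and rejects bad tables", {
  flat <- proportion_chi2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  skew <- proportion_chi2(rbind(c(20, 10), c(10, 20)))
  expect_equal(skew$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(skew$df, 1)

  expect_error(proportion_chi2(matrix(1:3, 1)), "2 rows")
  expect_error(proportion_chi2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(proportion_chi2(rbind(c(-1, 2), c(1, 2))), "nonnegative")
})

test_that("Spearman rho and its significance limit behave as documented", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  r1 <- spearman_with_limits(x, x * 2 + 1)
  expect_equal(r1$rho, 1)
  r2 <- spearman_with_limits(x, -x)
  expect_equal(r2$rho, -1)

  set.seed(91)
  a <- rnorm(150); b <- a + rnorm(150, sd = 3)
  r3 <- spearman_with_limits(a, b, label = "a vs b")
  expect_equal(r3$limit, qnorm(0.975) / sqrt(149))
  expect_equal(r3$limit, 0.1606, tolerance = 1e-3)
  expect_equal(r3$rho, hand_spearman(a, b), tolerance = 1e-10)

  expect_error(spearman_with_limits(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_with_limits(1:3, 3:1), "at least 4")
})

test_that("summary tables match direct recomputation from the segments", {
  sim <- generate_dataset(list(make_preset("high-flowering"),
                               make_preset("low-flowering")),
                          n_per_group = 120, years = c("Y1", "Y2"), seed = 13)
  fits <- hsmc_fit_by(sim$sequences, group_by = "genotype", K = 3,
                      max_iter = 40)
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    sub <- sim$sequences[sim$sequences$genotype == fits$genotype[i], ]
    class(sub) <- class(sim$sequences)
    label_zones(restore_states(sub, fits$fit[[i]]$model), fits$fit[[i]]$model)
  }))
  tb <- summary_tables(segs, sim$sequences, group_by = c("genotype", "year"))

  # occurrence cells equal direct counting over restored segments
  meta <- shoot_summaries(sim$sequences)
  meta$group <- paste(meta$genotype, meta$year, sep = ":")
  segm <- dplyr::left_join(segs, meta, by = "shoot_id")
  for (r in sample(nrow(tb$occurrence), 6)) {
    row <- tb$occurrence[r, ]
    ids <- meta$shoot_id[meta$group == row$group]
    direct <- length(unique(segm$shoot_id[segm$shoot_id %in% ids &
                                            as.character(segm$zone) == as.character(row$zone)])) /
      length(ids)
    expect_equal(row$occurrence, direct)
  }

  # zone length cells equal direct means over restored segments
  zm <- tb$zone_metamers[tb$zone_metamers$variable == "median_zone_metamers", ]
  for (r in seq_len(nrow(zm))) {
    ids <- meta$shoot_id[meta$group == zm$group[r]]
    lens <- segm$length[segm$shoot_id %in% ids &
                          as.character(segm$zone) == "median"]
    if (length(lens) == 0) {
      expect_true(is.na(zm$mean[r]) || is.nan(zm$mean[r]))
    } else {
      expect_equal(zm$mean[r], mean(lens))
    }
  }

  # letters on every compared variable are a valid clique cover
  expect_true(all(c("zone_metamers", "occurrence", "correlations") %in%
                    names(tb)))
})

test_that("survival-style proportion comparisons report groups and a chi2 test", {
  d <- tibble::tibble(genotype = c("A", "B", "C"),
                      alive = c(30, 18, 40), total = c(50, 50, 50))
  pt <- proportion_table(d, "genotype", "alive", "total")
  expect_equal(pt$proportions$proportion, c(0.6, 0.36, 0.8))
  direct <- proportion_chi2(cbind(d$alive, d$total - d$alive))
  expect_equal(pt$test$statistic, direct$statistic)
  expect_error(proportion_table(tibble::tibble(g = "A", a = 5, t = 3),
                                "g", "a", "t"), "exceed")
})
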