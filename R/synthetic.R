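#' Named synthetic genotype presets
#'
#' Each preset is a 3-transient-state left-right HSMC emulating the zone
#' structure of one-year-old shoots: a basal zone of latent buds exclusively
#' (state 1 emits `L` with probability 1 and no associated flowers), a median
#' flowering zone (state 2, floral-dominated with most of the associated
#' flower-bud mass) and a distal vegetative zone (state 3,
#' vegetative-dominated with little flower mass). The median and distal zones
#' are both skippable (positive `A[1, 3]` and `A[2, end]`). The numeric
#' values are illustrative preset choices, not field estimates; the three
#' presets differ in how strongly shoots flower:
#'
#' * `"high-flowering"` — high median-zone entry (`A[1,2] = 0.85`) and a long
#'   median zone;
#' * `"low-flowering"` — median zone entered about half the time and short;
#' * `"median-skipping"` — the median zone is usually skipped
#'   (`A[1,3] = 0.65`).
#'
#' Occupancy distributions are shifted negative binomials truncated to
#' `1..D_max` (basal support starts at 2 metamers so generated shoots always
#' have at least 2 nodes when only the basal zone is expressed).
#'
#' @param name Preset name.
#' @param D_max Occupancy support (default 30 metamers).
#' @return An object of class `synthetic_preset`: `name`, `model`
#'   (`hsmc_model`), `occ_spec` (per-state occupancy recipe used to apply
#'   year effects), `year_effect` (multiplicative shifts applied in the
#'   second simulated year), and a nominal `shoot_type_mix`.
#' @export
make_preset <- function(name = c("high-flowering", "low-flowering",
                                 "median-skipping"), D_max = 30) {
  name <- match.arg(name)
  spec <- switch(name,
    "high-flowering" = list(
      A = rbind(c(0, 0.85, 0.12, 0.03), c(0, 0, 0.75, 0.25), c(0, 0, 0, 1)),
      occ = list(c(min = 2, mean = 5.0, size = 5),
                 c(min = 1, mean = 3.2, size = 6),
                 c(min = 1, mean = 5.0, size = 5)),
      fate2 = c(0.05, 0.10, 0.85), flower2 = c(0.55, 0.33, 0.12),
      fate3 = c(0.08, 0.87, 0.05), flower3 = c(0.90, 0.08, 0.02)
    ),
    "low-flowering" = list(
      A = rbind(c(0, 0.45, 0.40, 0.15), c(0, 0, 0.55, 0.45), c(0, 0, 0, 1)),
      occ = list(c(min = 2, mean = 6.0, size = 5),
                 c(min = 1, mean = 1.8, size = 6),
                 c(min = 1, mean = 4.5, size = 5)),
      fate2 = c(0.10, 0.15, 0.75), flower2 = c(0.80, 0.15, 0.05),
      fate3 = c(0.06, 0.90, 0.04), flower3 = c(0.95, 0.04, 0.01)
    ),
    "median-skipping" = list(
      A = rbind(c(0, 0.25, 0.65, 0.10), c(0, 0, 0.60, 0.40), c(0, 0, 0, 1)),
      occ = list(c(min = 2, mean = 5.5, size = 5),
                 c(min = 1, mean = 2.2, size = 6),
                 c(min = 1, mean = 4.0, size = 5)),
      fate2 = c(0.08, 0.12, 0.80), flower2 = c(0.70, 0.22, 0.08),
      fate3 = c(0.07, 0.88, 0.05), flower3 = c(0.93, 0.05, 0.02)
    )
  )
  d <- t(vapply(spec$occ, function(o) shifted_nbinom_pmf(o, D_max),
                numeric(D_max)))
  b <- list(
    list(fate = setNames(c(1, 0, 0), FATE_LEVELS),
         flower = setNames(c(1, 0, 0), FLOWER_LEVELS)),
    list(fate = setNames(spec$fate2, FATE_LEVELS),
         flower = setNames(spec$flower2, FLOWER_LEVELS)),
    list(fate = setNames(spec$fate3, FATE_LEVELS),
         flower = setNames(spec$flower3, FLOWER_LEVELS))
  )
  model <- hsmc_model(pi = c(1, 0, 0), A = spec$A, d = d, b = b)
  structure(
    list(name = name, model = model, occ_spec = spec$occ,
         year_effect = c(occupancy = 0.8, median_entry = 0.8),
         shoot_type_mix = c(SS = 0.25, MS = 0.50, LS = 0.25)),
    class = "synthetic_preset"
  )
}

# Occupancy pmf: negative binomial shifted to start at `min`, truncated to
# 1..D_max and renormalized; parameterised by its (pre-truncation) mean.
shifted_nbinom_pmf <- function(o, D_max) {
  u <- seq_len(D_max)
  mu <- max(o[["mean"]] - o[["min"]], 0.05)
  p <- ifelse(u >= o[["min"]],
              stats::dnbinom(pmax(u - o[["min"]], 0), mu = mu,
                             size = o[["size"]]),
              0)
  p / sum(p)
}

#' @export
print.synthetic_preset <- function(x, ...) {
  cat("Synthetic genotype preset:", x$name, "\n")
  print(x$model)
  invisible(x)
}

# Second-year variant of a preset model: occupancy means and the median-zone
# entry probability are shrunk multiplicatively (an "off" year with shorter
# shoots and less flowering); the A[1, ] deficit moves to the skip routes.
apply_year_effect <- function(preset, D_max = preset$model$D_max) {
  f_occ <- preset$year_effect[["occupancy"]]
  f_entry <- preset$year_effect[["median_entry"]]
  occ <- lapply(preset$occ_spec, function(o) {
    o[["mean"]] <- max(o[["mean"]] * f_occ, o[["min"]] + 0.05)
    o
  })
  m <- preset$model
  m$d <- t(vapply(occ, function(o) shifted_nbinom_pmf(o, D_max),
                  numeric(D_max)))
  a12 <- m$A[1, 2] * f_entry
  deficit <- m$A[1, 2] - a12
  rest <- m$A[1, c(3, 4)]
  m$A[1, 2] <- a12
  m$A[1, c(3, 4)] <- rest + deficit * rest / sum(rest)
  validate_hsmc(m)
}

#' Generate a synthetic shoot-sequence dataset
#'
#' Simulates shoots from one or more presets over one or two "years".
#' Genotype labels are the preset names; in the second year each preset's
#' `year_effect` is applied (shorter zones, lower median-zone entry), so the
#' qualitative year effect of the field data — shorter shoots and less
#' flowering in the off year — is injected with a single source of truth.
#' Shoot length in cm is derived from the metamer count by the documented
#' monotone map `length_cm = 0.45 * n_metamers * exp(rnorm(1, 0, 0.25))`
#' (rounded to 1 mm), which spreads shoots across the SS/MS/LS classes.
#'
#' @param presets A `synthetic_preset` or list of them.
#' @param n_per_group Shoots per preset per year.
#' @param years Character vector of year labels (first is the reference year;
#'   the year effect applies to all later ones). Use a single label for a
#'   one-year design.
#' @param seed Integer seed; generation is byte-identical for identical
#'   (presets, seed).
#' @param length_slope,length_sigma Parameters of the metamer-to-cm map.
#' @return A list: `sequences` (a `shoot_sequences` tibble) and `truth` (the
#'   generating segmentations with `genotype`, `year`, `state`, `zone`,
#'   `start_rank`, `length`).
#' @export
generate_dataset <- function(presets, n_per_group = 150,
                             years = c("Y1", "Y2"), seed = 1,
                             length_slope = 0.45, length_sigma = 0.25) {
  if (inherits(presets, "synthetic_preset")) presets <- list(presets)
  withr::with_seed(as.integer(seed), {
    seq_parts <- list()
    truth_parts <- list()
    for (p in presets) {
      for (yi in seq_along(years)) {
        m <- if (yi == 1) p$model else apply_year_effect(p)
        sim <- simulate_shoots(m, n_per_group, genotype = p$name,
                               year = years[yi],
                               shoot_id_prefix = paste0(p$name, "_", years[yi]))
        n_met <- sim$sequences |>
          dplyr::count(.data$shoot_id, name = "n_metamers")
        len <- round(length_slope * n_met$n_metamers *
                       exp(rnorm(nrow(n_met), 0, length_sigma)), 1)
        len <- pmax(len, 0.1)
        sim$sequences$length_cm <-
          len[match(sim$sequences$shoot_id, n_met$shoot_id)]
        sim$truth$genotype <- p$name
        sim$truth$year <- years[yi]
        seq_parts <- c(seq_parts, list(sim$sequences))
        truth_parts <- c(truth_parts, list(sim$truth))
      }
    }
    seqs <- dplyr::bind_rows(seq_parts)
    class(seqs) <- c("shoot_sequences", class(tibble::tibble()))
    list(sequences = seqs, truth = dplyr::bind_rows(truth_parts))
  })
}

#' Parameter-recovery experiment
#'
#' For each sample size in `n_grid`: simulate that many shoots from the
#' preset (single year, no year effect), fit a K = 3 model by EM from the
#' deterministic initializer, align estimated states to the truth by the
#' bud-fate emission argmax, and report every free parameter's truth,
#' estimate and absolute error against the stated tolerances: transition
#' probabilities within 0.05, mean zone occupancies within 10% (relative),
#' emission probabilities within 0.05.
#'
#' @param preset A `synthetic_preset`.
#' @param n_grid Integer vector of sample sizes (default 500).
#' @param seed Integer seed.
#' @param tol_trans,tol_occ_rel,tol_emit Tolerances for the pass flags.
#' @param ... Passed to [hsmc_fit()].
#' @return A `recovery_report` tibble: `n`, `parameter`, `truth`, `estimate`,
#'   `abs_error`, `tolerance`, `pass`.
#' @export
recovery_experiment <- function(preset, n_grid = 500, seed = 1,
                                tol_trans = 0.05, tol_occ_rel = 0.10,
                                tol_emit = 0.05, ...) {
  truth <- preset$model
  K <- truth$K
  out <- lapply(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    sim <- generate_dataset(preset, n_per_group = n, years = "Y1",
                            seed = as.integer(seed) + gi - 1)
    fit <- hsmc_fit(sim$sequences, K = K, D_max = truth$D_max, ...)
    est <- align_states(fit$model, truth)
    rows <- list()
    add <- function(parameter, tr, es, tol, rel = FALSE) {
      err <- abs(es - tr)
      tolv <- if (rel) tol * abs(tr) else tol
      rows[[length(rows) + 1]] <<- tibble::tibble(
        n = n, parameter = parameter, truth = tr, estimate = es,
        abs_error = err, tolerance = tolv, pass = err <= tolv
      )
    }
    for (j in seq_len(K)) {
      for (k in seq_len(K + 1)) {
        if (k > j) {
          add(sprintf("A[%d,%s]", j, if (k > K) "end" else k),
              truth$A[j, k], est$A[j, k], tol_trans)
        }
      }
      add(sprintf("occupancy_mean[%d]", j),
          occupancy_means(truth)[j], occupancy_means(est)[j],
          tol_occ_rel, rel = TRUE)
      for (c in 1:3) {
        add(sprintf("fate[%d,%s]", j, FATE_LEVELS[c]),
            truth$b[[j]]$fate[c], est$b[[j]]$fate[c], tol_emit)
        add(sprintf("flower[%d,%s]", j, FLOWER_LEVELS[c]),
            truth$b[[j]]$flower[c], est$b[[j]]$flower[c], tol_emit)
      }
    }
    dplyr::bind_rows(rows)
  })
  rep <- dplyr::bind_rows(out)
  class(rep) <- c("recovery_report", class(rep))
  rep
}

# Permute the states of `est` so its bud-fate emission argmaxes match those
# of `truth`. Errors (rather than silently permuting) when the alignment is
# ambiguous.
align_states <- function(est, truth) {
  key <- function(m) vapply(m$b, function(e) which.max(e$fate), 0L)
  kt <- key(truth); ke <- key(est)
  if (anyDuplicated(kt) || anyDuplicated(ke)) {
    abort("State alignment failed: bud-fate emission argmaxes are not unique.")
  }
  perm <- match(kt, ke)
  if (anyNA(perm)) {
    abort("State alignment failed: estimated states do not cover the truth's fate argmaxes.")
  }
  K <- est$K
  out <- est
  out$pi <- est$pi[perm]
  out$d <- est$d[perm, , drop = FALSE]
  out$b <- est$b[perm]
  A <- est$A[perm, , drop = FALSE]
  A[, seq_len(K)] <- A[, perm, drop = FALSE]
  out$A <- A
  out
}
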