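#' Deterministic initial model for EM
#'
#' Builds a starting HSMC by splitting every shoot into `K` equal contiguous
#' blocks (node `t` of a shoot of length `T` goes to block
#' `ceiling(t * K / T)`). Emission distributions are the block-wise category
#' frequencies, floored at `1e-3` and renormalized so no observed category
#' starts at zero probability; occupancy distributions are a broad triangular
#' pmf centred on the mean block length; initial mass is all on state 1;
#' transition rows are uniform over the allowed later states and the end
#' state. Deterministic, so fits are exactly reproducible.
#'
#' @param seqs A `shoot_sequences` tibble.
#' @param K Number of transient states (default 3: basal, median, distal).
#' @param D_max Occupancy support (maximum zone length in metamers).
#' @return An `hsmc_model`.
#' @export
initialize_hsmc <- function(seqs, K = 3, D_max = 30) {
  shoots <- split_shoots(seqs)
  if (length(shoots) == 0) abort("No sequences supplied.")
  lens <- vapply(shoots, function(s) length(s$fate), 0L)
  if (max(lens) < K) {
    abort(paste0("K = ", K, " exceeds every sequence length (max ",
                 max(lens), ")."))
  }
  fate_counts <- matrix(0, K, 3)
  flower_counts <- matrix(0, K, 3)
  block_len <- matrix(0, K, 2)  # sum, n
  for (s in shoots) {
    Ti <- length(s$fate)
    blk <- ceiling(seq_len(Ti) * K / Ti)
    for (j in unique(blk)) {
      sel <- blk == j
      fate_counts[j, ] <- fate_counts[j, ] + tabulate(s$fate[sel], 3)
      flower_counts[j, ] <- flower_counts[j, ] + tabulate(s$flower[sel], 3)
      block_len[j, ] <- block_len[j, ] + c(sum(sel), 1)
    }
  }
  floor_norm <- function(x, floor = 1e-3) {
    p <- x / max(sum(x), 1)
    p <- pmax(p, floor)
    p / sum(p)
  }
  b <- lapply(seq_len(K), function(j) list(
    fate = setNames(floor_norm(fate_counts[j, ]), FATE_LEVELS),
    flower = setNames(floor_norm(flower_counts[j, ]), FLOWER_LEVELS)
  ))
  d <- t(vapply(seq_len(K), function(j) {
    mu <- if (block_len[j, 2] > 0) block_len[j, 1] / block_len[j, 2] else
      mean(lens) / K
    triangular_pmf(mu, D_max)
  }, numeric(D_max)))
  A <- matrix(0, K, K + 1)
  for (j in seq_len(K)) {
    allowed <- c(seq_len(K)[-seq_len(j)], K + 1)
    A[j, allowed] <- 1 / length(allowed)
  }
  hsmc_model(pi = c(1, rep(0, K - 1)), A = A, d = d, b = b)
}

# Broad triangular pmf on 1..D_max centred at mu, half-width max(mu, 3),
# with a tiny uniform floor so EM can move mass anywhere in the support.
triangular_pmf <- function(mu, D_max, floor = 1e-6) {
  u <- seq_len(D_max)
  w <- pmax(0, 1 - abs(u - mu) / max(mu, 3)) + floor
  w / sum(w)
}

#' Fit an HSMC by expectation-maximization
#'
#' Maximum-likelihood estimation over pooled shoot sequences with explicit
#' state durations. The E-step runs a forward-backward recursion per shoot,
#' consistent with the absorbing end-state convention (the final zone's length
#' is fully observed), yielding posterior expected counts of initial states,
#' state-to-state transition events (including to the end state), state
#' occupancy durations and per-state emission categories. The M-step
#' re-estimates `pi`, the transition rows, the occupancy pmfs and the emission
#' pmfs from the pooled expected counts. Iteration stops when the relative
#' log-likelihood improvement drops below `tol` or after `max_iter`
#' iterations.
#'
#' Occupancy pmf entries below `1e-12` are truncated and the pmf renormalized
#' after each M-step, preventing denormalized tails. Emission categories never
#' observed may go to probability zero. States with (numerically) no expected
#' visits keep their previous parameters.
#'
#' @param seqs A `shoot_sequences` tibble.
#' @param K Number of transient states; ignored when `init` is given.
#' @param init Optional starting `hsmc_model`; default
#'   `initialize_hsmc(seqs, K, D_max)`.
#' @param D_max Occupancy support; ignored when `init` is given.
#' @param tol Relative log-likelihood change below which EM stops
#'   (default `1e-6`). Use `Inf` to perform exactly one iteration.
#' @param max_iter Maximum number of EM iterations (default 500).
#' @param verbose Log per-iteration log-likelihood with `message()`.
#' @return An object of class `hsmc_fit`: `model`, `loglik` (final),
#'   `loglik_trace` (per-iteration, nondecreasing), `n_iter` (number of
#'   parameter updates performed), `converged`, `n_seq`, `n_nodes`.
#' @export
hsmc_fit <- function(seqs, K = 3, init = NULL, D_max = 30, tol = 1e-6,
                     max_iter = 500, verbose = FALSE) {
  if (is.null(init)) init <- initialize_hsmc(seqs, K = K, D_max = D_max)
  m <- validate_hsmc(init)
  K <- m$K
  D_max <- m$D_max
  shoots <- split_shoots(seqs)
  if (length(shoots) == 0) abort("No sequences supplied.")
  obs <- lapply(shoots, function(s) list(fate = s$fate, flower = s$flower))
  n_nodes <- sum(vapply(obs, function(o) length(o$fate), 0L))

  trace <- numeric(0)
  converged <- FALSE
  n_updates <- 0
  for (iter in seq_len(max_iter + 1)) {
    st <- em_estep(m, obs)
    if (!is.finite(st$loglik)) {
      abort(paste0(
        "Non-finite log-likelihood (", st$loglik, ") at EM iteration ", iter,
        ". An observed category has probability zero in every reachable ",
        "state; floor the initial emission probabilities."
      ))
    }
    trace <- c(trace, st$loglik)
    if (verbose) {
      inform(sprintf("EM iter %d: loglik %.6f", iter - 1, st$loglik))
    }
    if (iter > 1) {
      rel <- abs(st$loglik - trace[iter - 1]) / max(abs(st$loglik), .Machine$double.xmin)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter == max_iter + 1) break
    m <- em_mstep(m, st)
    n_updates <- n_updates + 1
  }

  structure(
    list(model = m, loglik = trace[length(trace)], loglik_trace = trace,
         n_iter = n_updates, converged = converged,
         n_seq = length(obs), n_nodes = n_nodes),
    class = "hsmc_fit"
  )
}

# One E-step over all sequences: total loglik + pooled expected counts.
em_estep <- function(m, obs) {
  lp <- model_logparams(m)
  K <- m$K
  acc <- list(loglik = 0, init = numeric(K),
              trans = matrix(0, K, K + 1), dur = matrix(0, K, m$D_max),
              fate = matrix(0, K, 3), flower = matrix(0, K, 3))
  for (o in obs) {
    logB <- emission_logprob(m, o$fate, o$flower)
    e <- hsmc_estep_cpp(lp$logpi, lp$logA, lp$logd, logB)
    acc$loglik <- acc$loglik + e$loglik
    if (!is.finite(e$loglik)) next
    acc$init <- acc$init + e$init
    acc$trans <- acc$trans + e$trans
    acc$dur <- acc$dur + e$dur
    for (c in 1:3) {
      selF <- o$fate == c
      selW <- o$flower == c
      if (any(selF)) acc$fate[, c] <- acc$fate[, c] +
          rowSums(e$gamma[, selF, drop = FALSE])
      if (any(selW)) acc$flower[, c] <- acc$flower[, c] +
          rowSums(e$gamma[, selW, drop = FALSE])
    }
  }
  acc
}

em_mstep <- function(m, st) {
  K <- m$K
  if (sum(st$init) > 0) m$pi <- st$init / sum(st$init)
  for (j in seq_len(K)) {
    rs <- sum(st$trans[j, ])
    if (rs > 1e-300) {
      row <- st$trans[j, ] / rs
      row[seq_len(j)] <- 0          # guard against numerical dust
      m$A[j, ] <- row / sum(row)
    }
    ds <- sum(st$dur[j, ])
    if (ds > 1e-300) {
      pmf <- st$dur[j, ] / ds
      pmf[pmf < 1e-12] <- 0
      m$d[j, ] <- pmf / sum(pmf)
    }
    fs <- sum(st$fate[j, ])
    if (fs > 1e-300) {
      m$b[[j]]$fate <- setNames(st$fate[j, ] / fs, FATE_LEVELS)
      m$b[[j]]$flower <- setNames(st$flower[j, ] / sum(st$flower[j, ]),
                                  FLOWER_LEVELS)
    }
  }
  m
}

#' @export
print.hsmc_fit <- function(x, ...) {
  cat("HSMC fit:", x$n_seq, "shoots,", x$n_nodes, "metamers\n")
  cat(sprintf("  log-likelihood %.4f after %d iteration(s) (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$model)
  invisible(x)
}

#' @export
tidy.hsmc_fit <- function(x, ...) tidy.hsmc_model(x$model, ...)

#' @export
glance.hsmc_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n_seq = x$n_seq, n_nodes = x$n_nodes, K = x$model$K,
    D_max = x$model$D_max
  )
}

#' Fit one HSMC per group of shoots
#'
#' Pools the shoots of each group (by default one model per genotype, over all
#' years and shoot types together) and fits each pool with [hsmc_fit()].
#'
#' @inheritParams hsmc_fit
#' @param group_by Character vector of metadata columns defining the pools
#'   (default `"genotype"`).
#' @return A tibble with the grouping columns and a list-column `fit` of
#'   `hsmc_fit` objects.
#' @export
hsmc_fit_by <- function(seqs, group_by = "genotype", K = 3, D_max = 30,
                        tol = 1e-6, max_iter = 500, verbose = FALSE) {
  bad <- setdiff(group_by, names(seqs))
  if (length(bad) > 0) {
    abort(paste0("Unknown grouping column(s): ", paste(bad, collapse = ", ")))
  }
  seqs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      hsmc_fit(d, K = K, D_max = D_max, tol = tol, max_iter = max_iter,
               verbose = verbose)
    })) |>
    dplyr::select(-"data")
}
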