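#' Construct a left-right hidden semi-Markov chain model
#'
#' The model has `K` transient states ordered base to tip plus an implicit
#' absorbing end state (column `K + 1` of the transition matrix). Each
#' transient state carries an explicit occupancy distribution over zone
#' lengths in metamers and a pair of categorical emission distributions, one
#' for the central bud fate (`L`, `V`, `F`) and one for the associated
#' flower-bud class (`0`, `1`, `2+`); the two observed variables are
#' conditionally independent given the state. The end state has no emissions
#' and no occupancy: a sequence ends exactly when the chain jumps to it, so
#' the final zone's length is fully observed.
#'
#' @param pi Numeric vector of `K` initial probabilities over transient states.
#' @param A Numeric `K x (K + 1)` transition matrix; row `j` gives transition
#'   probabilities from state `j` to strictly later transient states and, in
#'   the last column, to the end state. Entries at or below the diagonal must
#'   be zero (left-right: each state visited at most once).
#' @param d Numeric `K x D_max` matrix; row `j` is the occupancy pmf of state
#'   `j` over durations `1..D_max`.
#' @param b List of `K` elements, each `list(fate = , flower = )` with named
#'   probability vectors over `c("L","V","F")` and `c("0","1","2+")`.
#' @return A validated object of class `hsmc_model`.
#' @seealso [validate_hsmc()], [hsmc_loglik()], [simulate_shoots()], [hsmc_fit()]
#' @export
hsmc_model <- function(pi, A, d, b) {
  m <- structure(
    list(K = length(pi), D_max = ncol(d),
         pi = as.numeric(pi), A = unname(as.matrix(A)),
         d = unname(as.matrix(d)), b = b),
    class = "hsmc_model"
  )
  validate_hsmc(m)
}

check_simplex <- function(p, what, tol = 1e-9) {
  if (anyNA(p) || any(p < 0)) {
    abort(paste0("Negative or missing probability in ", what, "."))
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    abort(paste0(what, " sums to ", format(s), ", not 1."))
  }
  p / s
}

#' Validate an HSMC model
#'
#' Checks simplex constraints on initial, transition, occupancy and emission
#' probabilities and the strict upper-triangular (left-right) structure of the
#' transition matrix. Rows within `1e-9` of summing to one are renormalized;
#' anything further off is rejected with an error naming the parameter.
#'
#' @param m An `hsmc_model`.
#' @return The validated (possibly renormalized) model.
#' @export
validate_hsmc <- function(m) {
  K <- m$K
  if (K < 1) abort("Model needs at least one transient state.")
  if (!is.matrix(m$A) || nrow(m$A) != K || ncol(m$A) != K + 1) {
    abort("Transition matrix `A` must be K x (K + 1).")
  }
  if (!is.matrix(m$d) || nrow(m$d) != K) {
    abort("Occupancy matrix `d` must have K rows.")
  }
  if (length(m$b) != K) abort("Emission list `b` must have K elements.")

  m$pi <- check_simplex(m$pi, "initial probabilities `pi`")
  for (j in seq_len(K)) {
    if (any(m$A[j, seq_len(j)] != 0)) {
      abort(paste0("Left-right violation: A[", j,
                   ", i <= ", j, "] must be exactly 0."))
    }
    m$A[j, ] <- check_simplex(m$A[j, ], paste0("transition row A[", j, ", ]"))
    m$d[j, ] <- check_simplex(m$d[j, ], paste0("occupancy pmf d[", j, ", ]"),
                              tol = 1e-9)
    bf <- m$b[[j]]$fate
    bw <- m$b[[j]]$flower
    if (!identical(names(bf), FATE_LEVELS)) {
      abort(paste0("b[[", j, "]]$fate must be named ",
                   paste(FATE_LEVELS, collapse = ",")))
    }
    if (!identical(names(bw), FLOWER_LEVELS)) {
      abort(paste0("b[[", j, "]]$flower must be named ",
                   paste(FLOWER_LEVELS, collapse = ",")))
    }
    m$b[[j]]$fate <- check_simplex(bf, paste0("emission pmf b[[", j, "]]$fate"))
    m$b[[j]]$flower <- check_simplex(bw, paste0("emission pmf b[[", j, "]]$flower"))
  }
  m
}

#' @export
print.hsmc_model <- function(x, ...) {
  cat("Left-right hidden semi-Markov chain\n")
  cat("  transient states:", x$K, " (+ absorbing end state)\n")
  cat("  max zone length (D_max):", x$D_max, "metamers\n")
  occ <- vapply(seq_len(x$K), function(j) sum(x$d[j, ] * seq_len(x$D_max)), 0)
  cat("  mean occupancy:", paste(sprintf("%.2f", occ), collapse = ", "), "\n")
  fates <- vapply(x$b, function(e) names(which.max(e$fate)), "")
  cat("  dominant fates:", paste(fates, collapse = ", "), "\n")
  invisible(x)
}

# K x T matrix of per-node emission log-probabilities for integer-coded
# observations (fate in 1..3, flower in 1..3).
emission_logprob <- function(m, fate, flower) {
  lf <- log(vapply(m$b, function(e) e$fate, numeric(3)))     # 3 x K
  lw <- log(vapply(m$b, function(e) e$flower, numeric(3)))
  t(lf[fate, , drop = FALSE] + lw[flower, , drop = FALSE])   # K x T
}

model_logparams <- function(m) {
  list(logpi = log(m$pi), logA = log(m$A), logd = log(m$d))
}

#' Exact log-likelihood of shoot sequences under an HSMC
#'
#' Computes, per shoot, the natural-log probability of the observed bivariate
#' sequence by a forward recursion summing over every admissible segmentation
#' into zones, under the convention that the final zone ends exactly at the
#' last node and is followed by the jump to the absorbing end state.
#' Arithmetic is in log space, so probabilities of zero yield `-Inf` rather
#' than underflow or an error.
#'
#' @param seqs A `shoot_sequences` tibble.
#' @param m A validated `hsmc_model`.
#' @return A tibble with one row per shoot: `shoot_id`, `n_metamers`,
#'   `loglik`.
#' @export
hsmc_loglik <- function(seqs, m) {
  lp <- model_logparams(m)
  shoots <- split_shoots(seqs)
  ll <- vapply(shoots, function(s) {
    hsmc_forward_cpp(lp$logpi, lp$logA, lp$logd,
                     emission_logprob(m, s$fate, s$flower))
  }, 0)
  tibble::tibble(
    shoot_id = vapply(shoots, `[[`, "", "shoot_id"),
    n_metamers = vapply(shoots, function(s) length(s$fate), 0L),
    loglik = unname(ll)
  )
}

#' Simulate shoots from an HSMC
#'
#' Draws an initial state from `pi`, then repeatedly draws a zone length from
#' the state's occupancy distribution, emits that many (bud fate,
#' flower class) pairs i.i.d. from the state's emission distributions, and
#' draws the next state from the transition row until the end state is drawn.
#' The simulated sequence length is the sum of zone lengths. Reproducible for
#' a fixed seed set before the call (no global state is touched beyond R's
#' RNG stream).
#'
#' @param m A validated `hsmc_model`.
#' @param n Number of shoots to simulate.
#' @param genotype,year Metadata labels stamped on every simulated shoot.
#' @param shoot_id_prefix Prefix for generated shoot identifiers.
#' @return A list with `sequences` (a `shoot_sequences` tibble, without
#'   `length_cm`) and `truth` (the generating segmentation per shoot:
#'   `shoot_id`, `state`, `zone`, `start_rank`, `length`).
#' @export
simulate_shoots <- function(m, n, genotype = "sim", year = "Y1",
                            shoot_id_prefix = genotype) {
  K <- m$K
  rows <- vector("list", n)
  truth <- vector("list", n)
  zone_of <- zone_mapping(m, strict = FALSE)
  for (i in seq_len(n)) {
    st <- sample.int(K, 1, prob = m$pi)
    states <- integer(0); lens <- integer(0)
    fates <- character(0); flws <- character(0)
    repeat {
      u <- sample.int(m$D_max, 1, prob = m$d[st, ])
      states <- c(states, st); lens <- c(lens, u)
      fates <- c(fates, sample(FATE_LEVELS, u, replace = TRUE,
                               prob = m$b[[st]]$fate))
      flws <- c(flws, sample(FLOWER_LEVELS, u, replace = TRUE,
                             prob = m$b[[st]]$flower))
      nxt <- sample.int(K + 1, 1, prob = m$A[st, ])
      if (nxt == K + 1) break
      st <- nxt
    }
    Ti <- sum(lens)
    sid <- sprintf("%s_%04d", shoot_id_prefix, i)
    rows[[i]] <- tibble::tibble(
      shoot_id = sid, genotype = genotype, year = year,
      node_rank = seq_len(Ti), bud_fate = fates, assoc_flowers = flws
    )
    truth[[i]] <- tibble::tibble(
      shoot_id = sid, state = states,
      zone = unname(zone_of[states]),
      start_rank = cumsum(c(1L, utils::head(lens, -1))),
      length = lens
    )
  }
  seqs <- dplyr::bind_rows(rows)
  seqs$length_cm <- NA_real_
  seqs$fruit_count <- NA_integer_
  class(seqs) <- c("shoot_sequences", class(tibble::tibble()))
  list(sequences = seqs, truth = dplyr::bind_rows(truth))
}

#' Write / read an HSMC model as JSON
#'
#' The document stores `K`, `D_max`, `pi`, `A` (dense `K x (K+1)`), `d` (list
#' of occupancy pmfs) and `b` (per-state fate/flower pmfs) at full double
#' precision, so the round trip is exact.
#'
#' @param m An `hsmc_model`.
#' @param path JSON file path.
#' @return `write_hsmc()` returns `m` invisibly; `read_hsmc()` the model.
#' @export
write_hsmc <- function(m, path) {
  doc <- list(
    K = m$K, D_max = m$D_max, pi = m$pi,
    A = apply(m$A, 1, identity, simplify = FALSE),
    d = apply(m$d, 1, identity, simplify = FALSE),
    b = lapply(m$b, function(e) list(fate = as.list(e$fate),
                                     flower = as.list(e$flower)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(m)
}

#' @rdname write_hsmc
#' @export
read_hsmc <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  K <- doc$K
  A <- do.call(rbind, lapply(doc$A, function(r) as.numeric(unlist(r))))
  d <- do.call(rbind, lapply(doc$d, function(r) as.numeric(unlist(r))))
  b <- lapply(doc$b, function(e) list(
    fate = setNames(as.numeric(unlist(e$fate)), names(e$fate)),
    flower = setNames(as.numeric(unlist(e$flower)), names(e$flower))
  ))
  hsmc_model(pi = as.numeric(unlist(doc$pi)), A = A, d = d, b = b)
}

#' @export
tidy.hsmc_model <- function(x, ...) {
  K <- x$K
  rows <- list(
    tibble::tibble(term = "initial", state = seq_len(K), category = NA_character_,
                   estimate = x$pi),
    tibble::tibble(
      term = "transition",
      state = rep(seq_len(K), each = K + 1),
      category = rep(c(as.character(seq_len(K)), "end"), K),
      estimate = as.vector(t(x$A))
    ),
    tibble::tibble(
      term = "occupancy",
      state = rep(seq_len(K), each = x$D_max),
      category = rep(as.character(seq_len(x$D_max)), K),
      estimate = as.vector(t(x$d))
    ),
    dplyr::bind_rows(lapply(seq_len(K), function(j) tibble::tibble(
      term = rep(c("fate", "flower"), each = 3),
      state = j,
      category = c(FATE_LEVELS, FLOWER_LEVELS),
      estimate = c(x$b[[j]]$fate, x$b[[j]]$flower)
    )))
  )
  dplyr::bind_rows(rows)
}

#' Mean zone length implied by each state's occupancy distribution
#' @param m An `hsmc_model`.
#' @return Numeric vector of length `K`, in metamers.
#' @export
occupancy_means <- function(m) {
  as.numeric(m$d %*% seq_len(m$D_max))
}

# Probability that each transient state is ever visited, from pi and A.
# With a left-right topology this is a single forward pass.
visit_probabilities <- function(m) {
  v <- m$pi
  for (j in seq_len(m$K)) {
    later <- seq_len(m$K)[-seq_len(j)]
    if (length(later) > 0) v[later] <- v[later] + v[j] * m$A[j, later]
  }
  v
}

#' Expected shoot length (metamers) under the model
#' @param m An `hsmc_model`.
#' @return Expected number of metamers: sum over states of
#'   P(state visited) times its mean occupancy.
#' @export
expected_shoot_length <- function(m) {
  sum(visit_probabilities(m) * occupancy_means(m))
}
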