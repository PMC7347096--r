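# Brute-force enumeration oracles, independent of the package's recursions.
# A path is (states j1 < ... < jR, durations u1..uR with sum T); its
# probability is pi[j1] * prod(d, emissions, transitions) * A[jR, end].

rdirich <- function(n) { x <- rexp(n) + 1e-3; x / sum(x) }

random_model <- function(K, D_max) {
  A <- matrix(0, K, K + 1)
  for (j in seq_len(K)) {
    allowed <- c(seq_len(K)[-seq_len(j)], K + 1)
    A[j, allowed] <- rdirich(length(allowed))
  }
  d <- t(vapply(seq_len(K), function(j) rdirich(D_max), numeric(D_max)))
  b <- lapply(seq_len(K), function(j) list(
    fate = setNames(rdirich(3), c("L", "V", "F")),
    flower = setNames(rdirich(3), c("0", "1", "2+"))
  ))
  hsmc_model(pi = rdirich(K), A = A, d = d, b = b)
}

random_obs <- function(T_len) {
  list(fate = sample(c("L", "V", "F"), T_len, replace = TRUE),
       flower = sample(c("0", "1", "2+"), T_len, replace = TRUE))
}

obs_to_seqs <- function(obs, shoot_id = "s1") {
  tb <- tibble::tibble(
    shoot_id = shoot_id, genotype = "g", year = "Y1",
    node_rank = seq_along(obs$fate), bud_fate = obs$fate,
    assoc_flowers = obs$flower
  )
  if (length(obs$fate) >= 2) return(as_shoot_sequences(tb))
  # the numeric core accepts single-node sequences even though observed data
  # files require >= 2 metamers; bypass file-level validation here
  tb$length_cm <- NA_real_
  tb$fruit_count <- NA_integer_
  class(tb) <- c("shoot_sequences", class(tibble::tibble()))
  tb
}

# all compositions of T into R positive parts each <= D_max
compositions <- function(T_len, R, D_max) {
  if (R == 1) {
    if (T_len >= 1 && T_len <= D_max) return(list(T_len)) else return(list())
  }
  out <- list()
  for (u in seq_len(min(T_len - R + 1, D_max))) {
    for (rest in compositions(T_len - u, R - 1, D_max)) {
      out[[length(out) + 1]] <- c(u, rest)
    }
  }
  out
}

enumerate_paths <- function(m, T_len) {
  K <- m$K
  paths <- list()
  for (R in seq_len(min(K, T_len))) {
    for (states in utils::combn(K, R, simplify = FALSE)) {
      for (durs in compositions(T_len, R, m$D_max)) {
        paths[[length(paths) + 1]] <- list(states = states, durs = durs)
      }
    }
  }
  paths
}

path_prob <- function(m, path, obs) {
  fate_i <- match(obs$fate, c("L", "V", "F"))
  flw_i <- match(obs$flower, c("0", "1", "2+"))
  p <- m$pi[path$states[1]]
  pos <- 1
  for (r in seq_along(path$states)) {
    j <- path$states[r]
    u <- path$durs[r]
    p <- p * m$d[j, u]
    for (t in pos:(pos + u - 1)) {
      p <- p * m$b[[j]]$fate[fate_i[t]] * m$b[[j]]$flower[flw_i[t]]
    }
    pos <- pos + u
    p <- p * if (r < length(path$states)) m$A[j, path$states[r + 1]] else
      m$A[j, m$K + 1]
  }
  unname(p)
}

oracle_lik <- function(m, obs) {
  T_len <- length(obs$fate)
  sum(vapply(enumerate_paths(m, T_len), path_prob, 0, m = m, obs = obs))
}

oracle_best <- function(m, obs) {
  T_len <- length(obs$fate)
  paths <- enumerate_paths(m, T_len)
  if (length(paths) == 0) return(list(prob = 0, path = NULL))
  probs <- vapply(paths, path_prob, 0, m = m, obs = obs)
  list(prob = max(probs), path = paths[[which.max(probs)]])
}

# all observation sequences of length T over the 9 (fate, flower) pairs
all_obs <- function(T_len) {
  pairs <- expand.grid(fate = c("L", "V", "F"), flower = c("0", "1", "2+"),
                       stringsAsFactors = FALSE)
  idx <- expand.grid(rep(list(seq_len(9)), T_len))
  lapply(seq_len(nrow(idx)), function(i) {
    sel <- as.integer(idx[i, ])
    list(fate = pairs$fate[sel], flower = pairs$flower[sel])
  })
}

# deterministic single-state model: point-mass duration, delta emissions
delta_model <- function(dur = 4, D_max = 6) {
  d <- matrix(0, 1, D_max); d[1, dur] <- 1
  hsmc_model(
    pi = 1, A = matrix(c(0, 1), 1, 2), d = d,
    b = list(list(fate = setNames(c(1, 0, 0), c("L", "V", "F")),
                  flower = setNames(c(1, 0, 0), c("0", "1", "2+"))))
  )
}

# 3-state model with deterministic, state-unique emissions (L / F / V)
identifiable_model <- function(D_max = 8) {
  deltaf <- function(i) { v <- c(0, 0, 0); v[i] <- 1; v }
  d <- rbind(rdirich(D_max), rdirich(D_max), rdirich(D_max))
  hsmc_model(
    pi = c(1, 0, 0),
    A = rbind(c(0, 0.7, 0.2, 0.1), c(0, 0, 0.7, 0.3), c(0, 0, 0, 1)),
    d = d,
    b = list(
      list(fate = setNames(deltaf(1), c("L", "V", "F")),
           flower = setNames(c(1, 0, 0), c("0", "1", "2+"))),
      list(fate = setNames(deltaf(3), c("L", "V", "F")),
           flower = setNames(c(0.6, 0.3, 0.1), c("0", "1", "2+"))),
      list(fate = setNames(deltaf(2), c("L", "V", "F")),
           flower = setNames(c(0.9, 0.1, 0), c("0", "1", "2+")))
    )
  )
}

make_seq_tbl <- function(fates, flowers = NULL, shoot_id = "s1",
                         genotype = "g", year = "Y1") {
  if (is.null(flowers)) flowers <- rep("0", length(fates))
  tibble::tibble(
    shoot_id = shoot_id, genotype = genotype, year = year,
    node_rank = seq_along(fates), bud_fate = fates, assoc_flowers = flowers
  )
}
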