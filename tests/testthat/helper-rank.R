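# From-scratch textbook rank statistics, used as oracles for the statistics
# layer (independent of stats:: implementations).

hand_kw <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

hand_wmw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- U - mu
  z <- z - sign(z) * 0.5                        # continuity correction
  z <- z / sqrt(sigma2)
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
}

hand_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a letter display is valid iff letters separate exactly the significant pairs
letters_valid <- function(lab, P, alpha = 0.05) {
  g <- length(lab)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (j <= i || is.na(P[i, j])) next
      share <- length(intersect(strsplit(lab[i], "")[[1]],
                                strsplit(lab[j], "")[[1]])) > 0
      if (P[i, j] < alpha && share) return(FALSE)
      if (P[i, j] >= alpha && !share) return(FALSE)
    }
  }
  TRUE
}
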