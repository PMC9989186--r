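# Independent brute-force oracles, deliberately written in plain loops and
# kept separate from the package implementation.

# abridged life table evaluated straight from the defining formulas
oracle_life_table <- function(P, d, a = 0.5, split = 0.2, radix = 1e5) {
  K <- length(P)
  m <- numeric(K); q <- numeric(K)
  for (k in seq_len(K)) {
    m[k] <- d[k] / P[k]
    q[k] <- m[k] / (1 + a * m[k])
  }
  l <- numeric(K)
  l[1] <- radix
  if (K > 1) for (k in 2:K) l[k] <- (1 - q[k - 1]) * l[k - 1]
  L <- numeric(K)
  if (K == 1) {
    L[1] <- l[1] / m[1]
  } else {
    L[1] <- split * l[1] + (1 - split) * l[2]
    if (K > 2) for (k in 2:(K - 1)) L[k] <- (l[k] + l[k + 1]) / 2
    L[K] <- l[K] / m[K]
  }
  T <- numeric(K)
  for (k in K:1) T[k] <- L[k] + if (k < K) T[k + 1] else 0
  list(m = m, q = q, l = l, L = L, T = T, e = T / l)
}

# quartiles by explicit linear interpolation between order statistics
oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# survival of the Gompertz-Makeham + first-year-excess hazard on a fine grid
oracle_gm_e0 <- function(lambda, alpha, beta, excess, t_max = 60, dt = 1e-3) {
  t <- seq(0, t_max, by = dt)
  H <- lambda * t + (if (beta > 0) alpha / beta * (exp(beta * t) - 1)
                     else alpha * t) + excess * pmin(t, 1)
  S <- exp(-H)
  sum((S[-1] + S[-length(S)]) / 2) * dt
}

# small hand-built visit-record table; each row spec: list(id, visits=dates,
# birth, death, sex, bcs (vector recycled over visits), species, breed)
make_records <- function(pets) {
  rows <- lapply(pets, function(p) {
    visits <- as.Date(p$visits)
    data.frame(
      pet_id = p$id,
      species = p$species %||% "dog",
      breed = p$breed %||% "beagle",
      sex = p$sex %||% "female",
      birth_date = as.Date(p$birth %||% NA),
      death_date = as.Date(p$death %||% NA),
      visit_date = visits,
      bodyweight_kg = p$bw %||% 10,
      bcs_value = rep(p$bcs %||% 3L, length.out = length(visits)),
      bcs_scale = p$scale %||% 5L)
  })
  visit_records(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
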