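# Monte-Carlo binomial confidence intervals for life expectancy.
#
# Deaths are resampled as d*(x) ~ Binomial(P(x), d(x)/P(x)) independently
# per interval, the life table is rebuilt for each draw, and the 95% CI for
# e(x) is mean(e*) +/- z * sd(e*) over the iterations. A draw with zero
# deaths in the terminal interval would leave L(terminal) undefined; that
# interval is redrawn (rejection) and the number of rejections is recorded.

#' Monte-Carlo configuration
#'
#' @param n_iter number of iterations (>= 2); default 1e5, which is enough
#'   to stabilise the CI bounds to the 2 displayed decimals for populations
#'   of the size studied here (escalate to 1e6 for publication-grade runs).
#' @param seed optional RNG seed for reproducibility.
#' @param z critical value for the normal CI, default 1.96.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_iter = 1e5, seed = NULL, z = 1.96) {
  stopifnot(n_iter >= 2, z > 0)
  structure(list(n_iter = as.integer(n_iter), seed = seed, z = z),
            class = "mc_config")
}

#' Resample interval deaths from their binomial model
#'
#' P is unchanged; each d*(x) is an independent Binomial(P(x), d(x)/P(x))
#' draw using the current RNG state.
#'
#' @param counts `counts_vector`.
#' @return `counts_vector` with resampled deaths.
#' @export
resample_deaths <- function(counts) {
  P <- counts$P
  d_star <- rbinom(length(P), size = P, prob = counts$d / P)
  counts_vector(P, d_star, terminal_age = attr(counts, "terminal_age"))
}

# vectorised life-expectancy evaluation: D is an (iterations x K) matrix of
# death draws against a fixed P; returns the (iterations x K) matrix of e(x)
e_matrix <- function(D, P, config) {
  K <- length(P)
  m <- sweep(D, 2L, P, "/")
  q <- m / (1 + config$a * m)
  l <- matrix(0, nrow(D), K)
  l[, 1] <- config$radix
  if (K > 1L) for (k in 2:K) l[, k] <- l[, k - 1L] * (1 - q[, k - 1L])
  L <- matrix(0, nrow(D), K)
  s <- config$first_year_split
  if (K == 1L) {
    L[, 1] <- l[, 1] / m[, 1]
  } else {
    L[, 1] <- s * l[, 1] + (1 - s) * l[, 2]
    if (K > 2L) L[, 2:(K - 1L)] <- (l[, 2:(K - 1L)] + l[, 3:K]) / 2
    L[, K] <- l[, K] / m[, K]
  }
  TT <- L
  if (K > 1L) for (k in (K - 1L):1L) TT[, k] <- TT[, k] + TT[, k + 1L]
  TT / l
}

#' Monte-Carlo confidence intervals for e(x)
#'
#' @param counts observed `counts_vector`; the terminal interval must have
#'   at least one death.
#' @param config `mc_config`.
#' @param lt_config `lifetable_config` used inside each iteration.
#' @return object of class `ci_result`: data.table with columns
#'   `age_interval`, `mean_e`, `sd_e`, `ci_low`, `ci_high`; attributes
#'   `n_iter` and `n_rejected` (terminal redraws).
#' @export
monte_carlo_ci <- function(counts, config = mc_config(),
                           lt_config = lifetable_config()) {
  if (config$n_iter < 2) stop("n_iter must be at least 2")
  P <- counts$P
  d <- counts$d
  K <- length(P)
  if (d[K] <= 0) stop("terminal interval has zero observed deaths")
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- d / P
  n_iter <- config$n_iter
  chunk <- 20000L
  sum_e <- numeric(K); sumsq_e <- numeric(K); n_rejected <- 0L
  done <- 0L
  while (done < n_iter) {
    nb <- min(chunk, n_iter - done)
    D <- matrix(rbinom(nb * K, size = rep(P, each = nb),
                       prob = rep(p, each = nb)), nrow = nb, ncol = K)
    # terminal interval must keep at least one death: redraw offending rows
    zero <- which(D[, K] == 0L)
    while (length(zero)) {
      n_rejected <- n_rejected + length(zero)
      D[zero, K] <- rbinom(length(zero), size = P[K], prob = p[K])
      zero <- zero[D[zero, K] == 0L]
    }
    E <- e_matrix(D, P, lt_config)
    sum_e <- sum_e + colSums(E)
    sumsq_e <- sumsq_e + colSums(E * E)
    done <- done + nb
  }
  mean_e <- sum_e / n_iter
  sd_e <- sqrt(pmax(0, (sumsq_e - n_iter * mean_e^2) / (n_iter - 1)))
  out <- data.table(age_interval = counts$age_interval,
                    mean_e = mean_e, sd_e = sd_e,
                    ci_low = mean_e - config$z * sd_e,
                    ci_high = mean_e + config$z * sd_e)
  setattr(out, "n_iter", n_iter)
  setattr(out, "n_rejected", n_rejected)
  setattr(out, "class", c("ci_result", class(out)))
  out[]
}

#' Merge Monte-Carlo CIs into a life table
#'
#' @param lt `life_table`.
#' @param ci `ci_result` over the same intervals.
#' @return the life table with `ci_low`/`ci_high` filled.
#' @export
merge_ci <- function(lt, ci) {
  if (!identical(lt$age_interval, ci$age_interval))
    stop("life table and CI result cover different intervals")
  lt <- copy(lt)
  lt[, `:=`(ci_low = ci$ci_low, ci_high = ci$ci_high)]
  lt[]
}
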