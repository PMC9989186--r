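# Sullivan abridged life table over 1-year age intervals with an open
# terminal interval.
#
#   m(x) = d(x) / P(x)                      central death rate
#   q(x) = m(x) / (1 + a(x) m(x))           conditional death probability
#   l(0) = radix;  l(x) = (1 - q(x-1)) l(x-1)
#   L(0) = s l(0) + (1 - s) l(1)            s = first_year_split (0.2)
#   L(x) = (l(x) + l(x+1)) / 2              interior intervals
#   L(w) = l(w) / m(w)                      open terminal interval
#   T(x) = sum_{i >= x} L(i);  e(x) = T(x) / l(x)
#
# a(x) = 0.5 is used inside q(x) for every interval including the first;
# only L(0) carries the separate early-infancy weighting. This asymmetry is
# deliberate and matches the published tables.

#' Life-table configuration
#'
#' @param a fraction of the final year lived by pets dying in an interval
#'   (uniform-deaths assumption), default 0.5.
#' @param first_year_split weight of l(0) in L(0); default 0.2, reflecting
#'   the assumption that 80 percent of first-year deaths occur in the first
#'   months of life.
#' @param radix hypothetical number of births anchoring l(0); default 100000.
#' @return list of class `lifetable_config`.
#' @export
lifetable_config <- function(a = 0.5, first_year_split = 0.2, radix = 1e5) {
  stopifnot(a > 0, a < 1, first_year_split >= 0, first_year_split <= 1,
            radix > 0)
  structure(list(a = a, first_year_split = first_year_split, radix = radix),
            class = "lifetable_config")
}

#' Central death rate m(x) = d(x)/P(x)
#'
#' @param d deaths in the interval.
#' @param P mid-year population of the interval (must be positive).
#' @return numeric central death rate(s).
#' @export
central_death_rate <- function(d, P) {
  if (any(P <= 0))
    stop("empty age interval (P = 0) at position(s): ",
         paste(which(P <= 0), collapse = ", "))
  if (any(d < 0) || any(d > P)) stop("need 0 <= d <= P")
  d / P
}

#' Conditional death probability q(x) = m(x)/(1 + a(x) m(x))
#'
#' @param m central death rate(s), non-negative.
#' @param a fraction of interval lived by decedents, default 0.5.
#' @return numeric probability in \[0, 1\] (equal to 1 in the limit m = 1/a).
#' @export
death_probability <- function(m, a = 0.5) {
  if (any(m < 0)) stop("m must be non-negative")
  pmin(m / (1 + a * m), 1)
}

#' Survivorship column l(x)
#'
#' `l(0) = radix`; `l(x) = (1 - q(x-1)) l(x-1)`. The input `q` covers the
#' closed intervals 0..(w-1); the returned vector has one more element.
#'
#' @param q conditional death probabilities for the closed intervals.
#' @param radix cohort size at age 0.
#' @return numeric vector `l(0), ..., l(w)`.
#' @export
survivorship <- function(q, radix = 1e5) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  radix * cumprod(c(1, 1 - q))
}

#' Pet-years lived per interval L(x)
#'
#' First interval: `first_year_split * l(0) + (1 - split) * l(1)`; interior
#' intervals: midpoint of adjacent l; terminal open interval: `l(w)/m(w)`.
#'
#' @param l survivorship vector `l(0)..l(w)`.
#' @param m_terminal central death rate of the open terminal interval;
#'   must be positive.
#' @param config `lifetable_config`.
#' @return numeric vector `L(0)..L(w)`.
#' @export
person_years <- function(l, m_terminal, config = lifetable_config()) {
  if (m_terminal <= 0)
    stop("terminal interval has zero deaths; L(terminal) = l/m is undefined")
  K <- length(l)
  L <- numeric(K)
  s <- config$first_year_split
  if (K == 1L) {
    L[1] <- l[1] / m_terminal
    return(L)
  }
  L[1] <- s * l[1] + (1 - s) * l[2]
  if (K > 2L) L[2:(K - 1L)] <- (l[2:(K - 1L)] + l[3:K]) / 2
  L[K] <- l[K] / m_terminal
  L
}

#' Build a complete life table from interval counts
#'
#' Computes every column at full floating precision; rounding to the
#' published display precision happens only in [write_life_table()] /
#' [format_life_table()]. Trailing empty intervals (P = 0) are dropped and
#' the last populated interval becomes the open terminal interval, which
#' must contain at least one death.
#'
#' @param counts `counts_vector` (or data.frame with columns
#'   `age_interval`, `P`, `d`).
#' @param config `lifetable_config`.
#' @return object of class `life_table`: data.table with columns
#'   `age_interval`, `P`, `d`, `m`, `q`, `l`, `L`, `T`, `e`, `ci_low`,
#'   `ci_high` (CIs `NA` until filled by [monte_carlo_ci()]).
#' @export
build_life_table <- function(counts, config = lifetable_config()) {
  dt <- as.data.table(counts)[, .(age_interval, P, d)]
  # trailing empty intervals: last populated interval becomes the open one
  populated <- which(dt$P > 0)
  if (!length(populated)) stop("no populated age intervals")
  K <- max(populated)
  if (K < nrow(dt)) {
    dt <- dt[seq_len(K)]
    dt[K, age_interval := sub("-[0-9]+$", "+", age_interval)]
  }
  if (any(dt$P <= 0))
    stop("empty interior age interval (P = 0): ",
         paste(dt$age_interval[dt$P <= 0], collapse = ", "))
  if (dt$d[K] <= 0)
    stop("terminal interval has zero deaths; cannot close the table")
  m <- central_death_rate(dt$d, dt$P)
  q <- death_probability(m, config$a)
  l <- survivorship(if (K > 1L) q[-K] else numeric(0), config$radix)
  L <- person_years(l, m[K], config)
  T <- rev(cumsum(rev(L)))
  e <- T / l
  out <- data.table(age_interval = dt$age_interval, P = dt$P, d = dt$d,
                    m = m, q = q, l = l, L = L, T = T, e = e,
                    ci_low = NA_real_, ci_high = NA_real_)
  setattr(out, "config", config)
  setattr(out, "class", c("life_table", class(out)))
  out[]
}

#' Life expectancy at birth from a life table
#'
#' @param lt `life_table`.
#' @return `e` of the first (0-1) interval.
#' @export
life_expectancy_at_birth <- function(lt) lt$e[1]

#' Round a life table to the published display precision
#'
#' m and q to 4 decimals; l, L, T to integers; e and the CI bounds to 2
#' decimals. P and d are left as counts.
#'
#' @param lt `life_table`.
#' @return plain data.table at display precision.
#' @export
format_life_table <- function(lt) {
  dt <- as.data.table(lt)
  dt[, `:=`(m = round(m, 4), q = round(q, 4),
            l = round(l), L = round(L), T = round(T),
            e = round(e, 2), ci_low = round(ci_low, 2),
            ci_high = round(ci_high, 2))]
  dt[]
}

#' Write a life table to CSV or JSON
#'
#' The CSV mirrors the published column order at display precision; the
#' JSON variant keeps full precision.
#'
#' @param lt `life_table`.
#' @param path output path; extension `.json` selects the JSON writer.
#' @param rounded round the CSV to display precision (default TRUE).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path, rounded = TRUE) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(lt), path, digits = NA, na = "null")
  } else {
    out <- if (rounded) format_life_table(lt) else as.data.table(lt)
    fwrite(out, path)
  }
  invisible(path)
}
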