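# Shared internal helpers: seeded RNG scoping, truncated-normal draws,
# key-value config parsing, stable decile binning, config hashing.

# Evaluate expr under a given seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Inverse-CDF draws from N(mean, sd) truncated to [lower, upper].
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}

# Mean and SD of N(mu, sigma) truncated to [lower, upper] (closed form).
truncnorm_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a)
  pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying normal parameters whose truncation to [lower, upper] has the
# requested mean and SD; the generator calibrates marginals with this so
# published cohort moments are reproduced after truncation.
truncnorm_match <- function(target_mean, target_sd, lower = -Inf,
                            upper = Inf) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1L], exp(par[2L]), lower, upper)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj,
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 2000))
  list(mean = o$par[1L], sd = exp(o$par[2L]))
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  stats::setNames(as.list(vals), keys)
}

# Decile (or g-tile) assignment with stable tie-breaking: ties are broken
# by original row order so the bins always partition the order statistics.
stable_quantile_bins <- function(x, g = 10L) {
  n <- length(x)
  if (n < g) stop("need at least ", g, " observations to form ", g, " bins")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * g / n))
}

# Small stable FNV-1a hash of a character representation; used to stamp a
# run configuration into output files so runs are identifiable.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
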