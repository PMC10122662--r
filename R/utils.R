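# internal helpers shared across modules

# assert a scalar proportion in [0, 1]
check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# seeds handed to sub-generators must stay valid 32-bit integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# mean Poisson deviance (per observation); y log-term vanishes at y = 0
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * mean(term - (y - mu))
}

# Euclidean distances from each row of `a` to each row of `b` (dense, small n)
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

mode_value <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}
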