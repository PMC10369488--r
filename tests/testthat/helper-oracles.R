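# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes from the package
# code: lm()/cor() for the regression quantities, an explicit stack-based
# loop for the polyline simplification.

# textbook OLS slope via R's linear-model fitter
oracle_slope <- function(term, total, idx = seq_along(total)) {
  y <- term[idx] - mean(term[idx])
  x <- total[idx] - mean(total[idx])
  unname(stats::coef(stats::lm(y ~ x))[["x"]])
}

oracle_pearson <- function(term, total, idx = seq_along(total)) {
  stats::cor(term[idx], total[idx])
}

# non-recursive Ramer-Douglas-Peucker with an explicit work stack
oracle_rdp <- function(x, y, eps) {
  n <- length(x)
  keep <- c(1L, n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    span <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- span[1]; j <- span[2]
    if (j - i < 2L) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    mid <- (i + 1L):(j - 1L)
    d <- if (len == 0) {
      sqrt((x[mid] - x[i])^2 + (y[mid] - y[i])^2)
    } else {
      abs(dx * (y[mid] - y[i]) - dy * (x[mid] - x[i])) / len
    }
    k <- mid[which.max(d)]
    if (max(d) > eps) {
      keep <- c(keep, k)
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  sort(unique(keep))
}

# small random complete decomposition: nt terms that sum exactly to the total
random_exact_dataset <- function(seed, m = NULL, nt = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(5:20, 1)
  if (is.null(nt)) nt <- sample(2:50, 1)
  s <- sort(runif(m, 0, 10))
  while (any(diff(s) == 0)) s <- sort(runif(m, 0, 10))
  terms <- matrix(rnorm(m * nt), nrow = m)
  colnames(terms) <- sprintf("intra(a%d)", seq_len(nt))
  reg_dataset(s, rowSums(terms), terms)
}

# noisy sigmoid polyline fixture for the RDP checks
noisy_sigmoid <- function(seed, n = 50, height = 66, noise = 1) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n)
  y <- height / (1 + exp(-(x - 0.5) / 0.1)) + rnorm(n, sd = noise)
  list(x = x, y = y)
}
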