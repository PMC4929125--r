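# Independent oracles used across the suite. Each deliberately takes a
# different route from the package implementation.

# Non-wear oracle: plain epoch-by-epoch scan with explicit state. The package
# uses run-length encoding; this walks single epochs.
oracle_nonwear <- function(x, min_bout = 60, max_interrupt = 2) {
  n <- length(x)
  res <- list()
  i <- 1L
  while (i <= n) {
    if (x[i] != 0) { i <- i + 1L; next }
    last_zero <- i
    interrupts <- 0L
    j <- i + 1L
    while (j <= n) {
      if (x[j] == 0) {
        last_zero <- j
        j <- j + 1L
      } else if (interrupts < max_interrupt && j + 1L <= n && x[j + 1L] == 0) {
        interrupts <- interrupts + 1L   # isolated single nonzero, absorbed
        j <- j + 1L
      } else break
    }
    if (last_zero - i + 1L >= min_bout)
      res[[length(res) + 1L]] <- c(i, last_zero + 1L, interrupts)
    i <- last_zero + 1L
    while (i <= n && x[i] != 0) i <- i + 1L
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      n_interruptions = integer(0)))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1L], end = m[, 2L], n_interruptions = m[, 3L])
}

# random count series with zero-heavy stretches, for property-based search
random_count_series <- function(n, p_zero = 0.8, max_count = 5000) {
  x <- integer(n)
  nz <- stats::runif(n) > p_zero
  x[nz] <- sample.int(max_count, sum(nz), replace = TRUE)
  x
}

# 99th-percentile oracle: direct order-statistic interpolation,
# h = (n - 1) p + 1, q = x(floor(h)) + (h - floor(h)) (x(floor(h)+1) - x(floor(h)))
oracle_quantile <- function(x, p = 0.99) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# normal-equations least squares, for checking lm-based fits
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# small analysis dataset straight from the generative law (no processing)
make_direct_dataset <- function(n = 200, ratio = 0.931, baseline = 12.97,
                                sd_log = 0, seed = 1, n_studies = 2,
                                ages = NULL) {
  set.seed(seed)
  age <- if (is.null(ages)) runif(n, 5, 18) else ages
  n <- length(age)
  vpa <- baseline * ratio^(age - 5) * exp(rnorm(n, 0, sd_log))
  wear <- round(runif(n, 600, 940))   # varies, so the design is full rank
  data.frame(participant_id = sprintf("D%04d", seq_len(n)), age = age,
             vpa_min = vpa, mpa_min = 3 * vpa, wear_min = wear,
             sed_min = 349,
             study_id = rep_len(paste0("S", seq_len(n_studies)), n),
             sex = rep_len(c("male", "female"), n),
             ethnicity = "white", maternal_education = "high school",
             weight_status = "normal", region = "UK")
}
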