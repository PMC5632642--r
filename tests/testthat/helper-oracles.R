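# Independent oracles used to check the package's own implementations.

# Stacked multivariate-normal log-density with an explicitly assembled
# block covariance: V_j = Z_j G Z_j' + sigma^2 * C_j(phi), C_j[s,t] =
# phi^|year_s - year_t|. Independent of the whitening/Woodbury path used by
# the package.
brute_force_loglik <- function(data, fixed, random_slopes, params,
                               method = "ML") {
  d <- data[order(data$tree_id, data$year), ]
  y <- d$y
  X <- cbind(1, as.matrix(d[fixed]))
  Z <- X[, c(1L, match(random_slopes, fixed) + 1L), drop = FALSE]
  G <- diag(params$re_sd^2, length(params$re_sd))
  V <- matrix(0, nrow(d), nrow(d))
  for (tr in unique(d$tree_id)) {
    idx <- which(d$tree_id == tr)
    C <- params$phi^abs(outer(d$year[idx], d$year[idx], "-"))
    V[idx, idx] <- Z[idx, , drop = FALSE] %*% G %*% t(Z[idx, , drop = FALSE]) +
      params$sigma^2 * C
  }
  Vi <- solve(V)
  n <- length(y)
  if (method == "ML") {
    r <- y - X %*% params$beta
    -0.5 * (n * log(2 * pi) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(t(r) %*% Vi %*% r))
  } else {
    XtViX <- t(X) %*% Vi %*% X
    bh <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% bh
    p <- ncol(X)
    -0.5 * ((n - p) * log(2 * pi) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(XtViX)$modulus) +
              as.numeric(t(r) %*% Vi %*% r))
  }
}

# Least-squares circle through the three arc points (-L/2, 0), (L/2, 0),
# (0, h): solve the algebraic (Kasa) system x^2 + y^2 = 2ax + 2by + c.
circle_fit_radius <- function(L, h) {
  x <- c(-L / 2, L / 2, 0)
  y <- c(0, 0, h)
  A <- cbind(2 * x, 2 * y, 1)
  sol <- solve(A, x^2 + y^2)
  sqrt(sol[1]^2 + sol[2]^2 + sol[3])
}

# Random small grouped dataset (with year gaps) plus random parameters, for
# likelihood property tests.
random_small_instance <- function() {
  n_tree <- sample(2:4, 1)
  q_slopes <- sample(0:1, 1)
  rows <- do.call(rbind, lapply(seq_len(n_tree), function(j) {
    n_yr <- sample(3:6, 1)
    yrs <- sort(sample(2000:2009, n_yr))
    data.frame(tree_id = paste0("t", j), year = yrs)
  }))
  rows$x1 <- rnorm(nrow(rows))
  fixed <- "x1"
  random_slopes <- if (q_slopes == 1) "x1" else character()
  params <- list(beta = rnorm(2),
                 re_sd = abs(rnorm(1 + q_slopes, 0, 0.5)),
                 phi = runif(1, -0.8, 0.8),
                 sigma = runif(1, 0.2, 1))
  rows$y <- rnorm(nrow(rows))  # likelihood evaluated at arbitrary data
  list(data = rows, fixed = fixed, random_slopes = random_slopes,
       params = params)
}
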