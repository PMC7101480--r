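# Independent oracles used across the suite.

# True variance of the product of two independent binomial proportions by
# exhaustive enumeration over all (k_x, k_y) outcomes. Feasible for small n;
# independent of the closed-form implementation it checks.
enumeration_product_variance <- function(P_x, n_x, P_y, n_y) {
  kx <- 0:n_x
  ky <- 0:n_y
  px <- kx / n_x
  py <- ky / n_y
  wx <- dbinom(kx, n_x, P_x)
  wy <- dbinom(ky, n_y, P_y)
  prod_vals <- outer(px, py)
  w <- outer(wx, wy)
  mu <- sum(w * prod_vals)
  sum(w * (prod_vals - mu)^2)
}

# Central finite difference of a scalar function, default step 1e-6.
finite_diff <- function(f, x, i, h = 1e-6) {
  xp <- x; xm <- x
  xp[i] <- x[i] + h
  xm[i] <- x[i] - h
  (f(xp) - f(xm)) / (2 * h)
}

# logit of the product of antilogits: the function whose gradient the
# delta-method chain rule supplies at stratum level.
logit_of_product <- function(b) {
  stats::qlogis(stats::plogis(b[1]) * stats::plogis(b[2]))
}

# A small well-formed binary stratum table used by several files.
make_strata <- function() {
  tibble::tibble(
    region_id = rep(c("north", "south"), each = 2),
    facility_type = rep(c("hospital", "clinic"), 2),
    x_successes = c(30, 25, 40, 10),
    n_x = 100,
    readiness_kind = "binary",
    y_successes = c(45, 20, 30, 35),
    n_y = 50,
    y_mean = NA_real_,
    y_var = NA_real_,
    region_weight = rep(c(2, 1), each = 2)
  )
}
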