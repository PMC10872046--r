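# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check.

# check (pinball) loss of a candidate edge q for sample y at level tau
check_loss <- function(y, q, tau) {
  u <- y - q
  sum(u * (tau - (u < 0)))
}

# exhaustive check-loss minimization over a candidate alphabet; returns all
# minimizers (within tolerance), so flat intervals show both endpoints
check_loss_argmin <- function(y, tau, candidates = sort(unique(y))) {
  loss <- vapply(candidates, function(q) check_loss(y, q, tau), numeric(1))
  candidates[loss <= min(loss) + 1e-9]
}

# all nondecreasing samples of length n over alphabet 1..k (multisets)
enumerate_multisets <- function(n, k) {
  if (n == 1) return(lapply(seq_len(k), identity))
  out <- list()
  rec <- function(prefix, lo) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in lo:k) rec(c(prefix, v), v)
  }
  rec(integer(0), 1L)
  out
}

# weighted least squares by direct numerical minimization of the loss
# (BFGS with analytic gradient), independent of lm's QR solution
wls_optim_oracle <- function(X, y, w) {
  fn <- function(b) sum(w * (y - X %*% b)^2)
  gr <- function(b) as.numeric(-2 * t(X) %*% (w * (y - X %*% b)))
  b <- stats::optim(rep(0, ncol(X)), fn, gr, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 1000))$par
  # polish with Newton steps on the analytic gradient (LU solve, a route
  # independent of lm's QR decomposition)
  H <- 2 * t(X) %*% (w * X)
  for (i in 1:5) b <- b - solve(H, gr(b))
  b
}

# small deterministic regression table used across model tests
make_toy_table <- function(n = 60, seed = 42) {
  set.seed(seed)
  data.frame(
    shift_km = stats::rnorm(n, 20, 15),
    weight = stats::runif(n, 0.5, 2),
    Tmean = stats::rnorm(n, 7, 2),
    Tbreadth = stats::runif(n, 1, 4),
    Mmean = stats::rnorm(n, 0.3, 0.05),
    Mbreadth = stats::runif(n, 0.01, 0.08),
    wintering = sample(c("adult", "egg", "larva", "pupa"), n, TRUE),
    n_gen = sample(c("one", "two_plus"), n, TRUE),
    size = stats::rnorm(n, 30, 8),
    range_size = stats::runif(n, 100, 2500),
    stringsAsFactors = FALSE)
}

# covariate table assembled directly from a synthetic species pool: the
# truth's niche parameters become the regression covariates and the true
# shifts the response (unit weights)
truth_to_model_table <- function(truth) {
  data.frame(species_id = truth$species_id,
             shift_km = truth$true_shift_km,
             weight = 1,
             Tmean = truth$mean_MAT, Tbreadth = truth$sd_MAT,
             Mmean = truth$mean_SWC, Mbreadth = truth$sd_SWC,
             wintering = truth$wintering, n_gen = truth$n_gen,
             size = truth$body_size, range_size = truth$range_size,
             stringsAsFactors = FALSE)
}
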