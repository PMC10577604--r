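test_that("rank-sum exact p values match enumeration hand cases", {
  # identical multisets: every arrangement equally extreme
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # complete separation of 3 vs 3: the two extreme arrangements out of 20
  t2 <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t2$p, 0.1)
  expect_equal(t2$method, "exact enumeration")
  # swapping group labels leaves p unchanged (two-sided)
  expect_equal(compare_groups(c(4, 5, 6), c(1, 2, 3))$p, t2$p)
})

test_that("normal-approximation p is close to a permutation oracle", {
  set.seed(15)
  for (rep in 1:3) {
    x <- rnorm(15); y <- rnorm(15, 0.5)
    got <- compare_groups(x, y)
    expect_equal(got$method, "normal approximation (tie-corrected)")
    r <- rank(c(x, y))
    obs <- sum(r[1:15]); EW <- 15 * 31 / 2
    perm <- replicate(1e5, sum(r[sample.int(30, 15)]))
    p_perm <- mean(abs(perm - EW) >= abs(obs - EW) - 1e-9)
    expect_lt(abs(got$p - p_perm), 0.02)
  }
})

test_that("BH adjustment equals the hand step-up rule and brute force", {
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # brute-force max-min definition on all subsets of size <= 8
  set.seed(6)
  p <- round(runif(8), 3)
  adj <- bh_adjust(p)
  n <- length(p)
  o <- order(p)
  brute <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    brute[i] <- min(vapply(rank_i:n, function(j) p[o[j]] * n / j, 0), 1)
  }
  expect_equal(adj, brute)
  # monotone transform: ordering by raw p gives non-decreasing adjusted p
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH is independent of input order", {
  set.seed(61)
  p <- runif(12)
  perm <- sample(12)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("Spearman association is exact for n = 8 against full enumeration", {
  set.seed(19)
  x <- rnorm(8); y <- rnorm(8)
  got <- spearman_assoc(x, y)
  # enumerate all 8! rank assignments
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rx <- rank(x)
  rhos <- vapply(perms(1:8), function(ry) cor(rx, ry), 0)
  obs <- cor(rx, rank(y))
  expect_equal(got$r, obs)
  p_exact <- mean(abs(rhos) >= abs(obs) - 1e-12)
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  # degenerate directions
  expect_equal(spearman_assoc(1:10, 1:10)$r, 1)
  expect_equal(spearman_assoc(1:10, 10:1)$r, -1)
  expect_true(is.na(spearman_assoc(1:10, rep(1, 10))$r))
})

test_that("log-rank statistic agrees with survival::survdiff", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 40
    time <- rexp(n, 0.2); event <- rbinom(n, 1, 0.7)
    g <- rep(1:2, each = n / 2)
    mine <- logrank_test(time, event, g)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank permutation p matches an exhaustive oracle on toy arms", {
  time <- c(1, 2, 3, 10, 20, 30); event <- rep(1L, 6)
  g <- rep(1:2, each = 3)
  got <- logrank_test(time, event, g, p_method = "permutation",
                      n_perm = 20000L, seed = 2L)
  # exhaustive oracle over all 20 label assignments, statistic from survdiff
  combs <- utils::combn(6, 3)
  stats <- apply(combs, 2, function(ix) {
    gg <- rep(2L, 6); gg[ix] <- 1L
    survival::survdiff(survival::Surv(time, event) ~ gg)$chisq
  })
  p_exact <- mean(stats >= got$chisq - 1e-9)
  expect_lt(abs(got$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000) +
              1e-4)
})

test_that("median split builds the documented arms and degenerate KM cases", {
  # cloned arms: log-rank statistic 0, p = 1
  time <- rep(c(1, 2, 3, 4), 2); event <- rep(1L, 8)
  values <- rep(c(0, 1), each = 4)
  km <- median_split_km(values, time, event)
  expect_equal(km$logrank$chisq, 0)
  expect_equal(km$logrank$p, 1)
  expect_equal(as.vector(table(km$arm)), c(4L, 4L))

  # ties go to the low arm
  v <- c(1, 2, 2, 3, 4, 5)
  arm <- median_split_km(v, rexp(6) + 0.1, rep(1L, 6))$arm
  expect_equal(as.character(arm[v <= median(v)]), rep("low", sum(v <= median(v))))
  expect_equal(as.character(arm[v > median(v)]), rep("high", sum(v > median(v))))
  # a value equal to the cut goes low
  arm2 <- median_split_km(c(1, 2, 3, 3, 4, 9), rexp(6) + 0.1, rep(1L, 6))$arm
  expect_equal(sum(arm2 == "low"), 4L)

  expect_error(median_split_km(rep(1, 6), rexp(6), rep(1, 6)), "degenerate")
})

test_that("KM product-limit estimates match hand computation", {
  fit <- survival::survfit(survival::Surv(c(1, 2, 3), rep(1, 3)) ~ 1)
  expect_equal(summary(fit)$surv, c(2 / 3, 1 / 3, 0))
})

test_that("Cox regression is null-calibrated and recovers programmed effects", {
  set.seed(31)
  # null: covariate independent of survival
  coefs <- pvals <- numeric(60)
  for (r in 1:60) {
    n <- 200
    x <- rnorm(n)
    time <- rexp(n, 0.2); event <- rep(1L, n)
    fit <- cox_multivariate(data.frame(x = x), time, event)
    coefs[r] <- fit$table$coef[1]; pvals[r] <- fit$table$p[1]
  }
  expect_true(all(abs(coefs) < 0.3))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # recovery: log-HR -1 on a standardized feature
  hit <- 0
  for (r in 1:60) {
    n <- 200
    x <- rnorm(n)
    time <- rexp(n, 0.2 * exp(-1 * x))
    cens <- time > quantile(time, 0.8)
    event <- as.integer(!cens); time[cens] <- quantile(time, 0.8)
    fit <- cox_multivariate(data.frame(x = x), time, event)
    hit <- hit + as.integer(abs(fit$table$coef[1] + 1) <= 0.3)
  }
  expect_gte(hit / 60, 0.95)
})

test_that("Cox hazard ratio matches the two-sample rate ratio on exponential data", {
  set.seed(37)
  n <- 500
  g <- rep(0:1, each = n / 2)
  rate <- ifelse(g == 1, 0.6, 0.2)
  time <- rexp(n, rate); event <- rep(1L, n)
  fit <- cox_multivariate(data.frame(g = g), time, event)
  expect_equal(fit$table$hr[1], 3, tolerance = 0.1)
  expect_true(fit$converged)
})

test_that("Cox coefficients are equivariant under covariate rescaling", {
  set.seed(41)
  n <- 120
  x <- rnorm(n); time <- rexp(n, 0.3 * exp(-0.8 * x)); event <- rep(1L, n)
  f1 <- cox_multivariate(data.frame(x = x), time, event)
  f2 <- cox_multivariate(data.frame(x = 10 * x), time, event)
  expect_equal(f2$table$coef[1], f1$table$coef[1] / 10, tolerance = 1e-6)
  expect_equal(f2$table$p[1], f1$table$p[1], tolerance = 1e-6)
})

test_that("Cox flags monotone-likelihood separation instead of silent output", {
  time <- c(1, 2, 3, 10, 11, 12); event <- rep(1L, 6)
  x <- c(1, 1, 1, 0, 0, 0)  # perfect separation
  fit <- cox_multivariate(data.frame(x = x), time, event)
  expect_false(fit$converged)
})

test_that("FLIPI enters as ordinal by default and one-hot behind the flag", {
  set.seed(43)
  n <- 60
  fl <- sample(c("low", "intermediate", "high"), n, replace = TRUE)
  x <- rnorm(n); time <- rexp(n, 0.3); event <- rbinom(n, 1, 0.8)
  f1 <- cox_multivariate(data.frame(x = x), time, event, flipi = fl)
  expect_equal(nrow(f1$table), 2L)
  f2 <- cox_multivariate(data.frame(x = x), time, event, flipi = fl,
                         flipi_encoding = "onehot")
  expect_equal(nrow(f2$table), 3L)
})

test_that("association suite bookkeeping: rows, families, BH within family", {
  set.seed(47)
  n <- 24
  dat <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    ttp_years = rexp(n, 0.2) + 0.01,
                    event = rbinom(n, 1, 0.6),
                    flipi = sample(c("low", "intermediate", "high"), n, TRUE))
  for (comp in c("intra", "inter")) {
    dat[[paste0("density_a_", comp)]] <- rlnorm(n)
    dat[[paste0("mh_ab_", comp)]] <- runif(n)
  }
  out <- run_association_suite(dat, c("density_a", "mh_ab"))
  expect_equal(nrow(out), 4L)  # 2 features x 2 compartments
  expect_setequal(out$family, c("density", "colocalization"))
  expect_true(all(out$p_bh >= out$p_raw - 1e-12))
  # a feature with excessive missingness is dropped with a warning
  dat$density_b_intra <- NA_real_
  dat$density_b_inter <- NA_real_
  ws <- capture_warnings(
    out2 <- run_association_suite(dat, c("density_a", "mh_ab", "density_b")))
  expect_true(all(grepl("missing", ws)) && length(ws) == 2L)
  expect_equal(nrow(out2), 4L)
})
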