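test_that("group comparison routes by per-group normality", {
  set.seed(51)
  g <- rep(c("a", "b"), each = 60)
  normal <- c(rnorm(60, 5), rnorm(60, 5.2))
  r <- group_compare(normal, g)
  expect_identical(r$test_used, "t")
  expect_true(r$normal_route)

  skewed <- c(rexp(60), rexp(60, 0.8))^2
  r2 <- group_compare(skewed, g)
  expect_identical(r2$test_used, "mann_whitney")

  g3 <- rep(c("a", "b", "c"), each = 50)
  r3 <- group_compare(rnorm(150), g3)
  expect_identical(r3$test_used, "anova")
  r4 <- group_compare(rexp(150)^2, g3)
  expect_identical(r4$test_used, "kruskal_wallis")

  rc <- group_compare(sample(c("x", "y"), 120, TRUE),
                      sample(c("a", "b"), 120, TRUE))
  expect_identical(rc$test_used, "chi_squared")
})

test_that("routing agrees with direct Shapiro-Wilk calls on random data", {
  set.seed(52)
  for (k in 1:15) {
    g <- rep(c("a", "b"), each = 30)
    x <- if (k %% 2) rnorm(60) else exp(rnorm(60) * 1.5)
    expected_normal <- all(vapply(split(x, g), function(v)
      shapiro.test(v)$p.value > 0.05, logical(1)))
    r <- group_compare(x, g)
    expect_identical(r$test_used,
                     if (expected_normal) "t" else "mann_whitney")
  }
})

test_that("tiny groups force the nonparametric route with a warning", {
  expect_warning(r <- group_compare(c(1, 2, 5, 6, 7, 9), rep(c("a", "b"),
                                                             c(2, 4))),
                 "nonparametric")
  expect_identical(r$test_used, "mann_whitney")
})

test_that("identical groups sit at the null centre of their test", {
  set.seed(50)
  x0 <- rexp(30)^2                       # skewed: nonparametric route
  r <- suppressWarnings(group_compare(c(x0, x0),
                                      rep(c("a", "b"), each = 30)))
  expect_identical(r$test_used, "mann_whitney")
  expect_equal(unname(r$statistic), 30 * 30 / 2)  # U at its null centre
  # normal data, identical groups: t statistic at zero
  y0 <- rnorm(30)
  r2 <- group_compare(c(y0, y0), rep(c("a", "b"), each = 30))
  expect_identical(r2$test_used, "t")
  expect_equal(unname(r2$statistic), 0)
})

test_that("spearman matrix is symmetric with unit diagonal and sane nulls", {
  set.seed(53)
  df <- data.frame(a = rnorm(1000))
  df$b <- exp(df$a)             # strictly monotone
  df$c <- rnorm(1000)           # independent
  m <- spearman_matrix(df)
  expect_equal(m$rho["a", "b"], 1)
  expect_equal(m$p["a", "b"], 0)
  expect_identical(m$rho, t(m$rho))
  expect_equal(diag(m$rho), c(a = 1, b = 1, c = 1))
  expect_lt(abs(m$rho["a", "c"]), 0.1)
  # pairwise-complete observations
  df$c[1:100] <- NA
  m2 <- spearman_matrix(df)
  expect_equal(m2$n["a", "c"], 900)
  expect_equal(m2$n["a", "b"], 1000)
})

test_that("median dichotomization splits strictly above the median", {
  d <- dichotomize(data.frame(v = 1:5))
  expect_equal(sum(d$indicators[["v=high"]]), 2)   # {4, 5}
  expect_equal(sum(d$indicators[["v=low"]]), 3)
  # constant variable rejected with reason
  d2 <- dichotomize(data.frame(k = rep(3, 10)))
  expect_equal(ncol(d2$indicators), 0)
  expect_match(d2$info$reason, "constant")
  # categorical expansion
  d3 <- dichotomize(data.frame(g = c("x", "y", "z", "x")))
  expect_setequal(names(d3$indicators), c("g=x", "g=y", "g=z"))
})

test_that("dichotomization is idempotent", {
  set.seed(54)
  d1 <- dichotomize(data.frame(a = rnorm(40), g = sample(c("u", "v"), 40,
                                                         TRUE)))
  d2 <- dichotomize(d1$indicators)
  expect_identical(d1$indicators, d2$indicators)
})

test_that("the Haberman residual is zero under exact balanced independence", {
  tab <- matrix(25, 2, 2)
  expect_equal(haberman_residual(tab), 0)
})

test_that("residuals equal the explicit-loop formula on random tables", {
  set.seed(55)
  worst <- 0
  for (k in 1:200) {
    tab <- random_cooccurrence_table(n = sample(50:500, 1))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    worst <- max(worst, max(abs(haberman_residuals(tab) -
                                  brute_haberman(tab))))
  }
  expect_lt(worst, 1e-12)
})

test_that("residuals with a zero margin are undefined", {
  tab <- matrix(c(0, 0, 10, 20), 2, 2)   # empty first row
  expect_true(is.na(haberman_residual(tab)))
})

test_that("the null residual is approximately standard normal", {
  set.seed(56)
  d <- vapply(1:2000, function(i)
    haberman_residual(random_cooccurrence_table(400)), numeric(1))
  d <- d[!is.na(d)]
  expect_lt(abs(mean(d)), 0.08)
  expect_lt(abs(sd(d) - 1), 0.08)
})

test_that("a planted perfect co-occurrence yields a network edge", {
  set.seed(57)
  x <- runif(300) < 0.5
  ind <- data.frame(`a=high` = x, `b=high` = x,
                    `c=high` = runif(300) < 0.5, check.names = FALSE)
  g <- build_coincidence_network(ind)
  expect_true("a=high|b=high" %in%
                paste(pmin(g$edges$from, g$edges$to),
                      pmax(g$edges$from, g$edges$to), sep = "|"))
  expect_equal(g$nodes$prevalence[1], mean(x))
})

test_that("the network is invariant under variable reordering", {
  set.seed(58)
  ind <- as.data.frame(matrix(runif(200 * 6) < 0.4, 200, 6))
  ind <- as.data.frame(lapply(ind, as.logical))
  names(ind) <- paste0("v", 1:6)
  ind$v2 <- ind$v1 | (runif(200) < 0.2)          # dependent pair
  g1 <- build_coincidence_network(ind)
  g2 <- build_coincidence_network(ind[, sample(names(ind))])
  key <- function(g) sort(paste(pmin(g$edges$from, g$edges$to),
                                pmax(g$edges$from, g$edges$to)))
  expect_identical(key(g1), key(g2))
})

test_that("adjusted logistic regression recovers a planted coefficient", {
  set.seed(59)
  n <- 3000
  df <- data.frame(age = rnorm(n, 60, 10), metastasis = rbinom(n, 1, 0.4),
                   ecog = sample(0:3, n, TRUE), ldh = rnorm(n, 200, 60),
                   albumin = rnorm(n, 4, 0.5), urea = rnorm(n, 38, 12),
                   m = rnorm(n, 0, 4))
  lp <- -0.2 * df$m + 0.03 * df$age + 0.5 * df$metastasis - 4
  df$deceased <- rbinom(n, 1, plogis(lp))
  df$death_cause <- ifelse(df$deceased == 1, "tumor", NA)
  r <- adjusted_logistic(df, "m", "overall")
  expect_lt(abs(log(r$odds_ratio) - (-0.2)), 0.05)
  expect_true(r$ci_low < r$odds_ratio && r$odds_ratio < r$ci_high)
  expect_identical(r$method, "glm")
})

test_that("tumor-cause models exclude deaths from other causes", {
  set.seed(60)
  n <- 400
  df <- data.frame(age = rnorm(n, 60, 10), metastasis = rbinom(n, 1, 0.4),
                   ecog = sample(0:3, n, TRUE), ldh = rnorm(n, 200, 60),
                   albumin = rnorm(n, 4, 0.5), urea = rnorm(n, 38, 12),
                   m = rnorm(n))
  df$deceased <- rbinom(n, 1, 0.35)
  df$death_cause <- ifelse(df$deceased == 1,
                           sample(c("tumor", "toxicity", "other"),
                                  sum(df$deceased), TRUE), NA)
  r <- suppressWarnings(adjusted_logistic(df, "m", "tumor"))
  # survivors plus tumor-cause deaths only
  expect_equal(r$n, sum(df$deceased == 0) +
                 sum(df$death_cause == "tumor", na.rm = TRUE))
  expect_equal(r$events, sum(df$death_cause == "tumor", na.rm = TRUE))
})

test_that("Firth fallback gives finite estimates under perfect separation", {
  set.seed(61)
  n <- 80
  df <- data.frame(age = rnorm(n, 60, 10), metastasis = rbinom(n, 1, 0.4),
                   ecog = sample(0:3, n, TRUE), ldh = rnorm(n, 200, 60),
                   albumin = rnorm(n, 4, 0.5), urea = rnorm(n, 38, 12),
                   m = c(rnorm(40, -3), rnorm(40, 3)))
  df$deceased <- as.integer(df$m > 0)            # perfectly separated
  df$death_cause <- ifelse(df$deceased == 1, "tumor", NA)
  r <- suppressWarnings(adjusted_logistic(df, "m", "overall"))
  expect_identical(r$method, "firth")
  expect_true(is.finite(r$odds_ratio) && is.finite(r$ci_high))
})

test_that("Firth estimates agree with glm away from separation", {
  set.seed(62)
  n <- 2000
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(X %*% c(-0.5, 0.8, -0.3)))
  ff <- firth_logistic(X, y)
  gg <- glm(y ~ X[, 2] + X[, 3], family = binomial())
  expect_equal(unname(ff$coef), unname(coef(gg)), tolerance = 0.02)
  expect_true(ff$converged)
})
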