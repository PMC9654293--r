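#' Normality-routed group comparison
#'
#' Continuous variables are tested for normality per group (Shapiro-Wilk at
#' alpha 0.05); if every group is compatible with normality the comparison
#' uses a t-test (two groups) or one-way ANOVA (more), otherwise
#' Mann-Whitney U or Kruskal-Wallis. Categorical variables are compared
#' with a chi-squared test. Groups with fewer than three values force the
#' nonparametric route with a warning (Shapiro-Wilk is undefined there).
#'
#' @param values numeric vector (continuous) or factor/character
#'   (categorical).
#' @param groups grouping vector (>= 2 levels after dropping missings).
#' @param shapiro_alpha normality-rejection level.
#' @return list of class `group_test`: `test_used`, `statistic`, `p_value`,
#'   `summaries` (per-group mean/SD or counts/%), `normal_route`.
#' @export
group_compare <- function(values, groups, shapiro_alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)

  if (!is.numeric(values)) {
    tab <- table(values, groups)
    ct <- suppressWarnings(stats::chisq.test(tab))
    summaries <- as.data.frame.matrix(tab)
    return(structure(list(test_used = "chi_squared",
                          statistic = unname(ct$statistic),
                          p_value = ct$p.value, summaries = summaries,
                          normal_route = NA),
                     class = "group_test"))
  }

  by_group <- split(values, groups)
  sizes <- lengths(by_group)
  small <- sizes < 3
  if (any(small)) {
    warning("group(s) with < 3 values: nonparametric route forced",
            call. = FALSE)
    normal <- FALSE
  } else {
    # sd 0 within a group also rejects the parametric route
    normal <- all(vapply(by_group, function(g) {
      if (stats::sd(g) == 0) return(FALSE)
      stats::shapiro.test(g)$p.value > shapiro_alpha
    }, logical(1)))
  }

  if (normal) {
    if (nlevels(groups) == 2) {
      tt <- stats::t.test(values ~ groups)
      res <- list(test_used = "t", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      av <- stats::anova(stats::aov(values ~ groups))
      res <- list(test_used = "anova", statistic = av$`F value`[1],
                  p_value = av$`Pr(>F)`[1])
    }
  } else {
    if (nlevels(groups) == 2) {
      wt <- suppressWarnings(stats::wilcox.test(values ~ groups))
      res <- list(test_used = "mann_whitney",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      kw <- stats::kruskal.test(values, groups)
      res <- list(test_used = "kruskal_wallis",
                  statistic = unname(kw$statistic), p_value = kw$p.value)
    }
  }
  res$summaries <- data.frame(
    group = names(by_group), n = as.integer(sizes),
    mean = vapply(by_group, mean, numeric(1)),
    sd = vapply(by_group, stats::sd, numeric(1)))
  res$normal_route <- normal
  structure(res, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  invisible(x)
}

#' Group-comparison table over many variables
#'
#' Applies [group_compare()] to each variable against one grouping column,
#' yielding a survivors-versus-non-survivors style summary table.
#'
#' @param data data.frame.
#' @param variables character vector of columns to test.
#' @param group grouping column name.
#' @return data.frame: variable, test_used, statistic, p_value and
#'   per-group mean (SD) strings.
#' @export
group_compare_table <- function(data, variables, group) {
  rows <- lapply(variables, function(v) {
    res <- tryCatch(suppressWarnings(group_compare(data[[v]], data[[group]])),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, test_used = NA, statistic = NA,
                        p_value = NA, summary = NA))
    smry <- if (res$test_used == "chi_squared") {
      paste(utils::capture.output(print(res$summaries))[-1], collapse = "; ")
    } else {
      paste(sprintf("%s: %.2f (%.2f)", res$summaries$group,
                    res$summaries$mean, res$summaries$sd), collapse = "; ")
    }
    data.frame(variable = v, test_used = res$test_used,
               statistic = res$statistic, p_value = res$p_value,
               summary = smry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise-complete Spearman's rho between all numeric columns, with
#' p-values from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param data data.frame of continuous variables.
#' @return list of class `spearman_matrix` with matrices `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  v <- names(num); k <- length(v)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(v, v))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3) next
    r <- stats::cor(num[[i]][ok], num[[j]][ok], method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    pv <- if (i == j || abs(r) == 1) {
      if (i == j) NA_real_ else 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    p[i, j] <- p[j, i] <- pv
  }
  diag(rho) <- 1
  structure(list(rho = rho, p = p, n = nmat), class = "spearman_matrix")
}

#' Median dichotomization into category indicators
#'
#' Continuous variables are split at their median (value strictly greater
#' than the median is "high"); both levels become logical indicator
#' columns. Categorical variables are expanded into one indicator per
#' level. Logical columns are taken as already-dichotomized indicators and
#' pass through unchanged, so the operation is idempotent. Constant
#' variables are rejected with a reason.
#'
#' @param data data.frame.
#' @return list of class `dichotomized`: `indicators` (logical data.frame,
#'   columns named `var=level`), `info` (per-variable decisions: cutpoint
#'   or rejection reason).
#' @export
dichotomize <- function(data) {
  ind <- list(); info <- list()
  for (v in names(data)) {
    col <- data[[v]]
    if (is.logical(col)) {            # already an indicator
      ind[[v]] <- col
      info[[v]] <- data.frame(variable = v, type = "indicator",
                              cutpoint = NA_real_, reason = "")
      next
    }
    if (is.numeric(col)) {
      vals <- col[!is.na(col)]
      if (length(unique(vals)) < 2) {
        info[[v]] <- data.frame(variable = v, type = "rejected",
                                cutpoint = NA_real_,
                                reason = "constant variable")
        next
      }
      med <- stats::median(vals)
      if (all(vals <= med) || all(vals > med)) {
        info[[v]] <- data.frame(variable = v, type = "rejected",
                                cutpoint = med,
                                reason = "median split degenerate")
        next
      }
      ind[[paste0(v, "=high")]] <- col > med
      ind[[paste0(v, "=low")]]  <- col <= med
      info[[v]] <- data.frame(variable = v, type = "median_split",
                              cutpoint = med, reason = "")
    } else {
      f <- factor(col)
      if (nlevels(f) < 2) {
        info[[v]] <- data.frame(variable = v, type = "rejected",
                                cutpoint = NA_real_,
                                reason = "single category")
        next
      }
      for (lv in levels(f)) ind[[paste0(v, "=", lv)]] <- col == lv
      info[[v]] <- data.frame(variable = v, type = "categorical",
                              cutpoint = NA_real_, reason = "")
    }
  }
  structure(list(indicators = as.data.frame(ind, check.names = FALSE,
                                            optional = TRUE),
                 info = do.call(rbind, c(info, make.row.names = FALSE))),
            class = "dichotomized")
}

#' Adjusted standardized (Haberman) residual of a contingency cell
#'
#' For an observed count O in a cell with row margin r, column margin c and
#' total n, the residual is `(O - E) / sqrt(E (1 - r/n)(1 - c/n))` with
#' `E = r c / n`; it is approximately standard normal under independence.
#'
#' @param tab contingency table (matrix of counts).
#' @param cell cell whose residual to return, default `c(1, 1)` (the
#'   joint-presence cell of a co-occurrence table).
#' @return The residual `d` (NA with a message attribute when a margin is
#'   zero and the residual is undefined).
#' @examples
#' haberman_residual(matrix(c(25, 25, 25, 25), 2))  # 0 under independence
#' @export
haberman_residual <- function(tab, cell = c(1, 1)) {
  d <- haberman_residuals(tab)
  d[cell[1], cell[2]]
}

#' @rdname haberman_residual
#' @return `haberman_residuals()` returns the full residual matrix.
#' @export
haberman_residuals <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 1) stop("empty table", call. = FALSE)
  r <- rowSums(tab); c <- colSums(tab)
  E <- outer(r, c) / n
  denom <- sqrt(E * outer(1 - r / n, 1 - c / n))
  d <- (tab - E) / denom
  d[denom == 0] <- NA_real_   # zero margin: residual undefined
  d
}

#' Coincidence network of dichotomized categories
#'
#' For every pair of category indicators the 2x2 co-occurrence table is
#' tested with the adjusted standardized (Haberman) residual of the
#' joint-presence cell; an edge is drawn when the residual exceeds the
#' z-threshold and its one-sided p-value is below alpha. Node size is
#' category prevalence. Pairs with a zero margin are skipped with a reason.
#'
#' @param indicators logical data.frame from [dichotomize()].
#' @param alpha edge significance level.
#' @param threshold z-threshold on the residual; default is the one-sided
#'   normal quantile `qnorm(1 - alpha)` (co-occurrence is a directional
#'   hypothesis). Set `qnorm(1 - alpha/2)` for the two-sided convention.
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`, matching common practice in
#'   descriptive coincidence analyses; `"BH"` available).
#' @return list of class `coincidence_graph`: `nodes` (name, prevalence,
#'   n), `edges` (from, to, d, p_value), `skipped`, `graph` (igraph),
#'   `alpha`, `threshold`.
#' @export
build_coincidence_network <- function(indicators, alpha = 0.05,
                                      threshold = stats::qnorm(1 - alpha),
                                      p_adjust = "none") {
  stopifnot(is.data.frame(indicators),
            all(vapply(indicators, is.logical, logical(1))))
  vars <- names(indicators)
  nodes <- data.frame(
    name = vars,
    prevalence = vapply(indicators, function(x) mean(x, na.rm = TRUE),
                        numeric(1)),
    n = vapply(indicators, function(x) sum(!is.na(x)), numeric(1)))

  from <- to <- character(0); dv <- pv <- numeric(0)
  skipped <- data.frame(from = character(), to = character(),
                        reason = character())
  k <- length(vars)
  for (i in seq_len(max(k - 1, 0))) for (j in (i + 1):k) {
    x <- indicators[[i]]; y <- indicators[[j]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 1) next
    tab <- matrix(c(sum(x[ok] & y[ok]), sum(x[ok] & !y[ok]),
                    sum(!x[ok] & y[ok]), sum(!x[ok] & !y[ok])), 2, 2)
    d <- haberman_residuals(tab)[1, 1]
    if (is.na(d)) {
      skipped <- rbind(skipped,
                       data.frame(from = vars[i], to = vars[j],
                                  reason = "zero margin"))
      next
    }
    from <- c(from, vars[i]); to <- c(to, vars[j])
    dv <- c(dv, d); pv <- c(pv, stats::pnorm(d, lower.tail = FALSE))
  }
  padj <- stats::p.adjust(pv, method = p_adjust)
  keep <- is.finite(dv) & dv > threshold & padj < alpha
  edges <- data.frame(from = from[keep], to = to[keep], d = dv[keep],
                      p_value = padj[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, skipped = skipped,
                 graph = g, alpha = alpha, threshold = threshold),
            class = "coincidence_graph")
}

#' @export
print.coincidence_graph <- function(x, ...) {
  cat(sprintf("<coincidence_graph> %d nodes, %d significant edges (d > %.3f, alpha %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold, x$alpha))
  invisible(x)
}

#' Confounder-adjusted logistic regression of mortality
#'
#' Fits `outcome ~ measure + age + metastasis + ecog + ldh + albumin +
#' urea` on complete cases and reports the odds ratio per unit of the
#' measure (cm2/m2, or its follow-up change) with a Wald 95% CI. For
#' tumor-cause mortality, deaths from other causes are excluded so the
#' contrast is survivors versus tumor-cause deaths. Perfect separation is
#' detected and refit with Firth's penalized likelihood, labelled in the
#' output.
#'
#' @param data analysis table: one row per patient with the measure,
#'   `deceased`, `death_cause` and the confounder columns.
#' @param measure column name of the composition measure (baseline value or
#'   `delta_`-prefixed change).
#' @param outcome `"overall"` or `"tumor"`.
#' @param confounders confounder column names.
#' @param conf_level Wald confidence level.
#' @return one-row data.frame of class `adjusted_or`: measure, outcome, n,
#'   events, odds_ratio, ci_low, ci_high, p_value, method.
#' @export
adjusted_logistic <- function(data, measure,
                              outcome = c("overall", "tumor"),
                              confounders = c("age", "metastasis", "ecog",
                                              "ldh", "albumin", "urea"),
                              conf_level = 0.95) {
  outcome <- match.arg(outcome)
  stopifnot(measure %in% names(data),
            all(confounders %in% names(data)))
  df <- data
  if (outcome == "tumor") {
    df <- df[df$deceased == 0 |
               (!is.na(df$death_cause) & df$death_cause == "tumor"), ]
    df$y <- as.integer(df$deceased == 1)
  } else {
    df$y <- as.integer(df$deceased == 1)
  }
  cols <- c("y", measure, confounders)
  df <- df[stats::complete.cases(df[, cols]), cols]
  n <- nrow(df); events <- sum(df$y)
  npar <- length(confounders) + 2L
  if (min(events, n - events) < 10 * npar)   # events-per-parameter < 10
    warning(sprintf("only %d events for %d parameters (%s, %s)",
                    min(events, n - events), npar, measure, outcome),
            call. = FALSE)

  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, c(measure, confounders)]))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(is.na(stats::coef(fit)))
  if (separated) {
    ff <- firth_logistic(X, df$y)
    b <- ff$coef[measure]; se <- ff$se[measure]
    method <- "firth"
  } else {
    b <- stats::coef(fit)[measure]
    se <- sqrt(diag(stats::vcov(fit)))[measure]
    method <- "glm"
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(measure = measure, outcome = outcome, n = n, events = events,
             odds_ratio = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se),
             p_value = 2 * stats::pnorm(-abs(b / se)),
             method = method, row.names = NULL)
}

#' Firth-penalized logistic regression
#'
#' Newton-Raphson maximization of the Jeffreys-penalized binomial
#' likelihood (score corrected by the hat diagonal), which yields finite
#' estimates under separation.
#'
#' @param X model matrix (with intercept column).
#' @param y 0/1 response.
#' @param maxit,tol iteration controls.
#' @return list with `coef`, `se`, `iter`, `converged`.
#' @export
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    I <- crossprod(X, XW)
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * XW)          # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(Iinv %*% U)
    # dampen huge steps for stability under near-separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  Iinv <- solve(crossprod(X, X * w))
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(sqrt(diag(Iinv)), colnames(X)),
       iter = it, converged = max(abs(step)) < tol)
}
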