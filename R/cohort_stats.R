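# All permutations of 1..n as an n!-by-n index matrix, built iteratively
# and cached (n <= 9 is what the exact Spearman test needs at cohort scale).
.perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      left <- if (pos > 1) p[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos <= k - 1) p[, pos:(k - 1L), drop = FALSE] else NULL
      cbind(left, k, right)
    })
    p <- do.call(rbind, blocks)
  }
  storage.mode(p) <- "integer"
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with exact permutation p-value
#'
#' The coefficient is the Pearson correlation of midranks. For small
#' samples (n <= 9, the scale of the cohort) the two-sided p-value is
#' computed exactly by enumerating all n! permutations of one variable's
#' ranks (valid under ties, conditioning on the observed midranks); larger
#' samples use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param method `"auto"` (exact up to n = 9), `"exact_perm"`, or
#'   `"t_approx"`.
#' @return list with `rho`, `p.value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, method = c("auto", "exact_perm", "t_approx")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "auto") method <- if (n <= 9) "exact_perm" else "t_approx"
  if (method == "exact_perm") {
    if (n > 9) stop("exact enumeration supported for n <= 9")
    perms <- all_permutations(n)
    rxm <- matrix(rx[perms], nrow = nrow(perms))
    s <- as.vector(rxm %*% ry)
    # rho is affine in sum(rx_perm * ry): rho = (s - n*mx*my)/((n-1)*sx*sy)
    rho_all <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
  }
  list(rho = rho, p.value = p, n = n, method = method)
}

#' Screen user-specific factors against signal strength
#'
#' One Spearman correlation per factor against the response, uncorrected
#' p-values (mirroring the exploratory screen; Benjamini-Hochberg adjusted
#' values are appended when `adjust = TRUE`), factors ranked by absolute
#' coefficient. Rows with a non-finite response (degenerate d-prime) are
#' dropped with a warning; zero-variance factors are flagged and left
#' unranked.
#'
#' @param X data.frame or matrix of predictors (participants x factors).
#' @param y response vector (best signal strength per participant).
#' @param method p-value method passed to [spearman_cor()].
#' @param adjust add Benjamini-Hochberg adjusted p-values.
#' @return a `screen_report` data.frame: `factor`, `rho`, `p.value`,
#'   `rank`, `zero_variance`, `n`, and optionally `p.adjusted`.
#' @export
screen_factors <- function(X, y, method = "auto", adjust = FALSE) {
  X <- as.data.frame(X)
  if (nrow(X) < 3) stop("need >= 3 participants")
  if (ncol(X) < 1) stop("need >= 1 factor")
  keep <- is.finite(y)
  if (!all(keep)) {
    warning(sprintf("dropping %d participant(s) with non-finite response",
                    sum(!keep)))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  rows <- lapply(names(X), function(f) {
    v <- X[[f]]
    if (sd(v) == 0)
      return(data.frame(factor = f, rho = NA_real_, p.value = NA_real_,
                        zero_variance = TRUE, n = length(y)))
    sc <- spearman_cor(v, y, method = method)
    data.frame(factor = f, rho = sc$rho, p.value = sc$p.value,
               zero_variance = FALSE, n = sc$n)
  })
  rep <- do.call(rbind, rows)
  rep$rank <- NA_integer_
  ok <- !rep$zero_variance
  rep$rank[ok] <- rank(-abs(rep$rho[ok]), ties.method = "first")
  if (adjust) rep$p.adjusted <- stats::p.adjust(rep$p.value, "BH")
  rep <- rep[order(rep$rank, na.last = TRUE), ]
  rownames(rep) <- NULL
  class(rep) <- c("screen_report", "data.frame")
  rep
}

#' Lasso feature selection for signal strength predictors
#'
#' L1-penalised linear regression over a log-spaced penalty path, with
#' features standardised to zero mean / unit variance and the response
#' centred before fitting (so coefficients are comparable across factors).
#' The penalty is chosen by leave-one-out cross-validation with the
#' one-standard-error rule. Zero-variance factors get coefficient zero.
#'
#' @param X data.frame or matrix of predictors.
#' @param y response vector.
#' @param penalty_path optional decreasing lambda sequence; default is
#'   glmnet's path.
#' @param cv_folds number of CV folds; default `length(y)` (leave-one-out).
#' @param rule `"1se"` or `"min"` penalty selection.
#' @return a `lasso_report` data.frame (`factor`, `coefficient`,
#'   `selected`), ordered by absolute coefficient, with attributes
#'   `lambda` (selected penalty), `path` (lambda sequence) and
#'   `df_path` (nonzero-coefficient count along the path).
#' @export
lasso_select <- function(X, y, penalty_path = NULL, cv_folds = NULL,
                         rule = c("1se", "min")) {
  rule <- match.arg(rule)
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (n < 3) stop("need >= 3 participants")
  empty <- function() {
    rep <- data.frame(factor = names(X), coefficient = 0, selected = FALSE)
    attr(rep, "lambda") <- NA_real_
    class(rep) <- c("lasso_report", "data.frame")
    rep
  }
  if (sd(y) == 0) return(empty())
  sds <- vapply(X, sd, numeric(1))
  usable <- sds > 0
  if (sum(usable) < 2) return(empty())
  xs <- scale(as.matrix(X[, usable, drop = FALSE]))
  yc <- y - mean(y)
  cv_folds <- cv_folds %||% n
  foldid <- rep_len(seq_len(cv_folds), n)
  cv <- suppressWarnings(glmnet::cv.glmnet(
    xs, yc, lambda = penalty_path, foldid = foldid, grouped = FALSE,
    standardize = FALSE, intercept = FALSE
  ))
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- rep(0, ncol(X))
  names(beta) <- names(X)
  beta[usable] <- as.numeric(coef(cv$glmnet.fit, s = lam))[-1]
  rep <- data.frame(factor = names(X), coefficient = unname(beta),
                    selected = beta != 0)
  rep <- rep[order(-abs(rep$coefficient)), ]
  rownames(rep) <- NULL
  attr(rep, "lambda") <- lam
  attr(rep, "path") <- cv$glmnet.fit$lambda
  attr(rep, "df_path") <- cv$glmnet.fit$df
  class(rep) <- c("lasso_report", "data.frame")
  rep
}

#' Lasso solution at fixed penalties
#'
#' The coordinate-descent solution for pre-standardised inputs at given
#' penalty values, under the objective
#' `(1/(2n)) * RSS + lambda * sum(|beta|)` (no intercept, no internal
#' standardisation). Exposed for path diagnostics and closed-form checks.
#'
#' @param x numeric matrix (already standardised/centred as desired).
#' @param y centred response.
#' @param lambda decreasing penalty sequence.
#' @return coefficient matrix, one column per lambda.
#' @export
lasso_path_coefficients <- function(x, y, lambda) {
  fit <- glmnet::glmnet(x, y, lambda = lambda, standardize = FALSE,
                        intercept = FALSE,
                        thresh = 1e-12)
  as.matrix(fit$beta)
}

#' Nonparametric rank tests (signed-rank / rank-sum)
#'
#' Paired Wilcoxon signed-rank or independent Mann-Whitney rank-sum test,
#' two-sided. Exact null distributions are used for small untied samples
#' (signed-rank n <= 12, rank-sum n + m <= 20, matching full enumeration);
#' larger or tied samples use the normal approximation with tie
#' correction.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param exact override the exact/approximate choice.
#' @return list with `statistic` (V or W), `p.value`, `exact`, `method`.
#' @export
rank_tests <- function(a, b, paired = FALSE, exact = NULL) {
  if (paired && length(a) != length(b))
    stop("paired test needs equal lengths")
  if (paired && all(a == b)) {
    # all differences zero: no evidence against symmetry around zero
    return(list(statistic = 0, p.value = 1, exact = TRUE,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  if (is.null(exact)) {
    ties <- if (paired) any(duplicated(abs(a - b)[a != b]))
            else any(duplicated(c(a, b)))
    exact <- !ties && if (paired) length(a) <= 12
                      else length(a) + length(b) <= 20
  }
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = paired, exact = exact, correct = !exact)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = exact, method = wt$method)
}
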