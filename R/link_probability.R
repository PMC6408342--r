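#' Row-wise mixed-effects logistic estimation of link probabilities
#'
#' For one row `y` (length m, 0/1) of an incidence matrix and a correlation
#' matrix `V` over the m columns, the model is
#'
#'   logit(p_j) = alpha + b_j,   b ~ Normal(0, sigma^2 V)
#'
#' a logistic regression with a constant intercept and one Gaussian random
#' effect per column whose covariance is a scalar multiple of `V`. The
#' scalar `sigma` measures how predictive the correlation structure is for
#' this row's links. With one observation per random-effect level the
#' marginal likelihood has no closed form; it is maximized under a Laplace
#' approximation: an inner Newton iteration finds the posterior mode of
#' `b` for given `(alpha, sigma)`, and an outer quasi-Newton search
#' optimizes `(alpha, log sigma)`.
#'
#' Details that matter in practice:
#' * a weak Gaussian penalty on `alpha` (sd 10) guards against perfect
#'   separation;
#' * `sigma` is searched on the log scale within `[1e-4, 20]`; when the
#'   optimum sits at the lower boundary the fit collapses to the
#'   intercept-only logistic model and `sigma = 0` is reported;
#' * rows that are all 0 or all 1 carry no information about `sigma`; they
#'   return the Laplace-smoothed uniform probability `(s + 1) / (m + 2)`
#'   (`s` = row total) with `sigma = 0` and convergence flag
#'   `"degenerate"`, so every link still has a defined weight;
#' * fitted probabilities are clipped to `[1e-6, 1 - 1e-6]`, keeping the
#'   informed swap acceptance strictly positive.
#'
#' @param y binary vector of length `m` (one row of the incidence matrix).
#' @param V an `m x m` correlation matrix (regularized internally if
#'   singular).
#' @return a `row_fit` list: `alpha`, `sigma`, `b_hat`, `p` (fitted
#'   probabilities), `converged` (`"ok"`, `"degenerate"`, `"boundary"` or
#'   `"fallback"`), `log_likelihood` (penalized Laplace marginal).
#' @export
fit_row_model <- function(y, V) {
  y <- as.numeric(y)
  m <- length(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("y must be a binary 0/1 vector")
  if (nrow(V) != m) abort("length(y) must equal dim(V)")
  s <- sum(y)
  if (s == 0 || s == m) {
    p <- rep((s + 1) / (m + 2), m)
    return(new_row_fit(alpha = qlogis(p[1]), sigma = 0, b_hat = rep(0, m),
                       p = p, converged = "degenerate",
                       log_likelihood = sum(y * log(p) + (1 - y) * log1p(-p)),
                       labels = rownames(V)))
  }

  V <- regularize_correlation(V)
  ev <- eigen(unclass(V), symmetric = TRUE)
  lam <- pmax(ev$values, 1e-10)
  Vinv <- ev$vectors %*% (t(ev$vectors) / lam)
  Vmat <- unclass(V)

  alpha_sd <- 10
  b_warm <- rep(0, m)

  # inner Newton: posterior mode of b given (alpha, sigma); returns the
  # Laplace marginal log-likelihood (alpha-penalized) or -Inf on divergence
  laplace_obj <- function(alpha, sigma) {
    Q <- Vinv / sigma^2
    b <- b_warm
    obj <- function(b, eta, p) {
      sum(y * eta - log1pexp(eta)) - 0.5 * sum(b * (Q %*% b))
    }
    eta <- alpha + b
    p <- plogis(eta)
    f <- obj(b, eta, p)
    ok <- TRUE
    for (iter in 1:60) {
      g <- (y - p) - Q %*% b
      if (max(abs(g)) < 1e-9) break
      W <- p * (1 - p)
      H <- Q
      diag(H) <- diag(H) + W
      step <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      t_ls <- 1
      repeat {
        b_new <- b + t_ls * step
        eta_new <- alpha + b_new
        p_new <- plogis(eta_new)
        f_new <- obj(b_new, eta_new, p_new)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        t_ls <- t_ls / 2
        if (t_ls < 1e-8) { ok <- FALSE; break }
      }
      if (!ok) break
      b <- b_new; eta <- eta_new; p <- p_new; f <- f_new
    }
    if (!ok || !all(is.finite(b))) return(list(ll = -Inf, b = b_warm))
    b_warm <<- as.numeric(b)
    W <- p * (1 - p)
    # log det (I + sigma^2 W^{1/2} V W^{1/2}) via Cholesky
    sw <- sqrt(W)
    M <- diag(m) + sigma^2 * (sw * t(sw * Vmat))
    R <- tryCatch(chol((M + t(M)) / 2), error = function(e) NULL)
    if (is.null(R)) return(list(ll = -Inf, b = b_warm))
    ll <- f - sum(log(diag(R))) - alpha^2 / (2 * alpha_sd^2)
    list(ll = ll, b = as.numeric(b))
  }

  neg <- function(par) {
    out <- laplace_obj(par[1], exp(par[2]))
    if (!is.finite(out$ll)) 1e10 else -out$ll
  }

  alpha0 <- qlogis((s + 0.5) / (m + 1))
  opt <- tryCatch(
    nlminb(c(alpha0, log(0.5)), neg,
           lower = c(-30, log(1e-4)), upper = c(30, log(20))),
    error = function(e) NULL
  )

  # sigma = 0 reference: intercept-only penalized logistic
  nll0 <- function(a) -(sum(y * a - log1pexp(rep(a, m))) - a^2 / (2 * alpha_sd^2))
  opt0 <- optimize(nll0, c(-30, 30))
  ll0 <- -opt0$objective

  use_zero <- is.null(opt) || !is.finite(opt$objective) ||
    (-opt$objective) <= ll0 + 1e-8 || exp(opt$par[2]) <= 1.5e-4
  if (use_zero) {
    alpha <- opt0$minimum
    p <- rep(plogis(alpha), m)
    flag <- if (is.null(opt)) "fallback" else "boundary"
    return(new_row_fit(alpha = alpha, sigma = 0, b_hat = rep(0, m), p = p,
                       converged = flag, log_likelihood = ll0,
                       labels = rownames(V)))
  }

  alpha <- opt$par[1]
  sigma <- exp(opt$par[2])
  fit <- laplace_obj(alpha, sigma)
  p <- clip_prob(plogis(alpha + fit$b))
  flag <- if (sigma >= 20 * (1 - 1e-6)) "boundary" else "ok"
  new_row_fit(alpha = alpha, sigma = sigma, b_hat = fit$b, p = p,
              converged = flag, log_likelihood = fit$ll, labels = rownames(V))
}

clip_prob <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x + exp(-x), log1p(exp(pmin(x, 30))))

new_row_fit <- function(alpha, sigma, b_hat, p, converged, log_likelihood,
                        labels = NULL) {
  p <- clip_prob(p)
  if (!is.null(labels)) names(p) <- names(b_hat) <- labels
  structure(list(alpha = alpha, sigma = sigma, b_hat = b_hat, p = p,
                 converged = converged, log_likelihood = log_likelihood),
            class = "row_fit")
}

#' @export
print.row_fit <- function(x, ...) {
  cat(sprintf("<row_fit> alpha = %.3f, sigma = %.3f (%s), logLik = %.3f\n",
              x$alpha, x$sigma, x$converged, x$log_likelihood))
  invisible(x)
}

#' Estimate the full matrix of link probabilities
#'
#' Fits the row model ([fit_row_model()]) to every row of the incidence
#' matrix (or, under the `"cols"` perspective, every column via the
#' transpose) and assembles the per-link probabilities `p_ij`. For a food
#' web under the rows-given-V convention (rows = consumers) this is the
#' predator's-diet perspective — the probability of consumer `i` eating
#' resource `j` given the correlation structure over resources; the
#' `"cols"` perspective with a correlation structure over consumers is the
#' prey's-consumers perspective.
#'
#' The estimation happens once, before any randomization: every swap of
#' the informed null model is weighted relative to the original matrix.
#'
#' @param A an `incidence_matrix` (or `food_web`).
#' @param V a `correlation_matrix` over the columns of `A` (perspective
#'   `"rows"`) or over its rows (perspective `"cols"`); labels must match.
#' @param perspective `"rows"` (fit each row, V relates columns) or
#'   `"cols"` (fit each column, V relates rows).
#' @return a `probability_matrix`: an `n x m` matrix of probabilities with
#'   attributes `row_fits` (list of `row_fit`), `perspective` and
#'   `provenance`. [tidy()] extracts per-fit diagnostics.
#' @export
estimate_probability_matrix <- function(A, V, perspective = c("rows", "cols")) {
  perspective <- match.arg(perspective)
  work <- if (perspective == "rows") unclass(A) else t(unclass(A))
  need <- colnames(work)
  if (!setequal(rownames(V), need)) {
    abort("labels of V do not match the incidence matrix axis it should describe")
  }
  V <- regularize_correlation(V)
  Vo <- new_correlation_matrix(unclass(V)[need, need], need, attr(V, "provenance"))
  fits <- lapply(seq_len(nrow(work)), function(i) fit_row_model(work[i, ], Vo))
  P <- do.call(rbind, lapply(fits, `[[`, "p"))
  if (perspective == "cols") P <- t(P)
  dimnames(P) <- dimnames(A)
  structure(P,
            row_fits = setNames(fits, rownames(work)),
            perspective = perspective,
            provenance = attr(V, "provenance"),
            class = c("probability_matrix", "matrix", "array"))
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf("<probability_matrix> %d x %d, perspective = %s\n",
              nrow(x), ncol(x), attr(x, "perspective")))
  print(round(unclass(x)[seq_len(min(nrow(x), 6L)), seq_len(min(ncol(x), 6L)),
                         drop = FALSE], 3))
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' Tidy per-row fit diagnostics
#'
#' @param x a `probability_matrix`.
#' @param ... unused.
#' @return a tibble with one row per fitted unit: `unit`, `alpha`,
#'   `sigma`, `converged`, `log_likelihood`.
#' @method tidy probability_matrix
#' @export
tidy.probability_matrix <- function(x, ...) {
  fits <- attr(x, "row_fits")
  tibble(
    unit = names(fits),
    alpha = purrr::map_dbl(fits, "alpha"),
    sigma = purrr::map_dbl(fits, "sigma"),
    converged = purrr::map_chr(fits, "converged"),
    log_likelihood = purrr::map_dbl(fits, "log_likelihood")
  )
}

#' @method glance probability_matrix
#' @export
glance.probability_matrix <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_fits = nrow(td),
    perspective = attr(x, "perspective"),
    mean_sigma = mean(td$sigma),
    median_sigma = stats::median(td$sigma),
    n_degenerate = sum(td$converged == "degenerate"),
    n_nonconverged = sum(td$converged == "fallback"),
    total_log_likelihood = sum(td$log_likelihood)
  )
}

#' Heatmap of estimated link probabilities
#'
#' @param object a `probability_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_matrix
#' @export
autoplot.probability_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(unclass(object), responseName = "p"))
  names(df)[1:2] <- c("row", "col")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write fit diagnostics to a TSV report
#'
#' @param P a `probability_matrix`.
#' @param path output path.
#' @export
write_fit_report <- function(P, path) {
  write.table(tidy(P), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
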