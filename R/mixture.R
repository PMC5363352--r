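#' Univariate Gaussian mixture with an additive cohort factor
#'
#' EM fit of `y_i ~ Normal(mean[z_i] + beta[cohort_i], sd[z_i]^2)`: a
#' k-component Gaussian mixture whose component means are shifted by a
#' cohort-specific offset common to all components, absorbing differential
#' assay bias between cohorts so that class boundaries are shared. The
#' first cohort level is the reference with its offset fixed at 0.
#'
#' Initialization is by k-means on the (cohort-demeaned) values with
#' multiple restarts; each EM step performs the closed-form responsibility
#' update followed by coordinate updates of component means, cohort
#' offsets (precision-weighted) and variances, so the observed-data
#' log-likelihood is non-decreasing. Component standard deviations are
#' floored to prevent collapse onto single points.
#'
#' @param values Numeric vector (e.g. PC1 scores), optionally named.
#' @param k Number of components (>= 1, <= length(values)).
#' @param cohort Optional factor/character of cohort labels per value.
#' @param seed Integer seed controlling restarts; fits are deterministic
#'   given the seed.
#' @param n_restarts Number of k-means initializations (default 10).
#' @param tol Convergence threshold on the log-likelihood gain (1e-8).
#' @param max_iter Maximum EM iterations per restart (500).
#' @param sd_floor Lower bound on component standard deviations (1e-4).
#' @param equal_var Constrain all components to a common variance.
#' @return Object of class `mixture_fit`: `k`, `means`, `sds`, `weights`,
#'   `cohort_betas`, `responsibilities` (n x k), `loglik`, `loglik_trace`,
#'   `converged`, `values`, `cohort`.
#' @export
fit_gaussian_mixture <- function(values, k, cohort = NULL, seed = NULL,
                                 n_restarts = 10L, tol = 1e-8,
                                 max_iter = 500L, sd_floor = 1e-4,
                                 equal_var = FALSE) {
  y <- as.numeric(values)
  n <- length(y)
  stopifnot(k >= 1L, n >= k)
  if (is.null(cohort)) cohort <- rep("all", n)
  cohort <- as.character(cohort)
  stopifnot(length(cohort) == n)
  levs <- unique(cohort)
  ci <- match(cohort, levs)

  run_em <- function(mu0) {
    mu <- mu0
    sdv <- rep(max(sd(y) / k, sd_floor), k)
    w <- rep(1 / k, k)
    beta <- setNames(rep(0, length(levs)), levs)
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      adj <- y - beta[ci]
      logd <- vapply(seq_len(k), function(j)
        dnorm(adj, mu[j], sdv[j], log = TRUE) + log(w[j]), numeric(n))
      if (n == 1L) logd <- matrix(logd, nrow = 1L)
      mx <- apply(logd, 1L, max)
      ll_i <- mx + log(rowSums(exp(logd - mx)))
      ll <- sum(ll_i)
      trace <- c(trace, ll)
      r <- exp(logd - ll_i)  # responsibilities
      if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
      prev <- ll
      # M-step (coordinate ascent on Q)
      nk <- colSums(r)
      w <- nk / n
      mu <- colSums(r * (y - beta[ci])) / nk
      if (length(levs) > 1L) {
        prec <- sweep(r, 2L, sdv^2, "/")
        resid <- y - matrix(mu, n, k, byrow = TRUE)
        num <- rowSums(prec * resid)
        den <- rowSums(prec)
        for (cl in 2:length(levs)) {
          sel <- ci == cl
          beta[cl] <- sum(num[sel]) / sum(den[sel])
        }
      }
      dev2 <- (y - beta[ci] - matrix(mu, n, k, byrow = TRUE))^2
      if (equal_var) {
        sdv <- rep(max(sqrt(sum(r * dev2) / n), sd_floor), k)
      } else {
        sdv <- pmax(sqrt(colSums(r * dev2) / nk), sd_floor)
      }
    }
    degenerate <- any(colSums(r) < 1e-3) ||
      (!equal_var && any(sdv <= sd_floor & colSums(r) < 2))
    list(mu = mu, sd = sdv, w = w, beta = beta, r = r, trace = trace,
         loglik = trace[length(trace)], converged = converged,
         degenerate = degenerate)
  }

  with_seed(seed, {
    # demean by cohort for initialization only
    y0 <- y
    if (length(levs) > 1L)
      y0 <- y - (tapply(y, ci, mean)[ci] - mean(y))
    fits <- vector("list", n_restarts)
    for (s in seq_len(n_restarts)) {
      mu0 <- if (k == 1L) mean(y0) else {
        km <- tryCatch(kmeans(y0, centers = k, nstart = 1L),
                       error = function(e) NULL)
        if (is.null(km)) sort(sample(y0, k)) else sort(as.numeric(km$centers))
      }
      fits[[s]] <- tryCatch(run_em(mu0), error = function(e) NULL)
    }
    ok <- Filter(function(f) !is.null(f) && !f$degenerate, fits)
    if (length(ok) == 0L) {
      any_fit <- Filter(Negate(is.null), fits)
      if (length(any_fit) == 0L)
        stop("all EM restarts failed", call. = FALSE)
      warning("all EM restarts degenerate; returning best degenerate fit")
      ok <- any_fit
    }
    best <- ok[[which.max(vapply(ok, `[[`, numeric(1), "loglik"))]]
    structure(list(
      k = k, means = best$mu, sds = best$sd, weights = best$w,
      cohort_betas = best$beta, responsibilities = best$r,
      loglik = best$loglik, loglik_trace = best$trace,
      converged = best$converged, values = setNames(y, names(values)),
      cohort = cohort), class = "mixture_fit")
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: k=%d, loglik=%.3f, converged=%s\n",
              x$k, x$loglik, x$converged))
  cat("  means:", sprintf("%.3f", x$means), "\n")
  cat("  sds:  ", sprintf("%.3f", x$sds), "\n")
  invisible(x)
}

#' Call loss/normal/gain copy-number classes from a 3-component fit
#'
#' Components are ranked by mean on the oriented PC1 scale, where
#' deletions sit highest: the highest-mean component is `loss`, the middle
#' `normal`, the lowest `gain`. Each sample takes the class of maximal
#' responsibility, with that responsibility as the posterior; calls below
#' `min_posterior` are flagged uncertain.
#'
#' @param fit A `mixture_fit` with `k = 3`.
#' @param min_posterior Posterior below which a call is flagged (0.5).
#' @return Data.frame with `sample_id`, `class`, `posterior`, `uncertain`.
#' @export
call_copy_number <- function(fit, min_posterior = 0.5) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k != 3L) stop("copy-number calling expects k = 3", call. = FALSE)
  ord <- order(fit$means, decreasing = TRUE)
  cls <- character(3L)
  cls[ord] <- c("loss", "normal", "gain")
  idx <- max.col(fit$responsibilities, ties.method = "first")
  post <- fit$responsibilities[cbind(seq_along(idx), idx)]
  ids <- names(fit$values)
  if (is.null(ids)) ids <- sprintf("sample%04d", seq_along(idx))
  data.frame(sample_id = ids, class = cls[idx], posterior = post,
             uncertain = post < min_posterior, stringsAsFactors = FALSE)
}
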