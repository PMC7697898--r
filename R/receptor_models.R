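#' Construct a speciated-samples object
#'
#' @param X samples x species matrix of mass concentrations (ug/m3), with
#'   species column names.
#' @param sigma matrix of the same shape with strictly positive per-entry
#'   uncertainties.
#' @param periods optional data frame of per-sample period metadata.
#' @return a `speciated_samples` list.
#' @export
speciated_samples <- function(X, sigma, periods = NULL) {
  X <- as.matrix(X); sigma <- as.matrix(sigma)
  if (!all(dim(X) == dim(sigma)))
    stopf("X and sigma must have the same shape")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stopf("sigma must be strictly positive")
  structure(list(X = X, sigma = sigma, periods = periods),
            class = "speciated_samples")
}

#' Lawson-Hanson non-negative least squares
#'
#' Solves min ||A x - b||^2 subject to x >= 0 by the active-set method.
#' Exact for these small systems (a handful of sources), which keeps the
#' alternating factorization monotone.
#' @noRd
nnls_solve <- function(A, b, tol = NULL) {
  p <- ncol(A)
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  if (is.null(tol)) tol <- 1e-12 * max(abs(AtA))
  x <- numeric(p)
  passive <- logical(p)
  w <- Atb - AtA %*% x
  outer_it <- 0L
  while (any(!passive & w > tol) && outer_it < 50L * p) {
    outer_it <- outer_it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      P <- which(passive)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[P] <- x[P] > tol
      x[!passive] <- 0
    }
    w <- Atb - AtA %*% x
  }
  as.numeric(x)
}

#' Chemical mass balance fit by effective-variance least squares
#'
#' Solves the speciated mass balance `X = G F + E` for the source
#' contributions `G` when the source profiles `F` are known. Per sample,
#' the effective variance of species j is
#' `V_j = sigma_j^2 + sum_k g_k^2 sigma_f[k, j]^2`, combining measurement
#' and profile uncertainty scaled by the current contribution estimate;
#' the weighted least-squares solution with weights `1/V_j` is iterated to
#' a fixed point (max relative change in `g` below `tol`, or `max_iter`
#' passes). With zero profile uncertainty this reduces to a single weighted
#' least-squares solve. Contributions are not sign-constrained (classic
#' CMB); negative estimates raise a warning.
#'
#' @param samples a `speciated_samples` object.
#' @param profiles sources x species matrix of mass fractions with source
#'   rownames; species count must be >= source count and rows linearly
#'   independent.
#' @param profile_sigma optional matrix of per-entry profile uncertainties
#'   (same shape as `profiles`); `NULL` or all-zero gives the single-pass
#'   solution.
#' @param max_iter,tol effective-variance iteration controls.
#' @return a `cmb_fit`: `G` and `se` (samples x sources), `residuals`
#'   (`X - G F`), `converged` flags, `n_negative` count.
#' @export
cmb_fit <- function(samples, profiles, profile_sigma = NULL,
                    max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(samples, "speciated_samples"))
  Fm <- as.matrix(profiles)
  p <- nrow(Fm); m <- ncol(Fm); n <- nrow(samples$X)
  if (anyNA(samples$X)) stopf("CMB does not support missing species values")
  if (m < p) stopf("species count (%d) must be >= source count (%d)", m, p)
  qrF <- qr(t(Fm))
  if (qrF$rank < p) {
    dep <- rownames(Fm)[qrF$pivot[(qrF$rank + 1):p]]
    stopf("collinear source profiles: %s", paste(dep, collapse = ", "))
  }
  Fs2 <- if (is.null(profile_sigma)) matrix(0, p, m)
         else as.matrix(profile_sigma)^2
  iterate <- any(Fs2 > 0)
  G <- matrix(0, n, p, dimnames = list(NULL, rownames(Fm)))
  SE <- G
  converged <- logical(n)
  for (i in seq_len(n)) {
    y <- samples$X[i, ]
    s2 <- samples$sigma[i, ]^2
    g <- rep(0, p)
    for (it in seq_len(max_iter)) {
      v_eff <- s2 + as.numeric(g^2 %*% Fs2)
      W <- 1 / v_eff
      FW <- Fm * rep(W, each = p)          # p x m, rows weighted
      M <- FW %*% t(Fm)                    # F W F^T
      g_new <- as.numeric(solve(M, FW %*% y))
      delta <- max(abs(g_new - g) / pmax(abs(g_new), 1e-12))
      g <- g_new
      if (!iterate || delta < tol) break
    }
    converged[i] <- !iterate || delta < tol
    G[i, ] <- g
    SE[i, ] <- sqrt(diag(solve(M)))
  }
  n_neg <- sum(G < 0)
  if (n_neg)
    warning(sprintf("%d negative contribution estimates (CMB is unconstrained)",
                    n_neg), call. = FALSE)
  structure(list(G = G, se = SE, residuals = samples$X - G %*% Fm,
                 profiles = Fm, converged = converged, n_negative = n_neg),
            class = "cmb_fit")
}

#' Positive matrix factorization by uncertainty-weighted alternating NNLS
#'
#' Factorizes speciated samples as `X ~ G F` with both factors constrained
#' non-negative, minimising the uncertainty-weighted objective
#' `Q = sum_ij ((X_ij - sum_k g_ik f_kj) / sigma_ij)^2`. Each outer
#' iteration solves the exact weighted non-negative least-squares problem
#' for every row of `G` and then every column of `F`, so `Q` is
#' nonincreasing by construction (an increase beyond tolerance aborts as an
#' internal error). Restarts from seeded random non-negative initial
#' factors; the best final `Q` is kept. The factorization is
#' scale-ambiguous, so rows of `F` are normalised to sum to 1 (mass
#' fractions) with the scale absorbed into `G`. Per-sample standard errors
#' are not produced by this objective and are reported as unavailable.
#'
#' Missing entries in `X` are supported by down-weighting
#' (`sigma` set to 1e6) with a count recorded in `attr(, "n_downweighted")`.
#'
#' @param samples a `speciated_samples` object.
#' @param p number of sources (1 <= p < min(samples, species)).
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @param max_iter maximum outer iterations per restart.
#' @param tol relative Q change declaring convergence.
#' @return a `pmf_fit`: `G` (samples x sources), `F` (sources x species),
#'   `Q`, `dof` (`n*m - p*(n+m)`), `q_path` of the winning restart,
#'   `converged`.
#' @export
pmf_fit <- function(samples, p, seed = 1L, n_restarts = 10,
                    max_iter = 500, tol = 1e-9) {
  stopifnot(inherits(samples, "speciated_samples"))
  X <- samples$X; sigma <- samples$sigma
  n <- nrow(X); m <- ncol(X)
  if (p < 1 || p >= min(n, m)) stopf("need 1 <= p < min(%d, %d)", n, m)
  n_down <- sum(is.na(X))
  if (n_down) {
    sigma[is.na(X)] <- 1e6
    X[is.na(X)] <- 0
  }
  q_of <- function(G, Fm) sum(((X - G %*% Fm) / sigma)^2)
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      G <- matrix(stats::runif(n * p, 0.1, 1), n, p) * mean(abs(X))
      Fm <- matrix(stats::runif(p * m, 0.1, 1), p, m)
      Fm <- Fm / rowSums(Fm)
      q_prev <- q_of(G, Fm)
      q_path <- q_prev
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        for (i in seq_len(n))
          G[i, ] <- nnls_solve(t(Fm) / sigma[i, ], X[i, ] / sigma[i, ])
        for (j in seq_len(m))
          Fm[, j] <- nnls_solve(G / sigma[, j], X[, j] / sigma[, j])
        q <- q_of(G, Fm)
        if (q > q_prev * (1 + 1e-8) + 1e-12)
          stopf("internal error: Q increased between outer iterations")
        q_path <- c(q_path, q)
        if (q_prev - q <= tol * max(q_prev, 1e-300)) { converged <- TRUE; break }
        q_prev <- q
      }
      if (is.null(best) || q < best$Q)
        best <- list(G = G, F = Fm, Q = q, q_path = q_path,
                     converged = converged)
    }
  })
  # scale convention: profile rows are mass fractions summing to 1
  rs <- rowSums(best$F)
  keep <- rs > 0
  best$F[keep, ] <- best$F[keep, , drop = FALSE] / rs[keep]
  best$G[, keep] <- sweep(best$G[, keep, drop = FALSE], 2, rs[keep], "*")
  colnames(best$G) <- rownames(best$F) <- paste0("factor", seq_len(p))
  colnames(best$F) <- colnames(X)
  structure(list(G = best$G, F = best$F, Q = best$Q,
                 dof = n * m - p * (n + m), q_path = best$q_path,
                 converged = best$converged, se = NULL),
            n_downweighted = n_down, class = "pmf_fit")
}

#' Period summaries of receptor-model contributions
#'
#' Mean source contribution over the samples of each period. Standard
#' errors combine per-sample fit uncertainties in quadrature
#' (`sqrt(sum se^2)/n`); for fits without per-sample uncertainties (PMF)
#' the between-sample `sd/sqrt(n)` is used instead and flagged.
#'
#' @param fit a `cmb_fit` or `pmf_fit`.
#' @param grouping named list of sample-index vectors, one per period (a
#'   single period per sample is the degenerate case).
#' @return long data frame: `period`, `source`, `mean`, `se`, `n`; empty
#'   periods are omitted with a message.
#' @export
rm_period_summary <- function(fit, grouping) {
  G <- fit$G
  src <- colnames(G)
  empty <- names(grouping)[!lengths(grouping)]
  if (length(empty)) {
    message("omitting empty periods: ", paste(empty, collapse = ", "))
    grouping <- grouping[lengths(grouping) > 0]
  }
  out <- do.call(rbind, lapply(names(grouping), function(pd) {
    idx <- grouping[[pd]]
    mean_g <- colMeans(G[idx, , drop = FALSE])
    se <- if (!is.null(fit$se))
      sqrt(colSums(fit$se[idx, , drop = FALSE]^2)) / length(idx)
    else apply(G[idx, , drop = FALSE], 2, stats::sd) / sqrt(length(idx))
    data.frame(period = pd, source = src, mean = unname(mean_g),
               se = unname(se), n = length(idx), row.names = NULL)
  }))
  attr(out, "se_method") <- if (!is.null(fit$se)) "quadrature"
                            else "between-sample"
  out
}
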