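# Maximum-likelihood decomposition of DNA histograms: two bounding
# components (G1, G2+M) plus a constrained grid of S-phase components,
# fitted by expectation-maximization with the ordering/bounding constraints
# enforced by projection after each M-step.

#' Fit a multi-Gaussian model to DNA values
#'
#' Fits a `2 + n_s_components` mixture by EM. The bounding components are
#' initialized at the histogram's two modes (the second mode is sought near
#' twice the first; if absent it is placed there), S means are initialized
#' evenly between them and constrained to stay strictly inside the bounding
#' means at every iteration. Components whose sd collapses below a quarter
#' of the default bin width are pruned with a warning.
#'
#' @param values numeric DNA values (n >= 2000).
#' @param n_s_components number of S-phase components (>= 1).
#' @param init optional [gaussian_mixture()] used as the starting point.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   tail of the log-likelihood trace.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a [gaussian_mixture()] with attributes `iterations`, `loglik`
#'   and `loglik_trace`.
#' @export
fit_multigaussian <- function(values, n_s_components, init = NULL,
                              max_iter = 1000, tol = 1e-8) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 2000) stop("need at least 2000 values to fit (got ", n, ")")
  if (!is_count(n_s_components)) stop("n_s_components must be a positive integer")
  K <- n_s_components + 2L

  if (is.null(init)) {
    d <- density(values, n = 512)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1L
    pk <- pk[order(d$y[pk], decreasing = TRUE)]
    m1 <- d$x[pk[1]]
    cand <- pk[d$x[pk] > 1.6 * m1 & d$x[pk] < 2.4 * m1]
    m2 <- if (length(cand)) d$x[cand[which.max(d$y[cand])]] else 2 * m1
    mu <- c(m1, m1 + seq_len(n_s_components) / (n_s_components + 1) * (m2 - m1), m2)
    sg <- 0.04 * mu
    ar <- c(0.5, rep(0.4 / n_s_components, n_s_components), 0.1)
  } else {
    validate_mixture(init)
    if (length(init$mean) != K) stop("init must have ", K, " components")
    mu <- init$mean; sg <- init$sd; ar <- init$area
  }

  sd_floor <- diff(range(values)) / 256 / 4
  trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dens <- vapply(seq_along(mu), function(k) ar[k] * dnorm(values, mu[k], sg[k]),
                   numeric(n))
    rs <- rowSums(dens)
    rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rs))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    if (iter >= max_iter) {
      stop("EM did not converge in ", max_iter, " iterations; ",
           "log-likelihood trace tail: ",
           paste(format(tail(trace, 5), digits = 12), collapse = ", "))
    }
    ll_old <- ll
    resp <- dens / rs
    Nk <- colSums(resp)
    live <- Nk > 1e-8 * n
    for (k in seq_along(mu)) {
      if (!live[k]) next
      mu[k] <- sum(resp[, k] * values) / Nk[k]
      sg[k] <- sqrt(sum(resp[, k] * (values - mu[k])^2) / Nk[k])
    }
    ar <- Nk / n
    # projection: keep bounding components bounding, S means strictly inside
    if (mu[1] > mu[K]) { mu[c(1, K)] <- mu[c(K, 1)]; sg[c(1, K)] <- sg[c(K, 1)]
                         ar[c(1, K)] <- ar[c(K, 1)] }
    eps <- 1e-6 * max(mu[K] - mu[1], sd_floor)
    if (K > 2) {
      mid <- 2:(K - 1)
      mu[mid] <- pmin(pmax(mu[mid], mu[1] + eps), mu[K] - eps)
      mu[mid] <- sort(mu[mid])
    }
    sg <- pmax(sg, .Machine$double.eps)
  }

  pruned <- sg < sd_floor
  if (any(pruned)) {
    warning("component(s) with degenerate sd pruned: ",
            paste(which(pruned), collapse = ", "))
    keep <- !pruned
    mu <- mu[keep]; sg <- sg[keep]; ar <- ar[keep]
    ar <- ar / sum(ar)
    K <- length(mu)
  }
  ar <- ar / sum(ar)
  lab <- rep("S", K)
  lab[which.min(mu)] <- "G1"
  lab[which.max(mu)] <- "G2M"
  ord <- order(mu)
  out <- structure(list(mean = mu[ord], sd = sg[ord], area = ar[ord],
                        label = lab[ord]),
                   class = "gaussian_mixture")
  validate_mixture(out)
  attr(out, "iterations") <- iter
  attr(out, "loglik") <- trace[length(trace)]
  attr(out, "loglik_trace") <- trace
  out
}

#' Expression profile from mixture components
#'
#' The "perfect solution" route: components ordered by mean, each plotted
#' at the center of an interval equal to its area on the 0-1
#' cumulative-frequency scale (`x_i` = cumulative area before i + area_i/2),
#' with the component mean as the y value. Boundary points can then be
#' added with [insert_boundary_points()].
#'
#' @param mixture a [gaussian_mixture()] (areas summing to 1).
#' @param channel profile column name.
#' @return an [expression_profile]; component areas are carried as
#'   pseudo-counts (area fraction of 1e6) so frequency bookkeeping works.
#' @export
profile_from_mixture <- function(mixture, channel = "dna") {
  validate_mixture(mixture)
  a <- mixture$area
  x <- cumsum(a) - a / 2
  pts <- data.frame(x = x, count = as.integer(round(a * 1e6)),
                    synthetic = FALSE)
  pts[[channel]] <- mixture$mean
  pts[[paste0(channel, "_se")]] <- NA_real_
  new_expression_profile(pts, channels = channel)
}
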