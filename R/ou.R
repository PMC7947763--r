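# Brownian-motion and Ornstein-Uhlenbeck models for a continuous trait on
# a rooted phylogeny with branch lengths as time. The OU process
#   dX(t) = alpha (theta - X(t)) dt + sigma dB(t)
# has selection strength alpha toward optimum theta and drift intensity
# sigma; alpha -> 0 recovers Brownian motion (pure drift). Likelihoods are
# multivariate-normal over the tip values; under a regime painting each
# branch carries its own optimum.

#' Paint tree branches with selective regimes
#'
#' Branches whose descendant leaves all belong to a named clade get that
#' clade's regime; every other branch (and the root) gets `"background"`.
#' The clade stem branch is included by default.
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param clades Named list of character vectors of tip labels; must be
#'   disjoint.
#' @param include_stem Paint the stem branch of each clade?
#' @return Object of class `regime_painting`: character vector of regime
#'   names, one per edge (postorder edge order), with attributes `levels`
#'   and `tree`.
#' @export
paint_regimes <- function(tree, clades = list(), include_stem = TRUE) {
  tree <- tree_info(tree)$tree
  if (length(clades) > 1L) {
    all_taxa <- unlist(clades)
    if (anyDuplicated(all_taxa))
      stop("configuration error: overlapping clades")
  }
  reg <- rep("background", nrow(tree$edge))
  for (nm in names(clades)) {
    reg[clade_branches(tree, clades[[nm]], include_stem)] <- nm
  }
  structure(reg, levels = c("background", names(clades)), tree = tree,
            class = "regime_painting")
}

#' Brownian-motion log-likelihood
#'
#' Tips are jointly Gaussian with mean `root_state` and covariance
#' `sigma2 * s_ij`, where `s_ij` is the shared root-to-MRCA path length.
#'
#' @param tree Rooted `"phylo"`.
#' @param trait Named numeric vector over all tips.
#' @param sigma2 Drift variance rate (> 0).
#' @param root_state Trait value at the root.
#' @return Log-likelihood.
#' @export
bm_loglik <- function(tree, trait, sigma2, root_state) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("trait missing for some tips")
  V <- sigma2 * shared_path_matrix(tree)
  mvn_loglik(x, rep(root_state, length(x)), V)
}

# log density of x ~ N(mu, V) via Cholesky
mvn_loglik <- function(x, mu, V) {
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular covariance (duplicate zero-distance tips?)"))
  d <- x - mu
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# per-tip regime weight matrix W for the OU mean and the OU covariance,
# given alpha. Root state equals the root regime's optimum ("background"),
# so mean_i = sum_r W[i, r] * theta_r with the root-decay term folded into
# the background column.
ou_design <- function(tree, painting, alpha) {
  levels0 <- attr(painting, "levels")
  if (is.null(levels0)) levels0 <- unique(painting)
  if (length(levels0) == 1L) {
    # single regime: the segment weights and the root-decay term sum to 1
    n_tip <- length(tree$tip.label)
    return(matrix(1, n_tip, 1L,
                  dimnames = list(tree$tip.label, levels0)))
  }
  info <- tree_info(tree)
  tree <- info$tree
  n_tip <- info$n_tip
  depth <- info$depth
  levels <- attr(painting, "levels")
  if (is.null(levels)) levels <- unique(painting)
  W <- matrix(0, n_tip, length(levels), dimnames = list(tree$tip.label, levels))
  # accumulate exp-weighted segment contributions along each root-to-tip path
  parent_edge <- integer(info$n_node)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  for (i in seq_len(n_tip)) {
    Ti <- depth[i]
    v <- i
    while (v != info$root) {
      e <- parent_edge[v]
      p <- tree$edge[e, 1L]
      t_start <- depth[p]; t_end <- depth[v]
      w <- exp(-alpha * (Ti - t_end)) - exp(-alpha * (Ti - t_start))
      W[i, painting[e]] <- W[i, painting[e]] + w
      v <- p
    }
    W[i, "background"] <- W[i, "background"] + exp(-alpha * Ti)  # root state
  }
  W
}

#' Ornstein-Uhlenbeck log-likelihood
#'
#' Gaussian likelihood of tip values under a (possibly multi-optimum) OU
#' process: `mean_i` integrates the optima along the root-to-tip path with
#' exponential weights, `cov_ij = sigma2/(2 alpha) * exp(-alpha (T_i + T_j
#' - 2 s_ij)) * (1 - exp(-2 alpha s_ij))`, and the root state is fixed at
#' the background (root regime) optimum.
#'
#' @inheritParams bm_loglik
#' @param alpha Selection strength (> 0); use [bm_loglik()] for alpha = 0.
#' @param optima Named numeric vector of optima, one per regime level in
#'   `painting` (single unnamed value allowed for one regime).
#' @param painting A [paint_regimes()] painting; `NULL` means one regime.
#' @return Log-likelihood.
#' @export
ou_loglik <- function(tree, trait, alpha, sigma2, optima, painting = NULL) {
  if (alpha <= 0)
    stop("alpha must be > 0; the alpha = 0 limit is Brownian motion (bm_loglik)")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (is.null(painting)) painting <- paint_regimes(tree)
  tree <- attr(painting, "tree")
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("trait missing for some tips")
  levels <- attr(painting, "levels")
  if (is.null(names(optima)) && length(optima) == length(levels))
    names(optima) <- levels
  W <- ou_design(tree, painting, alpha)
  mu <- as.vector(W %*% optima[colnames(W)])
  s <- shared_path_matrix(tree)
  Ti <- diag(s)
  V <- (sigma2 / (2 * alpha)) *
    exp(-alpha * (outer(Ti, Ti, "+") - 2 * s)) * (1 - exp(-2 * alpha * s))
  mvn_loglik(x, mu, V)
}

#' Fit a trait evolution model on a phylogeny
#'
#' Maximum-likelihood fit of Brownian motion (`"BM"`, pure drift), a
#' single-optimum OU process (`"OU1"`, stabilizing selection), or a
#' multi-optimum OU process (`"OUk"`, one optimum per painted regime).
#' At each candidate (alpha, sigma2) the optima (and the BM root state)
#' are profiled out by generalized least squares; the remaining parameters
#' are optimised by Nelder-Mead from (alpha, sigma) = (1, 1) plus four
#' deterministically jittered restarts, with alpha searched on the log
#' scale within [1e-6, 1e3].
#'
#' Parameter counts (each successive comparison adds one degree of
#' freedom): BM {root state, sigma2}; OU1 {theta, alpha, sigma2}; OUk adds
#' one optimum per extra regime. The root state is tied to the root
#' regime's optimum for the OU models, keeping BM, OU1 and OUk nested.
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param trait Named numeric vector over the tips.
#' @param model One of `"BM"`, `"OU1"`, `"OUk"`.
#' @param painting A [paint_regimes()] painting (required for `"OUk"`).
#' @param restarts Number of jittered restarts after the (1, 1) start.
#' @return Object of class `ou_fit`: `model`, `alpha`, `sigma2`, `optima`
#'   (or `root_state` for BM), `loglik`, `k` (free parameters), `n_tips`,
#'   `convergence`, `painting`.
#' @examples
#' tr <- ape::rcoal(20)
#' x <- simulate_trait(tr, process = "BM", sigma2 = 1, root_state = 0,
#'                     seed = 1)$tip
#' fit_trait_model(tr, x, model = "BM")
#' @export
fit_trait_model <- function(tree, trait, model = c("BM", "OU1", "OUk"),
                            painting = NULL, restarts = 4L) {
  model <- match.arg(model)
  tree <- tree_info(tree)$tree
  x <- trait[tree$tip.label]
  if (length(x) < 3L || anyNA(x)) stop("need trait values for >= 3 tips")
  if (stats::sd(x) == 0)
    stop("degenerate input: constant trait across all tips (sigma2 -> 0 boundary)")

  if (model == "BM") {
    s <- shared_path_matrix(tree)
    fit1 <- function(par) {   # par = log sigma2; root state by GLS
      sigma2 <- exp(par[1])
      V <- sigma2 * s
      ch <- chol(V)
      one <- rep(1, length(x))
      iV1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
      x0 <- sum(iV1 * x) / sum(iV1 * one)
      -mvn_loglik(x, rep(x0, length(x)), V)
    }
    best <- optim_restarts(fit1, start = 0, restarts = restarts,
                           lower = log(1e-9), upper = log(1e9))
    sigma2 <- exp(best$par[1])
    V <- sigma2 * s
    ch <- chol(V)
    one <- rep(1, length(x))
    iV1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
    x0 <- sum(iV1 * x) / sum(iV1 * one)
    out <- list(model = "BM", alpha = 0, sigma2 = sigma2, root_state = x0,
                optima = NULL, loglik = -best$value, k = 2L,
                n_tips = length(x), convergence = best$convergence,
                painting = NULL, tree = tree)
    return(structure(out, class = "ou_fit"))
  }

  if (is.null(painting) || model == "OU1") painting1 <- paint_regimes(tree)
  pt <- if (model == "OUk") {
    if (is.null(painting)) stop("OUk requires a regime painting")
    painting
  } else painting1
  levels <- attr(pt, "levels")
  s <- shared_path_matrix(tree)
  Ti <- diag(s)

  nll <- function(par) {   # par = (log alpha, log sigma2); optima by GLS
    alpha <- exp(par[1]); sigma2 <- exp(par[2])
    if (alpha < 1e-6 || alpha > 1e3 || !is.finite(sigma2)) return(1e10)
    W <- ou_design(attr(pt, "tree"), pt, alpha)
    V <- (sigma2 / (2 * alpha)) *
      exp(-alpha * (outer(Ti, Ti, "+") - 2 * s)) * (1 - exp(-2 * alpha * s))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Wt <- backsolve(ch, W, transpose = TRUE)
    xt <- backsolve(ch, x, transpose = TRUE)
    theta <- tryCatch(qr.solve(crossprod(Wt), crossprod(Wt, xt)),
                      error = function(e) NULL)
    if (is.null(theta)) return(1e10)
    mu <- as.vector(W %*% theta)
    -mvn_loglik(x, mu, V)
  }
  # the (1, 1) convention start, jittered restarts, plus the near-BM
  # boundary so the alpha -> 0 limit is always examined
  best <- optim_restarts(nll, start = c(0, 0), restarts = restarts,
                         extra_starts = list(c(log(1e-5), 0)))
  alpha <- exp(best$par[1]); sigma2 <- exp(best$par[2])
  W <- ou_design(attr(pt, "tree"), pt, alpha)
  V <- (sigma2 / (2 * alpha)) *
    exp(-alpha * (outer(Ti, Ti, "+") - 2 * s)) * (1 - exp(-2 * alpha * s))
  ch <- chol(V)
  Wt <- backsolve(ch, W, transpose = TRUE)
  xt <- backsolve(ch, x, transpose = TRUE)
  theta <- drop(qr.solve(crossprod(Wt), crossprod(Wt, xt)))
  theta <- stats::setNames(as.numeric(theta), colnames(W))
  k <- 2L + length(theta)
  out <- list(model = model, alpha = alpha, sigma2 = sigma2,
              optima = theta, root_state = unname(theta["background"]),
              loglik = -best$value, k = k, n_tips = length(x),
              convergence = best$convergence, painting = pt,
              tree = attr(pt, "tree"))
  structure(out, class = "ou_fit")
}

# Nelder-Mead (or 1-D Brent) with deterministic jittered restarts from the
# conventional (alpha, sigma) = (1, 1) start; absolute tolerance 1e-8,
# at most 5000 evaluations per start
optim_restarts <- function(fn, start, restarts = 4L,
                           lower = -Inf, upper = Inf,
                           extra_starts = list()) {
  starts <- c(list(start), extra_starts)
  jit <- matrix(stats::qnorm(((1:(restarts * length(start))) - 0.5) /
                               (restarts * length(start))),
                nrow = restarts)
  for (r in seq_len(restarts))
    starts[[r + 1L]] <- start + 1.5 * jit[r, seq_along(start)]
  best <- NULL
  conv <- 1L
  for (s0 in starts) {
    o <- if (length(start) == 1L)
      stats::optim(s0, fn, method = "Brent", lower = max(lower, s0 - 25),
                   upper = min(upper, s0 + 25),
                   control = list(abstol = 1e-8, maxit = 5000))
    else
      stats::optim(s0, fn, method = "Nelder-Mead",
                   control = list(abstol = 1e-8, maxit = 5000))
    if (is.null(best) || o$value < best$value) { best <- o; conv <- o$convergence }
  }
  best$convergence <- conv
  best
}

#' Likelihood-ratio comparison of nested trait models
#'
#' Chi-square upper-tail p for 2 * (logL_full - logL_nested), with degrees
#' of freedom equal to the parameter-count difference. Negative statistics
#' within optimiser tolerance are clamped to 0. BM vs OU1 tests drift
#' against stabilizing selection; OU1 vs OUk tests one optimum against a
#' regime-specific shift.
#'
#' @param fit_nested,fit_full Two [fit_trait_model()] fits on the same data.
#' @return Object of class `ou_lrt`: `statistic`, `df`, `p_value`, and the
#'   model labels.
#' @export
compare_models <- function(fit_nested, fit_full) {
  if (fit_full$k <= fit_nested$k)
    stop("input error: models are not nested in the stated order")
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  if (stat < -1e-4)
    warning("full model fits worse than nested model beyond tolerance; ",
            "statistic clamped to 0 (optimiser non-convergence?)")
  stat <- max(stat, 0)
  df <- fit_full$k - fit_nested$k
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 nested = fit_nested$model, full = fit_full$model),
            class = "ou_lrt")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat("Trait model:", x$model, " logL =", format(x$loglik, digits = 6),
      " (", x$k, "parameters,", x$n_tips, "tips )\n")
  if (x$model == "BM")
    cat(sprintf("  sigma2 = %.4g, root state = %.4g\n", x$sigma2, x$root_state))
  else {
    cat(sprintf("  alpha = %.4g, sigma2 = %.4g\n", x$alpha, x$sigma2))
    cat("  optima:", paste(sprintf("%s = %.4g", names(x$optima), x$optima),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ou_fit <- function(object, ...) {
  if (object$model == "BM")
    c(sigma2 = object$sigma2, root_state = object$root_state)
  else c(alpha = object$alpha, sigma2 = object$sigma2,
         stats::setNames(object$optima, paste0("theta_", names(object$optima))))
}

#' @export
logLik.ou_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_tips,
            class = "logLik")
}

#' @export
summary.ou_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$painting)) {
    tb <- table(object$painting)
    cat("  regimes (branches):",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
print.ou_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*dlogL = %.4g, df = %d, p = %.4g\n",
              x$nested, x$full, x$statistic, x$df, x$p_value))
  invisible(x)
}
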