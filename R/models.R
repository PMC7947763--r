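#' Empirical amino-acid substitution models
#'
#' Builds a time-reversible 20-state substitution model from a named set of
#' empirical exchangeabilities (JTT by default) or from user-supplied
#' matrices, optionally with discrete-gamma rate heterogeneity across
#' sites. The instantaneous rate matrix is normalised so that one unit of
#' branch length corresponds to one expected substitution per site at the
#' equilibrium frequencies.
#'
#' Named models are sourced from the exchangeability tables shipped with
#' phangorn; alternative matrices (e.g. one trained on intrinsically
#' disordered mammalian proteins) can be plugged in via
#' [read_model_file()] or the `exchangeabilities`/`frequencies` arguments.
#'
#' @param name One of `"JTT"`, `"LG"`, `"WAG"`, `"Dayhoff"`, `"poisson"`,
#'   or `"custom"` (requires `exchangeabilities` and `frequencies`).
#' @param gamma_shape Shape of the gamma distribution of site rates, or
#'   `NULL` for equal rates.
#' @param ncat Number of discrete gamma categories (default 4).
#' @param exchangeabilities Optional 20x20 symmetric matrix (rows/columns
#'   in alphabetical one-letter order) overriding the named model.
#' @param frequencies Optional equilibrium frequency vector (alphabetical
#'   order, positive, summing to 1).
#' @return An object of class `aa_model` with elements `name`, `S`, `pi`,
#'   `Q` (normalised), `gamma_shape`, `ncat`, `rates` (discrete category
#'   rates averaging 1), and an internal eigendecomposition.
#' @export
aa_model <- function(name = "JTT", gamma_shape = NULL, ncat = 4L,
                     exchangeabilities = NULL, frequencies = NULL) {
  if (!is.null(exchangeabilities) || identical(name, "custom")) {
    S <- exchangeabilities
    pi <- frequencies
    if (is.null(S) || is.null(pi)) stop("custom model needs both matrices")
  } else if (identical(tolower(name), "poisson")) {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- if (is.null(frequencies)) rep(1 / 20, 20) else frequencies
  } else {
    em <- empirical_model_data(name)
    S <- em$S
    pi <- if (is.null(frequencies)) em$pi else frequencies
  }
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  pi <- stats::setNames(as.numeric(pi), AA_ALPHABET)
  if (any(pi <= 0)) stop("model error: equilibrium frequencies must be positive")
  pi <- pi / sum(pi)
  if (max(abs(S - t(S))) > 1e-8) stop("model error: exchangeabilities not symmetric")
  obj <- structure(list(name = name, S = S, pi = pi,
                        gamma_shape = gamma_shape, ncat = as.integer(ncat)),
                   class = "aa_model")
  obj$Q <- build_rate_matrix(obj)
  obj$eig <- reversible_eigen(obj$Q, pi)
  obj$rates <- if (is.null(gamma_shape)) 1 else
    discrete_gamma_rates(gamma_shape, obj$ncat)
  obj
}

# phangorn stores the PAML-order lower triangle of each empirical model;
# reorder to this package's alphabetical convention
empirical_model_data <- function(name) {
  key <- paste0(".", name)
  obj <- tryCatch(utils::getFromNamespace(key, "phangorn"),
                  error = function(e) stop("unknown model: ", name))
  paml_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  S <- matrix(0, 20, 20, dimnames = list(paml_order, paml_order))
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  pi <- stats::setNames(as.numeric(obj$bf), paml_order)
  list(S = S[AA_ALPHABET, AA_ALPHABET], pi = pi[AA_ALPHABET])
}

#' Read a substitution model from a plain-text matrix file
#'
#' The format mirrors the classical PAML `.dat` layout: 19 lines giving the
#' lower triangle of the symmetric exchangeability matrix (row 2 has one
#' value, row 20 has nineteen), followed by one line of 20 equilibrium
#' frequencies, all in the order ARNDCQEGHILKMFPSTWYV. Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path Path to the matrix file.
#' @inheritParams aa_model
#' @return An [aa_model].
#' @export
read_model_file <- function(path, gamma_shape = NULL, ncat = 4L) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  vals <- lapply(strsplit(ln, "\\s+"), as.numeric)
  if (length(vals) < 20L) stop("model file needs 19 triangle rows + 1 frequency row")
  paml_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  S <- matrix(0, 20, 20, dimnames = list(paml_order, paml_order))
  for (i in 1:19) {
    if (length(vals[[i]]) != i) stop("triangle row ", i, " must have ", i, " values")
    S[i + 1L, seq_len(i)] <- vals[[i]]
  }
  S <- S + t(S)
  pi <- vals[[20]]
  if (length(pi) != 20L) stop("frequency row must have 20 values")
  aa_model("custom", gamma_shape = gamma_shape, ncat = ncat,
           exchangeabilities = S[AA_ALPHABET, AA_ALPHABET],
           frequencies = stats::setNames(pi, paml_order)[AA_ALPHABET])
}

#' Normalised instantaneous rate matrix of a model
#'
#' Q[i,j] = S[i,j] * pi[j] off the diagonal, diagonal set so rows sum to 0,
#' and the whole matrix scaled so the expected rate at equilibrium,
#' -sum_i pi_i Q[i,i], equals 1 substitution per site per unit length.
#'
#' @param model An [aa_model] (or a list with `S` and `pi`).
#' @return A 20x20 rate matrix satisfying detailed balance.
#' @export
build_rate_matrix <- function(model) {
  S <- model$S; pi <- model$pi
  if (any(pi <= 0)) stop("model error: nonpositive frequency")
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# symmetric eigendecomposition of a reversible Q for fast matrix exponentials
reversible_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors * rep(1 / sq, times = 20L),   # diag(1/sq) %*% V
       right = t(e$vectors * rep(sq, times = 20L)))   # t(V) %*% diag(sq)
}

#' Transition probability matrix P(t)
#'
#' @param model An [aa_model].
#' @param t Branch length (>= 0).
#' @param rate Site-rate multiplier (>= 0), e.g. a discrete-gamma category
#'   rate.
#' @return Row-stochastic 20x20 matrix `expm(Q * t * rate)`.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0 || rate < 0) stop("input error: t and rate must be >= 0")
  P <- model$eig$left %*% (exp(model$eig$values * t * rate) * model$eig$right)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}

#' Discrete-gamma category rates
#'
#' Mean-of-bin discretisation: the gamma(shape, rate = shape) distribution
#' (mean 1) is cut at its `ncat` quantile boundaries and each category is
#' assigned the conditional mean of its bin, so the rates average exactly 1.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  if (shape <= 0) stop("shape must be > 0")
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape, rate = shape)
  r <- ncat * diff(stats::pgamma(b, shape + 1, rate = shape))
  r / mean(r) * 1  # guard against tail rounding; mean(r) is 1 up to fp error
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid model:", x$name,
      if (is.null(x$gamma_shape)) "(equal rates)" else
        sprintf("+G(shape=%.4g, %d categories)", x$gamma_shape, x$ncat), "\n")
  invisible(x)
}
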