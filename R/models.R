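#' Load an empirical amino-acid substitution model
#'
#' Reads the packaged JTT, WAG or Dayhoff model from its plain-text data file
#' (lower-triangle exchangeabilities followed by 20 equilibrium frequencies,
#' the layout the original model publications are distributed in). File
#' integrity is verified against the shipped md5 manifest.
#'
#' @param name One of \code{"JTT"}, \code{"WAG"}, \code{"Dayhoff"}.
#' @return An object of class \code{empirical_model}: a list with \code{name},
#'   \code{S} (symmetric 20x20 exchangeability matrix, zero diagonal) and
#'   \code{pi} (equilibrium frequencies, summing to 1), both indexed in
#'   \code{\link{aa_states}} order.
#' @export
load_model <- function(name = c("JTT", "WAG", "Dayhoff")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".dat"),
                      package = "opsinshift", mustWork = TRUE)
  manifest <- system.file("extdata", "models", "CHECKSUMS.md5",
                          package = "opsinshift", mustWork = TRUE)
  sums <- read.table(manifest, col.names = c("md5", "file"),
                     stringsAsFactors = FALSE)
  expect <- sums$md5[sums$file == basename(path)]
  got <- unname(tools::md5sum(path))
  if (length(expect) != 1L || !identical(got, expect)) {
    stop("checksum mismatch for model file ", basename(path))
  }
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 190L + 20L) {
    stop("malformed model file: expected 190 exchangeabilities + 20 frequencies")
  }
  S <- matrix(0, 20L, 20L, dimnames = list(aa_states(), aa_states()))
  k <- 0L
  for (i in 2:20) {          # row-wise lower triangle, as printed in the files
    S[i, seq_len(i - 1L)] <- vals[k + seq_len(i - 1L)]
    k <- k + i - 1L
  }
  S <- S + t(S)
  pi <- vals[191:210]
  pi <- pi / sum(pi)
  names(pi) <- aa_states()
  empirical_model(name, S, pi)
}

#' Construct an empirical model object
#'
#' @param name Model name.
#' @param S Symmetric nonnegative 20x20 exchangeability matrix, zero diagonal.
#' @param pi Length-20 probability vector, all entries > 0.
#' @return An \code{empirical_model} object.
#' @export
empirical_model <- function(name, S, pi) {
  if (!is.matrix(S) || any(dim(S) != 20L)) stop("S must be a 20x20 matrix")
  if (any(S < 0)) stop("exchangeabilities must be nonnegative")
  if (max(abs(S - t(S))) > 1e-10) stop("exchangeability matrix S is not symmetric")
  if (any(diag(S) != 0)) stop("exchangeability matrix must have zero diagonal")
  check_frequencies(pi)
  structure(list(name = name, S = S, pi = pi), class = "empirical_model")
}

check_frequencies <- function(pi) {
  if (length(pi) != 20L) stop("frequency vector must have length 20")
  if (any(pi <= 0)) stop("all equilibrium frequencies must be > 0")
  if (abs(sum(pi) - 1) > 1e-8) {
    stop("frequencies must sum to 1 (got ", format(sum(pi), digits = 12), ")")
  }
  invisible(pi)
}

#' Build a normalized reversible rate matrix
#'
#' Assembles Q[i,j] = S[i,j] * pi[j] for i != j, sets the diagonal so rows sum
#' to zero, and rescales the whole matrix so the mean substitution rate
#' -sum_i pi_i Q[i,i] equals 1, so branch lengths are in expected
#' substitutions per site. Passing \code{frequencies} (the "+F" option)
#' replaces the model's published frequencies with, e.g., frequencies observed
#' in an alignment.
#'
#' @param model An \code{empirical_model}.
#' @param frequencies Optional override probability vector (length 20, > 0,
#'   summing to 1), in \code{\link{aa_states}} order.
#' @return A \code{rate_matrix} object: list with \code{Q}, \code{pi},
#'   \code{name}, and a cached symmetric eigendecomposition used by
#'   \code{\link{transition_probabilities}}.
#' @export
build_rate_matrix <- function(model, frequencies = NULL) {
  stopifnot(inherits(model, "empirical_model"))
  pi <- if (is.null(frequencies)) model$pi else {
    check_frequencies(frequencies)
    f <- as.numeric(frequencies)
    names(f) <- aa_states()
    f
  }
  Q <- model$S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate model: zero mean rate")
  Q <- Q / scale
  # reversibility => D^{1/2} Q D^{-1/2} is symmetric; cache its eigensystem
  rpi <- sqrt(pi)
  B <- Q * (rpi %o% (1 / rpi))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(
    Q = Q, pi = pi, name = model$name,
    eig = list(values = e$values,
               right = e$vectors / rpi,         # D^{-1/2} V
               left  = t(e$vectors * rpi))      # V^T D^{1/2}
  ), class = "rate_matrix")
}

#' Transition probabilities over a branch
#'
#' P(t) = exp(Q t), computed from the cached symmetrized eigendecomposition of
#' the reversible rate matrix. Negative round-off of magnitude <= 1e-12 is
#' clipped to zero; rows sum to 1 to within 1e-10.
#'
#' @param Q A \code{rate_matrix} from \code{\link{build_rate_matrix}}.
#' @param t Branch length, >= 0 (expected substitutions per site).
#' @return 20x20 row-stochastic matrix; rows = ancestral state, columns =
#'   descendant state.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(inherits(Q, "rate_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a single nonnegative number")
  }
  e <- Q$eig
  P <- e$right %*% (exp(e$values * t) * e$left)
  P[P < 0 & P > -1e-12] <- 0
  P[P < 0] <- 0   # larger negatives cannot arise from a valid decomposition
  dimnames(P) <- dimnames(Q$Q)
  P
}
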