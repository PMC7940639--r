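# Internal numerical helpers shared across modules.

# Symmetric solve with a relative condition-number guard.  Fits entering the
# comparison machinery should already have passed the covariance eigenvalue
# screen, so a failure here is treated as a hard error, not smoothed over.
solve_sym <- function(S, b, max_condition = 1e12, label = "covariance") {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop("degenerate ", label, " matrix (non-positive-definite or condition number > ",
         format(max_condition), ")", call. = FALSE)
  }
  ch <- chol(S)
  backsolve(ch, forwardsolve(t(ch), b))
}

# log(det(S)) for a symmetric positive-definite matrix; errors otherwise.
logdet_sym <- function(S, label = "covariance") {
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop(label, " matrix is not positive-definite", call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

is_spd <- function(S, tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return(FALSE)
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > 0
}

# Evaluate an expression under a fixed RNG state without disturbing the
# caller's stream; `seed` must be a single integer < 2^31.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used only to fingerprint configurations in run manifests.  The xor only
# touches the low byte and the multiply is split to stay within exact
# double-precision integer arithmetic.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
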