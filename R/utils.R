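# internal helpers: angle conversions, seeded evaluation, validation

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles into [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL leaves the RNG stream alone.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# derive a distinct child seed (kept < 2^31 for 32-bit R integers)
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 9973 * k) %% 2147483647L)
}

abort_if <- function(cond, msg, class) {
  if (any(cond)) rlang::abort(msg, class = class)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
                 class = "cueweights_config_error")
  }
  invisible(x)
}

# rows of `m` scaled to unit Euclidean norm
normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

as_normal_matrix <- function(n, arg = "n") {
  if (is.numeric(n) && is.null(dim(n)) && length(n) == 3L) {
    n <- matrix(n, nrow = 1L)
  }
  n <- as.matrix(n)
  if (ncol(n) != 3L) {
    rlang::abort(sprintf("`%s` must be a length-3 vector or an n x 3 matrix.", arg),
                 class = "cueweights_validation_error")
  }
  storage.mode(n) <- "double"
  colnames(n) <- c("x", "y", "z")
  n
}

check_unit_rows <- function(n, arg = "n", tol = 1e-6) {
  bad <- abs(sqrt(rowSums(n^2)) - 1) > tol
  abort_if(bad, sprintf("`%s` contains non-unit vectors (beyond tolerance %g).", arg, tol),
           class = "cueweights_validation_error")
  invisible(n)
}
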