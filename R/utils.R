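# Internal helpers shared across modules.

# Deterministically derive n child seeds from one master seed. NULL master
# seed means "leave the RNG alone" and draws whatever comes next.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483647L, n)
}

check_square_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# Stable, dependency-free content hash (polynomial rolling hash over the
# deparsed object), used only to stamp outputs so a rerun with the same
# configuration can be recognised. Not cryptographic.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
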