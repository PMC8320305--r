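# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators do not
#' perturb the global stream.
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Round-half-up: the only rounding rule consistent with the top-fraction
# counts this package is designed to reproduce (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

stop_ironmap <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ironmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "ironmap_invalid_argument", ...) {
  if (!isTRUE(cond)) stop_ironmap(msg, class, ...)
  invisible(TRUE)
}

# Benjamini-Hochberg step-up, via stats::p.adjust.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Column standardization used by the PLS front end. Columns with (near-)zero
# variance get scale NA and are the caller's problem.
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- matrixStats::colSds(X)
  scl[scl < .Machine$double.eps^0.5] <- NA_real_
  list(x = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}

# Cheap deterministic string hash (FNV-1a, 32 bit) for run manifests.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h >= 2^31) * 2^31
    # 32-bit modular multiply without exceeding double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
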