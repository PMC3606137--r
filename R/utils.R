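# Shared internal helpers: the trial time grid, seed derivation and
# small argument checks.  All times are in ms relative to stimulus onset;
# rates are in spikes/ms throughout the package.

# Trial window.  Bins are 1 ms wide and labelled by their start time, so
# bin `tau` covers [tau, tau + 1) ms.  The stimulus is on over [0, 500) ms.
TRIAL_START <- -100L
TRIAL_END <- 700L
STIM_ON <- 0L
STIM_OFF <- 500L

#' Trial time grid
#'
#' Bin start times of the 1-ms simulation grid, spanning -100 ms to
#' +700 ms relative to stimulus onset (800 bins).
#'
#' @return Integer vector of bin start times in ms.
#' @export
trial_times <- function() {
  seq.int(TRIAL_START, TRIAL_END - 1L)
}

# Derive `n` child seeds from one master seed without disturbing the
# caller's RNG state.  Used so that pipeline stages (population, table,
# experiments, bootstraps) can be re-run independently.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Match strength values against a grid of levels without interpolation.
# Errors on absent values: the rate table is defined only on its grid.
match_level <- function(x, levels, what = "strength") {
  idx <- vapply(x, function(v) {
    hit <- which(abs(levels - v) < 1e-9)
    if (length(hit) != 1L) {
      stop(sprintf("%s %g is not a level of the table grid (%s)",
                   what, v, paste(signif(levels, 4), collapse = ", ")),
           call. = FALSE)
    }
    hit
  }, integer(1))
  idx
}

check_strength <- function(x, name) {
  if (any(!is.finite(x)) || any(x < -1 | x > 1)) {
    stop(sprintf("`%s` must lie in [-1, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Polynomial rolling hash of a character scalar (mod 2^31 - 1); used to
# stamp output manifests with a config fingerprint without adding a
# dependency.  Not cryptographic, just a stable fingerprint.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  m <- 2147483647
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
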