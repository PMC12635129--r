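# Shared internal helpers: condition constructors, seeded evaluation and the
# canonical limb-role / block vocabulary used throughout the package.

LIMB_ROLES <- c("ConA", "UncA", "IpsiL", "ContL")
LIMB_MARKERS <- c("LW", "RW", "LA", "RA")
BLOCK_NAMES <- c("B", "P1", "P2", "P3", "P4", "P5")

mk_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mobilekin_error"),
                      call = call))
}

#' Default 2-min analysis blocks
#'
#' Half-open intervals (seconds from recording start) for the baseline block
#' B = \[0, 120) and the five play blocks P1..P5 covering the 10-min play
#' phase in 2-min steps.
#'
#' @return A data frame with columns `block`, `start`, `end`.
#' @export
default_blocks <- function() {
  data.frame(block = BLOCK_NAMES,
             start = seq(0, 600, by = 120),
             end = seq(120, 720, by = 120))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    mk_error("seed must be a single number", "mobilekin_invalid_spec")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit sub-seed derivation so that per-session / per-limb
# streams are independent yet reproducible from one master seed.  All
# arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  as.integer((s * 69069 + as.numeric(index) * 1234567 + 1) %% m)
}
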