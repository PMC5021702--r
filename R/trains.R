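#' Burst-structured synthetic spike train
#'
#' Generates spike times from a two-level point process: burst onsets are a
#' homogeneous Poisson process at `burst_rate`, and each burst carries
#' `burst_length` spikes whose inter-spike intervals follow a dead-time
#' renewal model — a 2 ms absolute refractory period plus an exponential
#' tail, with the mean interval equal to `1/intra_burst_rate`. The dead
#' time keeps genuine single units clean of refractory-period violations,
#' as real neurons are. With `burst_length = 1` this reduces to a Poisson
#' train with a refractory floor. All output intervals are >= 1 ms.
#'
#' @param duration Recording length in seconds (> 0).
#' @param burst_rate Burst-onset rate, Hz.
#' @param intra_burst_rate Within-burst firing rate, Hz; must exceed
#'   `burst_rate`.
#' @param burst_length Spikes per burst (>= 1).
#' @param seed Integer seed; required (all stochastic generators in this
#'   package take explicit seeds).
#' @return Sorted numeric vector of spike times in seconds, all inside
#'   `[0, duration)`, with every inter-spike interval >= 1 ms.
#' @export
make_spike_train <- function(duration, burst_rate, intra_burst_rate,
                             burst_length, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (burst_rate <= 0 || intra_burst_rate <= 0)
    stop("rates must be positive")
  if (burst_length > 1 && intra_burst_rate <= burst_rate)
    stop("intra_burst_rate must exceed burst_rate")
  if (burst_length < 1) stop("burst_length must be >= 1")
  refractory <- 1e-3
  dead <- 2e-3
  mean_isi <- 1 / intra_burst_rate

  times <- local_seed(seed, {
    n_bursts <- stats::rpois(1, burst_rate * duration)
    onsets <- sort(stats::runif(n_bursts, 0, duration))
    unlist(lapply(onsets, function(t0) {
      isis <- if (mean_isi > dead)
        dead + stats::rexp(burst_length - 1L, 1 / (mean_isi - dead))
      else rep(max(mean_isi, refractory), burst_length - 1L)
      t0 + c(0, cumsum(isis))
    }))
  })
  if (length(times) == 0) return(numeric(0))
  times <- sort(times[times < duration])
  # enforce the global refractory floor across overlapping bursts
  keep <- c(TRUE, diff(times) >= refractory)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= refractory)
  }
  times
}

# Evaluate an expression with a local RNG state seeded by `seed`, restoring
# the caller's state afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
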