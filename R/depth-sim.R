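#' Simulate a windowed depth-of-coverage profile for a repeat array
#'
#' Produces per-window mean depths for a tandem repeat region (e.g. the Yq
#' heterochromatic satellite array) and a single-copy reference region.
#' Single-copy windows have expected depth `base_depth * g(GC)`; repeat
#' windows have expected depth `repeat_copy_factor * base_depth * g(GC)`,
#' where `g` is a smooth exponential GC-bias curve,
#' `g(gc) = exp(gc_bias_strength * (gc - 0.45))`, and windows carry
#' log-normal multiplicative noise.
#'
#' @param repeat_copy_factor True repeat copy number relative to single copy
#'   (must be > 0); the observed polymorphism spans roughly 24-900.
#' @param gc_bias_strength Strength of the GC-bias curve; 0 disables bias.
#' @param n_windows Windows per region (>= 10).
#' @param base_depth Expected single-copy depth.
#' @param window_size Window width in bases.
#' @param noise_sd Log-scale SD of per-window noise; 0 for deterministic
#'   depths.
#' @param seed Integer seed.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `gc`, `depth`, `region` (`"repeat"` or `"single_copy"`).
#' @export
generate_depth_profile <- function(repeat_copy_factor,
                                   gc_bias_strength = 0,
                                   n_windows = 100,
                                   base_depth = 2,
                                   window_size = 1000,
                                   noise_sd = 0.05,
                                   seed = 1L) {
  if (repeat_copy_factor <= 0) {
    stop("`repeat_copy_factor` must be positive", call. = FALSE)
  }
  if (n_windows < 10) {
    stop("need at least 10 windows per region", call. = FALSE)
  }
  with_seed(seed, {
    one_region <- function(region, factor, offset) {
      gc <- runif(n_windows, 0.3, 0.6)
      g <- exp(gc_bias_strength * (gc - 0.45))
      noise <- if (noise_sd > 0) rlnorm(n_windows, 0, noise_sd) else 1
      start <- offset + window_size * (seq_len(n_windows) - 1L)
      data.frame(chrom = "chrY", start = start, end = start + window_size,
                 gc = gc, depth = factor * base_depth * g * noise,
                 region = region, stringsAsFactors = FALSE)
    }
    rbind(one_region("single_copy", 1, 14500000L),
          one_region("repeat", repeat_copy_factor, 20000000L))
  })
}
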