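#' Simulate free-modulus magnitude-estimation ratings
#'
#' Generates pairwise dissimilarity ratings with the structure the behavioral
#' normalization assumes. Each stimulus has a latent perceptual position
#' \eqn{p_i = s_i^\gamma} (a compressive power function of particle size
#' \eqn{s_i}, default exponent 0.3), and the true dissimilarity of an ordered
#' pair is \eqn{|p_i - p_j|}. Because the rating scale is free-modulus, every
#' participant applies a private multiplicative scale (log-normal with spread
#' \code{scale_spread}); individual ratings are further perturbed by
#' log-normal noise of coefficient of variation \code{noise_cv} (mean 1).
#' Each block presents all 20 ordered pairs of the five stimuli once, in
#' randomized order.
#'
#' @param stimuli [stimulus_set()] data frame.
#' @param n_participants Number of simulated participants.
#' @param n_blocks Blocks per participant (default 5; the first block is
#'   conventionally treated as practice and dropped in analysis).
#' @param scale_spread Log-scale standard deviation of the per-participant
#'   multiplier (0 = common scale).
#' @param noise_cv Coefficient of variation of the trial-wise noise
#'   (0 = noiseless).
#' @param exponent Compressive exponent \eqn{\gamma} of the latent axis.
#' @param seed Integer seed or \code{NULL}.
#' @return A data frame with columns \code{participant}, \code{block},
#'   \code{stimulus_first}, \code{stimulus_second} (condition indices 1--5)
#'   and \code{rating}, plus an attribute \code{"latent"} holding the latent
#'   positions.
#' @examples
#' r <- generate_ratings(n_participants = 2, n_blocks = 1,
#'                       scale_spread = 0, noise_cv = 0, seed = 1)
#' nrow(r)  # 2 participants x 20 ordered pairs
#' @export
generate_ratings <- function(stimuli = stimulus_set(), n_participants,
                             n_blocks = 5, scale_spread = 0.5,
                             noise_cv = 0.2, exponent = 0.3, seed = NULL) {
  stopifnot(n_participants >= 1, n_blocks >= 1, noise_cv >= 0,
            scale_spread >= 0, exponent > 0)
  latent <- stimuli$particle_size^exponent
  pairs <- expand.grid(stimulus_second = 1:5, stimulus_first = 1:5)
  pairs <- pairs[pairs$stimulus_first != pairs$stimulus_second,
                 c("stimulus_first", "stimulus_second")]
  d_true <- abs(latent[pairs$stimulus_first] - latent[pairs$stimulus_second])
  sdlog_noise <- sqrt(log(1 + noise_cv^2))

  with_seed(seed, {
    out <- lapply(seq_len(n_participants), function(p) {
      mult <- exp(stats::rnorm(1, 0, scale_spread))
      blocks <- lapply(seq_len(n_blocks), function(b) {
        ord <- sample.int(nrow(pairs))
        noise <- if (noise_cv > 0) {
          stats::rlnorm(nrow(pairs), meanlog = -sdlog_noise^2 / 2,
                        sdlog = sdlog_noise)
        } else rep(1, nrow(pairs))
        data.frame(
          participant = p, block = b,
          stimulus_first = pairs$stimulus_first[ord],
          stimulus_second = pairs$stimulus_second[ord],
          rating = mult * d_true[ord] * noise[ord],
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, blocks)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "latent") <- latent
    out
  })
}
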