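#' The five-roughness stimulus set
#'
#' Properties of the five sandpaper stimuli used throughout the analyses:
#' mean abrasive particle size in micrometres (the physical roughness
#' intensity), the colour that identifies each intensity, and the displayed
#' mean luminance of that colour. Particle size is the tactile property of
#' interest; luminance is the low-level visual covariate the confirmatory
#' analysis contrasts it against.
#'
#' @return A data frame with columns \code{condition} (1--5, ordered by
#'   increasing particle size), \code{particle_size} (micrometres),
#'   \code{color}, and \code{luminance} (photometer units).
#' @examples
#' stimulus_set()
#' @export
stimulus_set <- function() {
  data.frame(
    condition = 1:5,
    particle_size = c(0.3, 12, 40, 60, 100),
    color = c("white", "yellow", "blue", "gray", "brown"),
    luminance = c(42.3, 31.7, 14.5, 29.6, 29.1),
    stringsAsFactors = FALSE
  )
}

#' Default session timing
#'
#' Timing constants of the block design, in seconds: a 10 s baseline opens
#' each run, every trial occupies 12 s, and the stimulation itself lasts 3 s.
#' Visual trials present the video at the start of the trial (3 s stimulation
#' followed by 9 s fixation); tactile trials stimulate 9 s into the trial
#' (7 s rest plus 2 s finger placement precede the 3 s exploration). A run of
#' 25 trials therefore lasts 310 s.
#'
#' @return Named list with elements \code{baseline}, \code{trial},
#'   \code{stimulation}, \code{stim_offset_tactile}, \code{stim_offset_visual}
#'   and \code{run_length} (all seconds).
#' @export
default_timing <- function() {
  list(
    baseline = 10,
    trial = 12,
    stimulation = 3,
    stim_offset_tactile = 9,
    stim_offset_visual = 0,
    run_length = 10 + 25 * 12
  )
}
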