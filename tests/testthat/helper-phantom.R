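# Shared fixtures and independent brute-force oracles.

# small, fast phantom; noiseless unless a noise model is passed
tiny_config <- function(..., noise = phantom_noise(), seed = 1L,
                        duration = 8) {
  phantom_config(image_shape = c(32L, 96L), duration = duration,
                 vessel = list(centerline = rbind(c(16, 8), c(16, 88)),
                               diameter = 8),
                 transit_speed = 40, noise = noise, seed = seed, ...)
}

# brute-force ROI mean: explicit loop over every pixel of every frame
bf_roi_mean <- function(stack, roi) {
  d <- dim(stack$frames)
  sapply(seq_len(d[1]), function(k) {
    acc <- c(); n <- 0
    for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
      if ((r - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2) {
        acc <- c(acc, stack$frames[k, r, cc]); n <- n + 1
      }
    }
    sum(acc) / n
  })
}

# brute-force exact signed-rank p: enumerate all 2^m sign assignments
bf_signrank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# raw (unsubtracted) twin of a subtracted stack, for polarity tests
as_raw_run <- function(stack, baseline = 500,
                       polarity = c("negative_contrast",
                                    "positive_contrast")) {
  polarity <- match.arg(polarity)
  raw <- if (polarity == "negative_contrast") baseline - stack$frames
  else baseline + stack$frames
  frame_stack(raw, frame_interval = stack$frame_interval,
              pixel_size = stack$pixel_size, polarity = polarity,
              subtracted = FALSE)
}
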