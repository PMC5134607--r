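# Fixtures built in code.

make_daily <- function(params, noise_sigma = 0, seed = 1, days = 1:365) {
  set.seed(seed)
  tibble::tibble(doy = days,
                 gcc = gu_curve(days, params) + rnorm(length(days), 0, noise_sigma))
}

# A uniform-colour frame.
make_frame <- function(r, g, b, h = 4, w = 4, source_id = "fix") {
  px <- array(0L, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  structure(list(pixels = px, time = NULL, source_id = source_id),
            class = "pheno_frame")
}

full_roi <- function(h = 4, w = 4) {
  build_roi_mask(rbind(c(0, 0), c(0, w - 1), c(h - 1, w - 1), c(h - 1, 0)),
                 h, w, name = "full")
}

# Two-class 20 x 20 scene: vegetation patch over flat interspace.
two_class_spec <- function(side = 20, seed = 11, noise_sigma = 0.003) {
  cm <- matrix(2L, side, side)
  cm[(side %/% 4):(3 * side %/% 4), (side %/% 5):(4 * side %/% 5)] <- 1L
  scene_spec(side, side, cm,
             classes = list(
               vegetation = list(type = "gu",
                                 params = gu_presets()$sagebrush_canopy),
               interspace = list(type = "flat", level = 0.308)),
             noise_sigma = noise_sigma, seed = seed)
}
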