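## numerical oracle for the body-constrained touch probability: the
## hand-stimulus offset has independent coordinates whose densities are
## convolutions of uniforms; integrate the offset density over the 15 cm
## contact disc
touch_probability_oracle <- function(r = 0.15) {
  # dx = hand_x - vis_x: difference of two U(-0.6, 0.6), triangular
  fx <- function(d) pmax(0, (1.2 - abs(d)) / 1.2^2)
  # dy = hand_y - vis_y with hand_y ~ U(0, 0.6), vis_y ~ U(0, 1.2)
  fy <- function(d) {
    vapply(d, function(dd) {
      lo <- max(0, dd); hi <- min(0.6, dd + 1.2)
      if (lo >= hi) return(0)
      integrate(function(h) dunif(h, 0, 0.6) * dunif(h - dd, 0, 1.2),
                lo, hi)$value
    }, numeric(1))
  }
  integrate(Vectorize(function(dx) {
    ylim <- sqrt(r^2 - dx^2)
    fx(dx) * integrate(fy, -ylim, ylim)$value
  }), -r, r)$value
}
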