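# small grids shared across tests; odd pixel counts put a pixel exactly at 0
tiny_grid <- function() pixel_grid(30, 61)      # 1 deg/px
small_grid <- function() pixel_grid(60, 121)    # 1 deg/px, full FOV
std_grid <- function() pixel_grid(60, 200)    # standard 200-px stimulus grid

# orientation battery used throughout
ors12 <- seq(0, 165, by = 15)

# direct (rendered, per-pixel) response of a DoG unit for cross-checks
direct_dog_response <- function(grid, sc, ss, cs, center, stim) {
  unit_response(dog_rf(grid, sc, ss, cs, center = center), stim)
}
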