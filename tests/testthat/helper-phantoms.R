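# Reduced-size phantom configurations used by the unit tests; geometry is
# scaled down from the defaults to keep the suite fast while preserving
# rim/cytoplasm proportions.

smallCellConfig <- function(preset = NULL, seed = 1L, noise = "none", ...) {
  cellPhantomConfig(preset = preset, seed = seed, noise = noise,
                    imageSize = 160L, cellRadius = 70,
                    nucleusRadiusRange = c(35, 44), ...)
}

smallTimelapseConfig <- function(preset = NULL, seed = 1L,
                                 noise = "none", ...) {
  timelapsePhantomConfig(preset = preset, seed = seed, noise = noise,
                         imageSize = 128L, cellRadius = 56, ...)
}

trueBackground <- function(manifest) {
  bg <- expectedValues(manifest)$background
  list(donor = bg, acceptor = bg)
}
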