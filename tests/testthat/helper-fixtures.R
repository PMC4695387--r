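# Shared fixtures built in code.

HLUM <- semeco_markers()

# Synthetic full 16-metabotype composition assembled from the printed
# community breakdown: prototroph 26.7%, the nine individually reported
# type frequencies, the remaining single-auxotroph class filling its loss
# bin (39.9 - 19.7 - 11.1 - 0.4 = 8.7), and the four triple-auxotroph
# classes splitting their 6.6% bin equally. Mask bit order H, L, U, M.
community_fixture <- function() {
  w <- c("1111" = 26.7,
         "1101" = 19.7,  # ura3-delta
         "1011" = 11.1,  # leu2-delta
         "1110" = 0.4,   # met15-delta
         "0111" = 8.7,   # his3-delta (imputed from the loss-1 bin)
         "0101" = 8.1,   # LEU2 MET15
         "1001" = 10.1,  # HIS3 MET15
         "1010" = 1.1,   # HIS3 URA3
         "0011" = 0.2,   # URA3 MET15
         "0110" = 0.5,   # LEU2 URA3
         "1100" = 0.6,   # HIS3 LEU2
         "1000" = 1.65, "0100" = 1.65, "0010" = 1.65, "0001" = 1.65,
         "0000" = 6.1)
  validate_composition(w, HLUM)
}

# Random valid composition over a marker set.
random_composition <- function(markers) {
  space <- enumerate_metabotypes(markers)
  validate_composition(setNames(stats::runif(length(space)), space), markers)
}
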