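# Frozen junction linker joint paths and spins for the default
# cloverleaf geometry (r0 = 20 A, 8-nt linkers, arms at 180/90/0/270 deg),
# solved once offline against an all-base superset stem context plus the
# frozen 5-nt arm caps. Entries follow chain order (into arm 2, arm 3,
# arm 4, back to the acceptor).
FROZEN_JUNCTION <- list(
  list(
    joints = matrix(c(-12.412392, 4.032279, 8.960225, -11.892904, 5.241591, 9.870004, -10.049286, 9.829349, 11.448120, -9.520062, 11.303441, 11.775190, -7.907101, 16.180068, 12.519354, -7.481887, 17.717075, 12.648978, -6.298930, 22.770357, 12.605912, -5.920864, 24.252620, 12.136909, -4.741328, 28.547340, 9.472144, -4.471762, 29.798707, 8.512240, -3.583478, 33.470664, 4.953506, -3.344052, 34.214271, 3.557181, -2.958053, 34.805009, -1.584700, -2.837694, 34.344005, -3.112112, -1.400329, 32.650222, -7.802740, -0.668774, 32.571579, -9.223530, -0.462726, 27.446258, -10.014436, -1.098608, 26.364851, -9.021353), ncol = 3, byrow = TRUE),
    outDir = c(0.927156, -0.335657, 0.166479),
    spins = c(15, 330, 255, 255, 225, 180, 135, 270)),
  list(
    joints = matrix(c(9.495820, 12.412392, -2.524742, 9.399654, 10.873507, -2.097443, 4.610765, 10.413257, -0.150235, 3.754010, 10.597328, 1.188454, 4.468634, 10.975598, 6.315162, 4.655186, 11.057214, 7.902152, 5.994401, 13.759873, 12.125781, 6.793934, 14.259010, 13.418688, 10.526974, 14.490210, 17.017002, 11.921371, 14.331602, 17.785441, 16.910977, 13.229274, 18.694075, 18.443816, 12.813842, 18.499600, 22.919867, 11.370224, 16.304643, 24.012532, 10.944904, 15.215980, 26.372289, 9.743616, 10.752197, 26.969615, 9.336507, 9.324800, 26.768678, 8.729295, 4.174283, 26.364851, 8.700230, 2.626355), ncol = 3, byrow = TRUE),
    outDir = c(-0.235153, -0.969322, 0.071541),
    spins = c(285, 30, 330, 270, 240, 0, 315, 285)),
  list(
    joints = matrix(c(12.412392, 4.112650, -8.923621, 11.014701, 4.358023, -8.184533, 10.120222, 3.791475, -3.103605, 11.385247, 3.273120, -2.272328, 13.340440, 1.017441, 1.973380, 13.900290, 0.362301, 3.321475, 14.205348, -2.649528, 7.537247, 13.956488, -3.729115, 8.691613, 12.765604, -7.657755, 11.867221, 12.186278, -8.931173, 12.643614, 9.576942, -13.103121, 14.293803, 8.605366, -14.345802, 14.561730, 4.959049, -18.039097, 14.590817, 3.662504, -18.963205, 14.432716, -0.686469, -21.692818, 13.676046, -2.009532, -22.525334, 13.334838, -3.871272, -25.432818, 9.459613, -3.991260, -26.364851, 8.164655), ncol = 3, byrow = TRUE),
    outDir = c(0.744490, -0.583057, -0.325238),
    spins = c(285, 255, 135, 90, 60, 345, 225, 180)),
  list(
    joints = matrix(c(8.146127, -12.412392, 5.494135, 8.231104, -11.812782, 6.975096, 4.405711, -9.194357, 9.309002, 2.864542, -8.970335, 9.675898, -1.306386, -6.371652, 11.345363, -2.591795, -5.522024, 11.776475, -6.800193, -2.763532, 13.048093, -8.161537, -1.976441, 13.343440, -12.398311, 0.878407, 14.258041, -13.506334, 2.024442, 14.395477, -16.952111, 5.494682, 12.657387, -17.637598, 6.544810, 11.663737, -18.569814, 10.096914, 7.996254, -18.869436, 10.813340, 6.597340, -19.940324, 11.107765, 1.527486, -20.635798, 10.979024, 0.092306, -24.898144, 9.338399, -2.372987, -26.364851, 8.723484, -2.548052), ncol = 3, byrow = TRUE),
    outDir = c(0.528745, 0.847799, -0.040804),
    spins = c(75, 315, 285, 180, 300, 285, 60, 60))
)
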