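# Frozen hairpin-cap joint paths and spins (loop lengths 3..8) in the
# stem-top template frame: solved once, offline, by the inverse-kinematics
# + clash-relaxation machinery with all-A loops against an all-base
# superset stem context. The 5-nt cap (used by the default cloverleaf)
# additionally respects a deep-stem context and a lateral-extent bound so
# multi-helix assemblies stay collision-free.
FROZEN_CAPS <- list(
  "3" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 5.973862, 1.638289, 2.418972, 10.349833, -0.043270, 0.191835, 10.950911, -1.207252, -0.726779, 12.646152, -5.347551, -3.357555, 12.968707, -6.454455, -4.466935, 13.464528, -9.012609, -8.955466, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(0.090316, -0.738015, 0.668712),
    spins = c(195, 330, 285)),
  "4" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 5.324259, 2.188879, 2.670042, 9.821199, 3.094272, 0.242141, 10.869008, 2.466657, -0.791394, 14.462236, 0.555045, -4.011854, 15.439150, -0.387263, -4.859022, 17.826068, -4.338242, -7.231636, 18.257388, -5.545556, -8.188900, 14.922105, -8.766641, -10.520724, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(0.483513, -0.478750, 0.732812),
    spins = c(315, 180, 45, 315)),
  "5" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 4.249782, -0.111037, 3.489174, 3.202474, -5.170131, 2.993569, 3.195577, -5.954459, 1.599015, 2.886294, -8.983044, -2.604428, 2.681294, -9.953940, -3.859551, 4.416684, -11.069714, -8.621943, 5.398698, -10.794879, -9.854872, 8.458839, -9.474400, -13.833411, 8.997990, -9.018375, -15.269154, 12.926342, -9.226094, -11.883625, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(-0.876479, -0.253991, -0.408991),
    spins = c(210, 180, 300, 270, 90)),
  "6" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 4.344740, 2.401852, 2.263790, 2.683404, 4.665424, -2.101196, 2.115717, 4.489187, -3.586683, 0.663428, 3.578927, -8.485580, 0.266006, 3.234959, -9.996786, -0.499680, 1.137332, -14.681932, -0.136561, 0.044409, -15.792635, 2.154006, -4.462073, -16.968149, 3.221280, -5.644461, -17.119428, 7.486091, -8.167912, -15.576546, 8.533377, -8.464008, -14.403721, 12.960491, -8.789708, -11.714579, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(-0.685082, -0.720412, 0.108027),
    spins = c(75, 45, 30, 345, 105, 0)),
  "7" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 4.420233, 2.319225, 2.778318, 6.676806, 6.644294, 1.006720, 7.362391, 7.833457, 0.184610, 10.525907, 10.560580, -2.896278, 11.705932, 10.743371, -3.961233, 15.050628, 10.462251, -7.919880, 15.926001, 9.782634, -9.073935, 18.352141, 6.653538, -12.429454, 19.300808, 5.801951, -13.396320, 19.674734, 0.758850, -14.564316, 19.013632, -0.644922, -14.173972, 18.678621, -5.671251, -12.924694, 18.770705, -6.966767, -11.990264, 15.007717, -9.834088, -9.855950, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(-0.753187, 0.137743, -0.643224),
    spins = c(225, 120, 0, 270, 30, 30, 135)),
  "8" = list(
    joints = matrix(c(4.608184, 0.823852, 2.241164, 3.973998, 2.184471, 2.794809, 2.619942, 6.271870, -0.102881, 2.284419, 6.773710, -1.584630, 1.577324, 8.213321, -6.520665, 1.615164, 8.440455, -8.104009, 2.262418, 8.643578, -13.249562, 2.636113, 8.532607, -14.801347, 4.788078, 6.691148, -19.150483, 5.331089, 5.825791, -20.381862, 8.483730, 2.724465, -23.098393, 9.423804, 1.635518, -22.398066, 11.182308, -3.189266, -21.645723, 11.707138, -4.573687, -21.039149, 13.128977, -8.470337, -17.919630, 13.886780, -9.685856, -17.206714, 13.820775, -9.460551, -12.021950, 13.544550, -9.577433, -10.450314), ncol = 3, byrow = TRUE),
    outDir = c(0.832133, 0.534497, 0.147878),
    spins = c(255, 195, 165, 45, 285, 210, 150, 255))
)
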