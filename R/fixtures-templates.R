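# Idealized full-atom ribonucleotide templates and A-form helix frames for
# the synthetic structure generator. The backbone is built from canonical
# A-form torsions by natural-extension placement; bond angles were calibrated
# (once, offline, deterministically) so that the screw transform relating
# consecutive residues has twist 32.7 degrees and rise 2.81 Angstrom. Base
# placement parameters (sugar ring orientation, glycosidic rotations and the
# duplex dyad) were fitted once to idealized Watson-Crick hydrogen-bond
# geometry and are frozen below. The resulting nucleotides are idealized and
# synthetic: chemically plausible, not refined against any experimental
# structure.

AFORM_TORSIONS <- c(alpha = -68, beta = 178, gamma = 54, delta = 82,
                    epsilon = -153, zeta = -71)

AFORM_ANGLES <- c(PO5C5 = 120.3244840231, O5C5C4 = 112.1347612964,
                  C5C4C3 = 116.3898835363, C4C3O3 = 111.2096682376,
                  C3O3P = 118.6064478832, O3PO5 = 103.4872341849)

# frozen base-placement parameters (see scratch fit): sugar ring twist psi,
# purine and pyrimidine glycosidic rotations (deg), dyad azimuth (rad) and
# axial offset (Angstrom); base 2D templates are used in mirrored form.
PAIRFIT <- list(psi = 124.0006323592, chiPur = 84.1258342439,
                chiPyr = 264.0611003254, phi = 19.7290134415,
                h = -11.6181311657, mirror = TRUE)

HELIX_TWIST <- 32.7   # degrees per step
HELIX_RISE <- 2.81    # Angstrom per step

BASE_ATOM_NAMES <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                     "O2", "O4", "N4", "O6", "N6", "N2",
                     "H1", "H3", "H21", "H22", "H41", "H42", "H61", "H62")

# ---- backbone -------------------------------------------------------------

buildBackboneCore <- function() {
  TOR <- AFORM_TORSIONS; ang <- AFORM_ANGLES
  P   <- c(0, 0, 0)
  O5p <- c(1.593, 0, 0)
  a <- ang[["PO5C5"]] * pi/180
  C5p <- O5p + 1.440 * c(-cos(a), sin(a), 0)
  C4p <- nerfPlace(P,   O5p, C5p, 1.510, ang[["O5C5C4"]], TOR[["beta"]])
  C3p <- nerfPlace(O5p, C5p, C4p, 1.524, ang[["C5C4C3"]], TOR[["gamma"]])
  O3p <- nerfPlace(C5p, C4p, C3p, 1.423, ang[["C4C3O3"]], TOR[["delta"]])
  OP1 <- nerfPlace(C5p, O5p, P,   1.485, 108.0, TOR[["alpha"]] + 120)
  OP2 <- nerfPlace(C5p, O5p, P,   1.485, 108.0, TOR[["alpha"]] - 120)
  Pn  <- nerfPlace(C4p, C3p, O3p, 1.607, ang[["C3O3P"]], TOR[["epsilon"]])
  O5n <- nerfPlace(C3p, O3p, Pn,  1.593, ang[["O3PO5"]], TOR[["zeta"]])
  C5n <- nerfPlace(O3p, Pn,  O5n, 1.440, ang[["PO5C5"]], TOR[["alpha"]])
  S <- kabschFit(rbind(P, O5p, C5p), rbind(Pn, O5n, C5n))
  bb <- rbind("P" = P, "OP1" = OP1, "OP2" = OP2, "O5'" = O5p, "C5'" = C5p,
              "C4'" = C4p, "C3'" = C3p, "O3'" = O3p)
  list(bb = bb, S = S)
}

# least-squares rigid fit Q ~ R P + t (rows = points); proper rotation
kabschFit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

applyRT <- function(M, R, t) sweep(M %*% t(R), 2, -t)

composeRT <- function(a, b) {  # apply b after a
  list(R = b$R %*% a$R, t = as.vector(b$R %*% a$t) + b$t)
}

invertRT <- function(a) list(R = t(a$R), t = -as.vector(t(a$R) %*% a$t))

identityRT <- function() list(R = diag(3), t = c(0, 0, 0))

powerRT <- function(a, k) {
  out <- identityRT()
  if (k >= 0) { for (i in seq_len(k)) out <- composeRT(out, a) }
  else { ai <- invertRT(a); for (i in seq_len(-k)) out <- composeRT(out, ai) }
  out
}

screwParams <- function(S) {
  tr <- max(-1, min(3, sum(diag(S$R))))
  theta <- acos((tr - 1)/2)
  ev <- eigen(S$R)
  axdir <- unitv(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
  rise <- sum(S$t * axdir)
  if (rise < 0) { axdir <- -axdir; rise <- -rise }
  A <- diag(3) - S$R
  axpt <- qr.solve(qr(A, LAPACK = TRUE), S$t - rise * axdir)
  list(twist = theta * 180/pi, rise = rise, axdir = axdir, axpt = axpt)
}

# ---- sugar ring -----------------------------------------------------------

buildSugar <- function(bb, psi) {
  C4p <- bb["C4'", ]; C3p <- bb["C3'", ]; C5p <- bb["C5'", ]
  e <- unitv(C3p - C4p)
  r0 <- (C5p - C4p); r0 <- unitv(r0 - e * sum(r0 * e))
  u <- as.vector(rotAxis(e, psi * pi/180) %*% r0)
  mid <- (C4p + C3p)/2
  R <- (1.524/2) / sin(36 * pi/180)
  ctr <- mid + (R * cos(36 * pi/180)) * u
  nrm <- unitv(cross3(e, u))
  ex <- unitv(C4p - ctr); ey <- cross3(nrm, ex)
  v3 <- C3p - ctr
  step <- atan2(sum(v3 * ey), sum(v3 * ex))
  ringAt <- function(th) ctr + R * (cos(th) * ex + sin(th) * ey)
  O4p <- ringAt(-step); C1p <- ringAt(-2 * step); C2p <- ringAt(-3 * step)
  nb <- nrm; if (sum(nb * (C5p - C4p)) < 0) nb <- -nb
  O2p <- C2p + 1.414 * unitv(0.55 * unitv(C2p - ctr) - 0.835 * nb)
  rbind(bb, "O4'" = O4p, "C1'" = C1p, "C2'" = C2p, "O2'" = O2p)
}

# ---- planar base templates ------------------------------------------------

# 2D construction: glycosidic nitrogen at the origin, base extending toward
# +x; pyrimidines are regular hexagons, purines a fused regular
# pentagon/hexagon; exocyclic atoms placed radially. Polar hydrogens only.
baseTemplate2d <- function(base, mirror = FALSE) {
  deg <- pi/180
  rot2 <- function(v, a) c(cos(a)*v[1] - sin(a)*v[2], sin(a)*v[1] + cos(a)*v[2])
  if (base %in% c("C", "U")) {
    ctr <- c(1.39, 0)
    angs <- c(180, 120, 60, 0, -60, -120)
    vs <- t(vapply(angs, function(a) ctr + 1.39 * c(cos(a*deg), sin(a*deg)),
                   numeric(2)))
    rownames(vs) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    rad <- function(nm) unitv(vs[nm, ] - ctr)
    ats <- rbind(vs, O2 = vs["C2", ] + 1.23 * rad("C2"))
    if (base == "U") {
      ats <- rbind(ats, O4 = vs["C4", ] + 1.23 * rad("C4"),
                   H3 = vs["N3", ] + 1.01 * rad("N3"))
    } else {
      N4 <- vs["C4", ] + 1.34 * rad("C4")
      ats <- rbind(ats, N4 = N4,
                   H41 = N4 + 1.01 * rot2(rad("C4"), 60*deg),
                   H42 = N4 + 1.01 * rot2(rad("C4"), -60*deg))
    }
    glyco <- "N1"
  } else {
    pr <- 1.38 / (2 * sin(36*deg))
    pctr <- c(pr, 0)
    pv <- t(vapply(c(180, 108, 36, -36, -108),
                   function(a) pctr + pr * c(cos(a*deg), sin(a*deg)),
                   numeric(2)))
    rownames(pv) <- c("N9", "C8", "N7", "C5", "C4")
    mid <- (pv["C4", ] + pv["C5", ])/2
    dirOut <- unitv(mid - pctr)
    d45 <- vnorm(pv["C4", ] - pv["C5", ])
    hctr <- mid + dirOut * sqrt(d45^2 - (d45/2)^2)
    th4 <- atan2(pv["C4", 2] - hctr[2], pv["C4", 1] - hctr[1])
    th5 <- atan2(pv["C5", 2] - hctr[2], pv["C5", 1] - hctr[1])
    stepd <- th5 - th4
    while (stepd > pi) stepd <- stepd - 2*pi
    while (stepd < -pi) stepd <- stepd + 2*pi
    hexAt <- function(k) hctr + d45 * c(cos(th4 - k*stepd), sin(th4 - k*stepd))
    ats <- rbind(pv, N3 = hexAt(1), C2 = hexAt(2), N1 = hexAt(3), C6 = hexAt(4))
    rad <- function(nm) unitv(ats[nm, ] - hctr)
    if (base == "A") {
      N6 <- ats["C6", ] + 1.34 * rad("C6")
      ats <- rbind(ats, N6 = N6,
                   H61 = N6 + 1.01 * rot2(rad("C6"), 60*deg),
                   H62 = N6 + 1.01 * rot2(rad("C6"), -60*deg))
    } else {
      N2 <- ats["C2", ] + 1.34 * rad("C2")
      ats <- rbind(ats, O6 = ats["C6", ] + 1.23 * rad("C6"),
                   H1 = ats["N1", ] + 1.01 * rad("N1"),
                   N2 = N2,
                   H21 = N2 + 1.01 * rot2(rad("C2"), 60*deg),
                   H22 = N2 + 1.01 * rot2(rad("C2"), -60*deg))
    }
    glyco <- "N9"
  }
  if (mirror) ats[, 2] <- -ats[, 2]
  list(atoms = ats, glyco = glyco)
}

attachBase3d <- function(sugar, base, chi, mirror = TRUE, extraRot = NULL) {
  C1p <- sugar["C1'", ]; O4p <- sugar["O4'", ]; C2p <- sugar["C2'", ]
  C4p <- sugar["C4'", ]; C3p <- sugar["C3'", ]
  ctr <- (C1p + C2p + C3p + C4p + O4p)/5
  nrm <- unitv(cross3(C3p - C4p, O4p - C4p))
  if (sum(nrm * (sugar["C5'", ] - C4p)) < 0) nrm <- -nrm
  el <- 35 * pi/180
  N <- C1p + 1.47 * unitv(cos(el) * unitv(C1p - ctr) + sin(el) * nrm)
  a1 <- unitv(N - C1p)
  ref <- unitv(cross3(a1, nrm))
  a2 <- as.vector(rotAxis(a1, chi * pi/180) %*% ref)
  b2 <- baseTemplate2d(base, mirror)
  xy <- b2$atoms
  m3 <- outer(xy[, 1], a1) + outer(xy[, 2], a2)
  m3 <- sweep(m3, 2, -N)
  rownames(m3) <- rownames(xy)
  if (!is.null(extraRot)) {
    # rotate base atoms about the glycosidic nitrogen (wobble adjustment)
    m3 <- sweep(sweep(m3, 2, N) %*% t(extraRot), 2, -N)
  }
  m3
}

# ---- assembled templates (cached) -----------------------------------------

.templateCache <- new.env(parent = emptyenv())

# Wobble adjustment: a small rigid-body transform (rotation vector about
# the C1' atom plus translation, fitted once offline) applied to the whole
# uridine template, shifting it from the Watson-Crick register into the
# G.U wobble hydrogen-bonding register while keeping the backbone links to
# the neighboring residues intact.
WOBBLE_RT <- list(rotvec = c(-0.0767680347, 0.0835628265, -0.0064224138),
                  shift = c(-0.3714910745, -0.5153044203, -0.2800139641))

applyWobble <- function(U) {
  v <- WOBBLE_RT$rotvec
  th <- sqrt(sum(v^2))
  R <- if (th < 1e-12) diag(3) else rotAxis(v / th, th)
  ctr <- U["C1'", ]
  sweep(sweep(sweep(U, 2, ctr) %*% t(R), 2, -ctr), 2, -WOBBLE_RT$shift)
}

#' @keywords internal
ntTemplates <- function() {
  if (!is.null(.templateCache$tpl)) return(.templateCache$tpl)
  core <- buildBackboneCore()
  sp <- screwParams(core$S)
  sug <- buildSugar(core$bb, PAIRFIT$psi)
  res1 <- lapply(c(A = "A", G = "G", C = "C", U = "U"), function(b) {
    chi <- if (b %in% c("A", "G")) PAIRFIT$chiPur else PAIRFIT$chiPyr
    rbind(sug, attachBase3d(sug, b, chi, PAIRFIT$mirror))
  })
  res1$Uw <- applyWobble(res1$U)
  # duplex dyad: two-fold rotation about an axis perpendicular to (and
  # intersecting) the helix axis
  refp <- c(1, 0, 0) - sp$axdir * sum(sp$axdir * c(1, 0, 0))
  d <- as.vector(rotAxis(sp$axdir, PAIRFIT$phi) %*% unitv(refp))
  q0 <- sp$axpt + PAIRFIT$h * sp$axdir
  Rd <- rotAxis(d, pi)
  dyad <- list(R = Rd, t = q0 - as.vector(Rd %*% q0))
  res2 <- lapply(res1, function(m) applyRT(m, dyad$R, dyad$t))
  # axis point at the axial height of the level-0 base pair (anchor for
  # placing helices at prescribed positions)
  ctr0 <- colMeans(rbind(res1$G, res2$C))
  axisAnchor <- sp$axpt + sum((ctr0 - sp$axpt) * sp$axdir) * sp$axdir
  tpl <- list(S = core$S, screw = sp, dyad = dyad, res1 = res1, res2 = res2,
              axisAnchor = axisAnchor)
  .templateCache$tpl <- tpl
  tpl
}

#' Canonical backbone torsions of the synthetic A-form generator
#'
#' @return named numeric vector (degrees): alpha, beta, gamma, delta,
#'   epsilon, zeta
#' @export
aformTorsions <- function() AFORM_TORSIONS
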