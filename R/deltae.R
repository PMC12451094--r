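#' CIEDE2000 colour difference
#'
#' The current CIE recommendation for perceptual colour difference between
#' two CIELAB colours, including the G rescaling of the a* axis (which
#' corrects chroma non-uniformity near the neutral axis), the lightness,
#' chroma and hue weighting functions, the mean-hue averaging rules, and the
#' rotation term `R_T` that corrects the blue region. Parametric factors
#' default to `k_L = k_C = k_H = 1` (reference viewing conditions).
#'
#' @param lab1,lab2 [lab_color()] objects (same illuminant and observer), or
#'   numeric length-3 vectors `c(L, a, b)`.
#' @param kL,kC,kH Parametric weighting factors.
#' @return The colour difference (non-negative scalar; 0 iff the inputs are
#'   identical).
#' @examples
#' delta_e2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485)) # 2.0425
#' @export
delta_e2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  p1 <- as_lab_triplet(lab1); p2 <- as_lab_triplet(lab2)
  if (inherits(lab1, "lab_color") && inherits(lab2, "lab_color") &&
      (lab1$illuminant != lab2$illuminant || lab1$observer != lab2$observer))
    stop("colours must share illuminant and observer", call. = FALSE)

  L1 <- p1[1]; a1 <- p1[2]; b1 <- p1[3]
  L2 <- p2[1]; a2 <- p2[2]; b2 <- p2[3]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- if (a1p == 0 && b1 == 0) 0 else (atan2(b1, a1p) * 180 / pi) %% 360
  h2p <- if (a2p == 0 && b2 == 0) 0 else (atan2(b2, a2p) * 180 / pi) %% 360

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0
         else if (abs(h2p - h1p) <= 180) h2p - h1p
         else if (h2p - h1p > 180) h2p - h1p - 360
         else h2p - h1p + 360
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p
         else if (abs(h1p - h2p) <= 180) (h1p + h2p) / 2
         else if (h1p + h2p < 360) (h1p + h2p + 360) / 2
         else (h1p + h2p - 360) / 2

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
        0.24 * cos(2 * hbp * pi / 180) +
        0.32 * cos((3 * hbp + 6) * pi / 180) -
        0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
       RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

as_lab_triplet <- function(x) {
  if (inherits(x, "lab_color")) return(c(x$L, x$a, x$b))
  v <- as.numeric(unlist(x))
  if (length(v) != 3) stop("expected a lab_color or c(L, a, b)", call. = FALSE)
  v
}
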