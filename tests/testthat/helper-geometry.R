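## Constructors for analytic test fixtures: ellipse/annulus contours and
## minimal annotations, all in the package's pixel convention.

ellipseContour <- function(cx, cy, a, b, angleDeg = 0, n = 128) {
  ## angleDeg: rotation of the a-axis from +x, measured towards +y (down)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rot <- angleDeg * pi / 180
  u <- c(cos(rot), sin(rot)); v <- c(-sin(rot), cos(rot))
  cbind(cx + a * cos(th) * u[1] + b * sin(th) * v[1],
        cy + a * cos(th) * u[2] + b * sin(th) * v[2])
}

## half-annulus crescent between radii r1 < r2, centred on (cx, cy),
## opening towards +x (temporal side), as a closed polygon
halfAnnulusContour <- function(cx, cy, r1, r2, n = 180) {
  th <- seq(-pi / 2, pi / 2, length.out = n)
  rbind(cbind(cx + r2 * cos(th), cy + r2 * sin(th)),
        cbind(cx + r1 * cos(rev(th)), cy + r1 * sin(rev(th))))
}

## minimal annotation: circular or elliptical disc + optional PPA + fovea
makeAnnotation <- function(disc, ppa = matrix(numeric(), 0, 2),
                           foveaXY, maskDim = c(256, 256)) {
  fundusAnnotation(discContour = disc, ppaContour = ppa, fovea = foveaXY,
                   vesselMask = matrix(FALSE, maskDim[1], maskDim[2]),
                   eye = "right")
}

## magnification model with unit camera constant at a given scale
magAtScale <- function(scaleMmPerPx, al = 25.51) {
  littmannScale(al, scaleMmPerPx / (0.01306 * (al - 1.82)))
}
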