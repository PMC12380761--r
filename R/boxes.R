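# ---------------------------------------------------------------------------
# Box geometry.  Boxes are matrices with columns (x1, y1, x2, y2) unless a
# function says otherwise; normalized center-format boxes are (cx, cy, w, h)
# in [0, 1].  Pixel centers sit at half-integer offsets; images are row-major
# with the origin at the top-left corner.
# ---------------------------------------------------------------------------

#' Convert center-format boxes to corner format
#' @param b matrix with columns (cx, cy, w, h).
#' @return matrix with columns (x1, y1, x2, y2).
#' @export
cxcywhToXyxy <- function(b) {
  b <- rbind(b)
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' Convert corner-format boxes to center format
#' @param b matrix with columns (x1, y1, x2, y2).
#' @return matrix with columns (cx, cy, w, h).
#' @export
xyxyToCxcywh <- function(b) {
  b <- rbind(b)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

#' Pairwise intersection-over-union
#'
#' @param a,b corner-format box matrices (na x 4, nb x 4).
#' @return an na x nb matrix of IoU values.
#' @export
boxIoU <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  na <- nrow(a); nb <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], na, nb), matrix(b[, 1], na, nb, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], na, nb), matrix(b[, 2], na, nb, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], na, nb), matrix(b[, 3], na, nb, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], na, nb), matrix(b[, 4], na, nb, byrow = TRUE))
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  uni <- matrix(aa, na, nb) + matrix(ab, na, nb, byrow = TRUE) - inter
  inter / pmax(uni, 1e-12)
}

# Complete IoU between matched rows of p and t (both n x 4 xyxy), plus the
# analytic gradient of CIoU w.r.t. the four coordinates of p.
ciouWithGrad <- function(p, t, eps = 1e-9) {
  p <- rbind(p); t <- rbind(t)
  n <- nrow(p)
  px1 <- p[, 1]; py1 <- p[, 2]; px2 <- p[, 3]; py2 <- p[, 4]
  tx1 <- t[, 1]; ty1 <- t[, 2]; tx2 <- t[, 3]; ty2 <- t[, 4]
  pw <- px2 - px1; ph <- py2 - py1
  tw <- tx2 - tx1; th <- ty2 - ty1
  ix1 <- pmax(px1, tx1); iy1 <- pmax(py1, ty1)
  ix2 <- pmin(px2, tx2); iy2 <- pmin(py2, ty2)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  uni <- pw * ph + tw * th - inter
  iou <- inter / (uni + eps)
  # enclosing box diagonal and center distance
  cx1 <- pmin(px1, tx1); cy1 <- pmin(py1, ty1)
  cx2 <- pmax(px2, tx2); cy2 <- pmax(py2, ty2)
  cw <- cx2 - cx1; ch <- cy2 - cy1
  c2 <- cw^2 + ch^2 + eps
  dx <- (px1 + px2 - tx1 - tx2) / 2
  dy <- (py1 + py2 - ty1 - ty2) / 2
  rho2 <- dx^2 + dy^2
  # aspect-ratio term
  v <- (4 / pi^2) * (atan(tw / pmax(th, eps)) - atan(pw / pmax(ph, eps)))^2
  alpha <- v / (1 - iou + v + eps)
  ciou <- iou - rho2 / c2 - alpha * v
  # --- gradients w.r.t. (px1, py1, px2, py2) -------------------------------
  # d inter / d coords
  di_dx1 <- ifelse(iw > 0 & ih > 0 & px1 > tx1, -ih, 0)
  di_dy1 <- ifelse(iw > 0 & ih > 0 & py1 > ty1, -iw, 0)
  di_dx2 <- ifelse(iw > 0 & ih > 0 & px2 < tx2, ih, 0)
  di_dy2 <- ifelse(iw > 0 & ih > 0 & py2 < ty2, iw, 0)
  # d area_p / d coords
  da_dx1 <- -ph; da_dy1 <- -pw; da_dx2 <- ph; da_dy2 <- pw
  du <- function(di, da) da - di
  diou_d <- function(di, da) (di * (uni + eps) - inter * du(di, da)) / (uni + eps)^2
  giou_x1 <- diou_d(di_dx1, da_dx1); giou_y1 <- diou_d(di_dy1, da_dy1)
  giou_x2 <- diou_d(di_dx2, da_dx2); giou_y2 <- diou_d(di_dy2, da_dy2)
  # rho2 / c2 term
  drho_dx1 <- dx; drho_dy1 <- dy; drho_dx2 <- dx; drho_dy2 <- dy  # times 1
  dcw_dx1 <- ifelse(px1 < tx1, -1, 0); dcw_dx2 <- ifelse(px2 > tx2, 1, 0)
  dch_dy1 <- ifelse(py1 < ty1, -1, 0); dch_dy2 <- ifelse(py2 > ty2, 1, 0)
  dc2_dx1 <- 2 * cw * dcw_dx1; dc2_dx2 <- 2 * cw * dcw_dx2
  dc2_dy1 <- 2 * ch * dch_dy1; dc2_dy2 <- 2 * ch * dch_dy2
  gpen_x1 <- (drho_dx1 * c2 - rho2 * dc2_dx1) / c2^2
  gpen_y1 <- (drho_dy1 * c2 - rho2 * dc2_dy1) / c2^2
  gpen_x2 <- (drho_dx2 * c2 - rho2 * dc2_dx2) / c2^2
  gpen_y2 <- (drho_dy2 * c2 - rho2 * dc2_dy2) / c2^2
  # aspect term (alpha treated as constant, the usual convention)
  ph_s <- pmax(ph, eps)
  datan <- -1 / (1 + (pw / ph_s)^2)
  dv_dw <- (8 / pi^2) * (atan(tw / pmax(th, eps)) - atan(pw / ph_s)) * datan / ph_s
  dv_dh <- (8 / pi^2) * (atan(tw / pmax(th, eps)) - atan(pw / ph_s)) * datan *
    (-pw / ph_s^2)
  gv_x1 <- -alpha * dv_dw * (-1); gv_x2 <- -alpha * dv_dw
  gv_y1 <- -alpha * dv_dh * (-1); gv_y2 <- -alpha * dv_dh
  list(ciou = ciou, iou = iou, v = v, alpha = alpha, rho2c2 = rho2 / c2,
       grad = cbind(giou_x1 - gpen_x1 + gv_x1,
                    giou_y1 - gpen_y1 + gv_y1,
                    giou_x2 - gpen_x2 + gv_x2,
                    giou_y2 - gpen_y2 + gv_y2))
}

#' Complete IoU of matched box pairs
#'
#' @param p,t corner-format box matrices of equal row count.
#' @return numeric vector of CIoU values (IoU minus center-distance and
#'   aspect-ratio penalties).
#' @export
boxCIoU <- function(p, t) ciouWithGrad(p, t)$ciou
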