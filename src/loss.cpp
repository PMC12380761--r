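// Detection-loss core for one image: task-aligned assignment, CIoU box term,
// binned-distribution (DFL) term, BCE class term, with gradients w.r.t. the
// raw head outputs.  Mirrors the reference R implementation (assignTargets /
// detectionLossImage); cross-checked against it in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double iou_pair(const double* a, const double* b) {
  double ix1 = std::max(a[0], b[0]), iy1 = std::max(a[1], b[1]);
  double ix2 = std::min(a[2], b[2]), iy2 = std::min(a[3], b[3]);
  double iw = std::max(ix2 - ix1, 0.0), ih = std::max(iy2 - iy1, 0.0);
  double inter = iw * ih;
  double ua = (a[2] - a[0]) * (a[3] - a[1]) + (b[2] - b[0]) * (b[3] - b[1]) - inter;
  return inter / std::max(ua, 1e-12);
}

List cpp_det_loss_image(NumericMatrix clsp, NumericMatrix prob,
                        NumericMatrix dist, NumericVector cx, NumericVector cy,
                        NumericVector stride, NumericMatrix gtb,
                        IntegerVector gtcls, int topk, double alpha,
                        double beta, int reg_max, double input,
                        double w_box, double w_dfl, double w_cls);

// [[Rcpp::export]]
List cpp_det_loss_image(NumericMatrix clsp, NumericMatrix prob,
                        NumericMatrix dist, NumericVector cx, NumericVector cy,
                        NumericVector stride, NumericMatrix gtb,
                        IntegerVector gtcls, int topk, double alpha,
                        double beta, int reg_max, double input,
                        double w_box, double w_dfl, double w_cls) {
  const int ncell = clsp.nrow(), nc = clsp.ncol();
  const int m = gtb.nrow();
  // decoded boxes (normalized xyxy)
  std::vector<double> bx(4 * (size_t)ncell);
  for (int i = 0; i < ncell; ++i) {
    bx[4 * (size_t)i + 0] = (cx[i] - dist(i, 0) * stride[i]) / input;
    bx[4 * (size_t)i + 1] = (cy[i] - dist(i, 1) * stride[i]) / input;
    bx[4 * (size_t)i + 2] = (cx[i] + dist(i, 2) * stride[i]) / input;
    bx[4 * (size_t)i + 3] = (cy[i] + dist(i, 3) * stride[i]) / input;
  }
  // --- assignment --------------------------------------------------------
  std::vector<int> assign(ncell, -1);
  std::vector<double> tscore(ncell, 0.0), iou_as(ncell, 0.0);
  if (m > 0) {
    arma::mat iou(ncell, m), metric(ncell, m);
    for (int j = 0; j < m; ++j) {
      double g[4] = { gtb(j, 0), gtb(j, 1), gtb(j, 2), gtb(j, 3) };
      for (int i = 0; i < ncell; ++i) {
        double xi = cx[i] / input, yi = cy[i] / input;
        bool inb = xi > g[0] && xi < g[2] && yi > g[1] && yi < g[3];
        double io = iou_pair(&bx[4 * (size_t)i], g);
        iou(i, j) = io;
        double sc = std::min(std::max(clsp(i, gtcls[j]), 1e-9), 1.0);
        metric(i, j) = inb ? std::pow(sc, alpha) * std::pow(std::max(io, 0.0), beta) : 0.0;
      }
    }
    std::vector<std::vector<int> > cand(m);
    for (int j = 0; j < m; ++j) {
      std::vector<int> idx;
      for (int i = 0; i < ncell; ++i) if (metric(i, j) > 0) idx.push_back(i);
      if (idx.empty()) {
        // fallback: best overlap, else nearest center
        int best = -1; double bv = 0;
        for (int i = 0; i < ncell; ++i)
          if (iou(i, j) > bv) { bv = iou(i, j); best = i; }
        if (best < 0) {
          double gx = (gtb(j, 0) + gtb(j, 2)) / 2, gy = (gtb(j, 1) + gtb(j, 3)) / 2;
          double bd = 1e30;
          for (int i = 0; i < ncell; ++i) {
            double dx = cx[i] / input - gx, dy = cy[i] / input - gy;
            double d2 = dx * dx + dy * dy;
            if (d2 < bd) { bd = d2; best = i; }
          }
        }
        metric(best, j) = 1e-9;
        cand[j].push_back(best);
        continue;
      }
      int k = std::min((int)idx.size(), topk);
      // stable partial sort: by metric desc, ties by lower index
      std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                        [&](int a, int b) {
                          if (metric(a, j) != metric(b, j))
                            return metric(a, j) > metric(b, j);
                          return a < b;
                        });
      idx.resize(k);
      cand[j] = idx;
    }
    // conflict resolution: a cell keeps the gt with highest IoU
    std::vector<int> claimed(ncell, -1);
    for (int j = 0; j < m; ++j)
      for (int i : cand[j]) {
        if (claimed[i] < 0 || iou(i, j) > iou(i, claimed[i])) claimed[i] = j;
      }
    for (int j = 0; j < m; ++j) {
      double mmax = 0, imax = 0;
      std::vector<int> rows;
      for (int i : cand[j]) if (claimed[i] == j) {
        rows.push_back(i);
        mmax = std::max(mmax, metric(i, j));
        imax = std::max(imax, iou(i, j));
      }
      for (int i : rows) {
        assign[i] = j;
        tscore[i] = metric(i, j) / (mmax + 1e-9) * std::max(imax, 1e-9);
        iou_as[i] = iou(i, j);
      }
    }
  }
  double tsum = 0;
  int nfg = 0;
  for (int i = 0; i < ncell; ++i) if (assign[i] >= 0) { tsum += tscore[i]; ++nfg; }
  double norm = std::max(tsum, 1.0);
  // --- classification (BCE over all cells/classes) -----------------------
  NumericMatrix g_cls(ncell, nc);
  double cls_loss = 0;
  const double eps = 1e-9;
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < ncell; ++i) {
      double p = clsp(i, c);
      double t = (assign[i] >= 0 && gtcls[assign[i]] == c) ? tscore[i] : 0.0;
      cls_loss += -(t * std::log(p + eps) + (1 - t) * std::log(1 - p + eps));
      g_cls(i, c) = (p - t) / norm * w_cls;
    }
  }
  cls_loss /= norm;
  // --- box (CIoU) and DFL terms ------------------------------------------
  NumericMatrix g_box(ncell, 4 * reg_max);
  double box_loss = 0, dfl_loss = 0;
  const double pi2 = M_PI * M_PI;
  for (int i = 0; i < ncell; ++i) {
    if (assign[i] < 0) continue;
    int j = assign[i];
    double w = tscore[i] / norm;
    double p1 = bx[4 * (size_t)i], q1 = bx[4 * (size_t)i + 1];
    double p2 = bx[4 * (size_t)i + 2], q2 = bx[4 * (size_t)i + 3];
    double t1 = gtb(j, 0), u1 = gtb(j, 1), t2 = gtb(j, 2), u2 = gtb(j, 3);
    double pw = p2 - p1, ph = q2 - q1, tw = t2 - t1, th = u2 - u1;
    double ix1 = std::max(p1, t1), iy1 = std::max(q1, u1);
    double ix2 = std::min(p2, t2), iy2 = std::min(q2, u2);
    double iw = std::max(ix2 - ix1, 0.0), ih = std::max(iy2 - iy1, 0.0);
    double inter = iw * ih;
    double uni = pw * ph + tw * th - inter;
    double iou = inter / (uni + eps);
    double cx1 = std::min(p1, t1), cy1 = std::min(q1, u1);
    double cx2 = std::max(p2, t2), cy2 = std::max(q2, u2);
    double cw = cx2 - cx1, ch = cy2 - cy1;
    double c2 = cw * cw + ch * ch + eps;
    double dx = (p1 + p2 - t1 - t2) / 2, dy = (q1 + q2 - u1 - u2) / 2;
    double rho2 = dx * dx + dy * dy;
    double ph_s = std::max(ph, eps), th_s = std::max(th, eps);
    double dat = std::atan(tw / th_s) - std::atan(pw / ph_s);
    double v = 4.0 / pi2 * dat * dat;
    double al = v / (1 - iou + v + eps);
    double ciou = iou - rho2 / c2 - al * v;
    box_loss += (1 - ciou) * w;
    // gradient of ciou w.r.t. (p1,q1,p2,q2)
    bool pos = iw > 0 && ih > 0;
    double di_dx1 = (pos && p1 > t1) ? -ih : 0.0;
    double di_dy1 = (pos && q1 > u1) ? -iw : 0.0;
    double di_dx2 = (pos && p2 < t2) ? ih : 0.0;
    double di_dy2 = (pos && q2 < u2) ? iw : 0.0;
    double da_dx1 = -ph, da_dy1 = -pw, da_dx2 = ph, da_dy2 = pw;
    double ue = uni + eps;
    double gi_x1 = (di_dx1 * ue - inter * (da_dx1 - di_dx1)) / (ue * ue);
    double gi_y1 = (di_dy1 * ue - inter * (da_dy1 - di_dy1)) / (ue * ue);
    double gi_x2 = (di_dx2 * ue - inter * (da_dx2 - di_dx2)) / (ue * ue);
    double gi_y2 = (di_dy2 * ue - inter * (da_dy2 - di_dy2)) / (ue * ue);
    double dcw_dx1 = p1 < t1 ? -1.0 : 0.0, dcw_dx2 = p2 > t2 ? 1.0 : 0.0;
    double dch_dy1 = q1 < u1 ? -1.0 : 0.0, dch_dy2 = q2 > u2 ? 1.0 : 0.0;
    double gp_x1 = (dx * c2 - rho2 * 2 * cw * dcw_dx1) / (c2 * c2);
    double gp_y1 = (dy * c2 - rho2 * 2 * ch * dch_dy1) / (c2 * c2);
    double gp_x2 = (dx * c2 - rho2 * 2 * cw * dcw_dx2) / (c2 * c2);
    double gp_y2 = (dy * c2 - rho2 * 2 * ch * dch_dy2) / (c2 * c2);
    double datan = -1.0 / (1 + (pw / ph_s) * (pw / ph_s));
    double dv_dw = 8.0 / pi2 * dat * datan / ph_s;
    double dv_dh = 8.0 / pi2 * dat * datan * (-pw / (ph_s * ph_s));
    double gv_x1 = al * dv_dw, gv_x2 = -al * dv_dw;
    double gv_y1 = al * dv_dh, gv_y2 = -al * dv_dh;
    double gc[4] = { gi_x1 - gp_x1 + gv_x1, gi_y1 - gp_y1 + gv_y1,
                     gi_x2 - gp_x2 + gv_x2, gi_y2 - gp_y2 + gv_y2 };
    // chain to side distances (stride units), then to bin logits
    double sN = stride[i] / input;
    double gdist[4] = { -(-gc[0] * sN) * w * w_box, -(-gc[1] * sN) * w * w_box,
                        -(gc[2] * sN) * w * w_box, -(gc[3] * sN) * w * w_box };
    // dfl target distances
    double td[4] = {
      (cx[i] / input - t1) * input / stride[i],
      (cy[i] / input - u1) * input / stride[i],
      (t2 - cx[i] / input) * input / stride[i],
      (u2 - cy[i] / input) * input / stride[i] };
    for (int sd = 0; sd < 4; ++sd) {
      double t = std::min(std::max(td[sd], 0.0), reg_max - 1 - 1e-3);
      int lo = (int)std::floor(t);
      int hi = lo + 1;
      double wh = t - lo, wl = 1 - wh;
      double pl = prob(i, sd * reg_max + lo), phh = prob(i, sd * reg_max + hi);
      dfl_loss += -(wl * std::log(pl + eps) + wh * std::log(phh + eps)) * w;
      double d = dist(i, sd);
      for (int b = 0; b < reg_max; ++b) {
        double pb = prob(i, sd * reg_max + b);
        double y = (b == lo ? wl : 0.0) + (b == hi ? wh : 0.0);
        double gz = (pb - y) * w * w_dfl            // dfl softmax CE
          + pb * (b - d) * gdist[sd];               // box term via expectation
        g_box(i, sd * reg_max + b) += gz;
      }
    }
  }
  double total = w_box * box_loss + w_dfl * dfl_loss + w_cls * cls_loss;
  return List::create(_["total"] = total, _["box"] = box_loss,
                      _["dfl"] = dfl_loss, _["cls"] = cls_loss,
                      _["g_cls"] = g_cls, _["g_box"] = g_box,
                      _["n_fg"] = nfg);
}

// Batch driver: gathers per-image cell matrices from per-level maps, runs
// the per-image loss, and scatters gradients back into per-level arrays.
// clsp/prob/dist: lists of (H,W,C,N) arrays per level; cx/cy/stride:
// precomputed per-cell vectors over the flattened level order; targets:
// list per image of list(gtb = m x 4 xyxy matrix, cls = integer vector).
// [[Rcpp::export]]
List cpp_det_loss_batch(List clspL, List probL, List distL,
                        NumericVector cx, NumericVector cy,
                        NumericVector stride, List targets, int topk,
                        double alpha, double beta, int reg_max, double input,
                        double w_box, double w_dfl, double w_cls) {
  const int L = clspL.size();
  std::vector<NumericVector> clspA(L), probA(L), distA(L);
  std::vector<int> hw(L);
  int nc = 0, N = 0, ncell = 0, regc = 0;
  for (int l = 0; l < L; ++l) {
    clspA[l] = as<NumericVector>(clspL[l]);
    probA[l] = as<NumericVector>(probL[l]);
    distA[l] = as<NumericVector>(distL[l]);
    IntegerVector d = clspA[l].attr("dim");
    hw[l] = d[0] * d[1];
    nc = d[2]; N = d[3];
    IntegerVector db = probA[l].attr("dim");
    regc = db[2];
    ncell += hw[l];
  }
  List gClsOut(L), gBoxOut(L);
  std::vector<double*> gClsP(L), gBoxP(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector d = clspA[l].attr("dim");
    NumericVector gc((R_xlen_t)hw[l] * nc * N);
    gc.attr("dim") = d;
    gClsOut[l] = gc;
    gClsP[l] = REAL(gc);
    IntegerVector db = probA[l].attr("dim");
    NumericVector gb((R_xlen_t)hw[l] * regc * N);
    gb.attr("dim") = db;
    gBoxOut[l] = gb;
    gBoxP[l] = REAL(gb);
  }
  NumericMatrix clsp(ncell, nc), prob(ncell, regc), dist(ncell, 4);
  double total = 0, box = 0, dfl = 0, cls = 0;
  for (int n = 0; n < N; ++n) {
    // gather
    int row0 = 0;
    for (int l = 0; l < L; ++l) {
      const double* cp = REAL(clspA[l]) + (size_t)n * hw[l] * nc;
      for (int c = 0; c < nc; ++c)
        std::copy(cp + (size_t)c * hw[l], cp + (size_t)(c + 1) * hw[l],
                  &clsp(row0, c));
      const double* pp = REAL(probA[l]) + (size_t)n * hw[l] * regc;
      for (int c = 0; c < regc; ++c)
        std::copy(pp + (size_t)c * hw[l], pp + (size_t)(c + 1) * hw[l],
                  &prob(row0, c));
      const double* dp = REAL(distA[l]) + (size_t)n * hw[l] * 4;
      for (int c = 0; c < 4; ++c)
        std::copy(dp + (size_t)c * hw[l], dp + (size_t)(c + 1) * hw[l],
                  &dist(row0, c));
      row0 += hw[l];
    }
    List tg = targets[n];
    NumericMatrix gtb = as<NumericMatrix>(tg["gtb"]);
    IntegerVector gtc = as<IntegerVector>(tg["cls"]);
    List r = cpp_det_loss_image(clsp, prob, dist, cx, cy, stride, gtb, gtc,
                                topk, alpha, beta, reg_max, input,
                                w_box, w_dfl, w_cls);
    total += as<double>(r["total"]);
    box += as<double>(r["box"]);
    dfl += as<double>(r["dfl"]);
    cls += as<double>(r["cls"]);
    NumericMatrix gc = r["g_cls"], gb = r["g_box"];
    row0 = 0;
    for (int l = 0; l < L; ++l) {
      double* dst = gClsP[l] + (size_t)n * hw[l] * nc;
      for (int c = 0; c < nc; ++c)
        std::copy(&gc(row0, c), &gc(row0, c) + hw[l], dst + (size_t)c * hw[l]);
      double* db = gBoxP[l] + (size_t)n * hw[l] * regc;
      for (int c = 0; c < regc; ++c)
        std::copy(&gb(row0, c), &gb(row0, c) + hw[l], db + (size_t)c * hw[l]);
      row0 += hw[l];
    }
  }
  return List::create(_["total"] = total / N, _["box"] = box / N,
                      _["dfl"] = dfl / N, _["cls"] = cls / N,
                      _["g_cls"] = gClsOut, _["g_box"] = gBoxOut);
}
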