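#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level matrices for 2-D images. Conventions (fixed across the package):
//  - levels are integers in 1..ng, NA marks pixels outside the validity mask;
//  - invalid pixels never pair with valid ones: they break runs, zones,
//    co-occurrence pairs and dependence neighbourhoods;
//  - GLCM: distance 1, four directions (0, 45, 90, 135 degrees), symmetrised,
//    counts summed over directions;
//  - GLRLM: maximal runs per direction, counts summed over the 4 directions;
//  - GLSZM: 8-connected zones of equal level;
//  - GLDM: dependence column j = (number of equal-valued 8-neighbours) + 1,
//    so an isolated pixel has dependence 1 and formulas stay zero-safe.

static inline bool valid_at(const int *lv, int nr, int nc, int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
  return lv[r + (size_t)nr * c] != NA_INTEGER;
}
static inline int level_at(const int *lv, int nr, int r, int c) {
  return lv[r + (size_t)nr * c];
}

static void glcm_fill(const int *lv, int nr, int nc, int ng, double *out) {
  // out is ng x ng, column-major
  const int dr[4] = {0, -1, -1, -1};
  const int dc[4] = {1, 1, 0, -1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid_at(lv, nr, nc, r, c)) continue;
      int a = level_at(lv, nr, r, c);
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (!valid_at(lv, nr, nc, r2, c2)) continue;
        int b = level_at(lv, nr, r2, c2);
        out[(a - 1) + (size_t)ng * (b - 1)] += 1.0;
        out[(b - 1) + (size_t)ng * (a - 1)] += 1.0;
      }
    }
  }
}

static void glrlm_fill(const int *lv, int nr, int nc, int ng, int maxlen,
                       double *out) {
  // out is ng x maxlen; scan maximal runs along 4 directions
  const int dr[4] = {0, 1, 1, 1};
  const int dc[4] = {1, 0, 1, -1};
  for (int d = 0; d < 4; ++d) {
    // start points: cells with no valid same-direction predecessor of any kind
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        int rp = r - dr[d], cp = c - dc[d];
        bool is_start = !(rp >= 0 && rp < nr && cp >= 0 && cp < nc);
        if (is_start) {
          // walk the full scan line from this boundary cell
          int rr = r, cc = c;
          int cur = NA_INTEGER, len = 0;
          while (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
            bool v = valid_at(lv, nr, nc, rr, cc);
            int g = v ? level_at(lv, nr, rr, cc) : NA_INTEGER;
            if (v && g == cur) {
              ++len;
            } else {
              if (cur != NA_INTEGER && len > 0)
                out[(cur - 1) + (size_t)ng * (len - 1)] += 1.0;
              cur = g;
              len = v ? 1 : 0;
            }
            rr += dr[d];
            cc += dc[d];
          }
          if (cur != NA_INTEGER && len > 0)
            out[(cur - 1) + (size_t)ng * (len - 1)] += 1.0;
        }
      }
    }
  }
  (void)maxlen;
}

static void glszm_zones(const int *lv, int nr, int nc,
                        std::vector<std::pair<int, int> > &zones) {
  // zones: (level, size) via 8-connected flood fill
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      size_t idx = r + (size_t)nr * c;
      if (seen[idx] || !valid_at(lv, nr, nc, r, c)) continue;
      int g = level_at(lv, nr, r, c);
      int size = 0;
      stack.clear();
      stack.push_back((int)idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int rr = cur % nr, cc = cur / nr;
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          for (int dc2 = -1; dc2 <= 1; ++dc2) {
            if (dr2 == 0 && dc2 == 0) continue;
            int r2 = rr + dr2, c2 = cc + dc2;
            if (!valid_at(lv, nr, nc, r2, c2)) continue;
            size_t i2 = r2 + (size_t)nr * c2;
            if (seen[i2]) continue;
            if (level_at(lv, nr, r2, c2) == g) {
              seen[i2] = 1;
              stack.push_back((int)i2);
            }
          }
        }
      }
      zones.push_back(std::make_pair(g, size));
    }
  }
}

static void gldm_fill(const int *lv, int nr, int nc, int ng, double *out) {
  // out is ng x 9 (dependence j = equal 8-neighbours + 1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid_at(lv, nr, nc, r, c)) continue;
      int g = level_at(lv, nr, r, c);
      int dep = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (valid_at(lv, nr, nc, r + dr, c + dc) &&
              level_at(lv, nr, r + dr, c + dc) == g)
            ++dep;
        }
      out[(g - 1) + (size_t)ng * dep] += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".cpp_glcm")]]
NumericMatrix cpp_glcm(IntegerMatrix lv, int ng) {
  NumericMatrix out(ng, ng);
  glcm_fill(lv.begin(), lv.nrow(), lv.ncol(), ng, out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericMatrix cpp_glrlm(IntegerMatrix lv, int ng) {
  int maxlen = std::max(lv.nrow(), lv.ncol());
  if (maxlen < 1) maxlen = 1;
  NumericMatrix out(ng, maxlen);
  glrlm_fill(lv.begin(), lv.nrow(), lv.ncol(), ng, maxlen, out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_glszm")]]
NumericMatrix cpp_glszm(IntegerMatrix lv, int ng) {
  std::vector<std::pair<int, int> > zones;
  glszm_zones(lv.begin(), lv.nrow(), lv.ncol(), zones);
  int maxsize = 1;
  for (size_t i = 0; i < zones.size(); ++i)
    if (zones[i].second > maxsize) maxsize = zones[i].second;
  NumericMatrix out(ng, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return out;
}

// [[Rcpp::export(name = ".cpp_gldm")]]
NumericMatrix cpp_gldm(IntegerMatrix lv, int ng) {
  NumericMatrix out(ng, 9);
  gldm_fill(lv.begin(), lv.nrow(), lv.ncol(), ng, out.begin());
  return out;
}

// All four matrices of every full win x win valid patch, one patch per row.
// family: 1 = glcm (K = ng*ng), 2 = glrlm (K = ng*win),
//         3 = glszm (K = ng*win*win), 4 = gldm (K = ng*9).
// Count layout within a row is column-major of the ng x maxj matrix, so
// row k of the result reshapes back with matrix(row, ng, maxj).
// [[Rcpp::export(name = ".cpp_patch_matrices")]]
List cpp_patch_matrices(IntegerMatrix lv, int ng, int family, int win) {
  int nr = lv.nrow(), nc = lv.ncol();
  int half = win / 2;
  std::vector<int> centers_r, centers_c;
  for (int c = half; c < nc - half; ++c) {
    for (int r = half; r < nr - half; ++r) {
      bool full = true;
      for (int dc = -half; dc <= half && full; ++dc)
        for (int dr = -half; dr <= half; ++dr)
          if (lv(r + dr, c + dc) == NA_INTEGER) {
            full = false;
            break;
          }
      if (full) {
        centers_r.push_back(r + 1);
        centers_c.push_back(c + 1);
      }
    }
  }
  int npatch = (int)centers_r.size();
  int maxj;
  switch (family) {
    case 1: maxj = ng; break;
    case 2: maxj = win; break;
    case 3: maxj = win * win; break;
    case 4: maxj = 9; break;
    default: stop("unknown family code");
  }
  size_t K = (size_t)ng * maxj;
  NumericMatrix counts(npatch, (int)K);
  std::vector<int> patch((size_t)win * win);
  std::vector<double> buf(K);
  std::vector<std::pair<int, int> > zones;
  for (int p = 0; p < npatch; ++p) {
    int r0 = centers_r[p] - 1 - half, c0 = centers_c[p] - 1 - half;
    for (int dc = 0; dc < win; ++dc)
      for (int dr = 0; dr < win; ++dr)
        patch[dr + (size_t)win * dc] = lv(r0 + dr, c0 + dc);
    std::fill(buf.begin(), buf.end(), 0.0);
    if (family == 1) {
      glcm_fill(&patch[0], win, win, ng, &buf[0]);
    } else if (family == 2) {
      glrlm_fill(&patch[0], win, win, ng, win, &buf[0]);
    } else if (family == 3) {
      zones.clear();
      glszm_zones(&patch[0], win, win, zones);
      for (size_t z = 0; z < zones.size(); ++z)
        buf[(zones[z].first - 1) + (size_t)ng * (zones[z].second - 1)] += 1.0;
    } else {
      gldm_fill(&patch[0], win, win, ng, &buf[0]);
    }
    for (size_t k = 0; k < K; ++k) counts(p, (int)k) = buf[k];
  }
  return List::create(_["counts"] = counts,
                      _["center_row"] = wrap(centers_r),
                      _["center_col"] = wrap(centers_c),
                      _["ng"] = ng, _["maxj"] = maxj,
                      _["n_valid"] = win * win);
}
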