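// Particle-based reaction-diffusion engine for protein self-assembly on
// liposomes: Brownian point particles in a 3D box with reflective walls,
// binding-radius bimolecular encounters (particles have no volume), and
// per-vesicle oligomer growth with stabilization of even-sized complexes.
//
// Species: soluble activator (cBid), soluble monomer (Bax), vesicles (LUVs)
// each carrying a count of bound activators and a single resident complex.
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline double reflect(double v, double L) {
  // reflective walls; handles multiple folds for large steps
  while (v < 0.0 || v > L) {
    if (v < 0.0) v = -v;
    if (v > L) v = 2.0 * L - v;
  }
  return v;
}

struct CellList {
  double cell;
  int nc;                    // cells per side
  std::vector<int> head;     // nc^3
  std::vector<int> nxt;      // per LUV
  double L;

  void init(double box, double cell_size, int n_items) {
    L = box;
    nc = std::max(1, (int)std::floor(box / cell_size));
    cell = box / nc;
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(n_items, -1);
  }
  inline int cidx(double v) const {
    int i = (int)std::floor(v / cell);
    if (i < 0) i = 0;
    if (i >= nc) i = nc - 1;
    return i;
  }
  inline int index(const Vec3 &p) const {
    return (cidx(p.x) * nc + cidx(p.y)) * nc + cidx(p.z);
  }
  void build(const std::vector<Vec3> &pos) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < (int)pos.size(); ++i) {
      int c = index(pos[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  // nearest item within radius r of p, or -1
  int nearest_within(const Vec3 &p, double r,
                     const std::vector<Vec3> &pos) const {
    double r2 = r * r, best = r2;
    int bi = -1;
    int cx = cidx(p.x), cy = cidx(p.y), cz = cidx(p.z);
    int reach = std::max(1, (int)std::ceil(r / cell));
    for (int dx = -reach; dx <= reach; ++dx) {
      int ix = cx + dx; if (ix < 0 || ix >= nc) continue;
      for (int dy = -reach; dy <= reach; ++dy) {
        int iy = cy + dy; if (iy < 0 || iy >= nc) continue;
        for (int dz = -reach; dz <= reach; ++dz) {
          int iz = cz + dz; if (iz < 0 || iz >= nc) continue;
          for (int j = head[(ix * nc + iy) * nc + iz]; j >= 0; j = nxt[j]) {
            double ddx = pos[j].x - p.x, ddy = pos[j].y - p.y,
                   ddz = pos[j].z - p.z;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= best) { best = d2; bi = j; }
          }
        }
      }
    }
    return bi;
  }
};

inline Vec3 random_point(double L) {
  Vec3 p;
  p.x = unif_rand() * L; p.y = unif_rand() * L; p.z = unif_rand() * L;
  return p;
}

// point at given distance from c in a uniformly random direction, reflected
inline Vec3 offset_point(const Vec3 &c, double dist, double L) {
  double u = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - u * u));
  Vec3 p;
  p.x = reflect(c.x + dist * s * std::cos(phi), L);
  p.y = reflect(c.y + dist * s * std::sin(phi), L);
  p.z = reflect(c.z + dist * u, L);
  return p;
}

inline void diffuse(std::vector<Vec3> &pos, double sd, double L) {
  if (sd <= 0.0) return;
  for (auto &p : pos) {
    p.x = reflect(p.x + sd * norm_rand(), L);
    p.y = reflect(p.y + sd * norm_rand(), L);
    p.z = reflect(p.z + sd * norm_rand(), L);
  }
}

} // namespace

// [[Rcpp::export(name = ".assembly_engine")]]
List assembly_engine(double box, int n_bax, int n_cbid, int n_luv,
                     double dt, double duration, double sample_dt,
                     double D_bax, double D_cbid, double D_luv,
                     double r_cbid_on, double r_bax_on_cbid,
                     double r_bax_on_bax,
                     double k_cbid_off, double k_mono_off, double k_shrink,
                     double even_stab, int cap) {
  if (n_luv < 1) stop("need at least one vesicle");
  RNGScope rng;

  std::vector<Vec3> bax, cbid, luv;
  bax.reserve(n_bax + 16); cbid.reserve(n_cbid + 16);
  for (int i = 0; i < n_bax; ++i) bax.push_back(random_point(box));
  for (int i = 0; i < n_cbid; ++i) cbid.push_back(random_point(box));
  luv.resize(n_luv);
  for (int i = 0; i < n_luv; ++i) luv[i] = random_point(box);
  std::vector<int> bound_cbid(n_luv, 0), csize(n_luv, 0);

  const double sd_bax = std::sqrt(2.0 * D_bax * dt);
  const double sd_cbid = std::sqrt(2.0 * D_cbid * dt);
  const double sd_luv = std::sqrt(2.0 * D_luv * dt);

  const double p_cbid_off = (k_cbid_off > 0) ? 1.0 - std::exp(-k_cbid_off * dt) : 0.0;
  const double p_mono_off = (k_mono_off > 0) ? 1.0 - std::exp(-k_mono_off * dt) : 0.0;
  const double p_shrink   = (k_shrink > 0) ? 1.0 - std::exp(-k_shrink * dt) : 0.0;
  const double p_shrink_even = (k_shrink > 0)
      ? 1.0 - std::exp(-k_shrink / even_stab * dt) : 0.0;
  const double p_join_odd_target = 1.0 / even_stab;  // growth into odd size

  double r_max = std::max(r_cbid_on, std::max(r_bax_on_cbid, r_bax_on_bax));
  double cell_size = std::max(r_max, box / 48.0);
  CellList cl;
  cl.init(box, cell_size, n_luv);

  const long n_steps = (long)std::llround(duration / dt);
  const long sample_every = std::max(1L, (long)std::llround(sample_dt / dt));
  const int n_samples = (int)(n_steps / sample_every) + 1;

  NumericVector s_time(n_samples);
  IntegerVector s_bax(n_samples), s_cbid(n_samples), s_occ(n_samples);
  IntegerMatrix s_hist(n_samples, cap);
  long capped_events = 0;

  int si = 0;
  auto record = [&](long step) {
    s_time[si] = step * dt;
    s_bax[si] = (int)bax.size();
    s_cbid[si] = (int)cbid.size();
    int occ = 0, total_bound = 0;
    for (int i = 0; i < n_luv; ++i) {
      if (csize[i] > 0) { ++occ; s_hist(si, csize[i] - 1)++; }
      total_bound += csize[i];
    }
    s_occ[si] = occ;
    if ((int)bax.size() + total_bound != n_bax)
      stop("mass conservation violated");  // internal consistency check
    ++si;
  };
  record(0);

  const double unbind_dist_cbid = 1.5 * std::max(r_cbid_on, 1e-6);
  const double unbind_dist_bax =
      1.5 * std::max(std::max(r_bax_on_cbid, r_bax_on_bax), 1e-6);

  for (long step = 1; step <= n_steps; ++step) {
    diffuse(bax, sd_bax, box);
    diffuse(cbid, sd_cbid, box);
    diffuse(luv, sd_luv, box);
    cl.build(luv);

    // cBid binding
    if (r_cbid_on > 0.0) {
      for (int i = (int)cbid.size() - 1; i >= 0; --i) {
        int j = cl.nearest_within(cbid[i], r_cbid_on, luv);
        if (j >= 0) {
          bound_cbid[j]++;
          cbid[i] = cbid.back();
          cbid.pop_back();
        }
      }
    }

    // Bax binding / complex growth
    for (int i = (int)bax.size() - 1; i >= 0; --i) {
      double r_look = r_max;
      int j = cl.nearest_within(bax[i], r_look, luv);
      if (j < 0) continue;
      double dx = luv[j].x - bax[i].x, dy = luv[j].y - bax[i].y,
             dz = luv[j].z - bax[i].z;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      bool via_cbid = (r_bax_on_cbid > 0.0) && bound_cbid[j] > 0 &&
                      d <= r_bax_on_cbid;
      bool via_bax = (r_bax_on_bax > 0.0) && csize[j] > 0 &&
                     d <= r_bax_on_bax;
      if (!via_cbid && !via_bax) continue;
      if (csize[j] >= cap) { ++capped_events; continue; }
      int new_size = csize[j] + 1;
      double p_acc = (new_size % 2 == 0) ? 1.0 : p_join_odd_target;
      if (p_acc >= 1.0 || unif_rand() < p_acc) {
        csize[j] = new_size;
        bax[i] = bax.back();
        bax.pop_back();
      }
    }

    // first-order events on vesicles
    for (int j = 0; j < n_luv; ++j) {
      if (bound_cbid[j] > 0 && p_cbid_off > 0.0) {
        int n_off = (int)R::rbinom((double)bound_cbid[j], p_cbid_off);
        for (int k = 0; k < n_off; ++k)
          cbid.push_back(offset_point(luv[j], unbind_dist_cbid, box));
        bound_cbid[j] -= n_off;
      }
      if (csize[j] == 1) {
        if (p_mono_off > 0.0 && unif_rand() < p_mono_off) {
          csize[j] = 0;
          bax.push_back(offset_point(luv[j], unbind_dist_bax, box));
        }
      } else if (csize[j] >= 2) {
        double p = (csize[j] % 2 == 0) ? p_shrink_even : p_shrink;
        if (p > 0.0 && unif_rand() < p) {
          csize[j]--;
          bax.push_back(offset_point(luv[j], unbind_dist_bax, box));
        }
      }
    }

    if (step % sample_every == 0 && si < n_samples) record(step);
  }

  return List::create(_["time"] = s_time, _["soluble_bax"] = s_bax,
                      _["soluble_cbid"] = s_cbid, _["occupied_luvs"] = s_occ,
                      _["size_hist"] = s_hist,
                      _["capped_events"] = (double)capped_events);
}
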