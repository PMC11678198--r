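#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Explicitly seeded xoshiro256++ generator: fast, and a given seed yields the
// same photon histories on every platform, independent of R's RNG state.
struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        // splitmix64 expansion of the scalar seed into the state
        uint64_t x = seed;
        for (int i = 0; i < 4; i++) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t v, int k) {
        return (v << k) | (v >> (64 - k));
    }
    inline uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }
    // uniform on (0, 1): never returns 0, safe for log()
    inline double u01() {
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
};

// Unpolarized Fresnel reflectance for a ray going from index ni into nt with
// incidence cosine ci (> 0). Returns 1 beyond the critical angle.
static inline double fresnel_r(double ni, double nt, double ci, double *ct_out) {
    if (ni == nt) { *ct_out = ci; return 0.0; }
    double si2 = 1.0 - ci * ci;
    double st2 = (ni / nt) * (ni / nt) * si2;
    if (st2 >= 1.0) { *ct_out = 0.0; return 1.0; } // total internal reflection
    double ct = std::sqrt(1.0 - st2);
    double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
    double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
    *ct_out = ct;
    return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein polar-cosine sampling (closed-form inverse CDF).
static inline double hg_cos(double g, double u) {
    if (g == 0.0) return 2.0 * u - 1.0;
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    return ct;
}

struct Kahan {
    double s, c;
    Kahan() : s(0.0), c(0.0) {}
    inline void add(double x) {
        double y = x - c;
        double t = s + y;
        c = (t - s) - y;
        s = t;
    }
};

// Photon-packet Monte Carlo for a homogeneous plane-parallel slab.
// z = 0 is the illuminated face, z = d the exit face. Specular reflection at
// the first interface is tallied into R. Packets leaving a face at radial
// distance > port_radius from the beam axis, or wandering laterally beyond
// lateral_max, count as port losses (L). Boundary reflection is handled
// statistically (full packet weight reflects or transmits), so a packet's
// weight changes only through the single-scattering albedo and roulette;
// every weight transfer is computed by subtraction, which keeps
// R + T + A + L equal to the launched weight to rounding error.
// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double mua, double mus, double g, double n_sample, double d,
                 double n_ambient, double inc_deg, double beam_radius,
                 double port_radius, double lateral_max, int n_photons,
                 double w_threshold, double survival_p, double seed) {
    Xoshiro rng((uint64_t) seed);
    const double mut = mua + mus;
    const double albedo = (mut > 0.0) ? mus / mut : 0.0;
    const double si = std::sin(inc_deg * M_PI / 180.0);
    const double ci = std::cos(inc_deg * M_PI / 180.0);
    const double port2 = port_radius * port_radius;
    const double lat2 = lateral_max * lateral_max;

    Kahan accR, accT, accA, accL;
    Kahan accR2, accT2; // sums of squared per-photon contributions

    for (int ip = 0; ip < n_photons; ip++) {
        // launch on a uniform disk, direction tilted in the x-z plane
        double rr = beam_radius * std::sqrt(rng.u01());
        double phi0 = 2.0 * M_PI * rng.u01();
        double x = rr * std::cos(phi0), y = rr * std::sin(phi0), z = 0.0;

        double pr = 0.0, pt = 0.0, pa = 0.0, pl = 0.0; // per-photon tallies
        double w = 1.0;

        // entry interface
        double ct;
        double rf = fresnel_r(n_ambient, n_sample, ci, &ct);
        if (rng.u01() < rf) {
            pr = w; // specular lobe collected by the sphere
            accR.add(pr); accR2.add(pr * pr);
            continue;
        }
        double st = (n_ambient / n_sample) * si;
        double ux = st, uy = 0.0, uz = ct;

        bool alive = true;
        while (alive) {
            // geometric step from the sampled optical path
            double s = (mut > 0.0) ? -std::log(rng.u01()) / mut : R_PosInf;

            // walk to the interaction point, crossing faces as needed
            for (;;) {
                double db = R_PosInf;
                if (uz > 0.0) db = (d - z) / uz;
                else if (uz < 0.0) db = -z / uz;
                if (db > s) { // interaction inside the slab
                    x += s * ux; y += s * uy; z += s * uz;
                    break;
                }
                // move to the face
                x += db * ux; y += db * uy;
                z = (uz > 0.0) ? d : 0.0;
                s -= db;
                if (x * x + y * y > lat2) { pl = w; alive = false; break; }
                double cb = std::fabs(uz);
                double ctt;
                double rb = fresnel_r(n_sample, n_ambient, cb, &ctt);
                if (rng.u01() < rb) {
                    uz = -uz; // internal reflection, continue the step
                } else {
                    if (x * x + y * y <= port2) {
                        if (uz < 0.0) pr = w; else pt = w;
                    } else {
                        pl = w; // escaped outside the sphere port
                    }
                    alive = false;
                    break;
                }
            }
            if (!alive) break;
            if (x * x + y * y > lat2) { pl = w; break; }

            // absorb by weight attenuation (difference form is exact)
            double w_new = w * albedo;
            pa += w - w_new;
            w = w_new;
            if (w <= 0.0) break;

            // scatter: Henyey-Greenstein polar angle, uniform azimuth
            double cth = hg_cos(g, rng.u01());
            double sth = std::sqrt(1.0 - cth * cth);
            double psi = 2.0 * M_PI * rng.u01();
            double cpsi = std::cos(psi), spsi = std::sin(psi);
            if (std::fabs(uz) > 0.99999) {
                ux = sth * cpsi;
                uy = sth * spsi;
                uz = (uz >= 0.0) ? cth : -cth;
            } else {
                double den = std::sqrt(1.0 - uz * uz);
                double uxn = sth * (ux * uz * cpsi - uy * spsi) / den + ux * cth;
                double uyn = sth * (uy * uz * cpsi + ux * spsi) / den + uy * cth;
                double uzn = -sth * cpsi * den + uz * cth;
                ux = uxn; uy = uyn; uz = uzn;
            }

            // Russian roulette; the weight defect is booked against A so the
            // per-run tally still sums to the launched weight
            if (w < w_threshold) {
                if (rng.u01() < survival_p) {
                    double w_boost = w / survival_p;
                    pa -= w_boost - w;
                    w = w_boost;
                } else {
                    pa += w;
                    break;
                }
            }
        }
        accR.add(pr); accT.add(pt); accA.add(pa); accL.add(pl);
        accR2.add(pr * pr); accT2.add(pt * pt);
    }

    const double n = (double) n_photons;
    double R = accR.s / n, T = accT.s / n, A = accA.s / n, L = accL.s / n;
    double varR = accR2.s / n - R * R;
    double varT = accT2.s / n - T * T;
    if (varR < 0.0) varR = 0.0;
    if (varT < 0.0) varT = 0.0;
    return List::create(
        _["R_total"] = R, _["T_total"] = T, _["A_total"] = A,
        _["L_lateral"] = L,
        _["se_R"] = std::sqrt(varR / n), _["se_T"] = std::sqrt(varT / n));
}
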